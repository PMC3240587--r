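# Time courses, conservation audits, oscillation detection, excitability.

test_that("trajectories conserve the molecular totals to 1e-6 relative", {
  cfg <- mm_cfg()
  p <- default_p()
  for (init in list(init_high_bd(), init_high_b())) {
    tr <- simulate_timecourse(p, cfg, init, t_end = 3600, n_out = 201)
    drift <- attr(trajectory_conservation(tr), "max_rel_drift")
    expect_true(all(drift < 1e-6))
    expect_gt(min(as.matrix(tr[, species_names(cfg)])), -1e-10)
  }
})

test_that("the two printed initial conditions reach opposite branches", {
  cfg <- mm_cfg()
  p <- default_p()
  tr1 <- simulate_timecourse(p, cfg, init_high_bd(), t_end = 3600,
                             n_out = 101)
  tr2 <- simulate_timecourse(p, cfg, init_high_b(), t_end = 3600,
                             n_out = 101)
  end1 <- unlist(tr1[nrow(tr1), species_names(cfg)])
  end2 <- unlist(tr2[nrow(tr2), species_names(cfg)])
  # high initial ubiquitinated Bmi1 -> low Zub / high Rd state
  expect_lt(end1[["Zub"]], 0.01)
  # high initial free Bmi1 -> high Zub / low Rd state
  expect_gt(end2[["Zub"]], 0.05)
  expect_gt(end1[["Rd"]], end2[["Rd"]])
})

test_that("a stable steady state stays put for an hour", {
  cfg <- mm_cfg()
  p <- default_p()
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  rest <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  tr <- simulate_timecourse(p, cfg, rest, t_end = 3600, n_out = 51)
  dev <- max(abs(as.matrix(tr[, species_names(cfg)]) -
                   rep(rest, each = nrow(tr))))
  expect_lt(dev, 1e-6)
})

test_that("an injected sinusoid is detected with the right period", {
  cfg <- mm_cfg()
  period <- 700
  tt <- seq(0, 14000, by = 10)
  sp <- species_names(cfg)
  df <- data.frame(time = tt)
  for (s in sp) df[[s]] <- 0.2
  df$Zub <- 0.2 + 0.1 * sin(2 * pi * tt / period)
  df$Ra <- 0.2 + 0.05 * sin(2 * pi * (tt - 100) / period)
  traj <- structure(df, class = c("prc1_trajectory", "data.frame"),
                    config = cfg, params = default_p())
  rep <- detect_oscillations(traj, transient_fraction = 0.1)
  expect_true(rep$is_oscillatory)
  expect_lt(abs(rep$period - period), 10 + 1e-9)  # one sampling step
  # Ra lags Zub by 100 s = 1/7 of a period
  expect_lt(abs(rep$phase_lags["Ra", "Zub"] - 100 / period), 0.03)
})

test_that("constant and decaying trajectories are not oscillatory", {
  cfg <- mm_cfg()
  tt <- seq(0, 10000, by = 20)
  df <- data.frame(time = tt)
  for (s in species_names(cfg)) df[[s]] <- 0.3
  traj <- structure(df, class = c("prc1_trajectory", "data.frame"),
                    config = cfg, params = default_p())
  expect_error(detect_oscillations(traj), "insufficient")
  df$Zub <- 0.3 + 0.2 * exp(-tt / 1500) * sin(2 * pi * tt / 600)
  traj2 <- structure(df, class = c("prc1_trajectory", "data.frame"),
                     config = cfg, params = default_p())
  rep2 <- detect_oscillations(traj2, transient_fraction = 0.1)
  expect_false(rep2$is_oscillatory)
})

test_that("the excitable point shows an all-or-none Zub increment threshold", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  spec <- perturbation_spec("state_increment", "Zub", NA)
  thr <- excitability_threshold(p, cfg, spec, bracket = c(0.01, 0.02),
                                t_end = 30000, rel_tol = 1e-3)
  expect_gt(thr$threshold, 0.01)
  expect_lt(thr$threshold, 0.02)
  # all-or-none: over-class deviation dwarfs sub-class deviation
  expect_gt(thr$over_response / thr$sub_response, 5)
  # both classes return to the basal state afterwards (computed at the
  # perturbed conserved totals: a Zub increment adds material to both the
  # Bmi1 and Ring1B pools)
  rest <- thr$rest
  for (mag in thr$bracket) {
    r <- classify_response(p, cfg, rest,
                           perturbation_spec("state_increment", "Zub", mag),
                           t_end = 1e5)
    fin <- unlist(r$trajectory[nrow(r$trajectory), species_names(cfg)])
    p_pert <- set_parameters(p, Bmi1_tot = p[["Bmi1_tot"]] + mag,
                             R1B_tot = p[["R1B_tot"]] + mag)
    ss_pert <- find_steady_states(p_pert, cfg, n_starts = 20, seed = 1)
    rest_pert <- Filter(function(s) s$stability == "stable",
                        ss_pert)[[1]]$state
    expect_lt(max(abs(fin - rest_pert)), 1e-4)
  }
})

test_that("a zero-magnitude perturbation is always sub-threshold", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  rest <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  r <- classify_response(p, cfg, rest,
                         perturbation_spec("state_increment", "Zub", 0),
                         t_end = 5000)
  expect_false(r$over_threshold)
  expect_lt(r$peak_deviation, 1e-8)
})

test_that("bisected threshold agrees with a dense magnitude sweep", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  rest <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  spec <- perturbation_spec("state_increment", "Zub", NA)
  thr <- excitability_threshold(p, cfg, spec, bracket = c(0.01, 0.03),
                                t_end = 30000, rest = rest)
  mags <- seq(0.01, 0.03, length.out = 21)
  over <- vapply(mags, function(m) classify_response(
    p, cfg, rest, perturbation_spec("state_increment", "Zub", m),
    t_end = 30000)$over_threshold, logical(1))
  sweep_thr <- mags[which(over)[1]]
  expect_lt(abs(thr$threshold - sweep_thr), diff(mags)[1] + 1e-9)
})

test_that("an invalid bracket is rejected naming the response classes", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  spec <- perturbation_spec("state_increment", "Zub", NA)
  expect_error(
    excitability_threshold(p, cfg, spec, bracket = c(0.001, 0.005),
                           t_end = 20000),
    "sub-threshold")
})

test_that("monoubiquitinated H2A shows the same all-or-none dichotomy", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  rest <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  dev_hu <- function(mag) {
    r <- classify_response(p, cfg, rest,
                           perturbation_spec("state_increment", "Zub", mag),
                           t_end = 30000)
    max(abs(r$trajectory$Hu - rest[["Hu"]]))
  }
  expect_gt(dev_hu(0.025) / dev_hu(0.012), 5)
})

test_that("overshoot metrics report slow recovery after the excursion", {
  cfg <- mm_cfg()
  p <- default_p(USP7_tot = 2, Bmi1_tot = 3)
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  rest <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  r <- classify_response(p, cfg, rest,
                         perturbation_spec("state_increment", "Zub", 0.03),
                         t_end = 60000)
  m <- overshoot_metrics(r$trajectory, rest)
  rd <- m[m$species == "Rd", ]
  expect_true(rd$recovered)
  expect_gt(rd$recovery_time, rd$time_to_peak)
  # identically-at-baseline trajectory gives all-zero metrics
  flat <- r$trajectory
  for (s in species_names(cfg)) flat[[s]] <- rest[[s]]
  m0 <- overshoot_metrics(flat, rest)
  expect_true(all(m0$peak_deviation == 0))
})

test_that("oscillation period from the report is tolerance-robust", {
  # relaxation trajectory built from the model at a hand-made forced limit
  # cycle is out of scope; instead check detector output is insensitive to
  # sampling density on the synthetic signal
  cfg <- mm_cfg()
  for (dt in c(5, 10)) {
    tt <- seq(0, 12000, by = dt)
    df <- data.frame(time = tt)
    for (s in species_names(cfg)) df[[s]] <- 0.1
    df$Zub <- 0.1 + 0.05 * sin(2 * pi * tt / 900)
    traj <- structure(df, class = c("prc1_trajectory", "data.frame"),
                      config = cfg, params = default_p())
    rep <- detect_oscillations(traj, transient_fraction = 0.1)
    expect_lt(abs(rep$period - 900) / 900, 0.01)
  }
})
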