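# Long-timescale extension and Michaelis-Menten vs mass-action variants.

test_that("degradation rates follow the half-life definition", {
  p <- make_long_timescale(default_p(), half_life_free = 3 * 3600)
  expect_equal(p[["dRd"]], log(2) / 10800)
  expect_equal(p[["dBd"]], log(2) / 10800)
  expect_error(make_long_timescale(default_p(), half_life_free = -1),
               "positive")
})

test_that("synthesis balances degradation of the conserved totals", {
  cfg <- mm_cfg()
  p <- default_p()
  ss <- find_steady_states(p, cfg, n_starts = 25, seed = 1)
  ref <- Filter(function(s) s$stability == "stable", ss)[[1]]$state
  pl <- make_long_timescale(p, reference_state = ref)
  cfgl <- model_config(timescale = "long")
  d <- ode_rhs(ref, pl, cfgl)
  # at the reference state the protein totals are stationary (synthesis
  # flux equals degradation flux); the internal distribution re-balances
  expect_lt(abs(sum(d[c("B", "Bd", "Z", "Zub")])), 1e-10)
  expect_lt(abs(sum(d[c("R", "Rd", "Z", "Zub", "Ra", "Ru")])), 1e-10)
  expect_equal(pl[["sB"]], pl[["dBd"]] * ref[["Bd"]])
  expect_equal(pl[["sR"]], pl[["dRd"]] * ref[["Rd"]])
})

test_that("the long model matches the short model over the first hour", {
  cfg <- mm_cfg()
  p <- default_p()
  pl <- make_long_timescale(p)
  cfgl <- model_config(timescale = "long")
  init <- make_state(cfg, Bd = 2.5, R = 1, H = 1)
  tr_s <- simulate_timecourse(p, cfg, init, t_end = 3600, n_out = 121)
  tr_l <- simulate_timecourse(pl, cfgl, init, t_end = 3600, n_out = 121)
  for (sp in c("Zub", "Rd", "Ra"))
    expect_lt(max(abs(tr_s[[sp]] - tr_l[[sp]])), 5e-3)
})

test_that("far beyond ten hours the long model settles to a fixed point", {
  cfg <- mm_cfg()
  p <- default_p(Bmi1_tot = 3.25, USP7_tot = 2)
  pl <- make_long_timescale(p)
  cfgl <- model_config(timescale = "long")
  init <- make_state(cfg, Bd = 3.25, R = 1, H = 1)
  tr <- simulate_timecourse(pl, cfgl, init, t_end = 60 * 3600, n_out = 400)
  late <- tr[tr$time > 55 * 3600, "Zub"]
  expect_lt(max(late) - min(late), 1e-5)
  fin <- unlist(tr[nrow(tr), species_names(cfgl)])
  expect_lt(sqrt(sum(ode_rhs(fin, pl, cfgl)^2)), 1e-7)
})

test_that("complex-protected species make the complex pool outlive free protein", {
  # only Bd/Rd degrade: an all-complex state loses no material, an
  # all-degradable state decays at the configured rate
  cfgl <- model_config(timescale = "long")
  pl <- make_long_timescale(default_p())
  pl2 <- set_parameters(pl, sB = 0, sR = 0)
  s_complex <- make_state(cfgl, Z = 1)
  s_free <- make_state(cfgl, Bd = 1, Rd = 1)
  d1 <- ode_rhs(s_complex, pl2, cfgl)
  expect_equal(sum(d1[c("B", "Bd", "Z", "Zub")]), 0, tolerance = 1e-12)
  d2 <- ode_rhs(s_free, pl2, cfgl)
  expect_lt(sum(d2[c("B", "Bd", "Z", "Zub")]), 0)
})

test_that("mass action agrees with the MM reduction below saturation", {
  cfg <- mm_cfg()
  cfgm <- model_config("mass_action")
  p <- default_p()
  pm <- default_parameters("mass_action", "mm_limit")
  for (b in c(0.3, 0.5)) {
    s1 <- find_steady_states(set_parameters(p, Bmi1_tot = b), cfg,
                             n_starts = 20, seed = 1)
    s2 <- find_steady_states(set_parameters(pm, Bmi1_tot = b), cfgm,
                             n_starts = 20, seed = 1)
    expect_length(s2, length(s1))
    a <- s1[[1]]$state[1:10]
    bb <- s2[[1]]$state[1:10]
    big <- a > 1e-4
    expect_lt(max(abs(a - bb)[big] / a[big]), 0.05)
  }
})

test_that("mass action reproduces the MM steady-state multiplicity", {
  cfgm <- model_config("mass_action")
  pm <- default_parameters("mass_action", "mm_limit")
  s_bi <- find_steady_states(pm, cfgm, n_starts = 25, seed = 1)
  expect_length(s_bi, 3)   # three coexisting states at the bistable anchor
  s_mono <- find_steady_states(set_parameters(pm, Bmi1_tot = 1), cfgm,
                               n_starts = 20, seed = 1)
  expect_length(s_mono, 1)
  expect_equal(s_mono[[1]]$stability, "stable")
})

test_that("H2A is strictly downstream: core dynamics ignore H and Hu", {
  cfg <- mm_cfg()
  p <- default_p()
  s1 <- make_state(cfg, B = 1, R = 0.5, Z = 0.2, Zub = 0.1, H = 1)
  s2 <- s1; s2[["H"]] <- 0.2; s2[["Hu"]] <- 0.8
  d1 <- ode_rhs(s1, p, cfg)
  d2 <- ode_rhs(s2, p, cfg)
  core <- c("B", "Bd", "R", "Rd", "Z", "Zub", "Ra", "Ru")
  expect_equal(d1[core], d2[core], tolerance = 1e-14)
})
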