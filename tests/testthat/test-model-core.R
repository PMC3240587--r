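# Reaction rates, stoichiometry, conservation and unit handling.

test_that("all rates vanish for the empty system and are non-negative", {
  cfg <- mm_cfg()
  p <- default_p()
  r0 <- rate_vector(make_state(cfg), p, cfg)
  expect_true(all(r0 == 0))
  for (seed in 1:5) {
    s <- random_state(cfg, seed)
    expect_true(all(rate_vector(s, p, cfg) >= 0))
  }
})

test_that("saturable complex deubiquitination is half-maximal at KM7", {
  cfg <- mm_cfg()
  p <- default_p()
  s <- make_state(cfg, Zub = p[["KM7"]], B = 0.3, R = 0.2, H = 1)
  r <- rate_vector(s, p, cfg)
  expect_equal(r[["r7"]], p[["k7"]] * p[["USP7_tot"]] / 2)
})

test_that("rates and rhs match independent formula-by-formula evaluation", {
  cfg <- mm_cfg()
  p <- default_p()
  for (seed in 1:6) {
    s <- random_state(cfg, seed)
    r <- rate_vector(s, p, cfg)
    hr <- hand_rates_mm(s, p)
    expect_equal(r[names(hr)], hr, tolerance = 1e-12)
    expect_equal(ode_rhs(s, p, cfg), hand_rhs_mm(s, p), tolerance = 1e-12)
  }
  # saturable reaction 10 variant
  cfg10 <- mm_cfg(reaction10_saturable = TRUE)
  s <- random_state(cfg10, 7)
  expect_equal(ode_rhs(s, p, cfg10), hand_rhs_mm(s, p, saturable10 = TRUE),
               tolerance = 1e-12)
})

test_that("feedback ablation makes self-ubiquitination first order", {
  cfg <- mm_cfg(feedback_enabled = FALSE)
  p <- default_p(k6 = 20, k9 = 20)
  s1 <- make_state(cfg, Z = 0.3, R = 0.2, Zub = 0.5, Ra = 0.4, Ru = 0.3,
                   H = 1)
  s2 <- make_state(cfg, Z = 0.3, R = 0.2, H = 1)  # no active forms at all
  r1 <- rate_vector(s1, p, cfg)
  r2 <- rate_vector(s2, p, cfg)
  expect_equal(r1[["r6"]], 20 * 0.3)
  expect_equal(r1[["r9"]], 20 * 0.2)
  expect_equal(r1[["r6"]], r2[["r6"]])   # independent of Zub, Ra, Ru
  expect_equal(r1[["r9"]], r2[["r9"]])
})

test_that("short-timescale rhs conserves the three molecular totals", {
  cfg <- mm_cfg()
  p <- default_p()
  for (seed in 1:6) {
    s <- random_state(cfg, seed)
    d <- ode_rhs(s, p, cfg)
    expect_equal(sum(d[c("R", "Rd", "Z", "Zub", "Ra", "Ru")]), 0,
                 tolerance = 1e-14)
    expect_equal(sum(d[c("B", "Bd", "Z", "Zub")]), 0, tolerance = 1e-14)
    expect_equal(sum(d[c("H", "Hu")]), 0, tolerance = 1e-14)
  }
})

test_that("mass-action variant conserves USP7 and counts C7 in all pools", {
  cfg <- model_config(variant = "mass_action")
  p <- default_parameters("mass_action")
  s <- random_state(cfg, 11)
  d <- ode_rhs(s, p, cfg)
  expect_lt(abs(sum(d[c("U", "C7")])), 1e-12)
  expect_lt(abs(sum(d[c("R", "Rd", "Z", "Zub", "Ra", "Ru", "C7")])), 1e-12)
  expect_lt(abs(sum(d[c("B", "Bd", "Z", "Zub", "C7")])), 1e-12)
  tot <- conserved_totals(s, cfg)
  expect_equal(tot[["USP7_total"]], s[["U"]] + s[["C7"]])
})

test_that("conserved_totals reproduces the printed initial-condition sums", {
  cfg <- mm_cfg()
  t1 <- conserved_totals(init_high_bd(), cfg)
  expect_equal(t1[["Bmi1_total"]], 2.5)
  expect_equal(t1[["Ring1B_total"]], 1.0)
  t2 <- conserved_totals(init_high_b(), cfg)
  expect_equal(t2[["Bmi1_total"]], 2.5)
  expect_equal(t2[["Ring1B_total"]], 1.0)
  t3 <- conserved_totals(make_state(cfg, R = 1), cfg)
  expect_equal(t3[["Ring1B_total"]], 1)
})

test_that("parameter validation catches missing and invalid entries", {
  cfg <- mm_cfg()
  p <- default_p()
  p2 <- p[setdiff(names(p), "k7")]
  expect_error(validate_parameters(p2, cfg), "k7")
  p3 <- p; p3[["k4"]] <- -1
  expect_error(validate_parameters(p3, cfg), "negative")
  p4 <- p; p4[["cRa"]] <- 2 * p4[["cZ"]]
  expect_error(validate_parameters(p4, cfg), "ranking")
  expect_error(rate_vector(make_state(cfg), default_parameters(),
                           model_config("mass_action")), "k7f")
})

test_that("nM unit conversion is an exact round trip and order-preserving", {
  p <- default_p()
  p_nm <- convert_units(p, "nM")
  expect_equal(p_nm[["Bmi1_tot"]], p[["Bmi1_tot"]] * 100)
  expect_equal(p_nm[["k5f"]], p[["k5f"]] / 100)
  expect_equal(p_nm[["k1"]], p[["k1"]])
  back <- convert_units(p_nm, "normalized")
  expect_equal(as.numeric(back), as.numeric(p), tolerance = 1e-14)
})

test_that("stoichiometry matrix columns sum to zero within conserved pools", {
  for (variant in c("MM", "mass_action")) {
    cfg <- model_config(variant)
    N <- stoichiometry_matrix(cfg)
    ring <- c("R", "Rd", "Z", "Zub", "Ra", "Ru",
              if (variant == "mass_action") "C7")
    bmi <- c("B", "Bd", "Z", "Zub", if (variant == "mass_action") "C7")
    expect_true(all(colSums(N[ring, , drop = FALSE]) == 0))
    expect_true(all(colSums(N[bmi, , drop = FALSE]) == 0))
    expect_true(all(colSums(N[c("H", "Hu"), , drop = FALSE]) == 0))
  }
})
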