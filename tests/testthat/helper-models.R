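# Shared fixtures: small parameter sets and state constructors used across
# the test files. Everything is built in code; no data files.

mm_cfg <- function(...) model_config(variant = "MM", ...)

default_p <- function(...) {
  p <- default_parameters()
  if (...length()) p <- set_parameters(p, ...)
  p
}

# the two printed initial conditions of the bistable time-course example
init_high_bd <- function(cfg = mm_cfg()) {
  make_state(cfg, Bd = 2.45, B = 0, Rd = 0.05, R = 0.9, Z = 0, Zub = 0.05,
             H = 1)
}
init_high_b <- function(cfg = mm_cfg()) {
  make_state(cfg, Bd = 1.08, B = 1.1, Rd = 0.12, R = 0.1, Z = 0.2,
             Zub = 0.12, Ra = 0.44, Ru = 0.02, H = 1)
}

# independent hand evaluation of every reaction rate (kept deliberately
# separate from rate_vector: one formula per line, no shared code path)
hand_rates_mm <- function(s, p, saturable10 = FALSE, feedback = TRUE,
                          u2scaled = FALSE) {
  A <- p[["wZ"]] * s[["Zub"]] + p[["wRa"]] * s[["Ra"]] + p[["wRu"]] * s[["Ru"]]
  if (!feedback) A <- 0
  U <- p[["USP7_tot"]]
  sat1 <- if (is.finite(p[["KM1"]])) p[["KM1"]] / (p[["KM1"]] + s[["B"]]) else 1
  sat3 <- if (is.finite(p[["KM3"]])) p[["KM3"]] / (p[["KM3"]] + s[["R"]]) else 1
  c(r1 = p[["k1"]] * s[["B"]] * sat1,
    r2 = p[["k2"]] * (if (u2scaled) U else 1) * s[["Bd"]],
    r3 = p[["k3"]] * s[["R"]] * sat3,
    r4 = p[["k4"]] * U * s[["Rd"]],
    r5f = p[["k5f"]] * s[["B"]] * s[["R"]],
    r5r = p[["k5r"]] * s[["Z"]],
    r6 = (p[["k6"]] + p[["k6a"]] * A) * s[["Z"]],
    r7 = p[["k7"]] * U * s[["Zub"]] / (p[["KM7"]] + s[["Zub"]]),
    r8f = p[["k8f"]] * s[["Zub"]],
    r8r = p[["k8r"]] * s[["B"]] * s[["Ra"]],
    r9 = (p[["k9"]] + p[["k9a"]] * A) * s[["R"]],
    r10 = if (saturable10)
      p[["k10"]] * U * s[["Ru"]] / (p[["KM10"]] + s[["Ru"]])
    else p[["k10"]] * U * s[["Ru"]],
    r11 = p[["k11"]] * U * s[["Ra"]],
    r12 = (p[["cZ"]] * s[["Zub"]] + p[["cRa"]] * s[["Ra"]] +
             p[["cRu"]] * s[["Ru"]]) * s[["H"]],
    r13 = p[["k13"]] * s[["Hu"]])
}

# hand-written per-species derivative sums (the stoichiometry oracle)
hand_rhs_mm <- function(s, p, ...) {
  r <- hand_rates_mm(s, p, ...)
  r5 <- r[["r5f"]] - r[["r5r"]]
  r8 <- r[["r8f"]] - r[["r8r"]]
  c(B = -r[["r1"]] + r[["r2"]] - r5 + r8,
    Bd = r[["r1"]] - r[["r2"]],
    R = -r[["r3"]] + r[["r4"]] - r5 - r[["r9"]] + r[["r10"]] + r[["r11"]],
    Rd = r[["r3"]] - r[["r4"]],
    Z = r5 - r[["r6"]] + r[["r7"]],
    Zub = r[["r6"]] - r[["r7"]] - r8,
    Ra = r8 - r[["r11"]],
    Ru = r[["r9"]] - r[["r10"]],
    H = -r[["r12"]] + r[["r13"]],
    Hu = r[["r12"]] - r[["r13"]])
}

random_state <- function(cfg, seed) {
  set.seed(seed)
  sp <- species_names(cfg)
  stats::setNames(round(stats::runif(length(sp), 0, 1.5), 4), sp)
}
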