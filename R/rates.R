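# Reaction rates, stoichiometry and ODE right-hand side.
#
# Reaction scheme (13 reactions; reversible ones are split into forward and
# reverse elementary rates so every returned rate is non-negative):
#   1  B   -> Bd        external ligase (SPOP/Cul-3) ubiquitinates Bmi1
#                       (optionally saturable: k1*B*KM1/(KM1+B); k1 is the
#                       low-substrate first-order slope, Vmax = k1*KM1)
#   2  Bd  -> B         DUB recycles Bmi1
#   3  R   -> Rd        E6-AP places K48 chains on Ring1B (optionally
#                       saturable, same convention with KM3)
#   4  Rd  -> R         DUB (USP7)
#   5  B + R <-> Z      complex formation
#   6  Z   -> Zub       self-ubiquitination of the complex (autocatalytic)
#   7  Zub -> Z         saturable deubiquitination (MM) or via explicit
#                       USP7 complex C7 (mass action: 7f/7r binding, 7cat)
#   8  Zub <-> B + Ra   dissociation releasing active free Ring1B
#   9  R   -> Ru        self-ubiquitination of free Ring1B (autocatalytic)
#   10 Ru  -> R         DUB; apparent first order, optionally saturable
#   11 Ra  -> R         DUB
#   12 H   -> Hu        H2A monoubiquitination by Zub, Ra, Ru (weights
#                       cZ > cRa >> cRu)
#   13 Hu  -> H         H2A deubiquitination
# Long timescale adds zero-order synthesis of B and R and first-order
# degradation of Bd and Rd (dashed reactions of the scheme).

.rate_names <- function(config) {
  r <- c("r1", "r2", "r3", "r4", "r5f", "r5r", "r6",
         if (config$variant == "MM") "r7" else c("r7f", "r7r", "r7cat"),
         "r8f", "r8r", "r9", "r10", "r11", "r12", "r13")
  if (config$timescale == "long") r <- c(r, "syn_B", "deg_Bd", "syn_R", "deg_Rd")
  r
}

#' Per-reaction rates
#'
#' Evaluates every reaction rate of the configured model at one state.
#' Reversible reactions (5, 8, and the mass-action USP7 binding step) are
#' reported as separate forward/reverse rates so all entries are
#' non-negative. The autocatalytic self-ubiquitination reactions 6 and 9
#' have rate `(k_basal + k_auto * A) * substrate` where
#' `A = wZ*Zub + wRa*Ra + wRu*Ru` is the weighted activity of the
#' self-ubiquitinated Ring1B forms (intermolecular autocatalysis).
#'
#' @param state named state vector (see [make_state()]).
#' @param params `prc1_params` vector (normalized units).
#' @param config a [model_config()] object.
#' @return Named non-negative numeric vector of rates.
#' @export
#' @examples
#' cfg <- model_config()
#' p <- default_parameters()
#' rate_vector(make_state(cfg, B = 1, R = 1), p, cfg)
rate_vector <- function(state, params, config = model_config()) {
  validate_parameters(params, config)
  s <- .check_state(state, config)
  p <- as.list(params)
  fb <- if (config$feedback_enabled) 1 else 0
  A <- p$wZ * s[["Zub"]] + p$wRa * s[["Ra"]] + p$wRu * s[["Ru"]]
  U_tot <- p$USP7_tot

  sat1 <- if (is.finite(p$KM1)) p$KM1 / (p$KM1 + s[["B"]]) else 1
  sat3 <- if (is.finite(p$KM3)) p$KM3 / (p$KM3 + s[["R"]]) else 1
  r <- c(
    r1 = p$k1 * s[["B"]] * sat1,
    r2 = p$k2 * (if (config$bmi1_dub_usp7_scaled) U_tot else 1) * s[["Bd"]],
    r3 = p$k3 * s[["R"]] * sat3,
    r5f = p$k5f * s[["B"]] * s[["R"]],
    r5r = p$k5r * s[["Z"]],
    r6 = (p$k6 + fb * p$k6a * A) * s[["Z"]],
    r8f = p$k8f * s[["Zub"]],
    r8r = p$k8r * s[["B"]] * s[["Ra"]],
    r9 = (p$k9 + fb * p$k9a * A) * s[["R"]],
    r12 = (p$cZ * s[["Zub"]] + p$cRa * s[["Ra"]] + p$cRu * s[["Ru"]]) * s[["H"]],
    r13 = p$k13 * s[["Hu"]])

  if (config$variant == "MM") {
    r <- c(r,
      r4 = p$k4 * U_tot * s[["Rd"]],
      r7 = p$k7 * U_tot * s[["Zub"]] / (p$KM7 + s[["Zub"]]),
      r10 = if (config$reaction10_saturable)
        p$k10 * U_tot * s[["Ru"]] / (p$KM10 + s[["Ru"]])
      else p$k10 * U_tot * s[["Ru"]],
      r11 = p$k11 * U_tot * s[["Ra"]])
  } else {
    U <- s[["U"]]
    r <- c(r,
      r4 = p$k4 * U * s[["Rd"]],
      r7f = p$k7f * U * s[["Zub"]],
      r7r = p$k7r * s[["C7"]],
      r7cat = p$k7cat * s[["C7"]],
      r10 = if (config$reaction10_saturable)
        p$k10 * U * s[["Ru"]] / (p$KM10 + s[["Ru"]])
      else p$k10 * U * s[["Ru"]],
      r11 = p$k11 * U * s[["Ra"]])
  }
  if (config$timescale == "long") {
    r <- c(r,
      syn_B = p$sB, deg_Bd = p$dBd * s[["Bd"]],
      syn_R = p$sR, deg_Rd = p$dRd * s[["Rd"]])
  }
  r[.rate_names(config)]
}

#' Stoichiometry matrix
#'
#' Species-by-reaction stoichiometry matrix of the configured model, with
#' rows ordered as [species_names()] and columns matching [rate_vector()].
#'
#' @param config a [model_config()] object.
#' @return Integer matrix (species x reactions).
#' @export
stoichiometry_matrix <- function(config = model_config()) {
  sp <- species_names(config)
  rn <- .rate_names(config)
  N <- matrix(0L, nrow = length(sp), ncol = length(rn),
              dimnames = list(sp, rn))
  add <- function(rxn, ...) {
    ch <- c(...)
    N[names(ch), rxn] <<- N[names(ch), rxn] + as.integer(ch)
  }
  add("r1", B = -1, Bd = 1)
  add("r2", Bd = -1, B = 1)
  add("r3", R = -1, Rd = 1)
  add("r4", Rd = -1, R = 1)
  add("r5f", B = -1, R = -1, Z = 1)
  add("r5r", Z = -1, B = 1, R = 1)
  add("r6", Z = -1, Zub = 1)
  if (config$variant == "MM") {
    add("r7", Zub = -1, Z = 1)
  } else {
    add("r7f", Zub = -1, U = -1, C7 = 1)
    add("r7r", C7 = -1, Zub = 1, U = 1)
    add("r7cat", C7 = -1, Z = 1, U = 1)
  }
  add("r8f", Zub = -1, B = 1, Ra = 1)
  add("r8r", B = -1, Ra = -1, Zub = 1)
  add("r9", R = -1, Ru = 1)
  add("r10", Ru = -1, R = 1)
  add("r11", Ra = -1, R = 1)
  add("r12", H = -1, Hu = 1)
  add("r13", Hu = -1, H = 1)
  if (config$timescale == "long") {
    add("syn_B", B = 1)
    add("deg_Bd", Bd = -1)
    add("syn_R", R = 1)
    add("deg_Rd", Rd = -1)
  }
  N
}

#' ODE right-hand side
#'
#' Time derivative of the state: the stoichiometry matrix applied to the
#' reaction rate vector. On the short timescale the three (four, for
#' mass action) conserved totals have exactly zero net derivative.
#'
#' @inheritParams rate_vector
#' @return Named numeric vector of d(state)/dt.
#' @export
ode_rhs <- function(state, params, config = model_config()) {
  r <- rate_vector(state, params, config)
  N <- stoichiometry_matrix(config)
  drop(N %*% r)
}

# Fast unchecked rhs used by integrators and root finders (same formulas as
# rate_vector/ode_rhs, inlined; kept in lockstep with them -- the test suite
# cross-checks the two paths).
.rhs_fast <- function(state, p, config) {
  fb <- if (config$feedback_enabled) 1 else 0
  B <- state[[1L]]; Bd <- state[[2L]]; R <- state[[3L]]; Rd <- state[[4L]]
  Z <- state[[5L]]; Zub <- state[[6L]]; Ra <- state[[7L]]; Ru <- state[[8L]]
  H <- state[[9L]]; Hu <- state[[10L]]
  A <- p[["wZ"]] * Zub + p[["wRa"]] * Ra + p[["wRu"]] * Ru
  ma <- config$variant == "mass_action"
  Ueff <- if (ma) state[[11L]] else p[["USP7_tot"]]

  r1 <- p[["k1"]] * B *
    (if (is.finite(p[["KM1"]])) p[["KM1"]] / (p[["KM1"]] + B) else 1)
  r2 <- p[["k2"]] * (if (config$bmi1_dub_usp7_scaled) p[["USP7_tot"]] else 1) * Bd
  r3 <- p[["k3"]] * R *
    (if (is.finite(p[["KM3"]])) p[["KM3"]] / (p[["KM3"]] + R) else 1)
  r4 <- p[["k4"]] * Ueff * Rd
  r5 <- p[["k5f"]] * B * R - p[["k5r"]] * Z
  r6 <- (p[["k6"]] + fb * p[["k6a"]] * A) * Z
  r8 <- p[["k8f"]] * Zub - p[["k8r"]] * B * Ra
  r9 <- (p[["k9"]] + fb * p[["k9a"]] * A) * R
  r10 <- if (config$reaction10_saturable)
    p[["k10"]] * Ueff * Ru / (p[["KM10"]] + Ru)
  else p[["k10"]] * Ueff * Ru
  r11 <- p[["k11"]] * Ueff * Ra
  r12 <- (p[["cZ"]] * Zub + p[["cRa"]] * Ra + p[["cRu"]] * Ru) * H
  r13 <- p[["k13"]] * Hu

  if (ma) {
    C7 <- state[[12L]]
    r7b <- p[["k7f"]] * Ueff * Zub - p[["k7r"]] * C7
    r7c <- p[["k7cat"]] * C7
    dZub_7 <- -r7b
    dZ_7 <- r7c
    dU <- -r7b + r7c
    dC7 <- r7b - r7c
  } else {
    r7 <- p[["k7"]] * p[["USP7_tot"]] * Zub / (p[["KM7"]] + Zub)
    dZub_7 <- -r7
    dZ_7 <- r7
    dU <- NULL
    dC7 <- NULL
  }

  dB <- -r1 + r2 - r5 + r8
  dBd <- r1 - r2
  dR <- -r3 + r4 - r5 - r9 + r10 + r11
  dRd <- r3 - r4
  dZ <- r5 - r6 + dZ_7
  dZub <- r6 + dZub_7 - r8
  dRa <- r8 - r11
  dRu <- r9 - r10
  dH <- -r12 + r13
  dHu <- r12 - r13

  if (config$timescale == "long") {
    dB <- dB + p[["sB"]]
    dBd <- dBd - p[["dBd"]] * Bd
    dR <- dR + p[["sR"]]
    dRd <- dRd - p[["dRd"]] * Rd
  }
  c(dB, dBd, dR, dRd, dZ, dZub, dRa, dRu, dH, dHu, dU, dC7)
}

#' Conserved totals of a state
#'
#' On the short timescale the scheme conserves total Ring1B
#' (`R + Rd + Z + Zub + Ra + Ru`), total Bmi1 (`B + Bd + Z + Zub`) and total
#' H2A (`H + Hu`); the mass-action variant additionally conserves total
#' USP7 (`U + C7`) and counts the USP7-bound complex `C7` in the Ring1B and
#' Bmi1 sums.
#'
#' @param state named state vector.
#' @param config a [model_config()] object.
#' @return Named numeric vector `Ring1B_total`, `Bmi1_total`, `H2A_total`
#'   (and `USP7_total` for the mass-action variant).
#' @export
#' @examples
#' cfg <- model_config()
#' conserved_totals(make_state(cfg, Bd = 2.45, R = 0.9, Rd = 0.05,
#'                             Zub = 0.05), cfg)
conserved_totals <- function(state, config = model_config()) {
  s <- .check_state(state, config)
  c7 <- if (config$variant == "mass_action") s[["C7"]] else 0
  out <- c(
    Ring1B_total = s[["R"]] + s[["Rd"]] + s[["Z"]] + s[["Zub"]] +
      s[["Ra"]] + s[["Ru"]] + c7,
    Bmi1_total = s[["B"]] + s[["Bd"]] + s[["Z"]] + s[["Zub"]] + c7,
    H2A_total = s[["H"]] + s[["Hu"]])
  if (config$variant == "mass_action")
    out <- c(out, USP7_total = s[["U"]] + s[["C7"]])
  out
}
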