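# Steady-state enumeration and stability analysis.
#
# Conservation laws are eliminated before root finding: the search runs in
# reduced coordinates (Bd, Rd, Z, Zub, Ra, Ru, Hu [, C7]) with B, R, H
# [, U] recovered from the conserved totals. This removes the neutral
# eigen-directions along the conservation laws, so the reduced Jacobian
# spectrum decides stability directly.

.reduced_names <- function(config) {
  c("Bd", "Rd", "Z", "Zub", "Ra", "Ru", "Hu",
    if (config$variant == "mass_action") "C7")
}

.full_from_reduced <- function(y, params, config) {
  ma <- config$variant == "mass_action"
  c7 <- if (ma) y[["C7"]] else 0
  B <- params[["Bmi1_tot"]] - y[["Bd"]] - y[["Z"]] - y[["Zub"]] - c7
  R <- params[["R1B_tot"]] - y[["Rd"]] - y[["Z"]] - y[["Zub"]] -
    y[["Ra"]] - y[["Ru"]] - c7
  H <- params[["H2A_tot"]] - y[["Hu"]]
  s <- c(B = B, Bd = y[["Bd"]], R = R, Rd = y[["Rd"]], Z = y[["Z"]],
         Zub = y[["Zub"]], Ra = y[["Ra"]], Ru = y[["Ru"]], H = H,
         Hu = y[["Hu"]])
  if (ma) s <- c(s, U = params[["USP7_tot"]] - c7, C7 = c7)
  s
}

.reduced_rhs <- function(y, params, config) {
  s <- .full_from_reduced(y, params, config)
  d <- .rhs_fast(s, params, config)
  names(d) <- species_names(config)
  d[.reduced_names(config)]
}

# residual for the damped least-squares root search; soft penalties keep the
# dependent concentrations non-negative without hard walls
.ss_residual <- function(y, params, config) {
  s <- .full_from_reduced(y, params, config)
  pen <- 1e3 * pmin(s[c("B", "R", "H", if (config$variant == "mass_action") "U")], 0)
  c(.reduced_rhs(y, params, config), pen)
}

.reduced_jacobian <- function(y, params, config, h = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dj <- h * (1 + abs(y[[j]]))
    yp <- y; yp[[j]] <- yp[[j]] + dj
    ym <- y; ym[[j]] <- ym[[j]] - dj
    J[, j] <- (.reduced_rhs(yp, params, config) -
                 .reduced_rhs(ym, params, config)) / (2 * dj)
  }
  dimnames(J) <- list(names(y), names(y))
  J
}

# seeded start points on the conservation simplex: corner-biased
# deterministic starts (mass concentrated in single pools) plus random
# interior points
.ss_starts <- function(params, config, n_starts, seed) {
  Bm <- params[["Bmi1_tot"]]; R1 <- params[["R1B_tot"]]
  mB <- min(Bm, R1)
  rn <- .reduced_names(config)
  zero <- stats::setNames(numeric(length(rn)), rn)
  mk <- function(...) { y <- zero; v <- c(...); y[names(v)] <- v; y }
  det <- list(
    mk(),                                 # everything free/unmodified
    mk(Zub = 0.9 * mB),                   # ignited complex branch
    mk(Z = 0.9 * mB),
    mk(Rd = 0.9 * R1, Bd = 0.9 * Bm),     # degradation-targeted corner
    mk(Ru = 0.9 * R1),
    mk(Ra = 0.45 * R1, Zub = 0.45 * mB),
    mk(Bd = 0.9 * Bm),
    mk(Rd = 0.9 * R1))
  n_rand <- max(0L, n_starts - length(det))
  rand <- vector("list", n_rand)
  if (n_rand > 0) {
    runif <- stats::runif
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    for (i in seq_len(n_rand)) {
      y <- zero
      zc <- runif(1, 0, mB)
      zubc <- runif(1, 0, mB - zc)
      y[["Z"]] <- zc; y[["Zub"]] <- zubc
      y[["Bd"]] <- runif(1, 0, max(Bm - zc - zubc, 0))
      rem <- max(R1 - zc - zubc, 0)
      fr <- runif(3)
      fr <- fr / max(sum(fr), 1) * runif(1)   # leave some free Ring1B
      y[["Rd"]] <- fr[1] * rem; y[["Ra"]] <- fr[2] * rem
      y[["Ru"]] <- fr[3] * rem
      y[["Hu"]] <- runif(1, 0, params[["H2A_tot"]])
      if (config$variant == "mass_action")
        y[["C7"]] <- runif(1, 0, min(params[["USP7_tot"]], zubc + 0.1))
      rand[[i]] <- y
    }
  }
  c(det, rand)
}

#' Find all steady states at fixed conserved totals
#'
#' Multi-start damped least-squares root search on the reduced (conservation
#' laws eliminated) coordinates, followed by deduplication and linear
#' stability analysis of each root via the reduced Jacobian spectrum.
#'
#' @param params `prc1_params` vector; the conserved totals (`Bmi1_tot`,
#'   `R1B_tot`, `H2A_tot`, `USP7_tot`) are taken from it.
#' @param config a [model_config()] object (short timescale).
#' @param n_starts number of start points (deterministic corner-biased
#'   starts plus seeded random interior starts).
#' @param seed integer seed for the random starts.
#' @param residual_tol acceptance threshold on the Euclidean norm of the
#'   ODE right-hand side at a root (normalized units).
#' @param dedup_tol relative Euclidean distance below which two roots are
#'   considered the same steady state.
#' @param eps_eig stability margin: stable iff all eigenvalue real parts
#'   are below `-eps_eig`; eigenvalues within `c(-eps_eig, eps_eig)` flag the
#'   root as marginal.
#' @return List of `prc1_steady_state` objects sorted by increasing `Zub`,
#'   each with fields `state` (full named state), `eigenvalues`,
#'   `stability` (`"stable"`/`"unstable"`), `marginal`, `residual_norm`.
#'   If no root is found the empty list carries attribute
#'   `no_root_found = TRUE`.
#' @export
#' @examples
#' \donttest{
#' ss <- find_steady_states(default_parameters(), model_config())
#' length(ss)
#' }
find_steady_states <- function(params, config = model_config(),
                               n_starts = 40, seed = 1,
                               residual_tol = 1e-8, dedup_tol = 1e-5,
                               eps_eig = 1e-9) {
  validate_parameters(params, config)
  if (config$timescale != "short")
    stop("steady-state enumeration is defined for the short-timescale model")
  starts <- .ss_starts(params, config, n_starts, seed)
  rn_red <- .reduced_names(config)
  roots <- list()
  for (y0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = y0, fn = .ss_residual, params = params,
                         config = config, lower = rep(0, length(y0)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    y <- fit$par
    s <- .full_from_reduced(y, params, config)
    if (any(s < -1e-9)) next
    res <- sqrt(sum(.reduced_rhs(y, params, config)^2))
    if (!is.finite(res) || res > residual_tol) next
    s <- pmax(s, 0)
    dup <- FALSE
    for (r in roots) {
      d <- sqrt(sum((r$state - s)^2)) / (1 + sqrt(sum(r$state^2)))
      if (d < dedup_tol) { dup <- TRUE; break }
    }
    if (dup) next
    J <- .reduced_jacobian(y, params, config)
    ev <- eigen(J, only.values = TRUE)$values
    roots[[length(roots) + 1L]] <- structure(
      list(state = s, eigenvalues = ev,
           stability = if (all(Re(ev) < -eps_eig)) "stable" else "unstable",
           marginal = any(abs(Re(ev)) <= eps_eig),
           residual_norm = res),
      class = "prc1_steady_state")
  }
  if (!length(roots)) {
    # fallback for badly scaled systems: relax dynamically from generic
    # initial conditions, then polish the endpoint by root search
    Bm <- params[["Bmi1_tot"]]; R1 <- params[["R1B_tot"]]
    relax_inits <- list(
      make_state(config, B = Bm, R = R1, H = params[["H2A_tot"]]),
      make_state(config, Bd = Bm, R = R1, H = params[["H2A_tot"]]))
    for (init in relax_inits) {
      tr <- tryCatch(
        simulate_timecourse(params, config, init, t_end = 5e4, n_out = 6),
        error = function(e) NULL)
      if (is.null(tr)) next
      y0 <- unlist(tr[nrow(tr), species_names(config)])[rn_red]
      fit <- tryCatch(
        minpack.lm::nls.lm(par = y0, fn = .ss_residual, params = params,
                           config = config, lower = rep(0, length(y0)),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      res <- sqrt(sum(.reduced_rhs(fit$par, params, config)^2))
      if (!is.finite(res) || res > residual_tol) next
      s <- pmax(.full_from_reduced(fit$par, params, config), 0)
      dup <- any(vapply(roots, function(r)
        sqrt(sum((r$state - s)^2)) / (1 + sqrt(sum(r$state^2))) < dedup_tol,
        logical(1)))
      if (dup) next
      J <- .reduced_jacobian(fit$par, params, config)
      ev <- eigen(J, only.values = TRUE)$values
      roots[[length(roots) + 1L]] <- structure(
        list(state = s, eigenvalues = ev,
             stability = if (all(Re(ev) < -eps_eig)) "stable" else "unstable",
             marginal = any(abs(Re(ev)) <= eps_eig),
             residual_norm = res),
        class = "prc1_steady_state")
    }
  }
  if (!length(roots)) {
    warning("no steady state found from ", length(starts), " starts")
    return(structure(list(), no_root_found = TRUE))
  }
  roots[order(vapply(roots, function(r) r$state[["Zub"]], numeric(1)))]
}

#' @export
print.prc1_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s%s, |rhs| = %.2e)\n", x$stability,
              if (isTRUE(x$marginal)) ", marginal" else "", x$residual_norm))
  print(round(x$state, 6))
  invisible(x)
}

#' Classify the dynamical regime from a steady-state list
#'
#' Labels follow the eigenvalue-count taxonomy used for the
#' (Bmi1, USP7) regime map: one stable state only -> `monostable`; two
#' stable separated by one unstable -> `bistable`; a single unstable state
#' -> `oscillatory`; one stable plus two unstable -> `excitable`; three or
#' more stable -> `multistable`; anything else -> `other`.
#'
#' @param steady_list list returned by [find_steady_states()].
#' @param params optional parameter vector (recorded in the result).
#' @return Character scalar regime label with attribute `counts`.
#' @export
classify_regime <- function(steady_list, params = NULL) {
  if (!length(steady_list)) stop("empty steady-state list: cannot classify")
  stab <- vapply(steady_list, function(s) s$stability, character(1))
  ns <- sum(stab == "stable"); nu <- sum(stab == "unstable")
  label <-
    if (ns >= 3) "multistable"
    else if (ns == 1 && nu == 0) "monostable"
    else if (ns == 2 && nu == 1) "bistable"
    else if (ns == 0 && nu == 1) "oscillatory"
    else if (ns == 1 && nu == 2) "excitable"
    else "other"
  structure(label, counts = c(stable = ns, unstable = nu))
}

# ---- quasi-steady-state nullcline curves --------------------------------

# Ring1B-cycle steady states at clamped free Bmi1 concentration B.
# Unknowns (R, Z, Zub, Ra, Ru); Rd is slaved to R by its own steady-state
# relation; equations: Ring1B conservation and d/dt = 0 for Z, Zub, Ra, Ru.
# Independent of Bmi1_tot by construction.
.ring_cycle_residual <- function(x, clamp, params, config) {
  B <- clamp
  p <- params
  R <- x[1]; Z <- x[2]; Zub <- x[3]; Ra <- x[4]; Ru <- x[5]
  U <- p[["USP7_tot"]]
  sat3 <- if (is.finite(p[["KM3"]])) p[["KM3"]] / (p[["KM3"]] + R) else 1
  Rd <- p[["k3"]] * R * sat3 / (p[["k4"]] * U)
  s <- c(B = B, Bd = 0, R = R, Rd = Rd, Z = Z, Zub = Zub, Ra = Ra,
         Ru = Ru, H = 0, Hu = 0)
  d <- .rhs_fast(s, p, config)
  names(d) <- species_names(config)[1:10]
  cons <- R + Rd + Z + Zub + Ra + Ru - p[["R1B_tot"]]
  # rate rows are scaled up so the damped least-squares search weighs them
  # comparably to the conservation constraint
  c(1e3 * d[c("Z", "Zub", "Ra", "Ru")], cons, 1e3 * pmin(x, 0))
}

# Complementary subsystem at clamped Zub: Bmi1 cycle, complex formation
# and the free-Ring1B reactions at steady state with both conservation
# laws; the Zub production/removal balance is the one equation left out.
# All species are eliminated analytically in favour of free Bmi1 (B); the
# remaining scalar equation is the free-Ring1B balance dB/dt = 0, whose
# roots are located by a sign scan plus bisection (this finds every branch
# of the folded curve).
.bmi_side_state <- function(B, Zub, p, config) {
  U <- p[["USP7_tot"]]
  u2 <- if (config$bmi1_dub_usp7_scaled) U else 1
  sat1 <- if (is.finite(p[["KM1"]])) p[["KM1"]] / (p[["KM1"]] + B) else 1
  Bd <- p[["k1"]] * B * sat1 / (p[["k2"]] * u2)
  Z <- p[["Bmi1_tot"]] - B - Bd - Zub
  if (Z < 0) return(NULL)
  Ra <- p[["k8f"]] * Zub / (p[["k8r"]] * B + p[["k11"]] * U)
  A0 <- p[["wZ"]] * Zub + p[["wRa"]] * Ra
  r6 <- (p[["k6"]] + p[["k6a"]] * A0) * Z      # wRu*Ru correction below
  r7 <- p[["k7"]] * U * Zub / (p[["KM7"]] + Zub)
  R <- (p[["k5r"]] * Z + r6 - r7) / (p[["k5f"]] * B)
  if (!is.finite(R) || R < 0) return(NULL)
  den <- p[["k10"]] * U - p[["k9a"]] * p[["wRu"]] * R
  if (den <= 0) return(NULL)
  Ru <- (p[["k9"]] + p[["k9a"]] * A0) * R / den
  sat3 <- if (is.finite(p[["KM3"]])) p[["KM3"]] / (p[["KM3"]] + R) else 1
  Rd_cons <- p[["R1B_tot"]] - R - Z - Zub - Ra - Ru
  if (Rd_cons < 0) return(NULL)
  c(B = B, Bd = Bd, R = R, Rd = Rd_cons, Z = Z, Zub = Zub, Ra = Ra,
    Ru = Ru)
}

# scalar residual in B: the one remaining equation of the subsystem is
# the free-Bmi1 balance dB/dt = 0
.bmi_side_f <- function(B, Zub, p, config) {
  st <- .bmi_side_state(B, Zub, p, config)
  if (is.null(st)) return(NA_real_)
  s <- c(st, H = 0, Hu = 0)
  d <- .rhs_fast(s, p, config)
  names(d) <- species_names(config)[1:10]
  d[["B"]]
}

.bmi_side_solutions <- function(Zub, params, config, n_grid = 200) {
  Bm <- params[["Bmi1_tot"]]
  grid <- seq(1e-4, Bm, length.out = n_grid)
  f <- vapply(grid, .bmi_side_f, numeric(1), Zub = Zub, p = params,
              config = config)
  sols <- list()
  for (i in seq_len(n_grid - 1L)) {
    if (is.na(f[i]) || is.na(f[i + 1L])) next
    if (f[i] == 0) {
      st <- .bmi_side_state(grid[i], Zub, params, config)
      if (!is.null(st)) sols[[length(sols) + 1L]] <- st
    } else if (f[i] * f[i + 1L] < 0) {
      root <- stats::uniroot(function(B) .bmi_side_f(B, Zub, params,
                                                     config),
                             c(grid[i], grid[i + 1L]), tol = 1e-12)$root
      st <- .bmi_side_state(root, Zub, params, config)
      if (!is.null(st)) sols[[length(sols) + 1L]] <- st
    }
  }
  sols
}

.qss_solve <- function(resfn, clamp, params, config, starts) {
  pts <- list()
  for (x0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = x0, fn = resfn, lower = rep(0, length(x0)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-15),
                         clamp = clamp, params = params, config = config),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- resfn(fit$par, clamp, params, config)
    if (sqrt(sum(r^2)) > 1e-5) next   # ~1e-8 on the unscaled rate rows
    dup <- any(vapply(pts, function(q)
      sqrt(sum((q - fit$par)^2)) < 1e-6 * (1 + sqrt(sum(q^2))), logical(1)))
    if (!dup) pts[[length(pts) + 1L]] <- fit$par
  }
  pts
}

#' Quasi-steady-state nullcline curves on the (Rd, Zub) plane
#'
#' Computes the two curves whose intersections are the system steady
#' states. The `Zub` curve holds the Bmi1 side out of the problem by
#' clamping free Bmi1 and solving the Ring1B ubiquitination cycle to steady
#' state (hence it is invariant under changes of `Bmi1_tot`); the `Rd`
#' curve clamps `Zub` and solves the complementary subsystem (Bmi1 cycle,
#' complex formation, free-Ring1B reactions) under both conservation laws,
#' so it shifts with `Bmi1_tot`.
#'
#' @param params `prc1_params` vector.
#' @param grid list with elements `B` (grid of clamped free-Bmi1 values for
#'   the Zub curve) and `Zub` (grid of clamped Zub values for the Rd
#'   curve); a single numeric vector is used for both.
#' @param config short-timescale [model_config()].
#' @return List of two data frames `zub_curve` and `rd_curve` with columns
#'   `clamped`, `Rd`, `Zub`, `converged`.
#' @export
qss_curves <- function(params, grid = NULL, config = model_config()) {
  validate_parameters(params, config)
  if (config$variant != "MM")
    stop("QSS nullclines are implemented for the MM variant")
  if (is.null(grid))
    grid <- list(B = seq(0.001, 0.98 * params[["Bmi1_tot"]], length.out = 80),
                 Zub = seq(0, 0.95 * min(params[["Bmi1_tot"]],
                                         params[["R1B_tot"]]),
                           length.out = 80))
  if (is.numeric(grid)) grid <- list(B = grid, Zub = grid)
  R1 <- params[["R1B_tot"]]
  base_starts <- list(
    c(R = 0.5 * R1, Z = 0.1 * R1, Zub = 0.01, Ra = 0.01, Ru = 0.01),
    c(R = 0.05 * R1, Z = 0.1 * R1, Zub = 0.6 * R1, Ra = 0.2 * R1, Ru = 0.01),
    c(R = 0.02 * R1, Z = 0.15 * R1, Zub = 0.1 * R1, Ra = 0.7 * R1,
      Ru = 0.005),
    c(R = 0.2 * R1, Z = 0.4 * R1, Zub = 0.2 * R1, Ra = 0.05, Ru = 0.05))
  zub_rows <- list()
  for (B in grid$B) {
    pts <- .qss_solve(.ring_cycle_residual, B, params, config, base_starts)
    if (!length(pts)) {
      zub_rows[[length(zub_rows) + 1L]] <-
        data.frame(clamped = B, Rd = NA_real_, Zub = NA_real_,
                   converged = FALSE)
    } else {
      for (x in pts) {
        sat3 <- if (is.finite(params[["KM3"]]))
          params[["KM3"]] / (params[["KM3"]] + x[1]) else 1
        Rd <- params[["k3"]] * x[1] * sat3 /
          (params[["k4"]] * params[["USP7_tot"]])
        zub_rows[[length(zub_rows) + 1L]] <-
          data.frame(clamped = B, Rd = Rd, Zub = x[3], converged = TRUE)
      }
    }
  }
  rd_rows <- list()
  for (Zub in grid$Zub) {
    sols <- .bmi_side_solutions(Zub, params, config)
    if (!length(sols)) {
      rd_rows[[length(rd_rows) + 1L]] <-
        data.frame(clamped = Zub, Rd = NA_real_, Zub = Zub,
                   converged = FALSE)
    } else {
      for (st in sols) {
        rd_rows[[length(rd_rows) + 1L]] <-
          data.frame(clamped = Zub, Rd = st[["Rd"]], Zub = Zub,
                     converged = TRUE)
      }
    }
  }
  list(zub_curve = do.call(rbind, zub_rows), rd_curve = do.call(rbind, rd_rows))
}
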