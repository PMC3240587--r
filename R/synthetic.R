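# Synthetic data: randomized parameter sets, noisy pseudo-observed time
# courses emulating quantified ubiquitination assays (densitometry of
# immunoblots), and parameter recovery by bounded multi-start least
# squares.

.rate_constant_names <- function(params) {
  intersect(names(params),
            c("k1", "k2", "k3", "k4", "k5f", "k5r", "k6", "k6a", "k7",
              "k8f", "k8r", "k9", "k9a", "k10", "k11", "cZ", "cRa", "cRu",
              "k13", "k7f", "k7r", "k7cat"))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Randomize a parameter set around a base set
#'
#' Multiplies every rate constant by an independent log-uniform factor in
#' `[1/fold_range, fold_range]`. Abundances (totals) and Michaelis
#' constants are held fixed unless `include_abundances`/`include_km`.
#'
#' @param base `prc1_params` base set.
#' @param fold_range maximal fold perturbation (>= 1).
#' @param seed integer seed (reproducible draws).
#' @param include_abundances also perturb the `_tot` abundances.
#' @param include_km also perturb `KM7`/`KM10`.
#' @return Perturbed `prc1_params` vector.
#' @export
#' @examples
#' p <- sample_parameters(default_parameters(), fold_range = 1.25, seed = 7)
sample_parameters <- function(base, fold_range = 1.25, seed = 1,
                              include_abundances = FALSE,
                              include_km = FALSE) {
  if (fold_range < 1) stop("fold_range must be >= 1")
  nm <- .rate_constant_names(base)
  if (include_km) nm <- c(nm, intersect(names(base), c("KM7", "KM10")))
  if (include_abundances)
    nm <- c(nm, intersect(names(base),
                          c("USP7_tot", "Bmi1_tot", "R1B_tot", "H2A_tot")))
  out <- base
  if (fold_range > 1) {
    f <- .with_seed(seed,
                    exp(stats::runif(length(nm), -log(fold_range),
                                     log(fold_range))))
    out[nm] <- base[nm] * f
  }
  out
}

#' Multiplicative measurement-noise model
#'
#' Log-normal multiplicative noise with a given coefficient of variation
#' and a detection floor, emulating densitometric quantification of
#' immunoblot band intensities (positive, heteroscedastic).
#'
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param floor detection floor (concentration); observations below it are
#'   clipped up to the floor.
#' @param seed integer seed.
#' @return A `prc1_noise` list.
#' @export
noise_model <- function(cv = 0.1, floor = 0, seed = 1) {
  if (cv < 0 || floor < 0) stop("cv and floor must be non-negative")
  structure(list(cv = cv, floor = floor, seed = seed),
            class = "prc1_noise")
}

.default_observables <- list(
  Zub = "Zub",
  Rd = "Rd",
  total_ub_R1B = c("Rd", "Ru", "Ra", "Zub"),
  active_ub_R1B = c("Zub", "Ra", "Ru"),
  Hu = "Hu")

#' Generate a noisy pseudo-observed time course
#'
#' Integrates the model, samples composite observables at the given times
#' (total ubiquitinated Ring1B `Rd + Ru + Ra + Zub`, total catalytically
#' active ubiquitinated Ring1B `Zub + Ra + Ru`, and single species), and
#' applies independent multiplicative log-normal noise with the configured
#' cv, clipping at the detection floor.
#'
#' @param params,config model.
#' @param init initial state.
#' @param times increasing sampling times (s).
#' @param noise a [noise_model()].
#' @param observables named list mapping observable names to the species
#'   summed for each; default includes the composite ubiquitinated-Ring1B
#'   readouts.
#' @return A `prc1_observations` object: data frame (`time`, one column
#'   per observable) with attributes `params`, `noise`, `observables`.
#' @export
noisy_timecourse <- function(params, config = model_config(), init, times,
                             noise = noise_model(),
                             observables = .default_observables) {
  if (is.unsorted(times, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  traj <- simulate_timecourse(params, config, init,
                              times = unique(c(0, times)))
  idx <- match(times, traj$time)
  clean <- vapply(observables, function(sp)
    rowSums(as.data.frame(traj[idx, sp, drop = FALSE])),
    numeric(length(times)))
  clean <- matrix(clean, nrow = length(times),
                  dimnames = list(NULL, names(observables)))
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    fac <- .with_seed(noise$seed,
                      matrix(stats::rlnorm(length(clean),
                                           meanlog = -sdlog^2 / 2,
                                           sdlog = sdlog),
                             nrow = nrow(clean)))
    obs <- clean * fac
  } else obs <- clean
  obs <- pmax(obs, noise$floor)
  structure(cbind(data.frame(time = times), as.data.frame(obs)),
            class = c("prc1_observations", "data.frame"),
            params = params, config = config, init = init, noise = noise,
            observables = observables)
}

#' Recover parameters from a pseudo-observed time course
#'
#' Bounded least squares (Levenberg-Marquardt in log-parameter space via
#' box transforms) fitting selected rate constants so that the simulated
#' observables match the observations, with multi-start from seeded
#' points.
#'
#' @param obs a `prc1_observations` object.
#' @param free_names character vector of parameter names to fit; empty
#'   returns the residual of the base parameters only.
#' @param bounds list of length-2 numeric intervals per free parameter, or
#'   a single interval recycled; defaults to 1/10 .. 10 times the base
#'   value.
#' @param seed integer seed for the start points.
#' @param n_starts number of start points (first start = base values).
#' @param base optional parameter vector used for fixed parameters and
#'   starts; defaults to the generating parameters stored in `obs`.
#' @return List: `estimate` (named vector), `residual` (root mean square),
#'   `converged`, `starts_tried`.
#' @export
recover_parameters <- function(obs, free_names, bounds = NULL, seed = 1,
                               n_starts = 5, base = NULL) {
  if (is.null(base)) base <- attr(obs, "params")
  config <- attr(obs, "config")
  init <- attr(obs, "init")
  observables <- attr(obs, "observables")
  times <- obs$time
  Y <- as.matrix(obs[, names(observables), drop = FALSE])
  scale <- pmax(colMeans(Y), 1e-6)

  resid_fn <- function(theta) {
    p <- base
    p[free_names] <- exp(theta)
    sim <- tryCatch(
      simulate_timecourse(p, config, init, times = unique(c(0, times)),
                          rtol = 1e-7, atol = 1e-9),
      error = function(e) NULL)
    if (is.null(sim)) return(rep(1e3, length(Y)))
    idx <- match(times, sim$time)
    S <- vapply(observables, function(sp)
      rowSums(as.data.frame(sim[idx, sp, drop = FALSE])),
      numeric(length(times)))
    as.numeric((S - Y) / rep(scale, each = length(times)))
  }
  if (!length(free_names)) {
    r <- resid_fn(numeric(0))
    return(list(estimate = stats::setNames(numeric(0), character(0)),
                residual = sqrt(mean(r^2)), converged = TRUE,
                starts_tried = 0L))
  }
  if (!all(free_names %in% names(base)))
    stop("unknown parameter(s): ",
         paste(setdiff(free_names, names(base)), collapse = ", "))
  if (is.null(bounds))
    bounds <- lapply(free_names, function(nm)
      c(base[[nm]] / 10, base[[nm]] * 10))
  if (is.numeric(bounds)) bounds <- rep(list(bounds), length(free_names))
  lo <- log(vapply(bounds, `[`, numeric(1), 1L))
  hi <- log(vapply(bounds, `[`, numeric(1), 2L))

  starts <- .with_seed(seed, {
    s0 <- log(pmin(pmax(base[free_names], exp(lo)), exp(hi)))
    more <- lapply(seq_len(max(0L, n_starts - 1L)), function(i)
      stats::runif(length(free_names), lo, hi))
    c(list(s0), more)
  })
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(resid_fn(fit$par)^2))
    if (is.null(best) || rms < best$residual)
      best <- list(estimate = stats::setNames(exp(fit$par), free_names),
                   residual = rms, converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    return(list(estimate = stats::setNames(rep(NA_real_, length(free_names)),
                                           free_names),
                residual = NA_real_, converged = FALSE,
                starts_tried = length(starts)))
  c(best, list(starts_tried = length(starts)))
}
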