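# Oscillation detection and characterization, excitability thresholds, and
# overshoot metrics for perturbation responses.

.find_peaks <- function(x, min_prom = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (min_prom > 0 && length(idx)) {
    keep <- vapply(idx, function(i) {
      lo <- max(1L, i - 50L); hi <- min(n, i + 50L)
      (x[i] - min(x[lo:hi])) >= min_prom
    }, logical(1))
    idx <- idx[keep]
  }
  idx
}

#' Perturbation specification
#'
#' Describes either an instantaneous increment of one species
#' (`state_increment`) or a rectangular fold-change pulse of one parameter
#' (`parameter_pulse`), as used for probing excitable responses.
#'
#' @param kind `"state_increment"` or `"parameter_pulse"`.
#' @param target species name (state increment) or parameter name
#'   (parameter pulse).
#' @param magnitude increment (concentration) or fold change of the
#'   parameter during the pulse.
#' @param start pulse start time (s), parameter pulse only.
#' @param duration pulse duration (s), parameter pulse only; must be > 0.
#' @return A `prc1_perturbation` list.
#' @export
#' @examples
#' perturbation_spec("state_increment", "Zub", 0.02)
#' perturbation_spec("parameter_pulse", "k6a", 1.4, start = 500,
#'                   duration = 85)
perturbation_spec <- function(kind = c("state_increment", "parameter_pulse"),
                              target, magnitude, start = 500,
                              duration = NULL) {
  kind <- match.arg(kind)
  if (kind == "parameter_pulse") {
    if (is.null(duration) || duration <= 0)
      stop("parameter_pulse requires duration > 0")
  }
  structure(list(kind = kind, target = target, magnitude = magnitude,
                 start = start, duration = duration),
            class = "prc1_perturbation")
}

# integrate the response to a perturbation applied to a rest state
.perturbed_trajectory <- function(params, config, rest, spec, t_end,
                                  n_out = 2001) {
  if (spec$kind == "state_increment") {
    init <- rest
    if (!spec$target %in% names(init)) stop("unknown species: ", spec$target)
    init[[spec$target]] <- init[[spec$target]] + spec$magnitude
    simulate_timecourse(params, config, init, t_end = t_end, n_out = n_out)
  } else {
    if (!spec$target %in% names(params))
      stop("unknown parameter: ", spec$target)
    t1 <- spec$start; t2 <- spec$start + spec$duration
    p_pulse <- params
    p_pulse[[spec$target]] <- params[[spec$target]] * spec$magnitude
    tr1 <- simulate_timecourse(params, config, rest, t_end = t1,
                               n_out = max(11L, ceiling(n_out * t1 / t_end)))
    s1 <- unlist(tr1[nrow(tr1), species_names(config)])
    tr2 <- simulate_timecourse(p_pulse, config, s1,
                               t_end = spec$duration, n_out = 201L)
    s2 <- unlist(tr2[nrow(tr2), species_names(config)])
    tr3 <- simulate_timecourse(params, config, s2, t_end = t_end - t2,
                               n_out = n_out)
    tr2$time <- tr2$time + t1
    tr3$time <- tr3$time + t2
    out <- rbind(tr1[-nrow(tr1), ], tr2[-nrow(tr2), ], tr3)
    attr(out, "config") <- config; attr(out, "params") <- params
    class(out) <- c("prc1_trajectory", "data.frame")
    out
  }
}

#' Detect and characterize sustained oscillations
#'
#' Discards an initial transient, finds peaks of every species, and reports
#' period (mean inter-peak interval of the reference species), peak-to-
#' trough amplitudes, and pairwise phase lags estimated by circular
#' cross-correlation at the period. A trajectory counts as oscillatory only
#' if the inter-peak intervals are regular (coefficient of variation
#' < 0.05) and the amplitude is sustained (last/first retained peak-to-
#' trough ratio > `sustain_ratio`).
#'
#' @param traj a `prc1_trajectory` (uniform time grid required).
#' @param transient_fraction fraction of the trajectory discarded as
#'   transient (default 0.3).
#' @param reference species used for the period estimate (default `"Zub"`).
#' @param min_peaks minimum number of reference peaks required (default 5);
#'   fewer raises an insufficient-data error.
#' @param sustain_ratio sustained-amplitude criterion (default 0.95).
#' @param min_amplitude peak-to-trough amplitude below which a species is
#'   treated as non-oscillating (default 1e-4).
#' @return A `prc1_oscillation` list: `is_oscillatory`, `period` (s),
#'   `amplitudes` (named vector), `phase_lags` (matrix, fraction of period;
#'   `lag[i, j] > 0` means species i peaks after species j), `ipi_cv`.
#' @export
detect_oscillations <- function(traj, transient_fraction = 0.3,
                                reference = "Zub", min_peaks = 5,
                                sustain_ratio = 0.95, min_amplitude = 1e-4) {
  config <- attr(traj, "config")
  sp <- species_names(config)
  keep <- traj$time >= transient_fraction * max(traj$time)
  tt <- traj$time[keep]
  dt <- stats::median(diff(tt))
  X <- as.matrix(traj[keep, sp])
  amp <- apply(X, 2L, function(x) max(x) - min(x))
  ref <- X[, reference]
  pk <- .find_peaks(ref, min_prom = 0.2 * amp[[reference]])
  if (length(pk) < min_peaks)
    stop("insufficient data: found ", length(pk), " peaks of ", reference,
         " after transient, need >= ", min_peaks)
  ipi <- diff(tt[pk])
  period <- mean(ipi)
  ipi_cv <- stats::sd(ipi) / period
  # sustained amplitude: compare peak-to-trough of last vs first full cycle
  cyc_amp <- function(i1, i2) {
    seg <- ref[i1:i2]; max(seg) - min(seg)
  }
  a_first <- cyc_amp(pk[1L], pk[2L])
  a_last <- cyc_amp(pk[length(pk) - 1L], pk[length(pk)])
  sustained <- a_first > 0 && (a_last / a_first) > sustain_ratio
  is_osc <- sustained && ipi_cv < 0.05 && amp[[reference]] > min_amplitude

  osc_sp <- names(amp)[amp > pmax(min_amplitude, 0.01 * amp[[reference]])]
  lags <- matrix(NA_real_, length(sp), length(sp),
                 dimnames = list(sp, sp))
  if (is_osc && length(osc_sp) >= 2) {
    nlag <- max(1L, round(period / dt))
    for (i in osc_sp) for (j in osc_sp) {
      cc <- stats::ccf(X[, i], X[, j], lag.max = nlag, plot = FALSE,
                       demean = TRUE)
      lag_t <- cc$lag[which.max(cc$acf)] * dt
      lags[i, j] <- (lag_t / period) %% 1
    }
  }
  structure(list(is_oscillatory = is_osc, period = period,
                 amplitudes = amp, phase_lags = lags, ipi_cv = ipi_cv,
                 n_peaks = length(pk)),
            class = "prc1_oscillation")
}

#' @export
print.prc1_oscillation <- function(x, ...) {
  if (x$is_oscillatory)
    cat(sprintf("Sustained oscillation: period %.1f s (ipi cv %.3f)\n",
                x$period, x$ipi_cv))
  else cat("No sustained oscillation detected\n")
  invisible(x)
}

#' Classify one perturbation response at an excitable rest state
#'
#' A response is a large excursion ("over threshold") when the peak
#' deviation of `readout` from rest exceeds `ratio` times the reference
#' deviation: the applied increment for state increments, or the
#' sub-threshold reference response for parameter pulses.
#'
#' @param params,config model; `rest` the stable rest state.
#' @param spec a [perturbation_spec()].
#' @param readout species monitored (default `"Zub"`).
#' @param ratio all-or-none classification ratio (default 10).
#' @param t_end integration horizon (s).
#' @param reference_deviation reference deviation for parameter pulses
#'   (peak deviation of a known sub-threshold response); required there.
#' @return List: `over_threshold` (logical), `peak_deviation`, `trajectory`.
#' @export
classify_response <- function(params, config, rest, spec, readout = "Zub",
                              ratio = 10, t_end = 20000,
                              reference_deviation = NULL) {
  tr <- .perturbed_trajectory(params, config, rest, spec, t_end)
  after <- tr$time >= if (spec$kind == "parameter_pulse") spec$start else 0
  dev <- abs(tr[[readout]][after] - rest[[readout]])
  peak <- max(dev)
  ref <- if (spec$kind == "state_increment") abs(spec$magnitude)
         else {
           if (is.null(reference_deviation))
             stop("parameter_pulse classification needs reference_deviation")
           reference_deviation
         }
  list(over_threshold = ref > 0 && peak > ratio * ref,
       peak_deviation = peak, trajectory = tr)
}

#' Excitability threshold by bisection
#'
#' Finds the all-or-none threshold of an excitable steady state: the
#' perturbation magnitude (state increment) or pulse duration (parameter
#' pulse) separating small, proportionate responses from large stereotyped
#' excursions. The bracket endpoints must classify to opposite response
#' classes.
#'
#' @param params `prc1_params` at an excitable parameter point.
#' @param config short-timescale [model_config()].
#' @param spec a [perturbation_spec()]; for state increments the bracket
#'   varies `magnitude`, for parameter pulses it varies `duration` (the
#'   fold change in `magnitude` is held fixed).
#' @param bracket length-2 interval with opposite response classes at its
#'   ends.
#' @param readout,ratio,t_end see [classify_response()].
#' @param rel_tol relative precision of the bisection (default 1e-3).
#' @param rest optional precomputed rest state; otherwise the stable steady
#'   state is located automatically.
#' @return List: `threshold`, `bracket` (final), `rest`,
#'   `sub_response`, `over_response` (peak deviations at the final
#'   bracket).
#' @export
excitability_threshold <- function(params, config = model_config(), spec,
                                   bracket, readout = "Zub", ratio = 10,
                                   t_end = 20000, rel_tol = 1e-3,
                                   rest = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (is.null(rest)) {
    ss <- find_steady_states(params, config, n_starts = 30, seed = 1)
    stable <- Filter(function(s) s$stability == "stable", ss)
    if (!length(stable)) stop("no stable rest state at this parameter point")
    rest <- stable[[1L]]$state
  }
  probe <- function(x) {
    sp <- spec
    if (spec$kind == "state_increment") sp$magnitude <- x
    else sp$duration <- x
    classify_response(params, config, rest, sp, readout = readout,
                      ratio = ratio, t_end = t_end,
                      reference_deviation =
                        if (spec$kind == "parameter_pulse") ref_dev else NULL)
  }
  ref_dev <- NULL
  if (spec$kind == "parameter_pulse") {
    # reference deviation: response at the lower bracket end
    sp <- spec; sp$duration <- bracket[1]
    tr <- .perturbed_trajectory(params, config, rest, sp, t_end)
    after <- tr$time >= spec$start
    ref_dev <- max(abs(tr[[readout]][after] - rest[[readout]]))
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- probe(lo); r_hi <- probe(hi)
  if (r_lo$over_threshold == r_hi$over_threshold)
    stop("invalid bracket: both ends classify as ",
         if (r_lo$over_threshold) "over-threshold" else "sub-threshold")
  if (r_lo$over_threshold) stop("invalid bracket: lower end over-threshold")
  sub_dev <- r_lo$peak_deviation; over_dev <- r_hi$peak_deviation
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    r <- probe(mid)
    if (r$over_threshold) { hi <- mid; over_dev <- r$peak_deviation }
    else { lo <- mid; sub_dev <- r$peak_deviation }
  }
  list(threshold = (lo + hi) / 2, bracket = c(lo, hi), rest = rest,
       sub_response = sub_dev, over_response = over_dev)
}

#' Overshoot metrics of a perturbation response
#'
#' Per-species peak deviation from baseline, time to peak, and recovery
#' time (first time after the peak when the trajectory re-enters the band
#' of 5 percent of the peak deviation around baseline and stays inside).
#'
#' @param traj a `prc1_trajectory`.
#' @param baseline the pre-perturbation steady state (named vector).
#' @param band recovery band as a fraction of peak deviation (default
#'   0.05).
#' @return Data frame: species, `peak_deviation`, `time_to_peak`,
#'   `recovery_time` (`NA` with `recovered = FALSE` if the trajectory never
#'   settles back).
#' @export
overshoot_metrics <- function(traj, baseline, band = 0.05) {
  config <- attr(traj, "config")
  sp <- species_names(config)
  out <- lapply(sp, function(s) {
    dev <- traj[[s]] - baseline[[s]]
    adev <- abs(dev)
    ip <- which.max(adev)
    peak <- adev[ip]
    if (peak == 0)
      return(data.frame(species = s, peak_deviation = 0, time_to_peak = 0,
                        recovery_time = 0, recovered = TRUE))
    thr <- band * peak
    inside <- adev <= thr
    rec <- NA_real_; recovered <- FALSE
    if (ip < length(adev)) {
      post <- inside[(ip + 1L):length(inside)]
      # last excursion outside the band determines recovery
      out_idx <- which(!post)
      if (!length(out_idx)) { j <- 1L } else if (max(out_idx) < length(post)) {
        j <- max(out_idx) + 1L
      } else j <- NA_integer_
      if (!is.na(j)) {
        rec <- traj$time[ip + j] - traj$time[1L]
        recovered <- TRUE
      }
    }
    data.frame(species = s, peak_deviation = peak,
               time_to_peak = traj$time[ip] - traj$time[1L],
               recovery_time = rec, recovered = recovered)
  })
  do.call(rbind, out)
}
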