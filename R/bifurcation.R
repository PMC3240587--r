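# One- and two-parameter steady-state scans: saddle-node (fold) detection,
# quasi-static hysteresis protocols, and (Bmi1, USP7) regime maps.

.states_at <- function(params, config, value, param_name, n_starts, seed,
                       warm = NULL) {
  p <- set_parameters(params, stats::setNames(value, param_name))
  ss <- suppressWarnings(find_steady_states(p, config, n_starts = n_starts,
                                            seed = seed))
  ss
}

#' One-parameter steady-state scan with fold detection
#'
#' Tracks all steady states over a grid of one scalar parameter (typically
#' `Bmi1_tot`) and locates saddle-node (fold) bifurcations where the number
#' of steady states changes by two, refining each fold by bisection.
#'
#' @param params base `prc1_params` vector.
#' @param config short-timescale [model_config()].
#' @param param_name name of the scanned scalar parameter.
#' @param range length-2 numeric interval.
#' @param n_points number of grid points (>= 3).
#' @param n_starts,seed multi-start controls passed to
#'   [find_steady_states()].
#' @param refine_rel relative precision of the bisection refinement of fold
#'   locations.
#' @return A `prc1_branch` object: list with `branch` (data frame: scanned
#'   value, species columns, `stability`), `folds` (numeric vector of fold
#'   parameter values, named P1, P2, ... in increasing order) and scan
#'   metadata.
#' @export
scan_1d <- function(params, config = model_config(), param_name = "Bmi1_tot",
                    range = c(0, 5), n_points = 41, n_starts = 30, seed = 1,
                    refine_rel = 1e-3) {
  stopifnot(length(range) == 2, n_points >= 3)
  if (!param_name %in% names(params))
    stop("unknown parameter: ", param_name)
  grid <- seq(range[1], range[2], length.out = n_points)
  sp <- species_names(config)
  rows <- list(); counts <- integer(n_points)
  for (i in seq_along(grid)) {
    ss <- .states_at(params, config, grid[i], param_name, n_starts, seed)
    if (!length(ss) && isTRUE(attr(ss, "no_root_found")))
      stop("no steady state found at ", param_name, " = ", grid[i])
    counts[i] <- length(ss)
    for (s in ss) {
      rows[[length(rows) + 1L]] <- data.frame(
        value = grid[i], as.list(s$state[sp]), stability = s$stability,
        check.names = FALSE)
    }
  }
  folds <- numeric(0)
  count_at <- function(x)
    length(.states_at(params, config, x, param_name, n_starts, seed))
  for (i in seq_len(n_points - 1L)) {
    if (counts[i + 1L] == counts[i]) next
    lo <- grid[i]; hi <- grid[i + 1L]
    n_lo <- counts[i]
    while ((hi - lo) > refine_rel * max(abs(hi), 1)) {
      mid <- (lo + hi) / 2
      if (count_at(mid) == n_lo) lo <- mid else hi <- mid
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  folds <- sort(folds)
  if (length(folds)) names(folds) <- paste0("P", seq_along(folds))
  structure(list(branch = do.call(rbind, rows), folds = folds,
                 param_name = param_name, range = range, grid = grid),
            class = "prc1_branch")
}

#' @export
print.prc1_branch <- function(x, ...) {
  cat("Steady-state scan over", x$param_name, "in [",
      x$range[1], ",", x$range[2], "]\n")
  cat("  branch points:", nrow(x$branch), "\n")
  if (length(x$folds)) {
    cat("  folds:", paste(sprintf("%s = %.4g", names(x$folds), x$folds),
                          collapse = ", "), "\n")
  } else cat("  folds: none\n")
  invisible(x)
}

#' Quasi-static hysteresis sweep
#'
#' Sweeps a parameter in small steps, relaxing to the continuation of the
#' currently occupied steady state at each step (warm-started root search),
#' and reports the parameter value at which the tracked branch disappears
#' and the state jumps to a distant branch ("go up"/"go down" switching).
#'
#' @param params base `prc1_params` vector.
#' @param config short-timescale [model_config()].
#' @param param_name scanned parameter name.
#' @param range length-2 interval; the sweep starts at `range[1]` for
#'   `direction = "up"` and at `range[2]` for `"down"`.
#' @param direction `"up"` or `"down"`.
#' @param step sweep step size (in parameter units).
#' @param jump_tol relative state distance between consecutive relaxed
#'   states that counts as a branch jump.
#' @return List with `switched` (logical), `threshold` (parameter value at
#'   the jump, `NA` if no jump: the no-switch flag), and the sweep `path`
#'   data frame.
#' @export
hysteresis_sweep <- function(params, config = model_config(),
                             param_name = "Bmi1_tot", range = c(0.5, 5),
                             direction = c("up", "down"), step = 0.05,
                             jump_tol = 0.25) {
  direction <- match.arg(direction)
  stopifnot(step > 0, length(range) == 2)
  vals <- if (direction == "up") seq(range[1], range[2], by = step)
          else seq(range[2], range[1], by = -step)
  ss0 <- .states_at(params, config, vals[1], param_name, 30, 1)
  if (!length(ss0)) stop("no steady state at sweep start")
  stable0 <- Filter(function(s) s$stability == "stable", ss0)
  if (!length(stable0)) stop("no stable steady state at sweep start")
  cur <- stable0[[1L]]$state
  rn <- .reduced_names(config)
  # when a conserved total is swept, each step's increment enters through
  # the corresponding free pool (material is added to / removed from the
  # unmodified species)
  free_pool <- c(Bmi1_tot = "B", R1B_tot = "R", H2A_tot = "H",
                 USP7_tot = "U")[param_name]
  path <- list()
  threshold <- NA_real_
  prev_v <- vals[1]
  for (v in vals) {
    p <- set_parameters(params, stats::setNames(v, param_name))
    if (!is.na(free_pool) && free_pool %in% names(cur))
      cur[[free_pool]] <- max(cur[[free_pool]] + (v - prev_v), 0)
    prev_v <- v
    y0 <- cur[rn]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = y0, fn = .ss_residual, params = p,
                         config = config, lower = rep(0, length(y0)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) ||
        sqrt(sum(.reduced_rhs(fit$par, p, config)^2)) > 1e-7) {
      # relax dynamically if the warm-started search stalls (saddle-node
      # ghosts just past a fold are slow: integrate in chunks until the
      # flow leaves the bottleneck, then polish)
      nxt <- cur
      for (chunk in 1:6) {
        tr <- simulate_timecourse(p, config, nxt, t_end = 5e4, n_out = 6)
        nxt <- pmax(unlist(tr[nrow(tr), species_names(config)]), 0)
        fit2 <- tryCatch(
          minpack.lm::nls.lm(par = nxt[rn], fn = .ss_residual, params = p,
                             config = config, lower = rep(0, length(rn)),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
          error = function(e) NULL)
        if (!is.null(fit2) &&
            sqrt(sum(.reduced_rhs(fit2$par, p, config)^2)) < 1e-8) {
          nxt <- pmax(.full_from_reduced(fit2$par, p, config), 0)
          break
        }
      }
    } else nxt <- pmax(.full_from_reduced(fit$par, p, config), 0)
    d <- sqrt(sum((nxt - cur)^2)) / (1 + sqrt(sum(cur^2)))
    path[[length(path) + 1L]] <- data.frame(value = v, as.list(nxt),
                                            jump = d > jump_tol,
                                            check.names = FALSE)
    if (is.na(threshold) && d > jump_tol) threshold <- v
    cur <- nxt
  }
  list(switched = !is.na(threshold), threshold = threshold,
       direction = direction, path = do.call(rbind, path))
}

#' Two-parameter regime map over Bmi1 and USP7 abundance
#'
#' Classifies the dynamical regime ([classify_regime()]) on a rectangular
#' grid of total Bmi1 and total USP7 abundances.
#'
#' @param params base `prc1_params` vector.
#' @param config short-timescale [model_config()].
#' @param bmi1_range,usp7_range axis intervals (normalized units).
#' @param resolution length-2 integer vector: grid points per axis.
#' @param n_starts,seed multi-start controls.
#' @return A `prc1_regime_map`: data frame with `Bmi1_tot`, `USP7_tot`,
#'   `regime`, `n_stable`, `n_unstable`.
#' @export
regime_map <- function(params, config = model_config(),
                       bmi1_range = c(0, 6), usp7_range = c(0, 4),
                       resolution = c(13, 9), n_starts = 25, seed = 1) {
  bg <- seq(bmi1_range[1], bmi1_range[2], length.out = resolution[1])
  ug <- seq(usp7_range[1], usp7_range[2], length.out = resolution[2])
  rows <- list()
  for (u in ug) for (b in bg) {
    p <- set_parameters(params, Bmi1_tot = b, USP7_tot = u)
    lab <- tryCatch({
      ss <- suppressWarnings(find_steady_states(p, config,
                                                n_starts = n_starts,
                                                seed = seed))
      if (!length(ss)) "other" else classify_regime(ss)
    }, error = function(e) "other")
    cnt <- attr(lab, "counts")
    rows[[length(rows) + 1L]] <- data.frame(
      Bmi1_tot = b, USP7_tot = u, regime = as.character(lab),
      n_stable = if (is.null(cnt)) NA_integer_ else cnt[["stable"]],
      n_unstable = if (is.null(cnt)) NA_integer_ else cnt[["unstable"]])
  }
  structure(do.call(rbind, rows), class = c("prc1_regime_map", "data.frame"))
}

#' @export
print.prc1_regime_map <- function(x, ...) {
  cat("Regime map (", nrow(x), "cells )\n")
  print(table(x$regime))
  invisible(x)
}
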