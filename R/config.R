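#' Model configuration for the Ring1B/Bmi1 ubiquitination network
#'
#' A `prc1_config` object selects which formulation of the kinetic scheme is
#' used by every other function in the package: the Michaelis-Menten (MM)
#' reduction, in which deubiquitination of the self-ubiquitinated
#' Ring1B-Bmi1 complex is a saturable lumped reaction, or the mass-action
#' (MA) formulation, in which the deubiquitinase (USP7) and its complex with
#' ubiquitinated substrate are explicit species and all USP7-catalysed
#' deubiquitinations are second order in free USP7.
#'
#' @param variant `"MM"` (Michaelis-Menten reduction, 10 species) or
#'   `"mass_action"` (elementary-step description, 12 species: free USP7 and
#'   the USP7-substrate complex are explicit).
#' @param timescale `"short"` (sub-hour: protein synthesis and proteasomal
#'   degradation neglected, totals conserved) or `"long"` (synthesis and
#'   degradation of Bmi1 and Ring1B included; requires `sB`, `sR`, `dBd`,
#'   `dRd` in the parameter set, see [make_long_timescale()]).
#' @param reaction10_saturable logical; if `TRUE` deubiquitination of free
#'   self-ubiquitinated Ring1B (reaction 10) follows saturable
#'   Michaelis-Menten kinetics with constant `KM10` instead of apparent
#'   first-order kinetics. Default `FALSE`.
#' @param feedback_enabled logical; if `FALSE` the autocatalytic
#'   self-ubiquitination feedback is ablated (`k6a` and `k9a` treated as 0).
#' @param bmi1_dub_usp7_scaled logical; if `TRUE` the deubiquitination of
#'   ubiquitinated Bmi1 (reaction 2, catalysed by an unidentified DUB) is
#'   scaled by total USP7 like the Ring1B-directed reactions; if `FALSE`
#'   (default) its rate is `k2 * Bd`, independent of USP7.
#' @param unit_system `"normalized"` (concentrations in units of the
#'   reference Ring1B abundance, 100 nM) or `"nM"`. All internal computation
#'   is in normalized units; nM inputs are converted once at the interface.
#'
#' @return An object of class `prc1_config` (a list with the validated
#'   fields above).
#' @seealso [default_parameters()], [ode_rhs()], [simulate_timecourse()]
#' @export
#' @examples
#' cfg <- model_config()
#' cfg_ma <- model_config(variant = "mass_action")
model_config <- function(variant = c("MM", "mass_action"),
                         timescale = c("short", "long"),
                         reaction10_saturable = FALSE,
                         feedback_enabled = TRUE,
                         bmi1_dub_usp7_scaled = FALSE,
                         unit_system = c("normalized", "nM")) {
  variant <- match.arg(variant)
  timescale <- match.arg(timescale)
  unit_system <- match.arg(unit_system)
  stopifnot(is.logical(reaction10_saturable), length(reaction10_saturable) == 1L,
            is.logical(feedback_enabled), length(feedback_enabled) == 1L,
            is.logical(bmi1_dub_usp7_scaled), length(bmi1_dub_usp7_scaled) == 1L)
  structure(
    list(variant = variant, timescale = timescale,
         reaction10_saturable = reaction10_saturable,
         feedback_enabled = feedback_enabled,
         bmi1_dub_usp7_scaled = bmi1_dub_usp7_scaled,
         unit_system = unit_system),
    class = "prc1_config")
}

#' @export
print.prc1_config <- function(x, ...) {
  cat("Ring1B/Bmi1 model configuration\n")
  cat("  variant:             ", x$variant, "\n")
  cat("  timescale:           ", x$timescale, "\n")
  cat("  reaction 10 saturable:", x$reaction10_saturable, "\n")
  cat("  autocatalytic feedback:", x$feedback_enabled, "\n")
  cat("  unit system:         ", x$unit_system, "\n")
  invisible(x)
}

#' Species names for a model configuration
#'
#' Order is fixed and used by every state vector in the package:
#' `B` free Bmi1, `Bd` degradation-targeted ubiquitinated Bmi1, `R` free
#' Ring1B, `Rd` degradation-targeted ubiquitinated Ring1B, `Z` Bmi1-Ring1B
#' complex, `Zub` self-ubiquitinated complex (strongest H2A ligase), `Ra`
#' active free self-ubiquitinated Ring1B (from Zub dissociation), `Ru`
#' weakly active free self-ubiquitinated Ring1B, `H` histone H2A, `Hu`
#' monoubiquitinated H2A. The mass-action variant appends `U` (free USP7)
#' and `C7` (USP7-Zub complex).
#'
#' @param config a [model_config()] object.
#' @return Character vector of species names.
#' @export
species_names <- function(config) {
  base <- c("B", "Bd", "R", "Rd", "Z", "Zub", "Ra", "Ru", "H", "Hu")
  if (config$variant == "mass_action") c(base, "U", "C7") else base
}

#' Construct a state vector
#'
#' Builds a full named state vector (all species of the configured variant),
#' defaulting unspecified species to zero.
#'
#' @param config a [model_config()] object.
#' @param ... named species concentrations (normalized units unless the
#'   config says nM).
#' @return Named numeric vector over [species_names()].
#' @export
#' @examples
#' make_state(model_config(), B = 2.5, R = 1)
make_state <- function(config, ...) {
  vals <- c(...)
  sp <- species_names(config)
  state <- stats::setNames(numeric(length(sp)), sp)
  if (length(vals)) {
    bad <- setdiff(names(vals), sp)
    if (length(bad))
      stop("unknown species for this variant: ", paste(bad, collapse = ", "))
    state[names(vals)] <- vals
  }
  if (any(state < 0)) stop("species concentrations must be non-negative")
  state
}

.check_state <- function(state, config) {
  sp <- species_names(config)
  if (is.null(names(state)) || !all(sp %in% names(state)))
    stop("state must be a named vector containing all of: ",
         paste(sp, collapse = ", "))
  state <- state[sp]
  if (any(state < -1e-12))
    stop("negative concentration in state: ",
         paste(sp[state < -1e-12], collapse = ", "))
  pmax(state, 0)
}
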