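# Structured configuration files (YAML key-value), result serialization
# and provenance records.

.known_config_keys <- c("variant", "timescale", "reaction10_saturable",
                        "feedback_enabled", "bmi1_dub_usp7_scaled",
                        "unit_system")
.known_run_keys <- c("model", "parameters", "initial_state", "command",
                     "options", "seed", "output_dir")

#' Write a model configuration, parameter set and initial state to file
#'
#' Serializes to a single YAML document with sections `model`,
#' `parameters` and optionally `initial_state`. Units follow the
#' `unit_system` of the model section.
#'
#' @param path output file path.
#' @param params `prc1_params` vector.
#' @param config [model_config()] object.
#' @param init optional named initial state.
#' @param extra optional named list merged into the document (e.g. `seed`,
#'   `command`, `options`, `output_dir`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, params, config = model_config(),
                               init = NULL, extra = NULL) {
  doc <- list(
    model = list(variant = config$variant, timescale = config$timescale,
                 reaction10_saturable = config$reaction10_saturable,
                 feedback_enabled = config$feedback_enabled,
                 bmi1_dub_usp7_scaled = config$bmi1_dub_usp7_scaled,
                 unit_system = config$unit_system),
    parameters = as.list(unclass(params)))
  if (!is.null(init)) doc$initial_state <- as.list(init)
  if (!is.null(extra)) doc <- c(doc, extra)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a model configuration file
#'
#' Parses and validates a YAML configuration written by
#' [write_model_config()] (or by hand). Unknown keys are rejected with the
#' offending key named; negative rate constants and incomplete parameter
#' sets are configuration errors. nM-unit documents are converted to the
#' internal normalized units on load.
#'
#' @param path file path.
#' @return List with `config` (`prc1_config`), `params` (`prc1_params`,
#'   normalized units), `init` (named state or `NULL`), and `run` (any
#'   further run options present).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$model)) stop("configuration error: missing 'model' section")
  bad <- setdiff(names(doc$model), .known_config_keys)
  if (length(bad))
    stop("configuration error: unknown model key(s): ",
         paste(bad, collapse = ", "))
  bad2 <- setdiff(names(doc), .known_run_keys)
  if (length(bad2))
    stop("configuration error: unknown top-level key(s): ",
         paste(bad2, collapse = ", "))
  m <- doc$model
  config <- model_config(
    variant = if (is.null(m$variant)) "MM" else m$variant,
    timescale = if (is.null(m$timescale)) "short" else m$timescale,
    reaction10_saturable = isTRUE(m$reaction10_saturable),
    feedback_enabled = !isFALSE(m$feedback_enabled),
    bmi1_dub_usp7_scaled = isTRUE(m$bmi1_dub_usp7_scaled),
    unit_system = if (is.null(m$unit_system)) "normalized" else m$unit_system)
  if (is.null(doc$parameters))
    stop("configuration error: missing 'parameters' section")
  pv <- unlist(doc$parameters)
  if (!is.numeric(pv)) stop("configuration error: non-numeric parameter value")
  neg <- names(pv)[pv < 0]
  if (length(neg))
    stop("configuration error: negative value for ",
         paste(neg, collapse = ", "))
  params <- structure(pv, class = "prc1_params",
                      variant = config$variant, source = path,
                      unit_system = config$unit_system)
  if (config$unit_system == "nM") {
    params <- convert_units(params, "normalized")
    config$unit_system <- "normalized"
  }
  validate_parameters(params, config)
  init <- NULL
  if (!is.null(doc$initial_state)) {
    iv <- unlist(doc$initial_state)
    if (any(iv < 0)) stop("configuration error: negative initial concentration")
    if (identical(attr(params, "unit_system"), "normalized") &&
        identical(m$unit_system, "nM")) iv <- iv / 100
    init <- do.call(make_state, c(list(config), as.list(iv)))
  }
  run <- doc[setdiff(names(doc), c("model", "parameters", "initial_state"))]
  list(config = config, params = params, init = init, run = run)
}

#' Write a trajectory (or any data frame) as CSV
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a scalar report as JSON
#' @param x list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# serializable steady-state report (eigenvalues as re/im pairs)
.steady_state_report <- function(ss) {
  lapply(ss, function(s) list(
    state = as.list(s$state),
    eigenvalues = lapply(s$eigenvalues, function(e)
      list(re = Re(e), im = Im(e))),
    stability = s$stability, marginal = s$marginal,
    residual_norm = s$residual_norm))
}

.provenance <- function(path_config, seed) {
  list(package = "prc1dyn",
       version = as.character(utils::packageVersion("prc1dyn")),
       config_sha = if (file.exists(path_config))
         as.character(tools::md5sum(path_config)) else NA_character_,
       seed = seed)
}
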