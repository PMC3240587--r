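# SBML Level 3 Version 2 export of the reaction network.
#
# The document is built directly with xml2 (species, compartments, global
# parameters, reactions with MathML kinetic laws). Reversible reactions
# are exported as single reversible SBML reactions whose kinetic law is
# the net forward rate.

.sbml_math <- function(expr_str) {
  # infix -> MathML for the restricted grammar used by the rate laws:
  # products of identifiers/numbers, sums, and a single division
  # (Michaelis-Menten). Parsed via R's own parser.
  to_mathml <- function(e) {
    if (is.numeric(e)) return(paste0("<cn>", format(e, digits = 15), "</cn>"))
    if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      args <- lapply(as.list(e)[-1L], to_mathml)
      sym <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "(" = NA_character_,
                    stop("unsupported operator in kinetic law: ", op))
      if (op == "(") return(args[[1L]])
      paste0("<apply><", sym, "/>", paste0(unlist(args), collapse = ""),
             "</apply>")
    } else stop("unsupported kinetic-law expression")
  }
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         to_mathml(str2lang(expr_str)), "</math>")
}

.sbml_rate_laws <- function(config, km1 = FALSE, km3 = FALSE) {
  A <- "(wZ * Zub + wRa * Ra + wRu * Ru)"
  fb <- config$feedback_enabled
  r6 <- if (fb) paste0("(k6 + k6a * ", A, ") * Z") else "k6 * Z"
  r9 <- if (fb) paste0("(k9 + k9a * ", A, ") * R") else "k9 * R"
  mm <- config$variant == "MM"
  U <- if (mm) "USP7_tot" else "U"
  r10 <- if (config$reaction10_saturable)
    paste0("k10 * ", U, " * Ru / (KM10 + Ru)")
  else paste0("k10 * ", U, " * Ru")
  laws <- list(
    r1 = list(reac = "B", prod = "Bd",
              law = if (km1) "k1 * B * KM1 / (KM1 + B)" else "k1 * B",
              rev = FALSE),
    r2 = list(reac = "Bd", prod = "B",
              law = if (config$bmi1_dub_usp7_scaled) "k2 * USP7_tot * Bd"
                    else "k2 * Bd", rev = FALSE),
    r3 = list(reac = "R", prod = "Rd",
              law = if (km3) "k3 * R * KM3 / (KM3 + R)" else "k3 * R",
              rev = FALSE),
    r4 = list(reac = "Rd", prod = "R", law = paste0("k4 * ", U, " * Rd"),
              rev = FALSE),
    r5 = list(reac = c("B", "R"), prod = "Z",
              law = "k5f * B * R - k5r * Z", rev = TRUE),
    r6 = list(reac = "Z", prod = "Zub", law = r6, rev = FALSE),
    r8 = list(reac = "Zub", prod = c("B", "Ra"),
              law = "k8f * Zub - k8r * B * Ra", rev = TRUE),
    r9 = list(reac = "R", prod = "Ru", law = r9, rev = FALSE),
    r10 = list(reac = "Ru", prod = "R", law = r10, rev = FALSE),
    r11 = list(reac = "Ra", prod = "R",
               law = paste0("k11 * ", U, " * Ra"), rev = FALSE),
    r12 = list(reac = "H", prod = "Hu",
               law = "(cZ * Zub + cRa * Ra + cRu * Ru) * H", rev = FALSE),
    r13 = list(reac = "Hu", prod = "H", law = "k13 * Hu", rev = FALSE))
  if (mm) {
    laws$r7 <- list(reac = "Zub", prod = "Z",
                    law = "k7 * USP7_tot * Zub / (KM7 + Zub)", rev = FALSE)
  } else {
    laws$r7bind <- list(reac = c("Zub", "U"), prod = "C7",
                        law = "k7f * U * Zub - k7r * C7", rev = TRUE)
    laws$r7cat <- list(reac = "C7", prod = c("Z", "U"), law = "k7cat * C7",
                       rev = FALSE)
  }
  if (config$timescale == "long") {
    laws$syn_B <- list(reac = character(0), prod = "B", law = "sB",
                       rev = FALSE)
    laws$deg_Bd <- list(reac = "Bd", prod = character(0), law = "dBd * Bd",
                        rev = FALSE)
    laws$syn_R <- list(reac = character(0), prod = "R", law = "sR",
                       rev = FALSE)
    laws$deg_Rd <- list(reac = "Rd", prod = character(0), law = "dRd * Rd",
                        rev = FALSE)
  }
  laws
}

#' Export the model as SBML Level 3
#'
#' Writes an SBML Level 3 Version 2 document containing every species of
#' the configured variant, all reactions with their kinetic laws (MathML),
#' and all rate constants as global parameters. The mass-action variant
#' includes the explicit USP7 and USP7-substrate complex species and the
#' elementary deubiquitination steps.
#'
#' @param params `prc1_params` (normalized units).
#' @param config [model_config()].
#' @param path output file path.
#' @param init optional named initial state for species
#'   `initialConcentration`s (defaults to zeros).
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(params, config = model_config(), path,
                        init = NULL, model_id = "ring1b_bmi1_h2a") {
  validate_parameters(params, config)
  sp <- species_names(config)
  if (is.null(init)) init <- make_state(config)
  laws <- .sbml_rate_laws(config, km1 = is.finite(params[["KM1"]]),
                          km3 = is.finite(params[["KM3"]]))
  used <- unique(unlist(regmatches(
    vapply(laws, `[[`, character(1), "law"),
    gregexpr("[A-Za-z_][A-Za-z0-9_]*", vapply(laws, `[[`, character(1),
                                              "law")))))
  pars <- setdiff(intersect(used, names(params)), sp)

  species_xml <- paste0(vapply(sp, function(s) sprintf(
    paste0("<species id=\"%s\" compartment=\"cell\" ",
           "initialConcentration=\"%s\" hasOnlySubstanceUnits=\"false\" ",
           "boundaryCondition=\"false\" constant=\"false\"/>"),
    s, format(init[[s]], digits = 15)), character(1)), collapse = "")
  params_xml <- paste0(vapply(pars, function(k) sprintf(
    "<parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
    k, format(params[[k]], digits = 15)), character(1)), collapse = "")
  rxn_xml <- paste0(vapply(names(laws), function(id) {
    l <- laws[[id]]
    refs <- function(tag, spv) {
      if (!length(spv)) return("")
      paste0("<listOf", tag, "s>",
             paste0(sprintf(paste0("<speciesReference species=\"%s\" ",
                                   "stoichiometry=\"1\" constant=\"true\"/>"),
                            spv), collapse = ""),
             "</listOf", tag, "s>")
    }
    sprintf(paste0("<reaction id=\"%s\" reversible=\"%s\">%s%s",
                   "<kineticLaw>%s</kineticLaw></reaction>"),
            id, tolower(as.character(l$rev)), refs("Reactant", l$reac),
            refs("Product", l$prod), .sbml_math(l$law))
  }, character(1)), collapse = "")

  doc_str <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
    "level=\"3\" version=\"2\">",
    "<model id=\"", model_id, "\" name=\"Ring1B/Bmi1/H2A ubiquitination\">",
    "<listOfCompartments>",
    "<compartment id=\"cell\" spatialDimensions=\"3\" size=\"1\" ",
    "constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>", species_xml, "</listOfSpecies>",
    "<listOfParameters>", params_xml, "</listOfParameters>",
    "<listOfReactions>", rxn_xml, "</listOfReactions>",
    "</model></sbml>")
  doc <- xml2::read_xml(doc_str)  # parse check before writing
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back the stoichiometry of an SBML export
#'
#' Parses an SBML file written by [export_sbml()] and reconstructs its
#' species-by-reaction stoichiometry matrix (net, reactants negative).
#' Used for round-trip validation.
#'
#' @param path SBML file path.
#' @return Integer matrix species x reactions.
#' @export
read_sbml_stoichiometry <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  spn <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rn <- xml2::xml_attr(rxns, "id")
  N <- matrix(0L, length(spn), length(rn), dimnames = list(spn, rn))
  for (i in seq_along(rxns)) {
    for (r in xml2::xml_find_all(rxns[[i]],
                                 ".//s:listOfReactants/s:speciesReference",
                                 ns)) {
      s <- xml2::xml_attr(r, "species")
      N[s, i] <- N[s, i] - as.integer(as.numeric(
        xml2::xml_attr(r, "stoichiometry")))
    }
    for (r in xml2::xml_find_all(rxns[[i]],
                                 ".//s:listOfProducts/s:speciesReference",
                                 ns)) {
      s <- xml2::xml_attr(r, "species")
      N[s, i] <- N[s, i] + as.integer(as.numeric(
        xml2::xml_attr(r, "stoichiometry")))
    }
  }
  N
}
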