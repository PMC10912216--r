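## External interfaces: a minimal SBML Level-3 subset (written and read with
## xml2, round-tripping the package's own mass-action networks), PEtab-style
## TSV tables for parameters / conditions / measurements, and a YAML study
## configuration.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a network to SBML (Level 3 subset)
#'
#' Species are written with initial amounts from `params`, reactions as
#' irreversible mass-action kinetic laws (product of the rate constant, an
#' optional abundance factor and all reactant/modifier species).
#'
#' @param net A `reaction_network`.
#' @param params Named native-scale parameter vector.
#' @param file Output path (`.xml`).
#' @param model_id Model identifier.
#' @return Invisibly, the file path.
#' @export
sbml_write <- function(net, params, file, model_id = "hgf_signaling") {
  x0 <- initial_state(net, params, dose = 0)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "2")
  model <- xml2::xml_add_child(doc, "model", id = model_id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  lsp <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    xml2::xml_add_child(lsp, "species", id = s$name, compartment = "cell",
                        initialAmount = format(x0[[s$name]], digits = 15),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = if (s$name == "HGF") "true"
                        else "false",
                        constant = "false")
  }
  lpar <- xml2::xml_add_child(model, "listOfParameters")
  for (p in names(params))
    xml2::xml_add_child(lpar, "parameter", id = p,
                        value = format(params[[p]], digits = 15),
                        constant = "true")
  lrx <- xml2::xml_add_child(model, "listOfReactions")
  for (r in net$reactions) {
    rx <- xml2::xml_add_child(lrx, "reaction", id = r$name,
                              reversible = "false")
    if (length(r$reactants)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in names(r$reactants))
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = as.character(r$reactants[[s]]),
                            constant = "true")
    }
    if (length(r$products)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(r$products))
        xml2::xml_add_child(lpr, "speciesReference", species = s,
                            stoichiometry = as.character(r$products[[s]]),
                            constant = "true")
    }
    if (length(r$modifiers)) {
      lmo <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in r$modifiers)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = s)
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    factors <- c(r$rate_parameter,
                 if (!is.na(r$abundance_factor)) r$abundance_factor,
                 rep(names(r$reactants), r$reactants), r$modifiers)
    if (length(factors) == 1) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Import a network from the SBML subset written by [sbml_write()]
#'
#' @param file SBML file path.
#' @return List with `net` (a `reaction_network`) and `params` (named
#'   native-scale vector).
#' @export
sbml_read <- function(file) {
  doc <- xml2::xml_ns_strip(xml2::read_xml(file))
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_names <- xml2::xml_attr(sp_nodes, "id")
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  params <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(rn) {
    get_sp <- function(path) {
      nodes <- xml2::xml_find_all(rn, path)
      ids <- xml2::xml_attr(nodes, "species")
      st <- as.integer(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1L
      stats::setNames(st, ids)
    }
    cis <- xml2::xml_text(xml2::xml_find_all(rn, ".//kineticLaw//ci"))
    cis_par <- cis[cis %in% names(params)]
    reaction(xml2::xml_attr(rn, "id"),
             reactants = get_sp(".//listOfReactants/speciesReference"),
             products = get_sp(".//listOfProducts/speciesReference"),
             modifiers = unname(names(get_sp(
               ".//listOfModifiers/modifierSpeciesReference"))),
             rate_parameter = cis_par[1],
             abundance_factor = if (length(cis_par) > 1) cis_par[2]
             else NA_character_)
  })
  species_list <- lapply(sp_names, function(nm)
    species(nm, "kinase",
            if (startsWith(nm, "p") || endsWith(nm, "_act") ||
                endsWith(nm, "_i")) "derived" else "free-parameter"))
  list(net = reaction_network(species_list, reactions), params = params)
}

#' Write PEtab-style TSV tables for a fit setup
#'
#' Emits `parameters.tsv` (log-scale nominal values and estimate flags),
#' `conditions.tsv` (condition-specific parameter overrides and the HGF
#' dose), and `measurements.tsv` (aligned data with noise values).
#'
#' @param dir Output directory (created if needed).
#' @param params Named native-scale base parameter vector.
#' @param cmap A `condition_map`.
#' @param data Aligned measurement `data.frame` (target, condition, dose,
#'   time, y, sigma).
#' @param estimate Character vector of parameters flagged for estimation.
#' @return Invisibly, the directory.
#' @export
petab_write <- function(dir, params, cmap, data,
                        estimate = dysregulated_parameters()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ptab <- data.frame(parameterId = names(params), parameterScale = "log",
                     nominalValue = unname(params),
                     estimate = as.integer(names(params) %in% estimate))
  utils::write.table(ptab, file.path(dir, "parameters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  conds <- lapply(cmap$conditions, function(cn) {
    ov <- cmap$overrides[[cn]]
    row <- data.frame(conditionId = cn)
    for (p in cmap$specific)
      row[[p]] <- if (!is.null(ov) && p %in% names(ov)) ov[[p]]
        else params[[p]]
    inp <- cmap$inputs[[cn]]
    row$hgf_dose <- if (!is.null(inp)) inp$dose else NA_real_
    row
  })
  utils::write.table(do.call(rbind, conds), file.path(dir, "conditions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mtab <- data.frame(observableId = data$target,
                     simulationConditionId = data$condition,
                     time = data$time, hgf_dose = data$dose,
                     measurement = data$y, noiseParameters = data$sigma)
  utils::write.table(mtab, file.path(dir, "measurements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read PEtab-style tables written by [petab_write()]
#'
#' @param dir Directory containing the TSV files.
#' @return List with `parameters`, `conditions`, `measurements` (the latter
#'   converted back to the aligned-data column convention).
#' @export
petab_read <- function(dir) {
  ptab <- utils::read.delim(file.path(dir, "parameters.tsv"))
  ctab <- utils::read.delim(file.path(dir, "conditions.tsv"))
  mtab <- utils::read.delim(file.path(dir, "measurements.tsv"))
  list(parameters = ptab, conditions = ctab,
       measurements = data.frame(target = mtab$observableId,
                                 condition = mtab$simulationConditionId,
                                 dose = mtab$hgf_dose, time = mtab$time,
                                 y = mtab$measurement,
                                 sigma = mtab$noiseParameters))
}

#' Read a YAML study configuration
#'
#' Recognized fields: `hypothesis` (diet-specific parameter names or one of
#' the named hypotheses), `doses`, `times`, `targets`, `n_replicates`.
#'
#' @param file YAML path.
#' @return List with a validated `design` (see [default_blot_design()]) and
#'   `hypothesis`.
#' @export
read_study_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  design <- default_blot_design()
  if (!is.null(cfg$targets)) design$targets <- cfg$targets
  if (!is.null(cfg$doses)) design$dose_response$doses <- as.numeric(cfg$doses)
  if (!is.null(cfg$times)) design$time_course$times <- as.numeric(cfg$times)
  if (!is.null(cfg$n_replicates)) design$n_replicates <- cfg$n_replicates
  hyp <- if (is.null(cfg$hypothesis)) "dysregulated" else cfg$hypothesis
  list(design = design, hypothesis = hyp)
}
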