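#' @useDynLib hgfdyn, .registration = TRUE
NULL

#' Define a model species
#'
#' @param name Unique species identifier.
#' @param role One of `"ligand"`, `"receptor"`, `"kinase"`, `"complex"`,
#'   `"substrate"`.
#' @param initial_source Either `"free-parameter"` (the pre-stimulation level is
#'   set by a protein-abundance parameter) or `"derived"` (zero before
#'   pre-equilibration; phosphorylated/active forms).
#' @return A `list` of class `hgf_species`.
#' @export
species <- function(name, role = c("kinase", "ligand", "receptor", "complex",
                                   "substrate"),
                    initial_source = c("derived", "free-parameter")) {
  role <- match.arg(role)
  initial_source <- match.arg(initial_source)
  structure(list(name = name, role = role, initial_source = initial_source),
            class = "hgf_species")
}

#' Define a mass-action reaction
#'
#' The rate is the product of the rate constant, all reactant concentrations and
#' all modifier concentrations (modifiers appear in the rate but are not
#' consumed). An optional `abundance_factor` names a protein-abundance parameter
#' that multiplies the rate constant; this realizes steady-state-style
#' parameter transformations for production reactions.
#'
#' @param name Reaction identifier.
#' @param reactants,products Named integer vectors of stoichiometric
#'   coefficients (names are species).
#' @param modifiers Character vector of modifier species.
#' @param rate_parameter Name of the rate-constant parameter.
#' @param abundance_factor Optional name of an abundance parameter multiplying
#'   the rate constant, or `NA`.
#' @return A `list` of class `hgf_reaction`.
#' @export
reaction <- function(name, reactants = integer(), products = integer(),
                     modifiers = character(), rate_parameter,
                     abundance_factor = NA_character_) {
  stoich_ok <- function(v) length(v) == 0 ||
    (all(v > 0) && all(v == round(v)) && !is.null(names(v)))
  if (!stoich_ok(reactants) || !stoich_ok(products))
    stop("stoichiometric coefficients must be positive integers with names")
  structure(list(name = name,
                 reactants = reactants, products = products,
                 modifiers = modifiers, rate_parameter = rate_parameter,
                 abundance_factor = abundance_factor),
            class = "hgf_reaction")
}

#' Assemble a reaction network
#'
#' @param species_list List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `list` of class `reaction_network` with the species table, the
#'   reaction list and the integer stoichiometry matrix (species x reactions).
#' @export
reaction_network <- function(species_list, reactions) {
  sp_names <- vapply(species_list, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("species names must be unique")
  ns <- length(sp_names)
  nr <- length(reactions)
  S <- matrix(0L, ns, nr, dimnames = list(sp_names,
                                          vapply(reactions, `[[`, "", "name")))
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    all_sp <- c(names(r$reactants), names(r$products), r$modifiers)
    if (!all(all_sp %in% sp_names))
      stop("reaction ", r$name, " references unknown species: ",
           paste(setdiff(all_sp, sp_names), collapse = ", "))
    for (s in names(r$reactants)) S[s, j] <- S[s, j] - as.integer(r$reactants[[s]])
    for (s in names(r$products))  S[s, j] <- S[s, j] + as.integer(r$products[[s]])
  }
  structure(list(species = data.frame(
    name = sp_names,
    role = vapply(species_list, `[[`, "", "role"),
    initial_source = vapply(species_list, `[[`, "", "initial_source"),
    stringsAsFactors = FALSE),
    reactions = reactions,
    stoichiometry_matrix = S),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$species), "species,",
      length(x$reactions), "reactions,",
      length(conserved_moieties(x)), "conserved moieties\n")
  invisible(x)
}

#' Names of the eleven modeled protein abundances
#' @return Character vector of abundance parameter names (`conc_*`).
#' @export
abundance_parameters <- function() {
  paste0("conc_", c("MET", "MEK", "ERK", "PI3K", "AKT", "TSC", "mTORC1",
                    "S6K", "S6", "mTORC2", "IRS1"))
}

#' Names of the dynamical parameters of the reference network
#'
#' 26 mass-action rate constants (one per reaction; the MET and IRS1 production
#' reactions use turnover constants multiplied by the respective abundance) plus
#' the HGF input conversion factor `hgf_scale` (ng/ml to molecules/cell
#' equivalents): 27 in total.
#'
#' @param net A `reaction_network`; defaults to the reference build.
#' @return Character vector of parameter names.
#' @export
dynamical_parameters <- function(net = build_hgf_network()) {
  c(unique(vapply(net$reactions, `[[`, "", "rate_parameter")), "hgf_scale")
}

#' Build the reference HGF signal-transduction network
#'
#' Mass-action network of HGF-induced MET activation feeding the MAPK cascade
#' (MEK/ERK), the PI3K-AKT axis (T308 then S473 phosphorylation) and mTOR
#' signaling (TSC-gated mTORC1 -> S6K -> S6; PI3K-induced mTORC2), with the two
#' S6K negative feedbacks on mTORC2 and IRS1. The reference build has 23
#' species and 26 reactions. HGF enters as a constant (non-depleting) modifier
#' switched on at stimulation.
#'
#' @return A `reaction_network`.
#' @export
build_hgf_network <- function() {
  sp <- list(
    species("HGF",        "ligand",   "derived"),
    species("MET",        "receptor", "free-parameter"),
    species("pMET",       "receptor", "derived"),
    species("MEK",        "kinase",   "free-parameter"),
    species("pMEK",       "kinase",   "derived"),
    species("ERK",        "kinase",   "free-parameter"),
    species("pERK",       "kinase",   "derived"),
    species("PI3K",       "kinase",   "free-parameter"),
    species("PI3K_act",   "kinase",   "derived"),
    species("AKT",        "kinase",   "free-parameter"),
    species("pAKT",       "kinase",   "derived"),
    species("ppAKT",      "kinase",   "derived"),
    species("TSC",        "complex",  "free-parameter"),
    species("TSC_i",      "complex",  "derived"),
    species("mTORC1",     "complex",  "free-parameter"),
    species("mTORC1_act", "complex",  "derived"),
    species("S6K",        "kinase",   "free-parameter"),
    species("pS6K",       "kinase",   "derived"),
    species("S6",         "substrate","free-parameter"),
    species("pS6",        "substrate","derived"),
    species("mTORC2",     "complex",  "free-parameter"),
    species("mTORC2_act", "complex",  "derived"),
    species("IRS1_act",   "substrate","free-parameter"))

  rx <- function(name, from = NULL, to = NULL, mod = character(), k,
                 abund = NA_character_) {
    reaction(name,
             reactants = if (is.null(from)) integer() else
               stats::setNames(1L, from),
             products = if (is.null(to)) integer() else stats::setNames(1L, to),
             modifiers = mod, rate_parameter = k, abundance_factor = abund)
  }
  rxns <- list(
    rx("prod_MET",     to = "MET",                      k = "k_turn_MET",
       abund = "conc_MET"),
    rx("deg_MET",      from = "MET",                    k = "k_deg_MET"),
    rx("basal_p_MET",  from = "MET",  to = "pMET",      k = "k_basal_MET"),
    rx("hgf_p_MET",    from = "MET",  to = "pMET", mod = "HGF",
       k = "k_hgf_MET"),
    rx("deg_pMET",     from = "pMET",                   k = "k_deg_pMET"),
    rx("p_MEK",        from = "MEK",  to = "pMEK", mod = "pMET",
       k = "k_phos_MEK"),
    rx("dp_MEK",       from = "pMEK", to = "MEK",       k = "k_dephos_MEK"),
    rx("p_ERK",        from = "ERK",  to = "pERK", mod = "pMEK",
       k = "k_phos_ERK"),
    rx("dp_ERK",       from = "pERK", to = "ERK",       k = "k_dephos_ERK"),
    rx("act_PI3K",     from = "PI3K", to = "PI3K_act",
       mod = c("pMET", "IRS1_act"),                     k = "k_act_PI3K"),
    rx("deact_PI3K",   from = "PI3K_act", to = "PI3K",  k = "k_deact_PI3K"),
    rx("p_AKT_T308",   from = "AKT",  to = "pAKT", mod = "PI3K_act",
       k = "k_phos_AKT"),
    rx("p_AKT_S473",   from = "pAKT", to = "ppAKT", mod = "mTORC2_act",
       k = "k_phos2_AKT"),
    rx("dp_AKT",       from = "ppAKT", to = "AKT",      k = "k_dephos_AKT"),
    rx("inact_TSC",    from = "TSC",  to = "TSC_i", mod = c("pERK", "pAKT"),
       k = "k_inact_TSC"),
    rx("react_TSC",    from = "TSC_i", to = "TSC",      k = "k_react_TSC"),
    rx("act_mTORC1",   from = "mTORC1", to = "mTORC1_act",
       k = "k_act_mTORC1"),
    rx("deact_mTORC1", from = "mTORC1_act", to = "mTORC1", mod = "TSC",
       k = "k_deact_mTORC1"),
    rx("p_S6K",        from = "S6K",  to = "pS6K", mod = "mTORC1_act",
       k = "k_phos_S6K"),
    rx("dp_S6K",       from = "pS6K", to = "S6K",       k = "k_dephos_S6K"),
    rx("p_S6",         from = "S6",   to = "pS6", mod = "pS6K",
       k = "k_phos_S6"),
    rx("dp_S6",        from = "pS6",  to = "S6",        k = "k_dephos_S6"),
    rx("act_mTORC2",   from = "mTORC2", to = "mTORC2_act", mod = "PI3K_act",
       k = "k_act_mTORC2"),
    rx("deact_mTORC2", from = "mTORC2_act", to = "mTORC2", mod = "pS6K",
       k = "k_deact_mTORC2"),
    rx("prod_IRS1",    to = "IRS1_act",                 k = "k_turn_IRS1",
       abund = "conc_IRS1"),
    rx("cons_IRS1",    from = "IRS1_act", mod = "pS6K", k = "k_cons_IRS1"))
  net <- reaction_network(sp, rxns)
  attr(net, "moieties") <- conserved_moieties(net)
  attr(net, "rate_factors") <- rate_factors(net)
  net
}

#' Conserved moieties of a reaction network
#'
#' Integer basis of the left null space of the stoichiometry matrix. Species
#' with zero rows (pure modifiers such as HGF) are reported as singleton
#' moieties. The basis is cached on the network after the first computation.
#'
#' @param net A `reaction_network`.
#' @return List of named integer vectors `v` with `v %*% S == 0` exactly.
#' @export
conserved_moieties <- function(net) {
  cached <- attr(net, "moieties")
  if (!is.null(cached)) return(cached)
  S <- net$stoichiometry_matrix
  ## reduced row echelon form of t(S) to find the left null space of S
  A <- t(S) * 1.0
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[piv, col]) < 1e-9) next
    if (piv != row) A[c(piv, row), ] <- A[c(row, piv), ]
    A[row, ] <- A[row, ] / A[row, col]
    for (r in seq_len(m)[-row]) A[r, ] <- A[r, ] - A[r, col] * A[row, ]
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  out <- list()
  for (f in free) {
    v <- numeric(n)
    v[f] <- 1
    for (i in seq_along(pivots)) v[pivots[i]] <- -A[i, f]
    ## rescale to smallest integer vector
    nz <- v[abs(v) > 1e-9]
    v <- v / min(abs(nz))
    vi <- round(v)
    if (max(abs(v - vi)) > 1e-6) { # rational entries: clear denominators
      for (d in 2:48) {
        vi <- round(v * d)
        if (max(abs(v * d - vi)) < 1e-6) break
      }
    }
    if (any(vi %*% S != 0)) next
    names(vi) <- rownames(S)
    out[[length(out) + 1L]] <- as.integer(vi) |> stats::setNames(rownames(S))
  }
  out
}

## per-reaction effective rate constants from a named native-scale parameter
## vector (applies the abundance transformation on production reactions)
reaction_rate_constants <- function(net, params) {
  vapply(net$reactions, function(r) {
    k <- params[[r$rate_parameter]]
    if (!is.na(r$abundance_factor)) k <- k * params[[r$abundance_factor]]
    k
  }, 0)
}
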