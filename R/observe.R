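## Observation layer: antibody observation functions mapping model states to
## immunoblot observables, multi-gel replicate alignment under the combined
## scaling / relative-error model, and absolute anchoring of LFQ intensities.

#' Construct an observation model
#'
#' Each observable is a linear map `scale * sum(states) + offset` of model
#' states. Antibody semantics: the Ser473 antibody detects exclusively the
#' doubly phosphorylated AKT; the Thr308 antibody detects Thr308
#' phosphorylation regardless of Ser473, i.e. pAKT + ppAKT.
#'
#' @param maps Named list: per observable a list with `states` (character),
#'   `scale` (> 0) and `offset` (>= 0).
#' @return Object of class `observation_model`.
#' @export
observation_model <- function(maps) {
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (is.null(m$scale)) maps[[nm]]$scale <- 1
    if (is.null(m$offset)) maps[[nm]]$offset <- 0
    if (maps[[nm]]$scale <= 0) stop("scale must be positive for ", nm)
    if (!length(m$states)) stop("observable ", nm, " maps to no state")
  }
  structure(list(maps = maps), class = "observation_model")
}

#' Reference observation model for the immunoblot targets
#' @param scales Optional named per-observable scale overrides.
#' @return An `observation_model` covering pMET, pERK, pAKT_T308, ppAKT_S473,
#'   pS6, pS6K and the totals tMET, tERK, tAKT, tS6.
#' @export
default_observation_model <- function(scales = NULL) {
  maps <- list(
    pMET = list(states = "pMET"),
    tMET = list(states = c("MET", "pMET")),
    pERK = list(states = "pERK"),
    tERK = list(states = c("ERK", "pERK")),
    pAKT_T308 = list(states = c("pAKT", "ppAKT")),
    ppAKT_S473 = list(states = "ppAKT"),
    tAKT = list(states = c("AKT", "pAKT", "ppAKT")),
    pS6 = list(states = "pS6"),
    tS6 = list(states = c("S6", "pS6")),
    pS6K = list(states = "pS6K"))
  if (!is.null(scales))
    for (nm in names(scales)) maps[[nm]]$scale <- scales[[nm]]
  observation_model(maps)
}

## linear map (species x observables) + offsets realizing an observation model
obs_matrix <- function(om, sp) {
  M <- matrix(0, length(sp), length(om$maps),
              dimnames = list(sp, names(om$maps)))
  off <- stats::setNames(numeric(length(om$maps)), names(om$maps))
  for (nm in names(om$maps)) {
    m <- om$maps[[nm]]
    missing <- setdiff(m$states, sp)
    if (length(missing))
      stop("missing state(s): ", paste(missing, collapse = ", "))
    M[m$states, nm] <- m$scale
    off[nm] <- m$offset
  }
  list(M = M, offset = off)
}

#' Apply an observation model to a trajectory
#'
#' @param traj A `trajectory_set`.
#' @param om An `observation_model`.
#' @return Matrix (time x observable) of observable values in arbitrary units.
#' @export
observe <- function(traj, om) {
  mm <- obs_matrix(om, rownames(traj$states))
  sweep(crossprod(traj$states, mm$M), 2, mm$offset, `+`)
}

#' Align multi-gel immunoblot replicates
#'
#' Maximum-likelihood alignment under the combined scaling and relative error
#' model `Y_ij ~ y_i / s_j`, `sigma_ij ~ e_rel * y_i / s_j`. On the log scale
#' the model is additive Gaussian and is solved per target as a two-way linear
#' model; the gauge is fixed by setting the geometric mean of the scaling
#' factors to 1 per target.
#'
#' @param raw `data.frame` with columns `target`, `condition`, `dose`, `time`,
#'   `experiment`, `value` (positive signals in arbitrary units).
#' @return Object of class `aligned_dataset`: `data` (target, condition,
#'   dose, time, value `y`, `sigma`), `scalings` (target, experiment, `s`),
#'   `e_rel` per target.
#' @export
align_replicates <- function(raw) {
  need <- c("target", "condition", "dose", "time", "experiment", "value")
  if (!all(need %in% names(raw)))
    stop("raw data must have columns ", paste(need, collapse = ", "))
  if (any(raw$value <= 0)) stop("raw signals must be positive")
  data_out <- list(); scal_out <- list(); erel <- c()
  for (tg in unique(raw$target)) {
    sub <- raw[raw$target == tg, , drop = FALSE]
    eff <- interaction(sub$condition, sub$dose, sub$time, drop = TRUE)
    gel <- factor(sub$experiment)
    ## connectivity of the effect/gel bipartite design
    g <- igraph::graph_from_edgelist(cbind(paste0("i:", as.character(eff)),
                                           paste0("j:", as.character(gel))),
                                     directed = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1) {
      blocks <- split(names(comp$membership), comp$membership)
      stop("disconnected alignment design for target ", tg, ": blocks ",
           paste(vapply(blocks, function(b) paste(b, collapse = "+"), ""),
             collapse = " | "))
    }
    ly <- log(sub$value)
    if (nlevels(gel) == 1) {
      mu <- tapply(ly, eff, mean)
      se <- rep(0, length(mu))
      sdr <- 0
      lgel <- stats::setNames(0, levels(gel))
    } else {
      fit <- stats::lm(ly ~ 0 + eff + gel,
                       contrasts = list(gel = "contr.sum"))
      cf <- stats::coef(fit)
      mu <- cf[paste0("eff", levels(eff))]
      gc <- cf[grep("^gel", names(cf))]
      lgel <- stats::setNames(c(gc, -sum(gc)), levels(gel))
      ## gauge: contr.sum centers the gel effects, so the geometric mean of
      ## the scaling factors s_j = exp(-gel effect) is already 1
      sdr <- stats::sigma(fit)
      se <- sqrt(diag(stats::vcov(fit)))[paste0("eff", levels(eff))]
    }
    key <- !duplicated(eff)
    ord <- match(levels(eff), as.character(eff[key]))
    base <- sub[key, c("condition", "dose", "time")][ord, , drop = FALSE]
    y <- exp(mu)
    sigma <- y * ifelse(is.na(se) | se == 0,
                        ifelse(sdr > 0, sdr, 1e-6), pmax(se, 1e-12))
    data_out[[tg]] <- data.frame(target = tg, base, y = unname(y),
                                 sigma = unname(sigma), row.names = NULL)
    scal_out[[tg]] <- data.frame(target = tg, experiment = names(lgel),
                                 s = exp(-unname(lgel)), row.names = NULL)
    erel[tg] <- sdr
  }
  structure(list(data = do.call(rbind, c(data_out, make.row.names = FALSE)),
                 scalings = do.call(rbind, c(scal_out,
                                             make.row.names = FALSE)),
                 e_rel = erel),
            class = "aligned_dataset")
}

#' Convert LFQ intensities to molecules per cell
#'
#' Anchors relative label-free quantification intensities to absolute numbers
#' using the AKT molecules/cell determination: every protein's molecules/cell
#' is its native-scale intensity times (AKT molecules/cell / AKT intensity).
#'
#' @param intensities Named vector of log2 LFQ intensities (one per protein).
#' @param akt_molecules AKT abundance in molecules/cell (> 0).
#' @param akt_name Name of the AKT entry in `intensities`.
#' @return Named vector of molecules/cell.
#' @export
lfq_to_molecules <- function(intensities, akt_molecules,
                             akt_name = "conc_AKT") {
  if (!akt_name %in% names(intensities)) stop("AKT missing from LFQ table")
  if (!is.finite(akt_molecules) || akt_molecules <= 0)
    stop("nonpositive AKT anchor")
  native <- 2^intensities
  native * (akt_molecules / native[[akt_name]])
}
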