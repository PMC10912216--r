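## Study-level pipeline helpers connecting the generators, the alignment and
## the estimation machinery for the SD/WD diet comparison.

#' Summarize an abundance dataset into likelihood observations
#'
#' Per (protein, diet): the mean log2 intensity with the standard error over
#' mice, anchored to absolute molecules/cell through the AKT quantitative
#' immunoblot determination (one shared conversion factor).
#'
#' @param abund Result of [gen_abundance_dataset()] (or a list with `table`
#'   and `akt_molecules`).
#' @param anchor_condition Diet whose AKT anchor fixes the conversion factor.
#' @return `data.frame` with columns `param`, `condition`, `log2_molecules`,
#'   `sd`, suitable for the `abundance` slot of [fit_problem()].
#' @export
abundance_observations <- function(abund, anchor_condition = "SD") {
  tab <- abund$table
  agg <- stats::aggregate(log2_intensity ~ protein + diet, tab,
                          function(v) c(m = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  m <- agg$log2_intensity[, "m"]
  se <- pmax(agg$log2_intensity[, "se"], 0.02)
  akt_int <- m[agg$protein == "conc_AKT" & agg$diet == anchor_condition]
  shift <- log2(abund$akt_molecules[[anchor_condition]]) - akt_int
  data.frame(param = agg$protein, condition = agg$diet,
             log2_molecules = m + shift, sd = se)
}

#' Build the SD/WD fit problem for a diet hypothesis
#'
#' @param aligned Aligned blot data (`data.frame` target/condition/dose/time/
#'   y/sigma), conditions `SD` and `WD`.
#' @param base_params Full native-scale parameter vector (fit starting
#'   values for the shared core).
#' @param hypothesis `"dysregulated"` (basal MET rate + 11 abundances
#'   diet-specific, the reference), `"none"` (12 parameters free but shared
#'   between diets) or `"all"` (every rate constant and abundance
#'   diet-specific); alternatively a character vector of diet-specific
#'   parameter names.
#' @param abundance Optional output of [abundance_observations()].
#' @param free_scales If `TRUE`, one free observation scale per blot target.
#' @param net,om Network and observation model.
#' @param default_width Log-scale half-width of the parameter box.
#' @return A `fit_problem` labeled with the hypothesis.
#' @export
diet_fit_problem <- function(aligned, base_params,
                             hypothesis = "dysregulated", abundance = NULL,
                             free_scales = TRUE, net = build_hgf_network(),
                             om = default_observation_model(),
                             default_width = log(30)) {
  dys <- dysregulated_parameters()
  label <- if (length(hypothesis) == 1 &&
               hypothesis %in% c("dysregulated", "none", "all"))
    hypothesis else "custom"
  specific <- switch(label,
    dysregulated = dys,
    none = character(),
    all = c(setdiff(dynamical_parameters(net), "hgf_scale"),
            abundance_parameters()),
    hypothesis)
  shared_free <- setdiff(dys, specific)
  free <- c(unlist(lapply(specific, function(p)
    paste(p, c("SD", "WD"), sep = "|"))), shared_free)
  if (free_scales)
    free <- c(free, paste0("scale_", unique(aligned$target)))
  fit_problem(net, om, aligned, base_params, free, abundance = abundance,
              default_width = default_width, label = label)
}

#' Data-informed starting point for a fit problem
#'
#' Model parameters start at the problem's base values; free abundance
#' parameters with matching abundance observations start at the observed
#' molecules/cell; free observation scales are then self-calibrated as the
#' geometric-mean ratio between the data and an initial simulation.
#'
#' @param problem A `fit_problem`.
#' @return Named log-scale start vector over the free parameters.
#' @export
informed_start <- function(problem) {
  pn <- vapply(strsplit(problem$free, "|", fixed = TRUE), `[[`, "", 1)
  cond <- vapply(strsplit(problem$free, "|", fixed = TRUE),
                 function(s) if (length(s) > 1) s[2] else NA_character_, "")
  p0 <- ifelse(startsWith(pn, "scale_"), 0, log(problem$base_params[pn]))
  names(p0) <- problem$free
  if (!is.null(problem$abundance)) {
    ab <- problem$abundance
    for (i in seq_along(p0)) {
      if (startsWith(pn[i], "conc_")) {
        hit <- ab$param == pn[i] &
          (is.na(cond[i]) | ab$condition == cond[i])
        if (any(hit))
          p0[i] <- mean(ab$log2_molecules[hit]) * log(2)
      }
    }
  }
  ## condition-specific basal MET phosphorylation rates: initialize from the
  ## basal pMET signal relative to the first condition, corrected for the MET
  ## abundance start (basal pMET ~ k_basal * conc_MET at the pre-stimulation
  ## steady state)
  kb_free <- problem$free[pn == "k_basal_MET" & !is.na(cond)]
  if (length(kb_free) > 1 && "pMET" %in% problem$data$target) {
    basal <- function(cn) {
      sub <- problem$data[problem$data$condition == cn &
                            problem$data$target == "pMET" &
                            (problem$data$time == 0 | problem$data$dose == 0),
                          , drop = FALSE]
      if (nrow(sub)) mean(sub$y) else NA_real_
    }
    conc_at <- function(cn) {
      nm <- paste("conc_MET", cn, sep = "|")
      if (nm %in% names(p0)) exp(p0[[nm]])
      else if ("conc_MET" %in% names(p0)) exp(p0[["conc_MET"]])
      else problem$base_params[["conc_MET"]]
    }
    conds_kb <- vapply(strsplit(kb_free, "|", fixed = TRUE), `[[`, "", 2)
    b <- vapply(conds_kb, basal, 0)
    if (all(is.finite(b)) && all(b > 0)) {
      rel <- (b / vapply(conds_kb, conc_at, 0))
      rel <- rel / rel[1]
      p0[kb_free] <- p0[kb_free] + log(rel)
    }
  }
  scales <- problem$free[startsWith(problem$free, "scale_")]
  if (length(scales)) {
    r0 <- fit_residuals(problem, p0)
    if (is.null(attr(r0, "failed"))) {
      ## reconstruct the simulated values from the standardized residuals,
      ## walking the evaluation plan in residual order
      rows <- list()
      for (cp in problem$plan) {
        for (dp in cp$dplans)
          rows[[length(rows) + 1L]] <- data.frame(
            target = dp$targets, y = dp$y, sigma = dp$sigma, blot = TRUE)
        nab <- if (!is.null(cp$abundance)) nrow(cp$abundance) else 0L
        if (nab > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            target = NA_character_, y = NA_real_, sigma = NA_real_,
            blot = rep(FALSE, nab))
      }
      ord <- do.call(rbind, rows)
      sim <- rep(NA_real_, nrow(ord))
      bi <- which(ord$blot)
      sim[bi] <- if (problem$log_residuals)
        exp(log(ord$y[bi]) + r0[bi] * ord$sigma[bi] / ord$y[bi])
      else ord$y[bi] + r0[bi] * ord$sigma[bi]
      for (sc in scales) {
        tg <- sub("^scale_", "", sc)
        sel <- ord$blot & ord$target %in% tg & sim > 0
        sel[is.na(sel)] <- FALSE
        if (any(sel))
          p0[sc] <- stats::median(log(ord$y[sel] / sim[sel]))
      }
    }
  }
  pmin(pmax(p0, problem$lower), problem$upper)
}

#' One parameter-recovery replicate of the diet study
#'
#' Generates a synthetic SD/WD dataset from the ground truth, aligns the
#' replicates, attaches abundance observations, fits the reference hypothesis
#' by multi-start optimization and profiles the WD-side dysregulated
#' parameters.
#'
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed for the generator and the fit.
#' @param design Blot design.
#' @param n_starts Multi-start count.
#' @param include_base Seed the first start at the reference parameterization
#'   (the package defaults), as in a warm-started replicate study.
#' @param profile_params Parameters to profile (default: the 12 WD-side
#'   dysregulated parameters).
#' @param with_abundance Include the abundance observations.
#' @param n_mice Mice per diet in the abundance dataset.
#' @param max_points Profile grid cap per side.
#' @return List with the fit, profiles, per-parameter truth coverage
#'   (`data.frame` param, truth, estimate, ci_lower, ci_upper, covered) and
#'   the problem.
#' @export
diet_recovery_study <- function(truth, seed = 1,
                                design = default_blot_design(),
                                n_starts = 2, include_base = TRUE,
                                profile_params = NULL,
                                with_abundance = TRUE, n_mice = 9,
                                max_points = 12) {
  raw <- gen_blot_dataset(truth, design, seed = seed)
  aligned <- align_replicates(raw)$data
  abund <- if (with_abundance)
    abundance_observations(gen_abundance_dataset(truth, n_mice = n_mice,
                                                 seed = seed + 1000))
  else NULL
  problem <- diet_fit_problem(aligned, truth$params_sd,
                              hypothesis = "dysregulated",
                              abundance = abund)
  fit <- multistart_fit(problem, n_starts = n_starts, seed = seed,
                        include_base = include_base)
  if (is.null(profile_params))
    profile_params <- paste(dysregulated_parameters(), "WD", sep = "|")
  J <- fd_jacobian(function(p) fit_residuals(problem, p),
                   fit$par[problem$free])
  profiles <- lapply(profile_params, function(p)
    profile_likelihood(problem, fit, p, max_points = max_points,
                       jacobian = J))
  names(profiles) <- profile_params
  true_full <- c(truth$params_sd[dysregulated_parameters()],
                 truth$params_wd[dysregulated_parameters()])
  names(true_full) <- c(paste(dysregulated_parameters(), "SD", sep = "|"),
                        paste(dysregulated_parameters(), "WD", sep = "|"))
  cov <- do.call(rbind, lapply(profile_params, function(p) {
    pr <- profiles[[p]]
    tv <- log(true_full[[p]])
    data.frame(param = p, truth = tv, estimate = fit$par[[p]],
               ci_lower = pr$ci[1], ci_upper = pr$ci[2],
               identifiable = pr$identifiable,
               covered = tv >= pr$ci[1] && tv <= pr$ci[2])
  }))
  rownames(cov) <- NULL
  list(fit = fit, profiles = profiles, coverage = cov, problem = problem)
}
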