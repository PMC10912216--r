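## Patient-cohort stage: adaptation of the calibrated mouse model to
## patient-derived hepatocytes, model-based patient features and
## (partial) Spearman correlation with clinical variables.

#' Adapt the mouse model to patient-derived hepatocyte data
#'
#' All mouse-derived parameters are fixed; a small subset is re-estimated by
#' multi-start maximum likelihood: patient-specific parameters (by default the
#' basal MET phosphorylation rate and the MET abundance) and human-shared
#' parameters (by default the HGF-induced MET phosphorylation rate and the
#' pMET degradation rate, identical across patients). Residuals are computed
#' on the log scale, matching the log-normal character of the patient blots.
#'
#' @param mouse_params Full native-scale parameter vector of the mouse fit.
#' @param data A `patient_dataset` (or a list with an aligned `data.frame`
#'   under `$aligned` with columns target, condition, dose, time, y, sigma).
#' @param patient_specific Parameters re-estimated per patient.
#' @param human_shared Parameters re-estimated once for all patients.
#' @param n_starts,seed Multi-start settings.
#' @param net,om Network and observation model.
#' @return Object of class `patient_fit`: the `fit_result`, per-patient
#'   native-scale estimates (`data.frame`), shared estimates, and flags for
#'   patients lacking basal measurements.
#' @export
adapt_to_patients <- function(mouse_params, data,
                              patient_specific = c("k_basal_MET", "conc_MET"),
                              human_shared = c("k_hgf_MET", "k_deg_pMET"),
                              n_starts = 4, seed = 1,
                              net = build_hgf_network(),
                              om = default_observation_model()) {
  ## gels never span patients, so replicate alignment runs per patient (each
  ## patient keeps its own per-target gauge, absorbed by the fit)
  aligned <- if (!is.null(data$aligned)) data$aligned else
    do.call(rbind, c(lapply(split(data$blots, data$blots$condition),
                            function(b) align_replicates(b)$data),
                     make.row.names = FALSE))
  patients <- sort(unique(aligned$condition))
  no_basal <- vapply(patients, function(p) {
    sub <- aligned[aligned$condition == p, ]
    !any(sub$time == 0 | sub$dose == 0)
  }, TRUE)
  free <- c(human_shared,
            if (length(patient_specific))
              unlist(lapply(patients, function(p)
                paste(patient_specific, p, sep = "|"))))
  if (!length(free)) {
    return(structure(list(fit = NULL, patients = patients,
                          estimates = NULL, shared = mouse_params,
                          params = stats::setNames(
                            rep(list(mouse_params), length(patients)),
                            patients),
                          no_basal = no_basal),
                     class = "patient_fit"))
  }
  problem <- fit_problem(net, om, aligned, mouse_params, free,
                         log_residuals = TRUE, default_width = log(30),
                         label = "patient_adaptation")
  fit <- multistart_fit(problem, n_starts = n_starts, seed = seed,
                        include_base = TRUE)
  params <- lapply(patients, function(p)
    resolve_fit_parameters(problem, fit$par, p))
  names(params) <- patients
  est <- data.frame(patient = patients,
                    t(vapply(patients, function(p)
                      params[[p]][patient_specific],
                      numeric(length(patient_specific)))))
  names(est)[-1] <- patient_specific
  rownames(est) <- NULL
  structure(list(fit = fit, patients = patients, estimates = est,
                 shared = exp(fit$par[human_shared]), params = params,
                 no_basal = no_basal),
            class = "patient_fit")
}

#' Model-based patient features
#'
#' Simulates each patient at the stimulation design and tabulates the basal
#' MET phosphorylation rate, the area under the ppAKT curve, the MET
#' abundance, and the interconnection ratios.
#'
#' @param pfit A `patient_fit`.
#' @param dose,times,window Simulation design for the AUC.
#' @param net,om Network and observation model.
#' @return `data.frame`: patient, k_basal, auc_ppAKT, k_total_MET,
#'   k_basal_over_auc, k_basal_over_met.
#' @export
patient_features <- function(pfit, dose = 40, times = seq(0, 120, by = 5),
                             window = c(0, 120), net = build_hgf_network(),
                             om = default_observation_model()) {
  rows <- lapply(pfit$patients, function(pt) {
    p <- pfit$params[[pt]]
    traj <- simulate_hgf(net, p, dose = dose, times = times, condition = pt)
    ft <- extract_features(traj, om, window = window)
    if (ft[["auc_ppAKT"]] <= 0 || p[["conc_MET"]] <= 0)
      stop("zero denominator in feature ratios for ", pt)
    data.frame(patient = pt, k_basal = p[["k_basal_MET"]],
               auc_ppAKT = ft[["auc_ppAKT"]],
               k_total_MET = p[["conc_MET"]],
               basal_pMET = ft[["basal_pMET"]])
  })
  out <- do.call(rbind, rows)
  out$k_basal_over_auc <- out$k_basal / out$auc_ppAKT
  out$k_basal_over_met <- out$k_basal / out$k_total_MET
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with AS 89 p-values
#'
#' Rank correlation coefficient with the p-value computed by the exact AS 89
#' algorithm (Best & Roberts) where applicable (no ties, n < 1290), falling
#' back to the t-approximation with a flag otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = if (!ties) "AS89 exact" else "t approximation (ties)")
}

#' Partial Spearman correlation with confounder adjustment
#'
#' Rank-transforms all variables, residualizes x and y on the confounders by
#' linear regression, correlates the residuals and tests with a
#' t-approximation on n - 2 - k degrees of freedom (rank-then-linear partial
#' correlation).
#'
#' @param x,y Numeric vectors.
#' @param confounders Numeric matrix or data.frame (n x k); `NULL` or zero
#'   columns reduces to [spearman_test()].
#' @return List with `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, confounders = NULL) {
  n <- length(x)
  if (is.null(confounders) || NCOL(confounders) == 0 ||
      NROW(confounders) == 0) {
    st <- spearman_test(x, y)
    return(list(rho = st$rho, p = st$p, n = n, df = n - 2))
  }
  Z <- as.matrix(confounders)
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > k + 2 observations")
  if (qr(cbind(1, Z))$rank < k + 1) stop("singular confounder matrix")
  rx <- rank(x); ry <- rank(y)
  rz <- apply(Z, 2, rank)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  rho <- stats::cor(ex, ey)
  df <- n - 2 - k
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Significance stars for p-values
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` p<0.001, `**` p<0.01, `*` p<0.05, else "".
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlate model features with clinical variables
#'
#' @param features `data.frame` with a `patient` column and feature columns.
#' @param clinical `data.frame` with a `patient` column and clinical columns.
#' @param feature_cols,clinical_cols Columns to correlate.
#' @param confounder_cols Optional clinical columns used for an additional
#'   partial-correlation block.
#' @return `data.frame` (feature, clinical, rho, p, stars, and partial_rho /
#'   partial_p if confounders were given).
#' @export
correlation_table <- function(features, clinical,
                              feature_cols = setdiff(names(features),
                                                     "patient"),
                              clinical_cols = setdiff(names(clinical),
                                                      "patient"),
                              confounder_cols = NULL) {
  m <- merge(features, clinical, by = "patient")
  rows <- list()
  for (f in feature_cols) for (cl in clinical_cols) {
    st <- spearman_test(m[[f]], m[[cl]])
    row <- data.frame(feature = f, clinical = cl, rho = st$rho, p = st$p,
                      stars = significance_stars(st$p))
    if (!is.null(confounder_cols)) {
      ps <- partial_spearman(m[[f]], m[[cl]],
                             m[, confounder_cols, drop = FALSE])
      row$partial_rho <- ps$rho
      row$partial_p <- ps$p
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Order patients by a model feature
#'
#' @param features `data.frame` from [patient_features()].
#' @param by Feature column (default the basal MET phosphorylation rate).
#' @param decreasing Sort order.
#' @return Character vector of patient identifiers; ties broken by id.
#' @export
rank_patients <- function(features, by = "k_basal", decreasing = TRUE) {
  if (!by %in% names(features)) stop("missing feature: ", by)
  if (anyNA(features[[by]])) stop("missing feature values in ", by)
  ord <- order(features[[by]], features$patient,
               decreasing = c(decreasing, FALSE), method = "radix")
  features$patient[ord]
}
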