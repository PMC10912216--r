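## Diet-perturbation analysis: WD-specific features, single-parameter SD->WD
## scans and per-parameter feature re-optimization.

#' Extract WD-discriminating features from a trajectory
#'
#' Basal pMET and basal ppERK are the t = 0 values of the corresponding
#' observables (the trajectory starts at the pre-stimulation steady state);
#' the ppAKT feature is the trapezoidal area under the Ser473 observable over
#' the stimulation window.
#'
#' @param traj A `trajectory_set` starting at t = 0.
#' @param om An `observation_model`.
#' @param window Integration window in minutes (default 0-240).
#' @return Named vector `c(basal_pMET, basal_ppERK, auc_ppAKT)`.
#' @export
extract_features <- function(traj, om, window = c(0, 240)) {
  if (window[1] < min(traj$times) || window[2] > max(traj$times))
    stop("window outside simulated times")
  obs <- observe(traj, om)
  keep <- traj$times >= window[1] & traj$times <= window[2]
  tt <- traj$times[keep]
  yy <- obs[keep, "ppAKT_S473"]
  auc <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  c(basal_pMET = unname(obs[1, "pMET"]),
    basal_ppERK = unname(obs[1, "pERK"]),
    auc_ppAKT = unname(auc))
}

## log-scale interpolation between SD and WD values of one parameter
interp_param <- function(sd_params, wd_params, param, frac) {
  p <- sd_params
  p[param] <- if (frac == 0) sd_params[[param]]
    else if (frac == 1) wd_params[[param]]
    else exp((1 - frac) * log(sd_params[[param]]) +
             frac * log(wd_params[[param]]))
  p
}

#' Single-parameter SD-to-WD scan
#'
#' Gradually shifts one dysregulated parameter from its SD estimate to its WD
#' estimate in `n_intervals` equal steps (log scale), keeping all other
#' parameters at SD values, and records the simulated trajectories and
#' features per fraction.
#'
#' @param net,om Network and observation model.
#' @param sd_params,wd_params Full native-scale parameter vectors.
#' @param param Parameter to scan; must be one of the dysregulated set.
#' @param n_intervals Number of intervals (default 5, i.e. 20% steps).
#' @param dose,times Stimulation design for the simulated trajectories.
#' @param window Feature window.
#' @return Object of class `scan_result`: `fractions`, `features` (matrix
#'   fractions x features), `trajectories` (list).
#' @export
parameter_scan <- function(net, om, sd_params, wd_params, param,
                           n_intervals = 5, dose = 40,
                           times = seq(0, 240, by = 5), window = c(0, 240)) {
  if (!param %in% dysregulated_parameters())
    stop(param, " is not a dysregulated parameter")
  fr <- seq(0, 1, length.out = n_intervals + 1)
  trajs <- lapply(fr, function(f)
    simulate_hgf(net, interp_param(sd_params, wd_params, param, f),
                 dose = dose, times = times,
                 condition = sprintf("%s_%d%%", param, round(100 * f))))
  feats <- t(vapply(trajs, extract_features, numeric(3), om = om,
                    window = window))
  structure(list(param = param, fractions = fr, features = feats,
                 trajectories = trajs),
            class = "scan_result")
}

#' Re-optimize one dysregulated parameter against the WD features
#'
#' The parameter may take any value between its SD and WD estimates (log
#' scale); the returned optimum minimizes the feature discrepancy, defined as
#' the sum of squared relative deviations of the three features from the WD
#' reference.
#'
#' @param net,om Network and observation model.
#' @param param Dysregulated parameter name.
#' @param sd_params,wd_params Full native-scale parameter vectors.
#' @param wd_features Target features (from the WD fit simulation).
#' @param dose,times,window Simulation design.
#' @return List with `param`, `fraction` (position in [0,1] between SD and
#'   WD), `value` (native scale), `features` achieved and `discrepancy`.
#' @export
reoptimize_feature <- function(net, om, param, sd_params, wd_params,
                               wd_features, dose = 40,
                               times = seq(0, 240, by = 10),
                               window = c(0, 240)) {
  if (!param %in% dysregulated_parameters())
    stop(param, " is not a dysregulated parameter")
  if (sd_params[[param]] == wd_params[[param]])
    stop("degenerate interval: SD and WD estimates are identical")
  feat_at <- function(f) {
    extract_features(
      simulate_hgf(net, interp_param(sd_params, wd_params, param, f),
                   dose = dose, times = times), om, window)
  }
  disc <- function(f) {
    sum(((feat_at(f) - wd_features) / wd_features)^2)
  }
  opt <- stats::optimize(disc, c(0, 1), tol = 1e-3)
  cand <- c(opt$minimum, 0, 1)
  vals <- c(opt$objective, disc(0), disc(1))
  bestf <- cand[which.min(vals)]
  list(param = param, fraction = bestf,
       value = unname(interp_param(sd_params, wd_params, param,
                                   bestf)[param]),
       features = feat_at(bestf), discrepancy = min(vals))
}

#' Rank dysregulated parameters by achievable WD-feature reproduction
#'
#' Runs [reoptimize_feature()] for every dysregulated parameter and ranks by
#' the minimized feature discrepancy (best reproducer first).
#'
#' @inheritParams reoptimize_feature
#' @param params Candidate parameters (default: the 12 dysregulated ones).
#' @return `data.frame` (param, fraction, discrepancy, and achieved features)
#'   sorted ascending by discrepancy.
#' @export
rank_feature_drivers <- function(net, om, sd_params, wd_params, wd_features,
                                 params = dysregulated_parameters(), ...) {
  rows <- lapply(params, function(p) {
    if (sd_params[[p]] == wd_params[[p]]) {
      ## no SD-WD freedom: candidate is stuck at the SD features
      ft <- extract_features(
        simulate_hgf(net, sd_params, dose = 40,
                     times = seq(0, 240, by = 10)), om)
      return(list(param = p, fraction = 0, features = ft,
                  discrepancy = sum(((ft - wd_features) / wd_features)^2)))
    }
    reoptimize_feature(net, om, p, sd_params, wd_params, wd_features, ...)
  })
  tab <- data.frame(
    param = vapply(rows, `[[`, "", "param"),
    fraction = vapply(rows, `[[`, 0, "fraction"),
    discrepancy = vapply(rows, `[[`, 0, "discrepancy"),
    t(vapply(rows, `[[`, numeric(3), "features")))
  tab <- tab[order(tab$discrepancy), ]
  rownames(tab) <- NULL
  tab
}
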