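## Synthetic-data generators: ground truth, immunoblot datasets, abundance
## tables, patient cohorts and FUCCI traces. Every generator is a pure
## function of (parameters, seed). The default kinetic values are synthetic
## order-of-magnitude choices tuned so that simulated dynamics qualitatively
## mirror HGF-stimulated hepatocytes (pMET peaking around 10 min, saturation
## of the dose response near 40 ng/ml, reduced AKT phosphorylation under the
## Western-diet parameterization); they are not estimates from any dataset.

#' Synthetic ground truth for the diet study
#'
#' Standard-diet (SD) and Western-diet (WD) parameter vectors that differ only
#' in the 12 dysregulated parameters: the basal MET phosphorylation rate
#' (`k_basal_MET`, default 5-fold increase in WD) and the abundances of the
#' eleven modeled proteins, with WD shifts down for MET, mTORC2 (SIN1) and S6
#' and up for TSC; the remaining seven abundances are diet-specific in the
#' bookkeeping but numerically equal.
#'
#' @param k_basal_fold WD/SD fold change of the basal MET phosphorylation rate.
#' @param abundance_fold Named vector of WD/SD abundance fold changes.
#' @param e_rel Relative error of the immunoblot noise model.
#' @param sd_scaling Log-sd of per-experiment scaling factors.
#' @return Object of class `ground_truth`: list with `params_sd`, `params_wd`
#'   (native scale), the condition map of the reference hypothesis, `e_rel`
#'   and `sd_scaling`.
#' @export
ground_truth <- function(k_basal_fold = 5,
                         abundance_fold = c(conc_MET = 0.6,
                                            conc_mTORC2 = 0.75,
                                            conc_S6 = 0.7, conc_TSC = 1.5),
                         e_rel = 0.1, sd_scaling = 0.5) {
  base <- default_true_parameters()
  wd <- base
  wd["k_basal_MET"] <- base["k_basal_MET"] * k_basal_fold
  wd[names(abundance_fold)] <- base[names(abundance_fold)] * abundance_fold
  cmap <- condition_map(
    conditions = c("SD", "WD"),
    specific = dysregulated_parameters(),
    overrides = list(WD = wd[dysregulated_parameters()]),
    inputs = list(SD = list(dose = 40), WD = list(dose = 40)))
  structure(list(params_sd = base, params_wd = wd, cmap = cmap,
                 e_rel = e_rel, sd_scaling = sd_scaling),
            class = "ground_truth")
}

#' Default synthetic true parameters (standard-diet reference)
#'
#' Units: molecules/cell for abundances, 1/min for first-order rate constants,
#' 1/(molecules/cell x min) and lower for modifier-dependent constants;
#' `hgf_scale` converts ng/ml of HGF into the internal input unit.
#'
#' @return Named native-scale parameter vector (11 abundances + 27 dynamical
#'   parameters).
#' @export
default_true_parameters <- function() {
  c(conc_MET = 5e4, conc_MEK = 4e5, conc_ERK = 6e5, conc_PI3K = 1e5,
    conc_AKT = 2e5, conc_TSC = 1e5, conc_mTORC1 = 5e4, conc_S6K = 2e5,
    conc_S6 = 1e6, conc_mTORC2 = 5e4, conc_IRS1 = 1e5,
    k_turn_MET = 0.05, k_deg_MET = 0.05, k_basal_MET = 0.005,
    k_hgf_MET = 1e-4, k_deg_pMET = 0.08,
    k_phos_MEK = 2e-5, k_dephos_MEK = 0.3,
    k_phos_ERK = 2e-6, k_dephos_ERK = 0.6,
    k_act_PI3K = 4e-11, k_deact_PI3K = 0.5,
    k_phos_AKT = 2e-6, k_phos2_AKT = 4e-5, k_dephos_AKT = 0.1,
    k_inact_TSC = 6e-11, k_react_TSC = 0.015,
    k_act_mTORC1 = 0.02, k_deact_mTORC1 = 1e-5,
    k_phos_S6K = 1e-5, k_dephos_S6K = 0.4,
    k_phos_S6 = 2e-6, k_dephos_S6 = 0.2,
    k_act_mTORC2 = 5e-6, k_deact_mTORC2 = 1e-5,
    k_turn_IRS1 = 0.2, k_cons_IRS1 = 1e-5,
    hgf_scale = 25)
}

#' Default immunoblot experiment design
#'
#' Mirrors the murine study design: a dose response (0.1-120 ng/ml, signals
#' read at 10 min) and a 40 ng/ml time course up to 240 min, both with a
#' basal (dose 0 / t 0) point.
#'
#' @param targets Observable names to measure.
#' @param n_replicates Number of experiments (gels) per diet.
#' @return List with `dose_response`, `time_course` and `targets`.
#' @export
default_blot_design <- function(targets = c("pMET", "pERK", "pAKT_T308",
                                            "ppAKT_S473", "pS6", "tMET"),
                                n_replicates = 3) {
  list(dose_response = list(doses = c(0, 0.1, 1, 2, 4, 10, 20, 40, 80, 120),
                            time = 10),
       time_course = list(dose = 40,
                          times = c(0, 5, 10, 20, 40, 60, 120, 180, 240)),
       targets = targets, n_replicates = n_replicates)
}

## noiseless observable table for one condition under a design
observable_truth <- function(net, params, design, om, condition) {
  tc <- design$time_course
  traj <- simulate_hgf(net, params, dose = tc$dose, times = tc$times,
                       condition = condition)
  obs_tc <- observe(traj, om)
  rows <- list()
  for (tg in design$targets) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, target = tg, dose = tc$dose, time = tc$times,
      truth = obs_tc[, tg])
  }
  dr <- design$dose_response
  x0 <- steady_state(net, params)
  for (d in dr$doses) {
    traj_d <- simulate_hgf(net, params, dose = d, times = c(0, dr$time),
                           condition = condition, x0 = x0)
    obs_d <- observe(traj_d, om)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, target = design$targets, dose = d,
      time = dr$time, truth = obs_d[2, design$targets])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  unique(out)
}

#' Generate a synthetic multi-gel immunoblot dataset
#'
#' Simulates the ground truth, applies the observation model, divides by a
#' log-normal per-(experiment, target) scaling factor and multiplies by
#' relative Gaussian noise, reproducing the scaling/error structure
#' `Y_ij ~ y_i / s_j`, `sigma_ij ~ e_rel * y_i / s_j`.
#'
#' @param truth A [ground_truth()] object.
#' @param design A [default_blot_design()] list.
#' @param seed Integer seed.
#' @param net Reaction network (defaults to the reference build).
#' @param om Observation model (defaults to [default_observation_model()]).
#' @return `data.frame` with columns target, condition, dose, time,
#'   experiment, value and the noiseless `truth`.
#' @export
gen_blot_dataset <- function(truth, design = default_blot_design(), seed = 1,
                             net = build_hgf_network(),
                             om = default_observation_model()) {
  if (!length(design$targets)) stop("invalid design: no targets")
  set.seed(seed)
  base <- rbind(
    observable_truth(net, truth$params_sd, design, om, "SD"),
    observable_truth(net, truth$params_wd, design, om, "WD"))
  out <- list()
  for (r in seq_len(design$n_replicates)) {
    for (tg in unique(base$target)) {
      s_j <- exp(stats::rnorm(1, 0, truth$sd_scaling))
      sub <- base[base$target == tg, ]
      noise <- 1 + truth$e_rel * stats::rnorm(nrow(sub))
      sub$experiment <- paste0("exp", r)
      sub$value <- pmax(sub$truth / s_j * noise, 1e-12)
      sub$scaling <- s_j
      out[[length(out) + 1L]] <- sub
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic LFQ-style protein-abundance dataset
#'
#' Per-mouse log2 intensities are log2(true concentration x a global
#' intensity factor) plus Gaussian noise; an AKT molecules/cell anchor is
#' attached for absolute calibration.
#'
#' @param truth A [ground_truth()] object.
#' @param n_mice Mice per diet (>= 2).
#' @param seed Integer seed.
#' @param log2_sd Per-measurement noise sd on the log2 scale.
#' @param intensity_factor Global intensity-per-molecule factor.
#' @return List with `table` (long data.frame: protein, diet, mouse,
#'   log2_intensity) and `akt_molecules` (the anchor, molecules/cell, keyed by
#'   diet).
#' @export
gen_abundance_dataset <- function(truth, n_mice = 9, seed = 1, log2_sd = 0.2,
                                  intensity_factor = 1e-3) {
  if (n_mice < 2) stop("need at least 2 mice per diet")
  set.seed(seed)
  prot <- abundance_parameters()
  rows <- list()
  for (diet in c("SD", "WD")) {
    p <- if (diet == "SD") truth$params_sd else truth$params_wd
    for (m in seq_len(n_mice)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = prot, diet = diet, mouse = paste0(diet, m),
        log2_intensity = log2(p[prot] * intensity_factor) +
          stats::rnorm(length(prot), 0, log2_sd))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       akt_molecules = c(SD = unname(truth$params_sd["conc_AKT"]),
                         WD = unname(truth$params_wd["conc_AKT"])))
}

#' Generate a synthetic patient cohort
#'
#' Per-patient basal MET phosphorylation rates are drawn log-uniformly over
#' `k_basal_range`; immunoblot time courses (1-120 min, human design) are
#' generated with the blot noise model; outcomes are monotone functions of
#' log k_basal plus noise; confounders are drawn independently; a PDGF-like
#' blood metric is anti-correlated with k_basal.
#'
#' @param n_patients Number of patients (>= 3).
#' @param seed Integer seed.
#' @param k_basal_range Range (native scale) of true basal rates.
#' @param outcome_noise Noise sd on the outcome scale.
#' @param e_rel,sd_scaling Blot noise parameters.
#' @param n_replicates Technical replicates (gels) per patient.
#' @return Object of class `patient_dataset`: list with `blots` (long
#'   data.frame), `clinical` (one row per patient), `truth` (per-patient true
#'   parameters).
#' @export
gen_patient_cohort <- function(n_patients = 7, seed = 1,
                               k_basal_range = c(0.002, 0.05),
                               outcome_noise = 0.25, e_rel = 0.15,
                               sd_scaling = 0.3, n_replicates = 2) {
  if (n_patients < 3) stop("need at least 3 patients")
  set.seed(seed)
  net <- build_hgf_network()
  om <- default_observation_model()
  base <- default_true_parameters()
  kb <- exp(stats::runif(n_patients, log(k_basal_range[1]),
                         log(k_basal_range[2])))
  met <- base["conc_MET"] * exp(stats::rnorm(n_patients, 0, 0.3))
  times <- c(0, 1, 3, 5, 10, 20, 40, 60, 120)
  targets <- c("pMET", "pERK", "ppAKT_S473", "pS6K", "tMET")
  blots <- list()
  for (i in seq_len(n_patients)) {
    p <- base
    p["k_basal_MET"] <- kb[i]
    p["conc_MET"] <- met[i]
    traj <- simulate_hgf(net, p, dose = 40, times = times,
                         condition = paste0("patient", i))
    obs <- observe(traj, om)
    for (r in seq_len(n_replicates)) {
      for (tg in targets) {
        s_j <- exp(stats::rnorm(1, 0, sd_scaling))
        noise <- 1 + e_rel * stats::rnorm(length(times))
        blots[[length(blots) + 1L]] <- data.frame(
          target = tg, condition = paste0("patient", i), dose = 40,
          time = times, experiment = paste0("p", i, "r", r),
          value = pmax(obs[, tg] / s_j * noise, 1e-12))
      }
    }
  }
  z <- scale(log(kb))[, 1]
  clinical <- data.frame(
    patient = paste0("patient", i = seq_len(n_patients)),
    k_basal_true = kb, conc_MET_true = met,
    age = round(stats::runif(n_patients, 40, 80)),
    bmi = round(stats::rnorm(n_patients, 27, 4), 1),
    fibrosis = sample(0:4, n_patients, replace = TRUE),
    cci = sample(0:10, n_patients, replace = TRUE),
    hgf_preop = exp(stats::rnorm(n_patients, 5, 0.4)),
    il6_d1 = exp(stats::rnorm(n_patients, 3, 0.5)),
    il8_d1 = exp(stats::rnorm(n_patients, 3, 0.5)),
    pdgf_d1 = exp(-0.8 * z + stats::rnorm(n_patients, 4, 0.2)),
    clavien_dindo = pmin(pmax(round(2 + 1.2 * z +
      stats::rnorm(n_patients, 0, outcome_noise)), 0), 5),
    complication_index = pmax(30 + 20 * z +
      stats::rnorm(n_patients, 0, 10 * outcome_noise), 0),
    icu_days = pmax(round(3 + 2 * z +
      stats::rnorm(n_patients, 0, 2 * outcome_noise)), 0),
    hospitalization_days = pmax(round(14 + 8 * z +
      stats::rnorm(n_patients, 0, 4 * outcome_noise)), 1),
    proliferation_fc = exp(0.3 * z + stats::rnorm(n_patients, 0.5, 0.2)))
  structure(list(blots = do.call(rbind, blots), clinical = clinical,
                 truth = data.frame(patient = clinical$patient,
                                    k_basal = kb, conc_MET = met)),
            class = "patient_dataset")
}

#' Generate synthetic FUCCI two-channel traces
#'
#' Builds piecewise-phase traces with a requested number of S->G2 transitions
#' per cell; channel intensities are placed in the corresponding quadrant with
#' noise kept below the threshold margins.
#'
#' @param entries_per_cell Integer vector: requested cell-cycle entries per
#'   cell.
#' @param seed Integer seed.
#' @param n_frames Frames per trace (15-min sampling by default).
#' @param dt Sampling interval in minutes.
#' @param thresholds Named vector `c(rfp, yfp)` of quadrant thresholds.
#' @param noise_sd Intensity noise sd (kept below the margin to the
#'   thresholds).
#' @return List of `fucci_trace` objects (times, rfp, yfp, thresholds, and the
#'   generating phase sequence).
#' @export
gen_fucci_traces <- function(entries_per_cell, seed = 1, n_frames = 260,
                             dt = 15, thresholds = c(rfp = 100, yfp = 100),
                             noise_sd = 10) {
  set.seed(seed)
  phases <- c("G1", "S", "G2", "M")
  lvl <- list(G1 = c(rfp = 200, yfp = 40), S = c(rfp = 200, yfp = 200),
              G2 = c(rfp = 40, yfp = 200), M = c(rfp = 40, yfp = 40))
  lapply(entries_per_cell, function(k) {
    ## one cycle G1->S->G2->M consumes 4 segments; k entries need 4k+1
    n_seg <- 4L * k + 1L
    if (n_seg > n_frames)
      stop("infeasible request: ", k, " entries do not fit in ", n_frames,
           " frames")
    cut <- sort(sample(seq_len(n_frames - 1L), n_seg - 1L))
    seg_len <- diff(c(0L, cut, n_frames))
    phase <- rep(phases[(seq_len(n_seg) - 1L) %% 4L + 1L], seg_len)
    mu <- do.call(rbind, lvl[phase])
    structure(list(
      times = (seq_len(n_frames) - 1L) * dt,
      rfp = pmax(mu[, "rfp"] + stats::rnorm(n_frames, 0, noise_sd), 0),
      yfp = pmax(mu[, "yfp"] + stats::rnorm(n_frames, 0, noise_sd), 0),
      thresholds = thresholds, phase_truth = phase),
      class = "fucci_trace")
  })
}
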