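test_that("generators are pure functions of parameters and seed", {
  gt <- ref_truth()
  des <- default_blot_design(targets = "pMET", n_replicates = 2)
  expect_identical(gen_blot_dataset(gt, des, seed = 3),
                   gen_blot_dataset(gt, des, seed = 3))
  expect_false(identical(gen_blot_dataset(gt, des, seed = 3)$value,
                         gen_blot_dataset(gt, des, seed = 4)$value))
  expect_identical(gen_abundance_dataset(gt, seed = 2),
                   gen_abundance_dataset(gt, seed = 2))
  c1 <- gen_patient_cohort(n_patients = 3, seed = 5)
  c2 <- gen_patient_cohort(n_patients = 3, seed = 5)
  expect_identical(c1$clinical, c2$clinical)
})

test_that("the SD/WD truth differs exactly in the declared dysregulated set", {
  gt <- ref_truth()
  diff_names <- names(gt$params_sd)[gt$params_sd != gt$params_wd]
  expect_true(all(diff_names %in% dysregulated_parameters()))
  expect_setequal(diff_names, c("k_basal_MET", "conc_MET", "conc_mTORC2",
                                "conc_S6", "conc_TSC"))
  expect_equal(gt$params_wd[["k_basal_MET"]] / gt$params_sd[["k_basal_MET"]],
               5)
  # abundance shift directions: MET, SIN1 (mTORC2), S6 down; TSC up
  expect_lt(gt$params_wd[["conc_MET"]], gt$params_sd[["conc_MET"]])
  expect_lt(gt$params_wd[["conc_mTORC2"]], gt$params_sd[["conc_mTORC2"]])
  expect_lt(gt$params_wd[["conc_S6"]], gt$params_sd[["conc_S6"]])
  expect_gt(gt$params_wd[["conc_TSC"]], gt$params_sd[["conc_TSC"]])
})

test_that("noise-free blot data equal the model observables", {
  gt <- ground_truth(e_rel = 0, sd_scaling = 0)
  des <- default_blot_design(targets = c("pMET", "ppAKT_S473"),
                             n_replicates = 1)
  des$dose_response$doses <- c(0, 40)
  raw <- gen_blot_dataset(gt, des, seed = 1)
  expect_equal(raw$value, raw$truth, tolerance = 1e-12)
  expect_true(all(raw$value > 0))
})

test_that("default-design data are nonzero for every target and diet", {
  gt <- ref_truth()
  des <- default_blot_design(n_replicates = 1)
  raw <- gen_blot_dataset(gt, des, seed = 6)
  agg <- stats::aggregate(value ~ target + condition, raw, min)
  expect_true(all(agg$value > 0))
  expect_setequal(unique(raw$condition), c("SD", "WD"))
  expect_setequal(unique(raw$target), des$targets)
})

test_that("alignment round-trip recovers the generated biological effects", {
  gt <- ground_truth(e_rel = 0.1, sd_scaling = 0.5)
  des <- default_blot_design(targets = c("pMET", "pERK"), n_replicates = 4)
  des$dose_response$doses <- c(0, 4, 40)
  raw <- gen_blot_dataset(gt, des, seed = 13)
  al <- align_replicates(raw)
  key <- merge(al$data,
               unique(raw[, c("target", "condition", "dose", "time",
                              "truth")]),
               by = c("target", "condition", "dose", "time"))
  # per-target gauge factor between aligned values and the truth
  within3 <- 0
  for (tg in unique(key$target)) {
    sub <- key[key$target == tg, ]
    gauge <- exp(mean(log(sub$y / sub$truth)))
    within3 <- within3 + sum(abs(sub$y - gauge * sub$truth) <=
                               3 * sub$sigma)
  }
  expect_gte(within3 / nrow(key), 0.95)
})

test_that("abundance generator flags the four shifted proteins", {
  gt <- ref_truth()
  hits <- 0L
  shifted <- c("conc_MET", "conc_mTORC2", "conc_S6", "conc_TSC")
  for (s in 1:10) {
    ab <- gen_abundance_dataset(gt, n_mice = 9, seed = 200 + s)
    ok <- vapply(shifted, function(pr) {
      sub <- ab$table[ab$table$protein == pr, ]
      stats::t.test(log2_intensity ~ diet, sub)$p.value < 0.05
    }, TRUE)
    if (all(ok)) hits <- hits + 1L
    med <- stats::aggregate(log2_intensity ~ protein + diet, ab$table,
                            stats::median)
    m <- function(pr, d) med$log2_intensity[med$protein == pr &
                                              med$diet == d]
    expect_lt(m("conc_MET", "WD"), m("conc_MET", "SD"))
    expect_gt(m("conc_TSC", "WD"), m("conc_TSC", "SD"))
  }
  expect_gte(hits, 9L)
})

test_that("a swap test shows no diet signal when SD and WD truths coincide", {
  gt <- ground_truth(k_basal_fold = 1,
                     abundance_fold = stats::setNames(numeric(0),
                                                      character(0)))
  expect_identical(gt$params_sd, gt$params_wd)
  ab <- gen_abundance_dataset(gt, n_mice = 9, seed = 33)
  ps <- vapply(abundance_parameters(), function(pr) {
    sub <- ab$table[ab$table$protein == pr, ]
    stats::t.test(log2_intensity ~ diet, sub)$p.value
  }, 0)
  expect_gte(sum(ps > 0.05), 9)  # at most ~chance-level false positives
})

test_that("patient outcomes become perfectly monotone as noise vanishes", {
  coh <- gen_patient_cohort(n_patients = 7, seed = 44, outcome_noise = 0)
  st <- spearman_test(coh$clinical$k_basal_true,
                      coh$clinical$complication_index)
  expect_equal(st$rho, 1)
  # the PDGF-like blood metric anti-correlates with the basal rate
  expect_lt(stats::cor(coh$clinical$k_basal_true, coh$clinical$pdgf_d1,
                       method = "spearman"), 0)
})

test_that("FUCCI generator honors entry requests and noise-free quadrants", {
  trs <- gen_fucci_traces(c(0, 1, 2), seed = 3, noise_sd = 0)
  for (i in seq_along(trs)) {
    expect_equal(count_entries(classify_phases(trs[[i]])), c(0L, 1L, 2L)[i])
    expect_identical(as.character(classify_phases(trs[[i]])),
                     trs[[i]]$phase_truth)
  }
  expect_error(gen_fucci_traces(100, seed = 1, n_frames = 30), "infeasible")
  # cohort bookkeeping: fraction of cells with at least one entry
  req <- c(rep(1, 43), rep(0, 57))
  trs2 <- gen_fucci_traces(req, seed = 10)
  counts <- vapply(trs2, function(tr) count_entries(classify_phases(tr)), 0L)
  expect_equal(mean(counts >= 1), 0.43)
})
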