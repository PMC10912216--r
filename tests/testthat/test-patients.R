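test_that("Spearman correlation handles monotone and degenerate inputs", {
  x <- c(1, 3, 4, 7, 9, 12, 20)
  expect_equal(spearman_test(x, x^3 + 2)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  expect_error(spearman_test(x, rep(1, 7)), "constant")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("AS 89 p-values match exact permutation enumeration at n = 7", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (q in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], q)
    out
  }
  all_perms <- perms(1:7)
  set.seed(14)
  for (rep in 1:3) {
    x <- stats::rnorm(7)
    y <- stats::rnorm(7)
    st <- spearman_test(x, y)
    rx <- rank(x)
    rhos <- vapply(all_perms, function(pp)
      stats::cor(rx, pp[rank(y)]), 0)
    p_exact <- mean(abs(rhos) >= abs(st$rho) - 1e-12)
    expect_equal(st$p, p_exact, tolerance = 1e-10)
    expect_match(st$method, "AS89")
  }
})

test_that("partial Spearman matches the closed-form partial correlation", {
  set.seed(21)
  n <- 1e4
  z <- stats::rnorm(n)
  x <- 0.6 * z + stats::rnorm(n)
  y <- -0.5 * z + 0.3 * x + stats::rnorm(n)
  ps <- partial_spearman(x, y, cbind(z))
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(ps$rho, closed, tolerance = 0.02)
  # conditioning on the common cause removes a spurious association
  y2 <- 2 * z + 0.001 * stats::rnorm(n)
  expect_lt(abs(partial_spearman(x, y2, cbind(z))$rho), 0.05)
  # no confounders: reduces to the plain Spearman test
  x7 <- c(2, 5, 1, 9, 4, 8, 3); y7 <- c(1, 4, 2, 8, 5, 9, 3)
  expect_equal(partial_spearman(x7, y7)$rho, spearman_test(x7, y7)$rho)
  expect_error(partial_spearman(x7, y7, cbind(1:7, 2 * (1:7))), "singular")
  expect_error(partial_spearman(1:5, 5:1,
                                cbind(1:5, c(2, 1, 3, 5, 4),
                                      c(1, 3, 2, 5, 4))),
               "n > k")
})

test_that("significance stars are a pure threshold function of p", {
  expect_identical(significance_stars(c(0.0005, 0.005, 0.04, 0.2, 0.05)),
                   c("***", "**", "*", "", ""))
})

test_that("patient ranking is deterministic with id tie-breaks", {
  ft <- data.frame(patient = c("p2", "p1", "p3"),
                   k_basal = c(0.5, 0.5, 0.9))
  expect_identical(rank_patients(ft), c("p3", "p1", "p2"))
  expect_identical(rank_patients(ft, decreasing = FALSE),
                   c("p1", "p2", "p3"))
  expect_identical(rank_patients(ft[3, , drop = FALSE]), "p3")
  expect_error(rank_patients(ft, by = "auc"), "missing feature")
})

test_that("synthetic cohorts carry a k_basal-linked outcome signal", {
  hits <- 0L
  for (s in 1:10) {
    coh <- gen_patient_cohort(n_patients = 7, seed = 400 + s)
    st <- spearman_test(coh$clinical$k_basal_true,
                        coh$clinical$complication_index)
    if (st$p < 0.05 && st$rho > 0) hits <- hits + 1L
    # confounders are generated independently of the basal rate
    expect_true(all(c("age", "bmi", "fibrosis", "cci") %in%
                      names(coh$clinical)))
  }
  expect_gte(hits, 9L)
})

test_that("model adaptation recovers the patient rank order end to end", {
  # low-noise regime: the rank-order oracle is exact when the per-patient
  # basal rates are well separated relative to the measurement noise and the
  # per-patient gel gauge
  coh <- gen_patient_cohort(n_patients = 5, seed = 69, e_rel = 0.05,
                            sd_scaling = 0.1,
                            k_basal_range = c(0.001, 0.1))
  pf <- adapt_to_patients(default_true_parameters(), coh, n_starts = 1,
                          seed = 6)
  m <- merge(pf$estimates, coh$truth, by = "patient")
  expect_equal(stats::cor(m$k_basal_MET, m$k_basal, method = "spearman"), 1)
  ft <- patient_features(pf)
  expect_identical(rank_patients(ft),
                   coh$truth$patient[order(-coh$truth$k_basal)])
  # measured basal pMET follows the fitted basal rate (rank agreement)
  expect_gte(stats::cor(ft$basal_pMET, ft$k_basal, method = "spearman"),
             0.75)
  # ratio features are consistent with their definition
  expect_equal(ft$k_basal_over_met, ft$k_basal / ft$k_total_MET)
  # empty free subset returns the mouse parameterization unchanged
  pf0 <- adapt_to_patients(default_true_parameters(), coh,
                           patient_specific = character(),
                           human_shared = character())
  expect_identical(pf0$params[[1]], default_true_parameters())
})

test_that("correlation tables annotate rho, p and stars consistently", {
  set.seed(8)
  ft <- data.frame(patient = paste0("p", 1:7), k_basal = exp(stats::rnorm(7)))
  cl <- data.frame(patient = paste0("p", 1:7),
                   outcome = rank(ft$k_basal) + stats::rnorm(7, 0, 0.1),
                   age = stats::rnorm(7, 60, 8))
  ct <- correlation_table(ft, cl, feature_cols = "k_basal",
                          clinical_cols = "outcome",
                          confounder_cols = "age")
  expect_true(all(abs(ct$rho) <= 1))
  expect_identical(ct$stars, significance_stars(ct$p))
  expect_true(all(c("partial_rho", "partial_p") %in% names(ct)))
})
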