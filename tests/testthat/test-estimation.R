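test_that("the objective is the sum of squared standardized residuals", {
  net <- ref_net()
  om <- default_observation_model()
  p <- default_true_parameters()
  tt <- c(0, 10, 60, 240)
  traj <- simulate_hgf(net, p, dose = 40, times = tt)
  obs <- observe(traj, om)
  data <- data.frame(target = rep(c("pMET", "pERK"), each = 4),
                     condition = "SD", dose = 40, time = rep(tt, 2),
                     y = c(obs[, "pMET"], obs[, "pERK"]),
                     sigma = c(obs[, "pMET"], obs[, "pERK"]) * 0.1)
  prob <- fit_problem(net, om, data, p, free = "k_basal_MET")
  p0 <- c(k_basal_MET = log(p[["k_basal_MET"]]))
  # predictions equal to data: zero objective
  expect_equal(as.numeric(negloglik(prob, p0)), 0, tolerance = 1e-12)
  # one point exactly 1 sigma off: unit objective
  data1 <- data
  data1$y[3] <- data1$y[3] + data1$sigma[3]
  prob1 <- fit_problem(net, om, data1, p, free = "k_basal_MET")
  expect_equal(as.numeric(negloglik(prob1, p0)), 1, tolerance = 1e-6)
  # brute-force oracle at a perturbed parameter: independent residual sum
  p2 <- p0 + 0.4
  pp <- p; pp["k_basal_MET"] <- exp(p2)
  traj2 <- simulate_hgf(net, pp, dose = 40, times = tt)
  obs2 <- observe(traj2, om)
  direct <- sum(((c(obs2[, "pMET"], obs2[, "pERK"]) - data$y) /
                   data$sigma)^2)
  expect_equal(as.numeric(negloglik(prob, p2)), direct, tolerance = 1e-6)
  # simulation-layer failures surface as a large finite objective with a
  # diagnostic instead of crashing the optimizer
  bad_om <- observation_model(list(pMET = list(states = "NOT_A_STATE"),
                                   pERK = list(states = "pERK")))
  bad <- fit_problem(net, bad_om, data, p, free = "k_basal_MET")
  nb <- negloglik(bad, p0)
  expect_true(is.finite(nb))
  expect_gt(as.numeric(nb), 1e6)
  expect_match(attr(nb, "failed"), "missing state")
})

test_that("the trust-region optimizer solves quadratic problems exactly", {
  target <- c(a = 1.3, b = -0.7)
  fn <- function(p) p - target
  res <- hgfdyn:::tr_minimize(fn, c(a = 5, b = 5), lower = c(-10, -10),
                              upper = c(10, 10))
  expect_equal(res$par, target, tolerance = 1e-7)
  expect_lt(res$objective, 1e-12)
  # frozen-Jacobian refinement also contracts and never increases
  r0 <- fn(c(a = 4, b = -4))
  J <- diag(2)
  ref <- hgfdyn:::gn_refine(fn, c(a = 4, b = -4), r0, J,
                            lower = c(-10, -10), upper = c(10, 10))
  expect_lte(ref$objective, sum(r0^2))
  expect_equal(ref$par, target, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("multi-start optimization is reproducible and sorts the waterfall", {
  fn <- function(p) c(p[["a"]] - 2, 3 * (p[["b"]] + 1))
  prob <- hgfdyn:::direct_fit_problem(fn, c(a = 0, b = 0))
  f1 <- multistart_fit(prob, n_starts = 8, seed = 123)
  f2 <- multistart_fit(prob, n_starts = 8, seed = 123)
  expect_identical(f1$waterfall, f2$waterfall)
  expect_false(is.unsorted(f1$waterfall))
  expect_equal(f1$objective, min(f1$starts$objective))
  expect_equal(f1$par[["a"]], 2, tolerance = 1e-6)
  expect_equal(f1$convergence_fraction, 1)
  expect_error(multistart_fit(prob, n_starts = 0), "n_starts")
})

test_that("profile likelihood reproduces the Gaussian confidence interval", {
  set.seed(11)
  sigma <- 0.5
  yobs <- stats::rnorm(20, 1.2, sigma)
  fn <- function(p) (p[["mu"]] - yobs) / sigma
  prob <- hgfdyn:::direct_fit_problem(fn, c(mu = 0))
  fit <- multistart_fit(prob, n_starts = 3, seed = 1)
  pr <- profile_likelihood(prob, fit, "mu", step0 = 0.05)
  half <- 1.96 * sigma / sqrt(20)
  expect_true(pr$identifiable)
  expect_equal(unname(pr$ci[["upper"]] - fit$par[["mu"]]), half,
               tolerance = 0.03)
  expect_equal(unname(fit$par[["mu"]] - pr$ci[["lower"]]), half,
               tolerance = 0.03)
  # profile lower envelope never undershoots the optimum
  expect_gte(min(pr$objective), fit$objective - 1e-6)
})

test_that("structural non-identifiability yields an unbounded flat profile", {
  fn <- function(p) c(p[["a"]] + p[["b"]] - 1, 0.01 * 0)
  prob <- hgfdyn:::direct_fit_problem(fn, c(a = 0.2, b = 0.2))
  fit <- multistart_fit(prob, n_starts = 2, seed = 4)
  pr <- profile_likelihood(prob, fit, "a", max_points = 20)
  expect_false(pr$identifiable)
  expect_true(all(is.infinite(pr$ci) | abs(pr$ci) >= 9))
  expect_lt(max(pr$objective) - fit$objective, 0.5)
})

test_that("BIC follows the closed form and selects parsimonious models", {
  expect_equal(bic(10, n_data = 100, k_params = 6) -
                 bic(10, n_data = 100, k_params = 5), log(100))
  expect_lt(bic(50, 200, 4), bic(50, 200, 7))
  expect_error(bic(10, n_data = 0, k_params = 2), "positive")
  # linear-Gaussian toy: objective from an analytic least-squares solution
  set.seed(9)
  x <- 1:12
  y <- 2 * x + stats::rnorm(12)
  fn <- function(p) (p[["slope"]] * x - y)
  prob <- hgfdyn:::direct_fit_problem(fn, c(slope = 0))
  fit <- multistart_fit(prob, n_starts = 2, seed = 2)
  slope_hat <- sum(x * y) / sum(x^2)
  expect_equal(fit$par[["slope"]], slope_hat, tolerance = 1e-6)
  expect_equal(bic(fit, n_data = 12, k_params = 1),
               sum((slope_hat * x - y)^2) + log(12), tolerance = 1e-6)
})

test_that("hypothesis comparison ties duplicates and penalizes dead weight", {
  fn1 <- function(p) c(p[["a"]] - 1, p[["a"]] - 1.2)
  fn2 <- function(p) c(p[["a"]] - 1, p[["a"]] - 1.2) # ignores p[["b"]]
  p1 <- hgfdyn:::direct_fit_problem(fn1, c(a = 0))
  p2 <- hgfdyn:::direct_fit_problem(fn2, c(a = 0, b = 0))
  p2$data <- p1$data
  cmp <- compare_hypotheses(list(small = p1, twin = p1, big = p2),
                            n_starts = 2, seed = 3)
  expect_equal(cmp$bic[cmp$hypothesis == "small"],
               cmp$bic[cmp$hypothesis == "twin"])
  expect_lt(cmp$bic[cmp$hypothesis == "small"],
            cmp$bic[cmp$hypothesis == "big"])
  expect_equal(cmp$hypothesis[which.min(cmp$bic)], cmp$hypothesis[1])
  p3 <- hgfdyn:::direct_fit_problem(function(p) p[["a"]], c(a = 0))
  expect_error(compare_hypotheses(list(p1, p3)), "share the same data")
})
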