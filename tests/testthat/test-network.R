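test_that("reference network has the published structure", {
  net <- ref_net()
  expect_equal(nrow(net$species), 23L)
  expect_equal(length(net$reactions), 26L)
  expect_equal(dim(net$stoichiometry_matrix), c(23L, 26L))
  # parameter bookkeeping: 27 dynamical + 11 abundances (x2 diets = 22)
  expect_length(dynamical_parameters(net), 27L)
  expect_length(abundance_parameters(), 11L)
  expect_length(dysregulated_parameters(), 12L)
  # both pathway branches, mTOR complexes and the feedback targets present
  expect_true(all(c("pMEK", "pERK", "PI3K_act", "ppAKT", "mTORC1_act",
                    "mTORC2_act", "IRS1_act", "pS6K") %in% net$species$name))
})

test_that("conserved moieties span the left null space exactly", {
  net <- ref_net()
  S <- net$stoichiometry_matrix
  mo <- conserved_moieties(net)
  expect_gt(length(mo), 0)
  for (v in mo) expect_true(all(v %*% S == 0))
  # numeric null-space dimension agrees with the returned basis size
  expect_equal(length(mo), nrow(S) - qr(t(S))$rank)
  # ERK + pERK is conserved; MET is in no (nontrivial) moiety
  in_moiety <- function(sp) any(vapply(mo, function(v)
    v[[sp]] != 0 && sum(v != 0) > 1, TRUE))
  expect_true(in_moiety("ERK"))
  expect_true(in_moiety("pERK"))
  expect_false(in_moiety("MET"))
  expect_false(in_moiety("pMET"))
})

test_that("condition resolution separates shared and diet-specific values", {
  ps <- parameter_set(default_true_parameters())
  shared_map <- condition_map(c("SD", "WD"))
  expect_identical(resolve_parameters(ps, shared_map, "SD"),
                   resolve_parameters(ps, shared_map, "WD"))
  gt <- ref_truth()
  vsd <- resolve_parameters(parameter_set(gt$params_sd), gt$cmap, "SD")
  vwd <- resolve_parameters(parameter_set(gt$params_sd), gt$cmap, "WD")
  differing <- names(vsd)[vsd != vwd]
  expect_true(all(differing %in% dysregulated_parameters()))
  expect_true(all(c("k_basal_MET", "conc_MET", "conc_TSC") %in% differing))
  expect_error(resolve_parameters(ps, gt$cmap, "HFD"), "unknown condition")
  expect_error(condition_map("SD", specific = "k_basal_MET",
                             overrides = list(SD = c(k_deg_MET = 1))),
               "shared parameter")
})

test_that("steady state matches closed forms and long-run integration", {
  # isolated turnover: R_ss = kp / kd
  ss <- steady_state(toy_turnover(), c(kp = 120, kd = 0.4),
                     x0 = c(R = 1))
  expect_equal(unname(ss[["R"]]), 300, tolerance = 1e-8)
  # full network: fixed-point property under further simulation
  net <- ref_net()
  p <- default_true_parameters()
  ss <- steady_state(net, p)
  traj <- simulate_hgf(net, p, dose = 0, times = c(0, 60, 240), x0 = ss)
  drift <- abs(traj$states[, 3] - traj$states[, 1]) /
    pmax(abs(traj$states[, 1]), 1)
  expect_lt(max(drift), 1e-6)
  # brute-force oracle: long-run numeric integration at random parameters
  set.seed(42)
  pr <- p * exp(stats::rnorm(length(p), 0, 0.3))
  names(pr) <- names(p)
  ss_newton <- steady_state(net, pr)
  x0 <- hgfdyn:::initial_state(net, pr, dose = 0)
  rk <- hgfdyn:::reaction_rate_constants(net, pr)
  out <- hgfdyn:::integrate_net(net, x0, rk, c(0, 1e6))
  ss_brute <- as.numeric(out[2, -1])
  expect_equal(unname(ss_newton), ss_brute,
               tolerance = 1e-6)
})

test_that("simulation matches the analytic two-state relaxation", {
  a <- 0.21; b <- 0.13
  x0 <- c(A = 1000, pA = 0)
  tt <- c(0, 1, 3, 8, 20, 50)
  traj <- simulate_hgf(toy_cycle(), c(a = a, b = b, hgf_scale = 1),
                       dose = 0, times = tt, x0 = x0)
  # pA(t) = total * a/(a+b) * (1 - exp(-(a+b) t))
  expect_equal(unname(traj$states["pA", ]),
               1000 * a / (a + b) * (1 - exp(-(a + b) * tt)),
               tolerance = 1e-6)
})

test_that("simulations preserve moieties, nonnegativity and basal constancy", {
  net <- ref_net()
  gt <- ref_truth()
  for (p in list(gt$params_sd, gt$params_wd)) {
    traj <- simulate_hgf(net, p, dose = 40, times = seq(0, 240, 10))
    expect_gte(min(traj$states), -1e-9)
    for (v in conserved_moieties(net)) {
      tot <- as.numeric(v %*% traj$states)
      if (abs(tot[1]) < 1e-12) next
      expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 1e-6)
    }
  }
  flat <- simulate_hgf(net, gt$params_sd, dose = 0, times = c(0, 30, 240))
  expect_lt(max(abs(flat$states - flat$states[, 1])) /
              max(flat$states), 1e-6)
})

test_that("peak pMET is non-decreasing in dose and WD suppresses ppAKT", {
  net <- ref_net()
  om <- default_observation_model()
  gt <- ref_truth()
  x0 <- steady_state(net, gt$params_sd)
  peaks <- vapply(c(0.1, 1, 4, 20, 40, 120), function(d) {
    tr <- simulate_hgf(net, gt$params_sd, d, c(0, 10), x0 = x0)
    observe(tr, om)[2, "pMET"]
  }, 0)
  expect_false(is.unsorted(peaks))
  f_sd <- extract_features(simulate_hgf(net, gt$params_sd, 40,
                                        seq(0, 240, 5)), om)
  f_wd <- extract_features(simulate_hgf(net, gt$params_wd, 40,
                                        seq(0, 240, 5)), om)
  expect_gt(f_wd[["basal_pMET"]], f_sd[["basal_pMET"]])
  expect_lt(f_wd[["auc_ppAKT"]], f_sd[["auc_ppAKT"]])
})

test_that("compiled derivatives agree with the R implementation", {
  net <- ref_net()
  p <- default_true_parameters()
  rk <- hgfdyn:::reaction_rate_constants(net, p)
  set.seed(7)
  for (i in 1:5) {
    x <- stats::setNames(stats::runif(23, 0, 1e5), net$species$name)
    r_rhs <- hgfdyn:::ma_rhs(net, x, rk)
    # drive the compiled code through a zero-length integration step
    out <- deSolve::lsoda(y = x, times = c(0, 1e-8), func = "hgfdyn_derivs",
                          parms = hgfdyn:::pack_ode_parms(net, rk),
                          dllname = "hgfdyn", initfunc = "hgfdyn_initmod")
    c_step <- (as.numeric(out[2, -1]) - unname(x)) / 1e-8
    expect_equal(unname(c_step), unname(r_rhs), tolerance = 1e-4)
  }
})
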