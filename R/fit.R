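## Maximum-likelihood calibration: weighted-residual objective over aligned
## immunoblot data and abundance observations, multi-start trust-region
## (Levenberg-Marquardt) optimization on the log-parameter scale, BIC and
## hypothesis comparison.

#' Construct a fit problem
#'
#' Free parameters live on the natural-log scale. A free parameter named
#' `"p"` is shared across all conditions; `"p|COND"` is specific to condition
#' `COND`. The -2 log-likelihood is the sum of squared standardized residuals
#' over blot data points (plus abundance observations if supplied), dropping
#' constant terms.
#'
#' @param net A `reaction_network`.
#' @param om An `observation_model`.
#' @param data Aligned measurements: `data.frame` with columns `target`,
#'   `condition`, `dose`, `time`, `y`, `sigma`.
#' @param base_params Full named native-scale parameter vector; fixed
#'   parameters keep these values.
#' @param free Character vector of free parameter names (`"p"` or `"p|COND"`).
#' @param lower,upper Named (or scalar) log-scale bounds for the free
#'   parameters; defaults are +/- `default_width` around log(base).
#' @param abundance Optional abundance observations: `data.frame` with columns
#'   `param`, `condition`, `log2_molecules`, `sd` entering the likelihood as
#'   log2-scale Gaussian observations of the abundance parameters.
#' @param log_residuals If `TRUE`, blot residuals are computed on the log
#'   scale (log-normal error model), as used for the patient data.
#' @param default_width Half-width of the default log-scale box.
#' @param label Hypothesis label used in comparisons.
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(net, om, data, base_params, free,
                        lower = NULL, upper = NULL, abundance = NULL,
                        log_residuals = FALSE, default_width = log(100),
                        label = "fit") {
  conds <- unique(data$condition)
  split_free <- strsplit(free, "|", fixed = TRUE)
  pname <- vapply(split_free, `[[`, "", 1)
  is_scale <- startsWith(pname, "scale_")
  unknown <- setdiff(pname[!is_scale], names(base_params))
  if (length(unknown))
    stop("free parameters not in base_params: ",
         paste(unknown, collapse = ", "))
  start <- numeric(length(free))
  start[!is_scale] <- log(base_params[pname[!is_scale]])
  names(start) <- free
  low <- start - default_width
  up <- start + default_width
  if (!is.null(lower)) low[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  if (any(!is.finite(low)) || any(!is.finite(up)))
    stop("every free parameter needs finite bounds")
  ## pre-resolved evaluation plan: per condition, per dose, the simulation
  ## grid and the index maps from simulated observables to data rows
  plan <- lapply(conds, function(cond) {
    sub <- data[data$condition == cond, , drop = FALSE]
    dplans <- lapply(unique(sub$dose), function(d) {
      ri <- sub$dose == d
      tt <- sort(unique(c(0, sub$time[ri])))
      list(dose = d, times = tt, t_idx = match(sub$time[ri], tt),
           targets = sub$target[ri], y = sub$y[ri], sigma = sub$sigma[ri])
    })
    ab <- if (!is.null(abundance))
      abundance[abundance$condition == cond, , drop = FALSE] else NULL
    list(condition = cond, dplans = dplans, abundance = ab)
  })
  structure(list(net = net, om = om, data = data, base_params = base_params,
                 free = free, lower = low, upper = up,
                 abundance = abundance, log_residuals = log_residuals,
                 label = label, conditions = conds, plan = plan,
                 ss_cache = new.env(parent = emptyenv())),
            class = "fit_problem")
}

## native-scale full parameter vector for one condition given log-scale free
## values; "scale_<target>" entries are observation scales, not model
## parameters, and are resolved separately
resolve_fit_parameters <- function(problem, p_log, condition) {
  p <- problem$base_params
  nm <- names(p_log)
  keep <- !startsWith(nm, "scale_")
  nm <- nm[keep]; p_log <- p_log[keep]
  shared <- !grepl("|", nm, fixed = TRUE)
  p[nm[shared]] <- exp(p_log[nm[shared]])
  spec <- strsplit(nm[!shared], "|", fixed = TRUE)
  for (s in spec) {
    if (s[2] == condition)
      p[s[1]] <- exp(p_log[[paste(s[1], s[2], sep = "|")]])
  }
  p
}

## per-target observation scale factors implied by the free parameters
resolve_obs_scales <- function(p_log, targets) {
  s <- stats::setNames(rep(1, length(targets)), targets)
  nm <- names(p_log)[startsWith(names(p_log), "scale_")]
  for (n in nm) {
    tg <- sub("^scale_", "", n)
    if (tg %in% targets) s[tg] <- exp(p_log[[n]])
  }
  s
}

## number of data points entering the likelihood
n_datapoints <- function(problem) {
  nrow(problem$data) +
    if (is.null(problem$abundance)) 0L else nrow(problem$abundance)
}

## fit-problem wrapper around a plain residual function (no ODE model);
## used for optimizer and profile-likelihood oracles
direct_fit_problem <- function(residual_fn, start, lower = start - 10,
                               upper = start + 10, label = "direct") {
  r0 <- residual_fn(start)
  structure(list(residual_fn = residual_fn, free = names(start),
                 lower = stats::setNames(lower, names(start)),
                 upper = stats::setNames(upper, names(start)),
                 data = data.frame(idx = seq_along(r0)), abundance = NULL,
                 base_params = exp(start), label = label,
                 conditions = character(0), plan = list(),
                 ss_cache = new.env(parent = emptyenv())),
            class = "fit_problem")
}

#' Standardized residual vector of a fit problem
#'
#' @param problem A `fit_problem`.
#' @param p_log Named log-scale vector of the free parameters.
#' @return Numeric residual vector; integration failures yield a vector of
#'   large constants (infinite objective surrogate) carrying attribute
#'   `failed`.
#' @export
fit_residuals <- function(problem, p_log) {
  if (!is.null(problem$residual_fn)) return(problem$residual_fn(p_log))
  res <- tryCatch({
    out <- list()
    k <- 0L
    for (cp in problem$plan) {
      p <- resolve_fit_parameters(problem, p_log, cp$condition)
      x0 <- steady_state(problem$net, p,
                         x_start = problem$ss_cache[[cp$condition]])
      problem$ss_cache[[cp$condition]] <- x0
      sc <- resolve_obs_scales(p_log, names(problem$om$maps))
      for (dp in cp$dplans) {
        traj <- simulate_hgf(problem$net, p, dose = dp$dose,
                             times = dp$times, x0 = x0,
                             condition = cp$condition)
        obs <- observe(traj, problem$om)
        sim <- obs[cbind(dp$t_idx, match(dp$targets, colnames(obs)))] *
          sc[dp$targets]
        k <- k + 1L
        out[[k]] <- if (problem$log_residuals)
          (log(pmax(sim, 1e-12)) - log(dp$y)) / (dp$sigma / dp$y)
        else (sim - dp$y) / dp$sigma
      }
      if (!is.null(cp$abundance) && nrow(cp$abundance)) {
        k <- k + 1L
        out[[k]] <- (log2(p[cp$abundance$param]) -
                       cp$abundance$log2_molecules) / cp$abundance$sd
      }
    }
    unlist(out[seq_len(k)], use.names = FALSE)
  }, error = function(e) {
    structure(rep(1e4, n_datapoints(problem)), failed = conditionMessage(e))
  })
  res
}

#' -2 log-likelihood (up to constants)
#'
#' @inheritParams fit_residuals
#' @return Sum of squared standardized residuals; `+Inf`-like large value if
#'   the integration failed (with attribute `failed`).
#' @export
negloglik <- function(problem, p_log) {
  r <- fit_residuals(problem, p_log)
  structure(sum(r^2), failed = attr(r, "failed"))
}

## Levenberg-Marquardt (trust-region least squares) with box bounds; thin
## wrapper used for fits and profile re-optimizations
tr_minimize <- function(residual_fn, start, lower, upper, maxiter = 75,
                        ftol = 1e-10, ptol = 1e-9) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                       lower = lower, upper = upper, fn = residual_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = ftol, ptol = ptol,
                         # forward-difference step ~1e-4: residuals carry
                         # ODE-solver noise well above machine precision
                         epsfcn = 1e-8,
                         maxfev = 100 * (length(start) + 1))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = start, objective = Inf, converged = FALSE))
  list(par = stats::setNames(fit$par, names(start)),
       objective = fit$deviance, converged = fit$info %in% 1:4)
}

#' Deterministic multi-start maximum-likelihood fit
#'
#' Starts are drawn by seeded Latin-hypercube sampling over the log-scale
#' bounds and each is optimized to local convergence with the
#' Levenberg-Marquardt trust-region method; the sorted final objectives form
#' the waterfall.
#'
#' @param problem A `fit_problem`.
#' @param n_starts Number of starts (>= 1).
#' @param seed Integer seed.
#' @param include_base If `TRUE`, the first drawn start is replaced by the
#'   data-informed starting point ([informed_start()]).
#' @param maxiter Iteration cap per start.
#' @param tol Objective tolerance defining convergence to the global optimum.
#' @param polish_iter If positive, the best solution is additionally polished
#'   with a derivative-free Nelder-Mead pass of this many iterations followed
#'   by a final trust-region refinement; the simplex search follows narrow
#'   curved valleys where finite-difference gradients carry solver noise.
#' @return Object of class `fit_result`: best log-scale parameters, best
#'   objective, sorted `waterfall`, per-start table, convergence fraction,
#'   data count and free-parameter count.
#' @export
multistart_fit <- function(problem, n_starts = 10, seed = 1,
                           include_base = FALSE, maxiter = 75, tol = 0.01,
                           polish_iter = 0) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  np <- length(problem$free)
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, np)
  starts <- sweep(sweep(u, 2, problem$upper - problem$lower, `*`),
                  2, problem$lower, `+`)
  colnames(starts) <- problem$free
  if (include_base)
    starts[1, ] <- informed_start(problem)
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tr_minimize(function(p) {
      names(p) <- problem$free
      fit_residuals(problem, p)
    }, stats::setNames(starts[i, ], problem$free),
    problem$lower, problem$upper, maxiter = maxiter)
  }
  obj <- vapply(runs, `[[`, 0, "objective")
  if (all(!is.finite(obj)))
    stop("all starts failed: ",
         paste(unique(vapply(runs, function(r)
           as.character(r$objective), "")), collapse = "; "))
  ord <- order(obj)
  best <- runs[[ord[1]]]
  if (polish_iter > 0 && is.finite(best$objective)) {
    clamp <- function(q) stats::setNames(pmin(pmax(q, problem$lower),
                                              problem$upper), problem$free)
    nm <- stats::optim(best$par, function(q)
      sum(fit_residuals(problem, clamp(q))^2),
      method = "Nelder-Mead",
      control = list(maxit = polish_iter, reltol = 1e-10))
    if (nm$value < best$objective) {
      ref <- tr_minimize(function(p) {
        names(p) <- problem$free
        fit_residuals(problem, p)
      }, clamp(nm$par), problem$lower, problem$upper, maxiter = maxiter)
      if (ref$objective < nm$value)
        best <- list(par = ref$par, objective = ref$objective)
      else best <- list(par = clamp(nm$par), objective = nm$value)
    }
  }
  structure(list(par = best$par, objective = best$objective,
                 waterfall = obj[ord],
                 starts = data.frame(start = seq_len(n_starts),
                                     objective = obj),
                 ## share of starts on the waterfall's lowest plateau (the
                 ## polished optimum may lie below it)
                 convergence_fraction = mean(obj <= obj[ord[1]] + tol),
                 n_data = n_datapoints(problem),
                 k_params = np, problem = problem),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$k_params, "free parameters,", x$n_data,
      "data points\n  best -2logL:", format(x$objective),
      " convergence:", round(100 * x$convergence_fraction), "% of",
      length(x$waterfall), "starts\n")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 ln(L)`; with the Gaussian residual convention the
#' `-2 ln(L)` term is the fit objective (constants dropped). Lower is better.
#'
#' @param fit A `fit_result` (or a number interpreted as the objective).
#' @param n_data Number of data points (defaults to the fit's count).
#' @param k_params Number of free parameters (defaults to the fit's count).
#' @return BIC value.
#' @export
bic <- function(fit, n_data = NULL, k_params = NULL) {
  obj <- if (inherits(fit, "fit_result")) fit$objective else fit
  if (is.null(n_data)) n_data <- fit$n_data
  if (is.null(k_params)) k_params <- fit$k_params
  if (n_data <= 0) stop("n_data must be positive")
  obj + k_params * log(n_data)
}

#' Compare diet-hypothesis fit problems by BIC
#'
#' All problems must share the same data; each is fitted by multi-start
#' optimization and ranked by BIC ascending.
#'
#' @param problems Named list of `fit_problem`s (names = hypothesis labels).
#' @param n_starts,seed,maxiter Passed to [multistart_fit()].
#' @param include_base Passed to [multistart_fit()].
#' @param polish_iter Nelder-Mead polish budget per hypothesis (see
#'   [multistart_fit()]); model selection presupposes converged fits.
#' @return `data.frame` (hypothesis, objective, k, n, bic) sorted by BIC, with
#'   the fits in `attr(,"fits")`.
#' @export
compare_hypotheses <- function(problems, n_starts = 5, seed = 1,
                               include_base = FALSE, maxiter = 75,
                               polish_iter = 2000) {
  ref <- problems[[1]]$data
  for (p in problems)
    if (!identical(p$data, ref))
      stop("hypotheses must share the same data")
  fits <- lapply(seq_along(problems), function(i)
    multistart_fit(problems[[i]], n_starts = n_starts, seed = seed + i,
                   include_base = include_base, maxiter = maxiter,
                   polish_iter = polish_iter))
  labels <- names(problems)
  if (is.null(labels)) labels <- vapply(problems, `[[`, "", "label")
  tab <- data.frame(
    hypothesis = labels,
    objective = vapply(fits, `[[`, 0, "objective"),
    k = vapply(fits, `[[`, 0L, "k_params"),
    n = vapply(fits, `[[`, 0L, "n_data"))
  tab$bic <- tab$objective + tab$k * log(tab$n)
  ord <- order(tab$bic)
  out <- tab[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  out
}
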