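## ODE simulation layer: compiled mass-action right-hand side (src/massaction.c)
## driven through deSolve::lsoda, steady-state pre-equilibration by long-run
## integration plus a Newton polish on the conservation-constrained system.

MA_PARMS_LEN <- 4096L

## pack network structure + per-reaction rate constants into the fixed-length
## parms vector consumed by the compiled derivatives; the structural part is
## cached in an environment keyed by the network identity
.pack_cache <- new.env(parent = emptyenv())

pack_ode_parms <- function(net, rate_k) {
  S <- net$stoichiometry_matrix
  key <- paste(nrow(S), ncol(S), sum(S != 0), sum(abs(S)),
               paste(rownames(S), collapse = ","),
               paste(colnames(S), collapse = ","), sep = "|")
  entry <- .pack_cache[[key]]
  if (is.null(entry)) {
    ns <- nrow(S); nr <- ncol(S)
    sp <- rownames(S)
    fac <- matrix(0, 3, nr)
    for (j in seq_len(nr)) {
      r <- net$reactions[[j]]
      f <- c(rep(names(r$reactants), r$reactants), r$modifiers)
      if (length(f) > 3) stop("more than 3 rate factors in reaction ", r$name)
      if (length(f)) fac[seq_along(f), j] <- match(f, sp)
    }
    nz <- which(S != 0, arr.ind = TRUE)
    tri <- rbind(nz[, 1], nz[, 2], S[nz])
    p <- c(ns, nr, nrow(nz), rate_k, as.numeric(fac), as.numeric(tri))
    if (length(p) > MA_PARMS_LEN) stop("network too large for packed parms")
    entry <- list(template = c(p, numeric(MA_PARMS_LEN - length(p))),
                  nr = nr)
    .pack_cache[[key]] <- entry
  }
  p <- entry$template
  p[3 + seq_len(entry$nr)] <- rate_k
  p
}

## R-side rate vector, RHS and Jacobian (used by the Newton polish and for
## testing the compiled code against an independent implementation); the
## factor-index structure is cached alongside the packed parms
rate_factors <- function(net) {
  cached <- attr(net, "rate_factors")
  if (!is.null(cached)) return(cached)
  nr <- length(net$reactions)
  sp <- net$species$name
  fac <- matrix(0L, 3, nr)
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    f <- c(rep(names(r$reactants), r$reactants), r$modifiers)
    if (length(f)) fac[seq_along(f), j] <- match(f, sp)
  }
  fac
}

ma_rates <- function(net, x, rate_k) {
  fac <- rate_factors(net)
  xp <- c(1, pmax(x, 0))  # index 1 = absent factor slot
  rate_k * xp[fac[1, ] + 1L] * xp[fac[2, ] + 1L] * xp[fac[3, ] + 1L]
}

ma_rhs <- function(net, x, rate_k) {
  as.numeric(net$stoichiometry_matrix %*% ma_rates(net, x, rate_k))
}

ma_jacobian <- function(net, x, rate_k) {
  S <- net$stoichiometry_matrix
  nr <- ncol(S)
  fac <- rate_factors(net)
  xp <- c(1, pmax(x, 0))
  f1 <- xp[fac[1, ] + 1L]; f2 <- xp[fac[2, ] + 1L]; f3 <- xp[fac[3, ] + 1L]
  dR <- matrix(0, nr, nrow(S))
  prods <- cbind(f2 * f3, f1 * f3, f1 * f2)
  for (m in 1:3) {
    sel <- which(fac[m, ] > 0L)
    for (j in sel)
      dR[j, fac[m, j]] <- dR[j, fac[m, j]] + rate_k[j] * prods[j, m]
  }
  S %*% dR
}

## pre-stimulation initial state: abundance parameters fill the unmodified
## pools, modified forms start at zero, HGF at the (scaled) dose
initial_state <- function(net, params, dose = 0) {
  sp <- net$species
  x <- stats::setNames(numeric(nrow(sp)), sp$name)
  pool <- c(MET = "conc_MET", MEK = "conc_MEK", ERK = "conc_ERK",
            PI3K = "conc_PI3K", AKT = "conc_AKT", TSC = "conc_TSC",
            mTORC1 = "conc_mTORC1", S6K = "conc_S6K", S6 = "conc_S6",
            mTORC2 = "conc_mTORC2", IRS1_act = "conc_IRS1")
  for (s in intersect(names(pool), sp$name))
    if (pool[[s]] %in% names(params)) x[s] <- params[[pool[[s]]]]
  if ("HGF" %in% sp$name)
    x["HGF"] <- dose * if ("hgf_scale" %in% names(params))
      params[["hgf_scale"]] else 1
  x
}

integrate_net <- function(net, x0, rate_k, times,
                          rtol = getOption("hgfdyn.rtol", 1e-8),
                          atol = getOption("hgfdyn.atol", 1e-10)) {
  out <- deSolve::lsoda(y = x0, times = times, func = "hgfdyn_derivs",
                        parms = pack_ode_parms(net, rate_k),
                        dllname = "hgfdyn", initfunc = "hgfdyn_initmod",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("ODE integration failed (istate ", attr(out, "istate")[1], ")")
  out
}

#' Pre-stimulation steady state
#'
#' Equilibrates the network at zero HGF dose: long-run numeric integration
#' followed by a Newton polish on the system with conservation relations
#' substituted for the dependent species.
#'
#' @param net A `reaction_network`.
#' @param params Named native-scale parameter vector (rate constants,
#'   abundances, `hgf_scale`).
#' @param x0 Optional reference state defining the conserved-moiety totals;
#'   defaults to [initial_state()] at dose 0.
#' @param tol Convergence tolerance on the relative right-hand side.
#' @param x_start Optional warm-start state for the Newton iteration (the
#'   conserved totals still come from `x0`).
#' @return Named steady-state vector.
#' @export
steady_state <- function(net, params, x0 = NULL, tol = 1e-10,
                         x_start = NULL) {
  rate_k <- reaction_rate_constants(net, params)
  if (is.null(x0)) x0 <- initial_state(net, params, dose = 0)
  scale <- max(abs(x0), 1)
  mo <- conserved_moieties(net)
  dep <- integer(0)
  C <- NULL
  for (v in mo) {
    cand <- setdiff(which(v != 0), dep)
    if (!length(cand)) next
    dep <- c(dep, cand[which.max(abs(v[cand]))])
    C <- rbind(C, v)
  }
  totals <- if (length(dep)) as.numeric(C %*% x0) else numeric(0)
  newton <- function(x, iters = 30) {
    for (it in seq_len(iters)) {
      f <- ma_rhs(net, x, rate_k)
      if (max(abs(f)) / scale < tol * 1e-2) break
      J <- ma_jacobian(net, x, rate_k)
      if (length(dep)) {
        f[dep] <- as.numeric(C %*% x) - totals
        J[dep, ] <- C
      }
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        xn <- x + lam * step
        if (all(xn > -0.2 * scale) || lam < 1e-3) break
        lam <- lam / 2
      }
      xn[xn < 0] <- 0
      x <- stats::setNames(xn, names(x0))
    }
    x
  }
  ## Newton directly from the supplied (or warm) state; numeric
  ## pre-equilibration in expanding windows as fallback for poor starts
  x <- newton(if (is.null(x_start)) x0 else x_start)
  if (max(abs(ma_rhs(net, x, rate_k))) / scale >= tol || any(x < 0)) {
    x <- x0
    t_end <- 1e4
    for (it in 1:4) {
      out <- integrate_net(net, x, rate_k, c(0, t_end))
      x <- stats::setNames(as.numeric(out[2, -1]), names(x0))
      if (max(abs(ma_rhs(net, x, rate_k))) / scale < tol) break
      t_end <- t_end * 100
    }
    x <- newton(x)
  }
  if (max(abs(ma_rhs(net, x, rate_k))) / scale > 1e-6)
    stop("steady state did not converge")
  x
}

#' Simulate an HGF stimulation time course
#'
#' The system is pre-equilibrated at zero dose, then HGF is applied as a
#' constant input from t = 0 and the trajectory integrated on the requested
#' time grid (minutes; states in molecules/cell).
#'
#' @param net A `reaction_network`.
#' @param params Named native-scale parameter vector.
#' @param dose HGF dose in ng/ml.
#' @param times Sorted output times starting at 0 (minutes).
#' @param condition Optional condition label stored with the trajectory.
#' @param x0 Optional pre-equilibrated state (skips the steady-state solve).
#' @return A `trajectory_set`: list with `times`, `states` (species x time
#'   matrix) and `condition`.
#' @export
simulate_hgf <- function(net, params, dose, times, condition = NA_character_,
                         x0 = NULL) {
  if (is.unsorted(times) || times[1] != 0)
    stop("times must be sorted and start at 0")
  if (is.null(x0)) x0 <- steady_state(net, params)
  if ("HGF" %in% net$species$name)
    x0["HGF"] <- dose * if ("hgf_scale" %in% names(params))
      params[["hgf_scale"]] else 1
  rate_k <- reaction_rate_constants(net, params)
  out <- integrate_net(net, x0, rate_k, times)
  states <- t(unname(out[, -1, drop = FALSE]))
  rownames(states) <- net$species$name
  if (min(states) < -1e-6 * max(abs(states)))
    stop("negative state beyond tolerance in simulation")
  states[states < 0] <- 0
  structure(list(times = times, states = states, condition = condition),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", nrow(x$states), "species x", length(x$times),
      "times", if (!is.na(x$condition)) paste0("(", x$condition, ")"), "\n")
  invisible(x)
}
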