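# Shared fixtures, memoized so expensive objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ref_net <- function() memo("net", build_hgf_network())

ref_truth <- function() memo("truth", ground_truth())

# reduced immunoblot design used by the calibration studies: full time course,
# three-dose response, five targets
reduced_design <- function() {
  des <- default_blot_design(targets = c("pMET", "pERK", "ppAKT_S473",
                                         "pS6", "tMET"))
  des$dose_response$doses <- c(0, 4, 40)
  des
}

# two-state phosphorylation cycle A <-> pA with rates (a, b); linear system
# with closed-form relaxation rate a + b
toy_cycle <- function() {
  memo("toy_cycle", {
    sp <- list(species("A", "kinase", "free-parameter"),
               species("pA", "kinase", "derived"))
    rx <- list(reaction("phos", reactants = c(A = 1L), products = c(pA = 1L),
                        rate_parameter = "a"),
               reaction("dephos", reactants = c(pA = 1L),
                        products = c(A = 1L), rate_parameter = "b"))
    reaction_network(sp, rx)
  })
}

# isolated receptor turnover: production and first-order degradation
toy_turnover <- function() {
  memo("toy_turnover", {
    sp <- list(species("R", "receptor", "free-parameter"))
    rx <- list(reaction("prod", products = c(R = 1L), rate_parameter = "kp"),
               reaction("deg", reactants = c(R = 1L), rate_parameter = "kd"))
    reaction_network(sp, rx)
  })
}

# deterministic multi-gel raw measurements from known (y, s), optionally noisy
make_raw_blots <- function(y, s, e_rel = 0, seed = NULL, target = "pMET") {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (j in seq_along(s)) {
    noise <- if (e_rel > 0) 1 + e_rel * stats::rnorm(length(y)) else 1
    rows[[j]] <- data.frame(target = target, condition = "SD", dose = 40,
                            time = seq_along(y), experiment = paste0("g", j),
                            value = y / s[j] * noise)
  }
  do.call(rbind, rows)
}

# direct trajectory container for feature tests
make_traj <- function(times, ppakt, pmet = 0, perk = 0) {
  states <- matrix(0, nrow = 23, ncol = length(times),
                   dimnames = list(ref_net()$species$name, NULL))
  states["ppAKT", ] <- ppakt
  states["pMET", ] <- pmet
  states["pERK", ] <- perk
  structure(list(times = times, states = states, condition = "toy"),
            class = "trajectory_set")
}
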