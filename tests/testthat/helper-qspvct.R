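# Shared fixtures and independent oracles.

# pre-treatment initial condition for the default patient (computed once)
fixture_default_init <- local({
  p <- default_parameters()
  fl <- plausibility_filter(grow_pretreatment(p, grid_days = 10), p)
  stopifnot(fl$accepted)
  fl$init
})

# small plausible cohort for trial-level tests (computed once)
make_fixture_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 20, seed = 101) {
    key <- paste(n, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_cohort(default_parameter_distributions(),
                                      n = n, seed = seed, grid_days = 10)
    cache[[key]]
  }
})

# brute-force Kaplan-Meier product-limit estimate (independent of the
# survival package): S(t) = prod over event times <= t of (1 - d_i/n_i)
km_brute_force <- function(times, censored, eval_times) {
  ev <- sort(unique(times[!censored]))
  vapply(eval_times, function(t0) {
    s <- 1
    for (te in ev[ev <= t0]) {
      n_risk <- sum(times >= te)
      d <- sum(times == te & !censored)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# steady state of the two-mask opening/closing Markov chain (states:
# 0, 1, 2 masks open; per-mask opening rate k*K_M, closing rate k)
mask_equilibrium_open_fraction <- function(K_M, k = 1) {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 2 * k * K_M; Q[2, 1] <- k
  Q[2, 3] <- k * K_M;     Q[3, 2] <- 2 * k
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 3))
  pi_ <- qr.solve(A, c(0, 0, 0, 1))
  1 - pi_[1]  # at least one mask open
}

# minimal hand-built trajectory carrying antibody state, for exposure
# oracles
make_const_exposure_traj <- function(amount_mol, days, compartment = "central",
                                     dose_mg_per_kg = 10) {
  p <- default_parameters()
  reg <- regimen(dose_mg_per_kg, interval_days = 2 * days,
                 duration_days = days, arm = "unmasked")
  st <- matrix(0, days + 1, length(qspvct:::.qsp_state_names),
               dimnames = list(NULL, qspvct:::.qsp_state_names))
  col <- switch(compartment, central = "Ac_C", tumor = "Ac_T",
                peripheral = "Ac_P", tdln = "Ac_LN")
  vol <- switch(compartment, central = p[["V_C"]], tumor = p[["V_T"]],
                peripheral = p[["V_P"]], tdln = p[["V_LN"]])
  st[, col] <- amount_mol / vol
  structure(list(time = 0:days, state = st,
                 diameter = rep(1, days + 1), params = p, regimen = reg),
            class = "qsp_trajectory")
}
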