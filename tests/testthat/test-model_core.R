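test_that("unmasked fraction matches the two-mask equilibrium and its limits", {
  expect_identical(unmasked_fraction(0), 0)
  expect_identical(unmasked_fraction(Inf), 1)
  expect_error(unmasked_fraction(-0.1), "non-negative")
  # strictly increasing
  g <- unmasked_fraction(c(0.001, 0.01, 0.1, 1, 10, 100))
  expect_true(all(diff(g) > 0))
  # brute-force steady state of the mask opening/closing chain
  for (km in c(0.02, 0.3, 1, 5))
    expect_equal(unmasked_fraction(km),
                 mask_equilibrium_open_fraction(km), tolerance = 1e-10)
  # frozen regression value at K_M = 1 (computed from the chain)
  expect_equal(unmasked_fraction(1), 0.75, tolerance = 1e-12)
})

test_that("tumor diameter geometry: zero, scaling and exact inversion", {
  p <- default_parameters()
  expect_identical(tumor_diameter(0, p), 0)
  n <- 10^(4:10)
  expect_equal(tumor_diameter(2 * n, p) / tumor_diameter(n, p),
               rep(2^(1 / 3), length(n)), tolerance = 1e-12)
  d <- c(0.5, 1, 2.7, 5)
  expect_equal(tumor_diameter(cells_from_diameter(d, p), p), d,
               tolerance = 1e-12)
  expect_error(tumor_diameter(-1, p), ">= 0")
})

test_that("derivatives: absorbing zero state, loss-only sign, errors", {
  p <- default_parameters()
  d0 <- qsp_derivatives(initial_state(p, 0), params = p)
  expect_true(all(d0 == 0))
  # growth rate 0 with cells and effectors present: cancer only decays
  pz <- default_parameters(k_growth = 0)
  s <- initial_state(pz, 1e9); s[["T8"]] <- 1e7; s[["Tr"]] <- 1e6
  expect_lte(qsp_derivatives(s, params = pz)[["C"]], 0)
  # configuration error names the missing parameter
  pb <- p[setdiff(names(p), "k_cvg")]
  expect_error(qsp_derivatives(s, params = pb), "k_cvg")
  s2 <- s; s2[["C"]] <- -1
  expect_error(qsp_derivatives(s2, params = pz), "negative state")
})

test_that("single-species logistic tumor matches the closed form", {
  p <- default_parameters(A_pool = 0, M_pool = 0, k_growth = 0.01,
                          C_max = 1e10)
  tr <- simulate_patient(p, init = initial_state(p, 1e6), t_span = 1000)
  C0 <- 1e6; K <- 1e10; r <- 0.01
  Cth <- K * C0 * exp(r * tr$time) / (K + C0 * (exp(r * tr$time) - 1))
  expect_equal(unname(tr$state[, "C"]), Cth, tolerance = 1e-6)
})

test_that("one bolus with linear elimination follows exponential decay", {
  p <- default_parameters(Q_T = 0, Q_P = 0, Q_LN = 0, k_cl = 0.3,
                          k_shed = 0, A_pool = 0, M_pool = 0)
  tr <- simulate_patient(p, init = initial_state(p, 0), t_span = 50,
                         regimen = regimen(10, 1000, 1000, "unmasked"))
  A0 <- 10 * p[["BW"]] / (p[["MW"]] * p[["V_C"]])
  expect_equal(unname(tr$state[, "Ac_C"]), A0 * exp(-0.3 * tr$time),
               tolerance = 1e-6)
})

test_that("antibody mass is conserved in the closed configuration", {
  p <- default_parameters(k_cl = 0, k_b_int = 0, k_cvg = 0)
  tr <- simulate_patient(p, init = initial_state(p, 1e9), t_span = 100,
                         regimen = regimen(10, 14, 100, "masked"))
  tot <- qspvct:::total_antibody(tr)
  dt <- qspvct:::dose_times(tr$regimen, 100)
  for (k in seq_along(dt)) {
    lo <- dt[k]; hi <- if (k < length(dt)) dt[k + 1] else 100
    idx <- which(tr$time > lo + 1e-9 & tr$time <= hi)
    expect_lt(diff(range(tot[idx])) / mean(tot[idx]), 1e-8)
  }
})

test_that("zero-dose regimen reproduces the dose-free simulation", {
  p <- default_parameters()
  a <- simulate_patient(p, init = fixture_default_init, t_span = 60)
  b <- simulate_patient(p, init = fixture_default_init, t_span = 60,
                        regimen = regimen(0, 14, 60, "masked"))
  expect_equal(a$state, b$state, tolerance = 1e-12)
})

test_that("compiled and R right-hand sides integrate identically", {
  p <- default_parameters()
  reg <- regimen(10, 14, 60, "masked")
  a <- simulate_patient(p, init = fixture_default_init, t_span = 60,
                        regimen = reg, grid_days = 5)
  b <- simulate_patient(p, init = fixture_default_init, t_span = 60,
                        regimen = reg, grid_days = 5, engine = "R")
  expect_equal(a$state, b$state, tolerance = 1e-6)
})

test_that("states remain non-negative within solver tolerance", {
  dists <- default_parameter_distributions()
  draws <- lhs_sample(dists, 5, seed = 77)
  for (i in seq_len(nrow(draws))) {
    pp <- qspvct:::apply_patient_params(draws[i, , drop = FALSE])
    tr <- simulate_patient(pp, init = fixture_default_init, t_span = 120,
                           regimen = regimen(10, 14, 120, "masked"))
    expect_gte(min(tr$state), -1e-9)
  }
})

test_that("checkpoint inhibition falls monotonically with antibody occupancy", {
  p <- default_parameters()
  s <- fixture_default_init
  occ0 <- synapse_occupancy(s, p)
  expect_true(all(occ0 >= 0 & occ0 <= 1))
  h <- sapply(c(0, 1e-12, 1e-11, 1e-10), function(b) {
    s2 <- s; s2[["Bc_T"]] <- b
    synapse_occupancy(s2, p)[["pd1_pdl1"]]
  })
  expect_true(all(diff(h) < 0))
})

test_that("solver and regimen argument validation", {
  p <- default_parameters()
  expect_error(simulate_patient(p, t_span = 0), "t_span")
  expect_error(regimen(interval_days = 0), "interval_days")
  expect_error(regimen(dose_mg_per_kg = -1), "dose")
  expect_error(validate_params(default_parameters(d0 = 0)), "d0")
  expect_error(validate_params(default_parameters(TCC = 0)), "TCC")
})

test_that("cleavage-rate sensitivity shrinks as the dose saturates", {
  # spread of final diameter across the calibrated k_cvg range, for
  # doses on the saturating side of the response threshold
  spread <- sapply(c(10, 20, 40), function(dose) {
    fd <- sapply(c(0.03, 0.13, 0.6), function(kc) {
      pk <- default_parameters(k_cvg = kc)
      tr <- simulate_patient(pk, init = fixture_default_init,
                             t_span = 400,
                             regimen = regimen(dose, 14, 400, "masked"),
                             rtol = 1e-6)
      tr$diameter[length(tr$diameter)]
    })
    diff(range(fd))
  })
  expect_true(all(diff(spread) < 0))
})
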