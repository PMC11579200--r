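test_that("immune ratio clamping follows the piecewise definition", {
  r <- compute_ratios(M1 = 1, M2 = 1, Treg = 0, CD8 = 2, CD4 = 1,
                      eps = 0.01)
  expect_equal(r$x1, 0.5)            # symmetric macrophages
  expect_equal(r$x2, 0.01)           # Treg fraction below the clamp
  # upper branch: raw fraction 0.999 clamps to 1 - eps
  r2 <- compute_ratios(999, 1, 1, 1, 1, eps = 0.01)
  expect_equal(r2$x1, 0.99)
  # lower branch with a zero numerator at eps = 0.05
  r3 <- compute_ratios(1, 1, 1, 1, CD4 = 0, eps = 0.05)
  expect_equal(r3$x3, 0.05)
  expect_error(compute_ratios(-1, 1, 1, 1, 1), ">= 0")
  expect_error(compute_ratios(1, 1, 1, 1, 1, eps = 0.5), "eps")
})

test_that("clamp invariant holds over random densities including zeros", {
  set.seed(42)
  for (rep in 1:50) {
    eps <- runif(1, 0.005, 0.2)
    n <- 40
    M <- matrix(rexp(5 * n), n, 5)
    M[sample(length(M), 25)] <- 0       # inject zeros, incl. 0/0 cases
    r <- compute_ratios(M[, 1], M[, 2], M[, 3], M[, 4], M[, 5], eps)
    expect_true(all(as.matrix(r) >= eps - 1e-15 &
                      as.matrix(r) <= 1 - eps + 1e-15))
  }
})

test_that("epsilon diagnostic is zero when the clamp leaves the median alone", {
  x <- c(0.2, 0.5, 0.8)
  d <- epsilon_diagnostic(x, c(0.1, 0.3))
  expect_equal(d$rel_error, c(0, 0))   # inactive clamp, then symmetric
  # the dip: eps equal to the raw median gives zero relative error
  set.seed(1)
  x2 <- rbeta(501, 2, 8)
  m <- median(x2)
  d2 <- epsilon_diagnostic(x2, c(m / 2, m, min(2 * m, 0.49)))
  expect_equal(d2$rel_error[2], 0)
  expect_gt(d2$rel_error[3], 0)        # clamp above the median pulls it up
  expect_true(is.na(epsilon_diagnostic(c(0, 0, 0), 0.1)$rel_error))
  expect_error(epsilon_diagnostic(numeric(0), 0.1), "nonempty")
})

test_that("kernel density estimates concentrate and normalize sensibly", {
  # uniform sample: back-transformed density near truth in the interior
  set.seed(5)
  u <- data.frame(x1 = runif(5000, 0.2, 0.8))
  f <- fit_density(u, constraints = "x1")
  fx <- f(data.frame(x1 = 0.5)) / 0.5  # log-space density -> density in x
  expect_lt(abs(fx - 1 / 0.6), 0.25 / 0.6)
  # an atom: evaluation elsewhere never exceeds the atom
  a <- data.frame(x1 = rep(0.3, 30))
  fa <- fit_density(a, constraints = "x1")
  expect_gt(fa(data.frame(x1 = 0.3)), fa(data.frame(x1 = 0.6)))
  # dimension contract
  r2 <- data.frame(x1 = runif(50, 0.1, 0.9), x2 = runif(50, 0.1, 0.9),
                   x3 = runif(50, 0.1, 0.9))
  expect_length(attr(fit_density(r2, c("x1", "x2")), "constraints"), 2)
  expect_length(attr(fit_density(r2, "x3"), "constraints"), 1)
  expect_error(fit_density(r2[1:5, ], "x1"), "at least")
})

test_that("inclusion probability is the clipped scaled density ratio", {
  fake <- structure(list(
    f_ref = function(x) rep(2, nrow(x)),
    f_pla = function(x) rep(1, nrow(x)),
    constraints = "x1", eps = 0.01, beta = 0.4, mode = "product"),
    class = "qsp_inclusion_model")
  x <- data.frame(x1 = c(0.3, 0.6))
  expect_equal(inclusion_probability(x, fake), c(0.8, 0.8))
  fake$beta <- 0
  expect_equal(inclusion_probability(x, fake), c(0, 0))
  fake$beta <- 10
  expect_equal(inclusion_probability(x, fake), c(1, 1))
  expect_error(inclusion_probability(x, list()), "qsp_inclusion_model")
})

test_that("beta calibration: matched cohorts accept nearly everyone", {
  ref <- ratios_from_table(make_omics_table(omics_spec(n = 1200, seed = 1)))
  pla <- ratios_from_table(make_omics_table(omics_spec(n = 1200, seed = 2)))
  m <- calibrate_beta(inclusion_model(ref, pla), pla, ref, seed = 3)
  sel <- select_vps(pla, m, seed = 4)
  expect_gt(sel$acceptance_rate_pct, 85)
})

test_that("clipping beyond the matching point raises the mismatch penalty", {
  sh <- make_shifted_cohorts(omics_spec(n = 1500, seed = 3), "x2", 1)
  ref <- ratios_from_table(sh$reference)
  pla <- ratios_from_table(sh$plausible)
  m <- inclusion_model(ref, pla, constraints = "x2")
  r <- m$f_ref(pla) / pmax(m$f_pla(pla), 1e-12)
  set.seed(11); u <- runif(nrow(pla))
  ks_at <- function(b) {
    sel <- u < pmin(1, b * r)
    qspvct:::.ks_mismatch(pla[sel, , drop = FALSE], ref, "x2")
  }
  b_star <- 0.4                     # mild clipping
  b_clip <- 5                       # clips most patients to p = 1
  expect_gt(mean(pmin(1, b_clip * r) == 1), 0.5)
  expect_gt(ks_at(b_clip), ks_at(b_star))
})

test_that("greedy (temperature-0) calibration never accepts a worse objective", {
  sh <- make_shifted_cohorts(omics_spec(n = 600, seed = 5), "x2", 1)
  ref <- ratios_from_table(sh$reference)
  pla <- ratios_from_table(sh$plausible)
  m <- calibrate_beta(inclusion_model(ref, pla, constraints = "x2"),
                      pla, ref, t0 = 0, iters = 150, seed = 6)
  expect_true(all(diff(attr(m, "trace")) >= 0))
  expect_gt(m$beta, 0)
})

test_that("stochastic selection respects the inclusion probabilities", {
  const_model <- function(p_const) structure(list(
    f_ref = function(x) rep(p_const, nrow(x)),
    f_pla = function(x) rep(1, nrow(x)),
    constraints = "x1", eps = 0.01, beta = 1, mode = "product"),
    class = "qsp_inclusion_model")
  x <- data.frame(x1 = runif(10000, 0.2, 0.8))
  sel <- select_vps(x, const_model(1), seed = 1)
  expect_equal(sel$acceptance_rate_pct, 100)
  sel0 <- select_vps(x, const_model(0), seed = 1)
  expect_identical(sum(sel0$selected), 0L)
  half <- select_vps(x, const_model(0.5), seed = 2)
  expect_gt(mean(half$selected), 0.48)
  expect_lt(mean(half$selected), 0.52)
  # acceptance rate uses the proposed-cohort denominator
  selp <- select_vps(x, const_model(1), seed = 1, n_proposed = 20000)
  expect_equal(selp$acceptance_rate_pct, 50)
  # empty plausible set
  e <- select_vps(x[0, , drop = FALSE], const_model(1), seed = 1)
  expect_identical(e$acceptance_rate_pct, 0)
})

test_that("selection pipeline is a pure function of its seeds", {
  sh <- make_shifted_cohorts(omics_spec(n = 800, seed = 7), "x2", 1)
  ref <- ratios_from_table(sh$reference)
  pla <- ratios_from_table(sh$plausible)
  run <- function() {
    m <- calibrate_beta(inclusion_model(ref, pla, constraints = "x2"),
                        pla, ref, seed = 8)
    select_vps(pla, m, seed = 9)
  }
  expect_identical(run(), run())
})

test_that("acceptance-rate table spans all 7 subsets and detects shifts", {
  sh <- make_shifted_cohorts(omics_spec(n = 900, seed = 12), "x2", 1.5)
  ref <- ratios_from_table(sh$reference)
  pla <- ratios_from_table(sh$plausible)
  tab <- acceptance_rate_table(pla, ref, seed = 13, iters = 200)
  expect_identical(nrow(tab), 7L)
  expect_setequal(tab$constraints,
                  c("x1", "x2", "x3", "x1+x2", "x1+x3", "x2+x3",
                    "x1+x2+x3"))
  # the shifted ratio is the more stringent single constraint
  expect_lt(tab$acceptance_rate_pct[tab$constraints == "x2"],
            tab$acceptance_rate_pct[tab$constraints == "x1"])
  expect_error(fit_density(pla, character(0)), "constraint")
})
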