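test_that("RECIST classes follow the 20% / -30% limits and CR threshold", {
  tr_of <- function(pct, d0 = 3) list(time = 0:10,
                                      diameter = c(rep(d0, 10),
                                                   d0 * (1 + pct / 100)))
  expect_equal(as.character(recist_classify(3, tr_of(25))$class), "PD")
  expect_equal(as.character(recist_classify(3, tr_of(-35))$class), "PR")
  expect_equal(as.character(recist_classify(3, tr_of(0))$class), "SD")
  expect_equal(recist_classify(3, tr_of(25))$percent_change, 25)
  # a tumor vanishing below the CR diameter is complete response
  expect_equal(as.character(recist_classify(
    3, list(time = 0:1, diameter = c(3, 0.1)))$class), "CR")
  expect_error(recist_classify(0, tr_of(0)), "baseline")
})

test_that("progression time follows the nadir-referenced +20% rule", {
  shr <- make_toy_trajectory("shrinking", d0 = 3, duration = 200,
                             final_pct = -40)
  pt <- progression_time(shr, 3)
  expect_true(pt$censored)
  expect_equal(pt$time, 200)
  flat <- make_toy_trajectory("flat", d0 = 3, duration = 100)
  expect_true(progression_time(flat, 3)$censored)
  nr <- make_toy_trajectory("nadir-rebound", d0 = 3, duration = 200,
                            final_pct = -2, nadir_day = 100,
                            nadir_pct = -30)
  pt2 <- progression_time(nr, 3)
  expect_false(pt2$censored)
  expect_equal(pt2$time, nr$ground_truth$progression_day)
  # baseline-referenced variant progresses later on the same trajectory
  gr <- make_toy_trajectory("growing", d0 = 3, duration = 50,
                            final_pct = 30)
  pn <- progression_time(gr, 3, reference = "nadir")
  pb <- progression_time(gr, 3, reference = "baseline")
  expect_equal(pn$time, pb$time)   # monotone growth: nadir = baseline
  expect_equal(pn$time, gr$ground_truth$progression_day)
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  # no events
  k0 <- km_pfs(c(50, 60, 70), c(TRUE, TRUE, TRUE))
  expect_true(all(k0$surv == 1))
  expect_true(all(k0$lower == 1 & k0$upper == 1))
  # two events, no censoring
  k2 <- km_pfs(c(10, 20), c(FALSE, FALSE))
  expect_equal(k2$surv[k2$time == 10], 0.5)
  expect_equal(k2$surv[k2$time == 20], 0)
  expect_equal(k2$surv[1], 1)      # curve starts at 1
  # CI brackets the estimate and survival is non-increasing
  set.seed(3)
  k3 <- km_pfs(rexp(40, 0.02), runif(40) < 0.3)
  expect_true(all(diff(k3$surv) <= 1e-12))
  ok <- !is.na(k3$lower)
  expect_true(all(k3$lower[ok] <= k3$surv[ok] + 1e-12))
  expect_true(all(k3$upper[ok] >= k3$surv[ok] - 1e-12))
})

test_that("Kaplan-Meier matches a brute-force oracle on 50 random datasets", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    times <- sample(1:40, n, replace = TRUE)
    cens <- runif(n) < 0.4
    km <- km_pfs(times, cens)
    ref <- km_brute_force(times, cens, km$time)
    expect_equal(km$surv, ref, tolerance = 1e-12)
  }
})

test_that("exposure AUC matches closed forms", {
  p <- default_parameters()
  # zero drug
  tr0 <- make_const_exposure_traj(0, days = 20)
  expect_equal(exposure_auc(tr0, "central"), 0)
  # constant active amount a over T days: 100 a T / (D m)
  a <- 2e-7  # mol
  tr <- make_const_exposure_traj(a, days = 20, dose_mg_per_kg = 10)
  D <- 10 * p[["BW"]]
  expect_equal(exposure_auc(tr, "central"),
               100 * a * p[["MW"]] * 20 / (D * 5000), tolerance = 1e-12)
  # piecewise-linear series: trapezoid equals the hand computation
  tr2 <- make_const_exposure_traj(a, days = 4)
  ramp <- c(0, 1, 3, 2, 2) * 1e-7 / p[["V_C"]]
  tr2$state[, "Ac_C"] <- ramp
  hand <- sum((ramp[-1] + ramp[-5]) / 2) * p[["V_C"]] * p[["MW"]] * 100 /
    (10 * p[["BW"]] * 5000)
  expect_equal(exposure_auc(tr2, "central"), hand, tolerance = 1e-12)
  expect_error(exposure_auc(tr, "central", masses_g = c(central = 0)),
               "mass")
})

test_that("degenerate cohorts classify as expected", {
  # static tumor, no immune system: stable disease, ORR 0, censored PFS
  p0 <- default_parameters(k_growth = 0, A_pool = 0, M_pool = 0)
  init <- initial_state(p0, cells_from_diameter(3, p0))
  coh <- structure(list(
    params = data.frame(k_growth = 0, A_pool = 0, M_pool = 0),
    init = matrix(init, 1, dimnames = list(NULL, names(init))),
    n_proposed = 1, n_plausible = 1), class = "qsp_cohort")
  tl <- run_trial(coh, regimen(10, 14, 100, "masked"), base = p0)
  expect_equal(as.character(tl$outcomes$class), "SD")
  expect_equal(tl$orr_pct, 0)
  expect_true(tl$outcomes$censored)
  # dose 0 on a growing patient: progressive disease
  pg <- default_parameters()
  cohg <- structure(list(
    params = data.frame(TCC = 93),
    init = matrix(fixture_default_init, 1,
                  dimnames = list(NULL, names(fixture_default_init))),
    n_proposed = 1, n_plausible = 1), class = "qsp_cohort")
  tg <- run_trial(cohg, regimen(0, 14, 200, "masked"), base = pg)
  expect_equal(as.character(tg$outcomes$class), "PD")
})

test_that("cohort trials: ORR bounds, order invariance, localization", {
  coh <- make_fixture_cohort(20, 101)
  tl <- run_trial(coh, regimen(10, 14, 200, "masked"), rtol = 1e-6)
  expect_gte(tl$orr_pct, 0); expect_lte(tl$orr_pct, 100)
  n_ok <- sum(!tl$outcomes$failed)
  expect_equal(tl$orr_pct,
               100 * sum(tl$outcomes$class %in% c("PR", "CR")) / n_ok)
  # order invariance
  perm <- rev(seq_len(nrow(coh$params)))
  cohp <- coh
  cohp$params <- coh$params[perm, , drop = FALSE]
  cohp$init <- coh$init[perm, , drop = FALSE]
  tlp <- run_trial(cohp, regimen(10, 14, 200, "masked"), rtol = 1e-6)
  expect_equal(tlp$orr_pct, tl$orr_pct)
  expect_equal(sort(tlp$outcomes$percent_change),
               sort(tl$outcomes$percent_change), tolerance = 1e-9)
  # masked-arm tumor exposure is not below central exposure (cleavage
  # and target binding retain active drug in the tumor)
  expect_true(all(tl$outcomes$auc_tumor >= tl$outcomes$auc_central))
  # spider series starts at zero percent change
  first <- tl$spider[tl$spider$time == 0, "percent_change"]
  expect_equal(first, rep(0, n_ok), tolerance = 1e-9)
})

test_that("trial outputs serialize to the expected CSV set", {
  coh <- make_fixture_cohort(20, 101)
  tl <- run_trial(structure(list(params = coh$params[1:3, , drop = FALSE],
                                 init = coh$init[1:3, , drop = FALSE]),
                            class = "qsp_cohort"),
                  regimen(10, 14, 60, "masked"), rtol = 1e-6)
  d <- tempfile(); dir.create(d)
  write_trial(tl, d, prefix = "arm")
  expect_true(all(file.exists(file.path(
    d, paste0("arm_", c("outcomes", "spider", "pfs", "exposure"),
              ".csv")))))
})
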