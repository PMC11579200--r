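test_that("PRCC recovers perfect monotone dependence and the null", {
  set.seed(21)
  X <- matrix(runif(400 * 4), 400, 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- X[, 1]^3                      # monotone in p1, independent of rest
  rho <- prcc(X, y)
  expect_gt(rho[["p1"]], 0.999)
  expect_true(all(abs(rho[c("p2", "p3", "p4")]) < 0.15))
  # null: no dependence at all
  set.seed(22)
  Xn <- matrix(runif(1000 * 3), 1000, 3,
               dimnames = list(NULL, paste0("q", 1:3)))
  yn <- rnorm(1000)
  expect_true(all(abs(prcc(Xn, yn)) < 0.1))
  expect_true(all(abs(prcc(Xn, yn)) <= 1))
})

test_that("single-parameter PRCC equals the Spearman correlation", {
  set.seed(23)
  x <- matrix(rlnorm(200), dimnames = list(NULL, "a"))
  y <- rnorm(200, sd = 2) + log(x[, 1])
  expect_equal(unname(prcc(x, y)),
               cor(x[, 1], y, method = "spearman"), tolerance = 1e-12)
})

test_that("PRCC is invariant under monotone transforms of an input", {
  set.seed(24)
  X <- matrix(runif(300 * 3, 0.1, 2), 300, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 2 * X[, 2] + rnorm(300, sd = 0.3)
  X2 <- X; X2[, 1] <- exp(X[, 1]); X2[, 2] <- X[, 2]^3
  expect_equal(prcc(X, y), prcc(X2, y), tolerance = 1e-12)
})

test_that("PRCC guards: constant columns, undersized samples, matrices", {
  X <- cbind(a = runif(50), b = rep(1, 50))
  expect_warning(r <- prcc(X, rnorm(50)), "constant")
  expect_named(r, "a")
  expect_error(prcc(matrix(runif(12), 3, 4), rnorm(3)), "n > p")
  Y <- cbind(y1 = runif(50), y2 = runif(50))
  tab <- prcc_table(cbind(a = runif(50), b = runif(50)), Y)
  expect_identical(dim(tab), c(2L, 2L))
  expect_true(all(abs(tab) <= 1))
})

test_that("responder comparison: separation, identity and star thresholds", {
  snames <- qspvct:::.qsp_state_names
  mk_states <- function(n, t8) {
    m <- matrix(1, n, length(snames), dimnames = list(NULL, snames))
    m[, "T8"] <- t8
    m[, c("T4", "Tr", "M1", "M2")] <- 100
    m
  }
  fake_trial <- function(classes, post) structure(list(
    outcomes = data.frame(patient = seq_along(classes), failed = FALSE,
                          class = classes),
    final_state = post), class = "qsp_trial")
  # responders shifted +10 sigma on CD8: three stars
  cls <- rep(c("PR", "PD"), each = 50)
  set.seed(31)
  post <- mk_states(100, c(rnorm(50, 1100, 10), rnorm(50, 1000, 10)))
  pre <- mk_states(100, rnorm(100, 1000, 10))
  cmp <- compare_responders(fake_trial(cls, post), pre)
  row <- cmp[cmp$biomarker == "CD8" & cmp$timepoint == "post", ]
  expect_lt(row$p_value, 0.001)
  expect_equal(row$stars, "***")
  # identical groups: p near 1, no stars
  post2 <- mk_states(100, rep(1000, 100))
  cmp2 <- compare_responders(fake_trial(cls, post2), post2)
  expect_true(all(cmp2$p_value > 0.9))
  expect_true(all(cmp2$stars == ""))
  # star mapping at the published cutpoints
  expect_identical(qspvct:::.stars(c(0.03, 0.009, 0.0009, 0.2)),
                   c("*", "**", "***", ""))
  # degenerate groups are skipped with a warning
  expect_warning(out <- compare_responders(
    fake_trial(rep("PD", 10), mk_states(10, 1)), mk_states(10, 1)),
    "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("rank-sum p-values are uniform under the null", {
  # group size 100: the normal-approximation p-values are dense enough
  # for a continuous-uniform KS reference
  set.seed(32)
  ps <- replicate(500, suppressWarnings(
    wilcox.test(rnorm(100), rnorm(100), exact = FALSE)$p.value))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("median-split labels follow the tie convention", {
  r <- data.frame(x1 = c(0.5, 0.5, 0.5), x2 = c(0.1, 0.9, 0.5),
                  x3 = c(0.2, 0.4, 0.6))
  lab <- median_split_waterfall(r)
  expect_true(all(lab$x1 == "high"))          # ties count as high
  expect_identical(as.character(lab$x2), c("low", "high", "high"))
  expect_error(median_split_waterfall(r[0, ]), "empty")
})

test_that("median-split flags a built-in ratio/response association", {
  # construct outcomes where high x2 co-occurs with progression
  set.seed(33)
  x2 <- runif(200)
  pd <- runif(200) < plogis(6 * (x2 - 0.5))
  lab <- median_split_waterfall(data.frame(x1 = runif(200), x2 = x2,
                                           x3 = runif(200)))
  expect_gt(mean(lab$x2[pd] == "high"), 0.5)
})

test_that("geometric median matches its closed forms", {
  expect_equal(geometric_median(c(10, 100, 1000)), 100)
  expect_equal(geometric_median(42), 42)
  set.seed(34)
  x <- rlnorm(10000, 4.5, 0.5)
  expect_lt(abs(geometric_median(x) - exp(4.5)) / exp(4.5), 0.03)
  expect_error(geometric_median(c(1, 0)), "positive")
})

test_that("Wilson intervals bracket the point estimate", {
  ci <- wilson_ci(16, 100)
  expect_lt(ci[1], 16); expect_gt(ci[2], 16)
  expect_gte(wilson_ci(0, 50)[1], 0)
  expect_lte(wilson_ci(50, 50)[2], 100)
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("TCC percentile bands partition the distribution into tenths", {
  d <- data.frame(name = "TCC", distribution = "lognormal",
                  p1 = log(93), p2 = 1, lower = NA, upper = NA,
                  units = "clones")
  for (g in 1:10) {
    bb <- qspvct:::.band_bounds(d[1, ], (g - 1) / 10, g / 10)
    expect_equal(bb, qlnorm(c((g - 1) / 10, g / 10), log(93), 1),
                 tolerance = 1e-12)
  }
  # truncation contract: the top band samples only above the 90th centile
  d$lower <- 1; d$upper <- 1e4
  bb <- qspvct:::.band_bounds(d[1, ], 0.9, 1)
  dg <- d; dg$lower <- bb[1]; dg$upper <- bb[2]
  s <- lhs_sample(dg, 200, seed = 35)$TCC
  expect_true(all(s >= bb[1] & s <= bb[2]))
  expect_gte(min(s), qspvct:::.qsp_quantile(0.9, "lognormal", log(93), 1,
                                            1, 1e4) - 1e-9)
  expect_error(tcc_stratified_trial(
    d[0, , drop = FALSE], 10, regimen(10, 14, 50)), "TCC")
})
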