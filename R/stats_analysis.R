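## stats_analysis: PRCC global sensitivity, responder/non-responder
## biomarker comparison, median-split waterfall labels, and
## TCC-percentile-stratified response analysis.

#' Partial rank correlation coefficients
#'
#' Rank-transforms every column of \code{X} and \code{y}; for each
#' parameter \eqn{j}, correlates the residuals of rank\eqn{(x_j)} and
#' rank\eqn{(y)} after linear regression of each on all other
#' rank-transformed parameters.  With a single parameter this reduces
#' exactly to the Spearman correlation.  Constant columns are dropped
#' with a warning (their PRCC is undefined); a singular partial
#' regression flags the parameter with \code{NA}.
#'
#' @param X numeric matrix or data.frame, n patients x p parameters.
#' @param y numeric outcome/biomarker vector, length n.
#' @return named numeric vector of PRCCs in \[-1, 1\] (NA where
#'   undefined).
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  const <- apply(X, 2, function(v) length(unique(v)) <= 1)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  p <- ncol(X)
  if (!p) return(stats::setNames(numeric(0), character(0)))
  if (nrow(X) <= p + 2)
    stop("need n > p + 2 observations for PRCC", call. = FALSE)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- stats::setNames(rep(NA_real_, p), colnames(X))
  for (j in seq_len(p)) {
    Zo <- cbind(1, R[, -j, drop = FALSE])
    fit_x <- stats::lm.fit(Zo, R[, j])
    fit_y <- stats::lm.fit(Zo, ry)
    ex <- fit_x$residuals; ey <- fit_y$residuals
    if (stats::sd(ex) == 0 || stats::sd(ey) == 0) next  # singular
    out[j] <- stats::cor(ex, ey)
  }
  out
}

#' @rdname prcc
#' @param Y matrix/data.frame of biomarkers (columns).
#' @return for \code{prcc_table()}: matrix of PRCCs, parameters x
#'   biomarkers, suitable for bubble-plot rendering.
#' @export
prcc_table <- function(X, Y) {
  Y <- as.matrix(Y)
  out <- sapply(seq_len(ncol(Y)), function(k)
    suppressWarnings(prcc(X, Y[, k])))
  colnames(out) <- colnames(Y)
  out
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
}

## biomarker panel computed from a state matrix (rows = patients)
.biomarker_panel <- function(states) {
  T8 <- states[, "T8"]; T4 <- states[, "T4"]; Tr <- states[, "Tr"]
  M1 <- states[, "M1"]; M2 <- states[, "M2"]
  data.frame(
    CD8 = T8, CD4 = T4, Treg = Tr,
    Teff_Treg = T8 / pmax(Tr, 1),
    M1_M2 = M1 / pmax(M2, 1)
  )
}

#' Responder vs non-responder biomarker comparison
#'
#' Responders are PR/CR patients.  For each biomarker (CD8, CD4 and
#' Treg tumor densities, Teff/Treg and M1/M2 ratios) and timepoint
#' (pre- and post-treatment), a two-sided Mann-Whitney rank-sum test
#' compares the two groups; stars encode p < 0.05 (*), < 0.01 (**),
#' < 0.001 (***).  A Welch t-test is available by config.
#'
#' @param trial a \code{qsp_trial} (provides RECIST classes and
#'   post-treatment states).
#' @param pre_states matrix of pre-treatment states (cohort
#'   \code{init}), same row order as the trial cohort.
#' @param test \code{"ranksum"} (default) or \code{"welch"}.
#' @return tidy data.frame: biomarker, timepoint, n per group, group
#'   medians, p-value, stars.
#' @export
compare_responders <- function(trial, pre_states,
                               test = c("ranksum", "welch")) {
  test <- match.arg(test)
  ok <- !trial$outcomes$failed
  resp <- ok & trial$outcomes$class %in% c("PR", "CR")
  nonresp <- ok & !trial$outcomes$class %in% c("PR", "CR")
  if (sum(resp) < 2 || sum(nonresp) < 2) {
    warning("fewer than 2 patients in a response group; comparison skipped")
    return(data.frame())
  }
  panels <- list(pre = .biomarker_panel(pre_states),
                 post = .biomarker_panel(trial$final_state))
  rows <- list()
  for (tp in names(panels)) {
    pan <- panels[[tp]]
    for (bm in names(pan)) {
      a <- pan[[bm]][resp]; b <- pan[[bm]][nonresp]
      pv <- if (test == "ranksum")
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
      else stats::t.test(a, b)$p.value
      if (is.na(pv)) pv <- 1  # identical constant groups
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, timepoint = tp,
        n_responder = sum(resp), n_nonresponder = sum(nonresp),
        median_responder = stats::median(a),
        median_nonresponder = stats::median(b),
        p_value = pv, stars = .stars(pv))
    }
  }
  do.call(rbind, rows)
}

#' Median-split labels for color-coded waterfall plots
#'
#' For each immune ratio, labels every patient \code{"high"} when the
#' pre-treatment ratio is greater than or equal to the cohort median
#' (ties count as high) and \code{"low"} otherwise.
#'
#' @param ratios data.frame of pre-treatment ratios (x1, x2, x3) of the
#'   virtual cohort.
#' @return data.frame of factor labels, one column per ratio.
#' @export
median_split_waterfall <- function(ratios) {
  if (!nrow(ratios)) stop("cohort is empty", call. = FALSE)
  out <- lapply(ratios, function(x) {
    factor(ifelse(x >= stats::median(x), "high", "low"),
           levels = c("low", "high"))
  })
  as.data.frame(out)
}

#' Geometric median
#'
#' \code{exp(median(log(x)))}; reported for cohort TCC values, where it
#' summarizes the heavy-tailed clone-count distribution.
#'
#' @param x positive sample.
#' @return geometric median.
#' @export
geometric_median <- function(x) {
  if (any(x <= 0)) stop("samples must be positive", call. = FALSE)
  exp(stats::median(log(x)))
}

#' Wilson score interval
#'
#' @param k successes, @param n trials, @param conf_level level.
#' @return c(lower, upper) on the percentage scale.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  100 * c(max(0, ctr - hw), min(1, ctr + hw))
}

## percentile band [lo, hi] of a (possibly truncated) marginal, as new
## truncation bounds on the same family
.band_bounds <- function(d, lo, hi) {
  qf <- function(u) .qsp_quantile(u, d$distribution, d$p1, d$p2,
                                  d$lower, d$upper)
  c(qf(lo), qf(hi))
}

#' TCC-percentile-stratified virtual trials
#'
#' Splits the tumor-specific T-cell clone (TCC) distribution — the
#' model's proxy for tumor mutational burden — into 10
#' equal-probability percentile bands.  For each band, runs the full
#' generate / select / trial pipeline with the TCC marginal truncated
#' to the band and all other distributions unchanged, and reports the
#' virtual-cohort ORR with a Wilson 95\% confidence interval.
#'
#' @param dists parameter distribution table containing a \code{TCC}
#'   row.
#' @param n_per_group proposed patients per band.
#' @param regimen trial [regimen()].
#' @param seed master seed (per-group seeds derive from it).
#' @param ref_ratios reference (omics) ratios for the selection step;
#'   when NULL the selection step is skipped and all plausible
#'   patients are treated (selection-free mode for sensitivity runs).
#' @param constraints active constraint subset for selection.
#' @param eps ratio clamp.
#' @param base baseline parameter vector.
#' @param n_groups number of percentile bands (default 10).
#' @param trial_args named list of extra arguments for [run_trial()]
#'   (e.g. \code{list(rtol = 1e-6)}).
#' @param ... passed to [generate_cohort()].
#' @return data.frame: group, tcc_lo, tcc_hi, n_proposed, n_plausible,
#'   n_virtual, n_responders, orr_pct, ci_lo, ci_hi.
#' @export
tcc_stratified_trial <- function(dists, n_per_group, regimen, seed = 1L,
                                 ref_ratios = NULL,
                                 constraints = c("x1", "x2", "x3"),
                                 eps = 0.01,
                                 base = default_parameters(),
                                 n_groups = 10, trial_args = list(),
                                 ...) {
  it <- which(dists$name == "TCC")
  if (!length(it)) stop("TCC not present in dists", call. = FALSE)
  rows <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    bb <- .band_bounds(dists[it, ], (g - 1) / n_groups, g / n_groups)
    dg <- dists
    dg$lower[it] <- bb[1L]; dg$upper[it] <- bb[2L]
    gseed <- seed + 1000L * g
    coh <- generate_cohort(dg, n = n_per_group, seed = gseed,
                           base = base, ...)
    n_virtual <- 0L; orr <- NA_real_; ci <- c(NA_real_, NA_real_)
    nresp <- NA_integer_
    if (coh$n_plausible > 0) {
      vcoh <- coh
      if (!is.null(ref_ratios) && coh$n_plausible >= 20) {
        pla <- ratios_from_cohort(coh, eps)
        m <- inclusion_model(ref_ratios, pla, constraints, eps)
        m <- calibrate_beta(m, pla, ref_ratios, seed = gseed + 1L)
        sel <- select_vps(pla, m, seed = gseed + 2L, coh$n_proposed)
        vcoh$params <- coh$params[sel$selected, , drop = FALSE]
        vcoh$init <- coh$init[sel$selected, , drop = FALSE]
      }
      n_virtual <- nrow(vcoh$params)
      if (n_virtual > 0) {
        tl <- do.call(run_trial,
                      c(list(cohort = vcoh, regimen = regimen,
                             base = base, keep_spider = FALSE),
                        trial_args))
        ok <- !tl$outcomes$failed
        nresp <- sum(tl$outcomes$class[ok] %in% c("PR", "CR"))
        orr <- tl$orr_pct
        ci <- wilson_ci(nresp, sum(ok))
      } else {
        warning("group ", g, ": no virtual patients selected")
      }
    } else {
      warning("group ", g, ": no plausible patients")
    }
    rows[[g]] <- data.frame(
      group = g, tcc_lo = bb[1L], tcc_hi = bb[2L],
      n_proposed = n_per_group, n_plausible = coh$n_plausible,
      n_virtual = n_virtual, n_responders = nresp,
      orr_pct = orr, ci_lo = ci[1L], ci_hi = ci[2L])
  }
  do.call(rbind, rows)
}
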