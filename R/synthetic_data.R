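## synthetic_data: generators for every external input the pipeline
## needs — omics-like immune-subset tables (synthetic stand-ins for an
## immunogenomics-portal export), shifted cohort pairs for selection
## tests, and toy tumor-size trajectories with known ground truth.

#' Specification of a synthetic omics reference table
#'
#' Marginals are beta distributions (bounded, right-skewed with the
#' default shapes, so that raw ratios put some mass below the clamp and
#' above one minus the clamp); dependence is a Gaussian copula on the
#' rank-correlation matrix.  A scalar marginal entry denotes a point
#' mass.
#'
#' @param n number of samples.
#' @param marginals named list over \code{M1, M2, Treg, CD8, CD4}: each
#'   \code{c(shape1, shape2)} of a beta distribution, or a single
#'   number for a point mass.
#' @param corr optional 5x5 rank-correlation matrix (row/col order as
#'   in \code{marginals}); NULL for independence.
#' @param seed RNG seed.
#' @return list of class \code{omics_spec}.
#' @export
omics_spec <- function(n = 500,
                       marginals = list(M1 = c(0.8, 8), M2 = c(2, 6),
                                        Treg = c(0.9, 10),
                                        CD8 = c(0.7, 6), CD4 = c(2.5, 5)),
                       corr = NULL, seed = 1L) {
  stopifnot(n >= 1,
            all(c("M1", "M2", "Treg", "CD8", "CD4") %in% names(marginals)))
  structure(list(n = n, marginals = marginals, corr = corr, seed = seed),
            class = "omics_spec")
}

#' Generate a synthetic omics reference table
#'
#' Gaussian-copula construction: draw correlated standard normals
#' (rank correlations converted to the copula's Pearson correlations by
#' \eqn{2\sin(\pi\rho_s/6)}), map through the normal CDF, and apply the
#' beta marginal quantile functions.  Deterministic per seed.  The
#' generating spec is attached as attribute \code{"ground_truth"}.
#'
#' @param spec an [omics_spec()].
#' @return data.frame with columns \code{sample_id, M1, M2, Treg, CD8,
#'   CD4} (proportions, each >= 0).
#' @export
make_omics_table <- function(spec = omics_spec()) {
  cols <- c("M1", "M2", "Treg", "CD8", "CD4")
  k <- length(cols)
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n * k), spec$n, k)
  if (!is.null(spec$corr)) {
    S <- 2 * sin(pi * as.matrix(spec$corr) / 6)
    diag(S) <- 1
    Lt <- tryCatch(chol(S), error = function(e)
      stop("infeasible correlation matrix (not positive definite)",
           call. = FALSE))
    Z <- Z %*% Lt
  }
  U <- stats::pnorm(Z)
  out <- data.frame(sample_id = sprintf("S%05d", seq_len(spec$n)))
  for (j in seq_len(k)) {
    m <- spec$marginals[[cols[j]]]
    out[[cols[j]]] <- if (length(m) == 1L) rep(m, spec$n)
    else stats::qbeta(U[, j], m[1L], m[2L])
  }
  attr(out, "ground_truth") <- spec
  out
}

## shift one raw ratio of a subset table by a location offset on the
## log-odds scale (keeps the (0,1) support intact, so the shifted and
## unshifted distributions overlap everywhere), rebuilding the single
## column that realizes the new ratio
.shift_ratio_cols <- function(tab, shift, magnitude) {
  clamp01 <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  move <- function(raw) stats::plogis(stats::qlogis(clamp01(raw)) +
                                        magnitude)
  if (shift == "x1") {
    raw <- ifelse(tab$M1 + tab$M2 > 0, tab$M1 / (tab$M1 + tab$M2), 0.5)
    r <- move(raw)
    tab$M1 <- r / (1 - r) * tab$M2
  } else if (shift == "x2") {
    raw <- ifelse(tab$Treg + tab$CD8 > 0, tab$Treg / (tab$Treg + tab$CD8),
                  0.5)
    r <- move(raw)
    tab$Treg <- r / (1 - r) * tab$CD8
  } else {
    raw <- ifelse(tab$CD4 + tab$CD8 > 0, tab$CD4 / (tab$CD4 + tab$CD8),
                  0.5)
    r <- move(raw)
    tab$CD4 <- r / (1 - r) * tab$CD8
  }
  tab
}

#' Paired reference / plausible-like tables with a known ratio shift
#'
#' Generates two tables from the same marginal specification (different
#' seeds) and applies a location shift of \code{magnitude} to the
#' designated raw ratio of the second table only, leaving the other two
#' ratios untouched.  Used to exercise the selection machinery against
#' a known distribution mismatch.
#'
#' @param spec base [omics_spec()].
#' @param shift which ratio to shift: \code{"x1"}, \code{"x2"} or
#'   \code{"x3"}.
#' @param magnitude location shift on the log-odds (logit) scale (may
#'   be negative); a logit shift preserves the (0,1) support, so the
#'   two cohorts overlap everywhere and differ by a known monotone
#'   displacement.  Extreme values are clamped by [compute_ratios()]
#'   like any other sample.
#' @return list with \code{reference} and \code{plausible} tables and a
#'   \code{ground_truth} record.
#' @export
make_shifted_cohorts <- function(spec = omics_spec(), shift = "x2",
                                 magnitude = 1) {
  shift <- match.arg(shift, c("x1", "x2", "x3"))
  ref <- make_omics_table(spec)
  spec2 <- spec; spec2$seed <- spec$seed + 1L
  pla <- make_omics_table(spec2)
  if (magnitude != 0) pla <- .shift_ratio_cols(pla, shift, magnitude)
  list(reference = ref, plausible = pla,
       ground_truth = list(shift = shift, magnitude = magnitude,
                           spec = spec))
}

#' Toy tumor-size trajectories with known ground truth
#'
#' Analytic diameter series for exercising the RECIST classifier,
#' progression-time rule and survival estimator: linear
#' \code{"shrinking"}/\code{"growing"} to a final percent change,
#' \code{"flat"}, or \code{"nadir-rebound"} (linear decline to a nadir,
#' then linear regrowth to a final percent change).  The returned
#' object carries the analytically known RECIST class and
#' nadir-referenced progression day as \code{ground_truth}.
#'
#' @param kind trajectory shape.
#' @param d0 baseline diameter (cm).
#' @param duration days (grid step 1 day).
#' @param final_pct percent change at the final day.
#' @param nadir_day,nadir_pct nadir location for
#'   \code{"nadir-rebound"}.
#' @return list with \code{time}, \code{diameter},
#'   \code{ground_truth} (class, progression day, censored flag).
#' @export
make_toy_trajectory <- function(kind = c("shrinking", "growing", "flat",
                                         "nadir-rebound"),
                                d0 = 3, duration = 200, final_pct = -40,
                                nadir_day = 100, nadir_pct = -30) {
  kind <- match.arg(kind)
  tt <- seq(0, duration, by = 1)
  d <- switch(kind,
    flat = rep(d0, length(tt)),
    shrinking = ,
    growing = d0 * (1 + final_pct / 100 * tt / duration),
    `nadir-rebound` = {
      dn <- d0 * (1 + nadir_pct / 100)
      df <- d0 * (1 + final_pct / 100)
      ifelse(tt <= nadir_day,
             d0 + (dn - d0) * tt / nadir_day,
             dn + (df - dn) * (tt - nadir_day) / (duration - nadir_day))
    })
  if (any(d < 0)) stop("trajectory would cross zero diameter")
  ## analytic nadir-referenced progression (threshold +20% over nadir)
  dend <- d[length(d)]
  pc <- 100 * (dend - d0) / d0
  cls <- if (pc >= 20) "PD" else if (pc <= -30) "PR" else "SD"
  prog_day <- NA_real_; censored <- TRUE
  if (kind == "growing" && final_pct > 0) {
    t_star <- 0.2 / (final_pct / 100) * duration  # d exceeds 1.2 d0
    cand <- tt[d > 1.2 * d0]
    if (length(cand)) { prog_day <- cand[1L]; censored <- FALSE }
    stopifnot(is.na(prog_day) || prog_day >= t_star)
  } else if (kind == "nadir-rebound") {
    dn <- d0 * (1 + nadir_pct / 100)
    cand <- tt[tt > nadir_day & d > 1.2 * pmin(dn, d0)]
    if (length(cand)) { prog_day <- cand[1L]; censored <- FALSE }
  }
  list(time = tt, diameter = d,
       ground_truth = list(class = cls, percent_change = pc,
                           progression_day = prog_day,
                           censored = censored))
}
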