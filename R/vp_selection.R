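## vp_selection: epsilon-clamped immune subset ratios, density-ratio
## inclusion probabilities, beta calibration by simulated annealing,
## stochastic virtual-patient selection.

.ratio_names <- c("x1", "x2", "x3")

## clamp a raw fraction to [eps, 1 - eps]; a 0/0 denominator is mapped
## to the uninformative midpoint 0.5 before clamping (documented tie
## convention)
.clamp_ratio <- function(num, den, eps) {
  raw <- ifelse(den > 0, num / den, 0.5)
  pmin(pmax(raw, eps), 1 - eps)
}

#' Immune subset ratios (epsilon-clamped)
#'
#' The three immune subset ratios used for virtual-patient selection:
#' \deqn{x_1 = M_1/(M_1+M_2),\quad x_2 = T_{reg}/(T_{reg}+CD8),\quad
#'       x_3 = CD4/(CD4+CD8),}
#' each clamped to \eqn{[\varepsilon, 1-\varepsilon]} to avoid
#' divergences of the log-ratio: values above \eqn{1-\varepsilon} are
#' set to \eqn{1-\varepsilon}, values below \eqn{\varepsilon} to
#' \eqn{\varepsilon}.  The ratios are unit-free, so they can be
#' computed identically from model cell densities (cells/mL tumor) and
#' from omics immune-subset proportions of leukocytes.  A 0/0
#' denominator is mapped to 0.5 (no information) before clamping.
#'
#' @param M1,M2,Treg,CD8,CD4 non-negative densities or proportions
#'   (vectorized).
#' @param eps clamp constant, 0 < eps < 0.5 (default 0.01).
#' @return data.frame with columns \code{x1, x2, x3}, all in
#'   \eqn{[\varepsilon, 1-\varepsilon]}.
#' @export
#' @examples
#' compute_ratios(M1 = 1, M2 = 1, Treg = 0, CD8 = 2, CD4 = 1, eps = 0.05)
compute_ratios <- function(M1, M2, Treg, CD8, CD4, eps = 0.01) {
  if (eps <= 0 || eps >= 0.5)
    stop("eps must satisfy 0 < eps < 0.5", call. = FALSE)
  if (any(c(M1, M2, Treg, CD8, CD4) < 0))
    stop("densities must be >= 0", call. = FALSE)
  data.frame(
    x1 = .clamp_ratio(M1, M1 + M2, eps),
    x2 = .clamp_ratio(Treg, Treg + CD8, eps),
    x3 = .clamp_ratio(CD4, CD4 + CD8, eps)
  )
}

#' @rdname compute_ratios
#' @param tab data.frame with columns \code{M1, M2, Treg, CD8, CD4}
#'   (an omics reference table or a cohort pre-treatment table).
#' @export
ratios_from_table <- function(tab, eps = 0.01) {
  compute_ratios(tab$M1, tab$M2, tab$Treg, tab$CD8, tab$CD4, eps)
}

## pre-treatment immune ratios of a plausible cohort
ratios_from_cohort <- function(cohort, eps = 0.01) {
  s <- cohort$init
  compute_ratios(s[, "M1"], s[, "M2"], s[, "Tr"], s[, "T8"], s[, "T4"],
                 eps)
}

#' Clamp-sensitivity diagnostic
#'
#' For each candidate clamp value \eqn{\varepsilon}, the relative error
#' of the median of the clamped sample against the raw median,
#' \eqn{(\tilde y(\varepsilon) - \tilde y)/\tilde y}.  The error is 0
#' whenever the clamp does not move the median — in particular it dips
#' to 0 when \eqn{\varepsilon} equals the raw sample median.
#'
#' @param samples raw (unclamped) fractions in \[0, 1\].
#' @param eps_grid candidate clamp values in (0, 0.5).
#' @return data.frame with columns \code{eps} and \code{rel_error}
#'   (NA when the raw median is 0).
#' @export
epsilon_diagnostic <- function(samples, eps_grid) {
  if (!length(samples)) stop("samples must be nonempty", call. = FALSE)
  m0 <- stats::median(samples)
  rel <- vapply(eps_grid, function(e) {
    if (m0 == 0) return(NA_real_)
    m <- stats::median(pmin(pmax(samples, e), 1 - e))
    (m - m0) / m0
  }, numeric(1))
  data.frame(eps = eps_grid, rel_error = rel)
}

## ---- density estimation over log-ratio space ------------------------

## 1-D Gaussian KDE with Silverman bandwidth, evaluable anywhere; a
## degenerate sample falls back to a narrow fixed-width kernel
.kde1d <- function(z) {
  n <- length(z)
  h <- stats::bw.nrd0(z)
  if (!is.finite(h) || h <= 0) h <- max(1e-6, 1e-3 * abs(z[1L]))
  function(q) vapply(q, function(qi) mean(stats::dnorm(qi, z, h)),
                     numeric(1))
}

#' Fit ratio densities for the inclusion model
#'
#' Gaussian kernel density estimates on the log-transformed active
#' ratios.  In \code{mode = "product"} (default) each active ratio gets
#' an independent 1-D estimator and the joint density is their product;
#' \code{mode = "joint"} uses a product-kernel multivariate KDE with
#' per-dimension Silverman bandwidths (a correlated joint estimate).
#'
#' @param ratios data.frame of clamped ratios (columns among
#'   \code{x1, x2, x3}).
#' @param constraints character subset of \code{c("x1","x2","x3")} to
#'   use (the active constraints).
#' @param min_samples minimum sample size (default 20).
#' @param mode \code{"product"} or \code{"joint"}.
#' @return function mapping a ratio data.frame to density values.
#' @export
fit_density <- function(ratios, constraints = .ratio_names,
                        min_samples = 20, mode = c("product", "joint")) {
  mode <- match.arg(mode)
  if (!length(constraints)) stop("empty constraint subset", call. = FALSE)
  constraints <- match.arg(constraints, .ratio_names, several.ok = TRUE)
  if (nrow(ratios) < min_samples)
    stop("need at least ", min_samples, " samples to fit densities",
         call. = FALSE)
  Z <- log(as.matrix(ratios[, constraints, drop = FALSE]))
  if (mode == "product") {
    kdes <- lapply(seq_along(constraints), function(j) .kde1d(Z[, j]))
    f <- function(x) {
      q <- log(as.matrix(x[, constraints, drop = FALSE]))
      v <- rep(1, nrow(q))
      for (j in seq_along(constraints)) v <- v * kdes[[j]](q[, j])
      v
    }
  } else {
    h <- apply(Z, 2, function(z) {
      b <- stats::bw.nrd0(z); if (!is.finite(b) || b <= 0) 1e-6 else b
    })
    f <- function(x) {
      q <- log(as.matrix(x[, constraints, drop = FALSE]))
      vapply(seq_len(nrow(q)), function(i) {
        k <- rep(1, nrow(Z))
        for (j in seq_along(constraints))
          k <- k * stats::dnorm(q[i, j], Z[, j], h[j])
        mean(k)
      }, numeric(1))
    }
  }
  structure(f, constraints = constraints, mode = mode,
            n = nrow(ratios), class = c("qsp_density", "function"))
}

#' Inclusion model: reference vs plausible ratio densities
#'
#' @param ref_ratios clamped ratios of the omics reference samples.
#' @param pla_ratios clamped ratios of the plausible cohort.
#' @param constraints active constraint subset.
#' @param eps the clamp used to build both ratio sets.
#' @param beta normalization factor (calibrate with [calibrate_beta()]).
#' @param mode density mode, see [fit_density()].
#' @param min_samples minimum per-side sample size.
#' @return object of class \code{qsp_inclusion_model}.
#' @export
inclusion_model <- function(ref_ratios, pla_ratios,
                            constraints = .ratio_names, eps = 0.01,
                            beta = 1, mode = "product",
                            min_samples = 20) {
  structure(list(
    f_ref = fit_density(ref_ratios, constraints, min_samples, mode),
    f_pla = fit_density(pla_ratios, constraints, min_samples, mode),
    constraints = constraints, eps = eps, beta = beta, mode = mode
  ), class = "qsp_inclusion_model")
}

#' @export
print.qsp_inclusion_model <- function(x, ...) {
  cat("<qsp_inclusion_model> constraints {",
      paste(x$constraints, collapse = ", "), "}, beta = ",
      signif(x$beta, 4), ", mode = ", x$mode, "\n", sep = "")
  invisible(x)
}

.density_floor <- 1e-12

#' Inclusion probability
#'
#' \eqn{p = \min(1, \beta f_{ref}(x) / f_{pla}(x))}, with the plausible
#' density floored at 1e-12 to avoid division blow-ups.
#'
#' @param x ratio data.frame (one row per patient).
#' @param model a fitted [inclusion_model()].
#' @return probabilities in \[0, 1\].
#' @export
inclusion_probability <- function(x, model) {
  if (!inherits(model, "qsp_inclusion_model"))
    stop("model must be a qsp_inclusion_model", call. = FALSE)
  fr <- model$f_ref(x)
  fp <- pmax(model$f_pla(x), .density_floor)
  pmin(1, pmax(0, model$beta * fr / fp))
}

## per-constraint KS statistic between a selected subset and the
## reference ratios
.ks_mismatch <- function(sel_ratios, ref_ratios, constraints) {
  if (!nrow(sel_ratios)) return(length(constraints))
  sum(vapply(constraints, function(k) {
    suppressWarnings(stats::ks.test(sel_ratios[[k]], ref_ratios[[k]]))$statistic
  }, numeric(1)))
}

#' Calibrate the normalization factor beta by simulated annealing
#'
#' Maximizes (expected selected-cohort size) minus a distribution
#' mismatch penalty \eqn{\lambda \sum_i KS(selected_i, reference_i)}
#' over \eqn{\log_{10}\beta}, by simulated annealing with geometric
#' cooling.  Selection inside the objective uses common random numbers
#' (one uniform draw per patient, fixed across proposals), so the
#' objective is deterministic given the seed and the annealing is
#' reproducible.  With initial temperature 0 the algorithm reduces to
#' a greedy hill-climb that never accepts a worse objective.
#'
#' @param ref_ratios,pla_ratios clamped ratio data.frames.
#' @param model an [inclusion_model()] (its beta is ignored).
#' @param lambda mismatch penalty weight; the default
#'   (\code{4 * nrow(pla_ratios)}) prices 0.25 units of summed KS
#'   mismatch at the whole cohort, so the annealing settles at the
#'   clipping knee where selection reshapes the cohort toward the
#'   reference instead of accepting everyone whenever a real
#'   distribution shift exists.
#' @param iters annealing iterations (default 500).
#' @param t0 initial temperature (default 1; 0 gives greedy descent).
#' @param cooling geometric cooling factor (default 0.99).
#' @param step proposal standard deviation on log10(beta).
#' @param seed RNG seed.
#' @return the model with calibrated \code{beta} and attributes
#'   \code{objective}, \code{trace}.
#' @export
calibrate_beta <- function(model, pla_ratios, ref_ratios,
                           lambda = NULL, iters = 500, t0 = 1,
                           cooling = 0.99, step = 0.25, seed = 1L) {
  if (is.null(lambda)) lambda <- 4 * nrow(pla_ratios)
  set.seed(seed)
  u <- stats::runif(nrow(pla_ratios))   # common random numbers
  fr <- model$f_ref(pla_ratios)
  fp <- pmax(model$f_pla(pla_ratios), .density_floor)
  ratio <- fr / fp
  objective <- function(b10) {
    p <- pmin(1, pmax(0, 10^b10 * ratio))
    sel <- u < p
    sum(sel) - lambda * .ks_mismatch(pla_ratios[sel, , drop = FALSE],
                                     ref_ratios, model$constraints)
  }
  cur <- 0; cur_obj <- objective(cur)
  best <- cur; best_obj <- cur_obj
  temp <- t0
  trace <- numeric(iters)
  for (i in seq_len(iters)) {
    prop <- cur + stats::rnorm(1, 0, step)
    prop <- min(max(prop, -4), 4)
    obj <- objective(prop)
    accept <- obj >= cur_obj ||
      (temp > 0 && stats::runif(1) < exp((obj - cur_obj) / temp))
    if (accept) { cur <- prop; cur_obj <- obj }
    if (cur_obj > best_obj) { best <- cur; best_obj <- cur_obj }
    temp <- temp * cooling
    trace[i] <- best_obj
  }
  model$beta <- 10^best
  attr(model, "objective") <- best_obj
  attr(model, "trace") <- trace
  model
}

#' Select virtual patients
#'
#' Accepts each plausible patient independently with its inclusion
#' probability.
#'
#' @param pla_ratios clamped ratios of the plausible cohort (one row
#'   per patient).
#' @param model calibrated [inclusion_model()].
#' @param seed RNG seed.
#' @param n_proposed size of the original proposed cohort (for the
#'   acceptance-rate denominator); defaults to the plausible count.
#' @return list with logical \code{selected}, \code{p} (inclusion
#'   probabilities), and \code{acceptance_rate_pct} = 100 x selected /
#'   proposed.
#' @export
select_vps <- function(pla_ratios, model, seed = 1L,
                       n_proposed = nrow(pla_ratios)) {
  if (!nrow(pla_ratios))
    return(list(selected = logical(0), p = numeric(0),
                acceptance_rate_pct = 0))
  p <- inclusion_probability(pla_ratios, model)
  set.seed(seed)
  sel <- stats::runif(nrow(pla_ratios)) < p
  list(selected = sel, p = p,
       acceptance_rate_pct = 100 * sum(sel) / max(n_proposed, 1))
}

## all non-empty subsets of the three constraints
.constraint_subsets <- function() {
  s <- unlist(lapply(1:3, function(k)
    utils::combn(.ratio_names, k, simplify = FALSE)), recursive = FALSE)
  names(s) <- vapply(s, paste, "", collapse = "+")
  s
}

#' Acceptance-rate table over constraint subsets
#'
#' For every non-empty subset of \{x1, x2, x3\}, fits the inclusion
#' model on that subset, calibrates beta, selects virtual patients from
#' the same starting cohort, and reports the percentage of the
#' originally proposed patients accepted as virtual.
#'
#' @param pla_ratios plausible-cohort ratios (shared across subsets).
#' @param ref_ratios omics reference ratios.
#' @param n_proposed proposed-cohort size (denominator).
#' @param eps clamp constant used for the ratios.
#' @param seed RNG seed (per-subset seeds derive from it).
#' @param ... passed to [calibrate_beta()].
#' @return data.frame with columns \code{constraints},
#'   \code{acceptance_rate_pct}, \code{beta}, \code{n_selected}.
#' @export
acceptance_rate_table <- function(pla_ratios, ref_ratios,
                                  n_proposed = nrow(pla_ratios),
                                  eps = 0.01, seed = 1L, ...) {
  subsets <- .constraint_subsets()
  rows <- lapply(seq_along(subsets), function(i) {
    cs <- subsets[[i]]
    m <- inclusion_model(ref_ratios, pla_ratios, constraints = cs,
                         eps = eps)
    m <- calibrate_beta(m, pla_ratios, ref_ratios, seed = seed + i, ...)
    sel <- select_vps(pla_ratios, m, seed = seed + 100L + i, n_proposed)
    data.frame(constraints = names(subsets)[i],
               acceptance_rate_pct = sel$acceptance_rate_pct,
               beta = m$beta, n_selected = sum(sel$selected))
  })
  do.call(rbind, rows)
}

#' Read an omics reference table
#'
#' CSV with columns \code{sample_id, M1, M2, Treg, CD8, CD4}
#' (immune-subset proportions of leukocytes, each >= 0).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_omics_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "M1", "M2", "Treg", "CD8", "CD4")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("omics table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- tab[, setdiff(need, "sample_id")]
  if (any(num < 0)) stop("omics proportions must be >= 0", call. = FALSE)
  tab
}
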