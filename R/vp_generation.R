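## vp_generation: Latin hypercube sampling of proposed patients,
## pre-treatment growth simulation, plausibility filtering, and
## extraction of pre-treatment initial conditions.

## inverse-CDF of a (possibly truncated) marginal from the parameter
## distribution table
.qsp_quantile <- function(u, family, p1, p2, lower, upper) {
  lower <- if (is.na(lower)) -Inf else lower
  upper <- if (is.na(upper)) Inf else upper
  F <- switch(family,
    uniform    = list(q = function(x) stats::qunif(x, p1, p2),
                      p = function(x) stats::punif(x, p1, p2)),
    loguniform = list(q = function(x) exp(stats::qunif(x, log(p1), log(p2))),
                      p = function(x) stats::punif(log(x), log(p1), log(p2))),
    normal     = list(q = function(x) stats::qnorm(x, p1, p2),
                      p = function(x) stats::pnorm(x, p1, p2)),
    lognormal  = list(q = function(x) stats::qlnorm(x, p1, p2),
                      p = function(x) stats::plnorm(x, p1, p2)),
    fixed      = return(rep(p1, length(u))),
    stop("unknown distribution family: ", family, call. = FALSE))
  ## truncation by CDF inversion restricted to [F(lower), F(upper)]
  plo <- if (is.finite(lower)) F$p(lower) else 0
  phi <- if (is.finite(upper)) F$p(upper) else 1
  F$q(plo + u * (phi - plo))
}

#' Latin hypercube sample of patient parameters
#'
#' Draws \code{n} proposed patients from the per-parameter marginal
#' distributions by Latin hypercube sampling: for every parameter,
#' exactly one sample falls in each of the \code{n} equal-probability
#' strata of its (truncated) marginal.  Reproducible: the same seed
#' yields an identical sample.
#'
#' @param dists parameter distribution table
#'   (see [default_parameter_distributions()]).
#' @param n number of patients (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame, one row per patient, one column per parameter,
#'   with attribute \code{"seed"}.
#' @export
lhs_sample <- function(dists, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_distribution_set(dists)
  set.seed(seed)
  U <- lhs::randomLHS(n, nrow(dists))
  out <- as.data.frame(lapply(seq_len(nrow(dists)), function(j) {
    d <- dists[j, ]
    .qsp_quantile(U[, j], d$distribution, d$p1, d$p2, d$lower, d$upper)
  }))
  names(out) <- dists$name
  attr(out, "seed") <- seed
  out
}

#' Simulate pre-treatment tumor growth
#'
#' Therapy-free simulation from a small cancer-cell inoculum over a
#' long growth horizon; the trajectory is later scanned for the first
#' crossing of the patient's target pre-treatment diameter.
#'
#' @param params full model parameter vector for one patient.
#' @param horizon growth horizon in days (default 8000, a computational
#'   parameter, not a biological tumor age).
#' @param inoculum_cells starting cancer-cell count (default 100).
#' @param grid_days output grid for the growth phase (default 5 days;
#'   the crossing state is interpolated, see [plausibility_filter()]).
#' @param ... passed to [simulate_patient()].
#' @return a \code{qsp_trajectory}.
#' @export
grow_pretreatment <- function(params, horizon = 8000,
                              inoculum_cells = 100, grid_days = 5, ...) {
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  simulate_patient(params, init = initial_state(params, inoculum_cells),
                   t_span = horizon, regimen = no_treatment(),
                   grid_days = grid_days, ...)
}

#' Default plausibility rules
#'
#' The only rule stated by the selection procedure is that the growth
#' profile must reach the target pre-treatment diameter within the
#' horizon; the remaining rules are package conventions: all species
#' finite and non-negative at the crossing, plus optional bounds on
#' pre-treatment immune densities.
#'
#' @param immune_bounds optional named list of \code{c(lower, upper)}
#'   bounds on state entries at the crossing (e.g.
#'   \code{list(T8 = c(1e3, 1e10))}).
#' @return list of rules for [plausibility_filter()].
#' @export
plausibility_rules <- function(immune_bounds = NULL) {
  list(immune_bounds = immune_bounds)
}

## first index i with d[i] >= target (diameter crossing), or NA
.first_crossing <- function(d, target) {
  i <- which(d >= target)
  if (!length(i)) NA_integer_ else i[1L]
}

#' Plausibility filter and pre-treatment initial condition
#'
#' A proposed patient is plausible iff the pre-treatment growth
#' trajectory reaches the target initial diameter within the horizon
#' and all plausibility rules pass.  On acceptance, the model state at
#' the first crossing becomes the pre-treatment initial condition:
#' the crossing time is located by linear interpolation of the
#' cancer-cell count between grid points (the diameter-to-cell map is
#' inverted exactly, so the interpolated state hits the target diameter
#' to machine precision), and all other species are interpolated
#' linearly at that time.
#'
#' @param traj growth trajectory from [grow_pretreatment()].
#' @param params the patient's full model parameter vector (target
#'   diameter is \code{params["d0"]}).
#' @param rules from [plausibility_rules()].
#' @return list with \code{accepted} flag and, when accepted,
#'   \code{init} (pre-treatment state), \code{time_to_target} (days)
#'   and \code{diameter} (the interpolated crossing diameter).
#' @export
plausibility_filter <- function(traj, params, rules = plausibility_rules()) {
  target <- params[["d0"]]
  i <- .first_crossing(traj$diameter, target)
  reject <- function() list(accepted = FALSE, init = NULL,
                            time_to_target = NA_real_)
  if (is.na(i)) return(reject())
  if (i == 1L) {
    init <- traj$state[1L, ]
    tt <- traj$time[1L]
  } else {
    Cstar <- cells_from_diameter(target, params)
    C1 <- traj$state[i - 1L, "C"]; C2 <- traj$state[i, "C"]
    w <- if (C2 > C1) (Cstar - C1) / (C2 - C1) else 1
    w <- min(max(w, 0), 1)
    init <- (1 - w) * traj$state[i - 1L, ] + w * traj$state[i, ]
    init[["C"]] <- Cstar
    tt <- (1 - w) * traj$time[i - 1L] + w * traj$time[i]
  }
  if (any(!is.finite(init)) || any(init < 0)) return(reject())
  ib <- rules$immune_bounds
  if (!is.null(ib)) {
    for (nm in names(ib)) {
      v <- init[[nm]]
      if (v < ib[[nm]][1L] || v > ib[[nm]][2L]) return(reject())
    }
  }
  list(accepted = TRUE, init = init, time_to_target = tt,
       diameter = tumor_diameter(init[["C"]], params))
}

#' Generate a plausible-patient cohort
#'
#' Samples \code{n} proposed patients ([lhs_sample()]), simulates each
#' patient's pre-treatment growth ([grow_pretreatment()]) and keeps the
#' plausible ones ([plausibility_filter()]).  One master seed governs
#' the whole cohort; per-patient stochastic elements (none in the
#' deterministic growth model) would derive child seeds from it.
#'
#' @param dists parameter distribution table.
#' @param n number of proposed patients.
#' @param seed master seed.
#' @param base full baseline parameter vector overridden per patient.
#' @param horizon,inoculum_cells,grid_days see [grow_pretreatment()].
#' @param rules plausibility rules.
#' @param ... further arguments to [simulate_patient()].
#' @return object of class \code{qsp_cohort}: list with
#'   \code{params} (data.frame, plausible patients' sampled
#'   parameters), \code{init} (matrix of pre-treatment states),
#'   \code{time_to_target}, \code{n_proposed}, \code{n_plausible},
#'   \code{seed}.
#' @export
generate_cohort <- function(dists = default_parameter_distributions(),
                            n = 200, seed = 1L,
                            base = default_parameters(),
                            horizon = 8000, inoculum_cells = 100,
                            grid_days = 5,
                            rules = plausibility_rules(), ...) {
  proposed <- lhs_sample(dists, n, seed)
  keep <- logical(n)
  inits <- matrix(NA_real_, n, length(.qsp_state_names),
                  dimnames = list(NULL, .qsp_state_names))
  ttt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pp <- apply_patient_params(proposed[i, , drop = FALSE], base)
    tr <- try(grow_pretreatment(pp, horizon, inoculum_cells, grid_days,
                                ...),
              silent = TRUE)
    if (inherits(tr, "try-error")) next
    fl <- plausibility_filter(tr, pp, rules)
    if (fl$accepted) {
      keep[i] <- TRUE
      inits[i, ] <- fl$init
      ttt[i] <- fl$time_to_target
    }
  }
  structure(list(
    params = proposed[keep, , drop = FALSE],
    init = inits[keep, , drop = FALSE],
    time_to_target = ttt[keep],
    n_proposed = n,
    n_plausible = sum(keep),
    seed = seed
  ), class = "qsp_cohort")
}

#' @export
print.qsp_cohort <- function(x, ...) {
  cat("<qsp_cohort> ", x$n_plausible, " plausible of ", x$n_proposed,
      " proposed patients (", round(100 * x$n_plausible /
        max(x$n_proposed, 1), 1), "%)\n", sep = "")
  invisible(x)
}

#' Write / read a cohort
#'
#' One CSV row per plausible patient with the sampled parameters, and a
#' companion CSV of pre-treatment initial-condition states.
#'
#' @param cohort a \code{qsp_cohort}.
#' @param path base CSV path; states go to \code{*_init.csv}.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cbind(cohort$params,
                         time_to_target = cohort$time_to_target),
                   path, row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$init),
                   paste0(tools::file_path_sans_ext(path), "_init.csv"),
                   row.names = FALSE)
  invisible(path)
}
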