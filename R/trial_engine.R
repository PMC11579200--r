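## trial_engine: RECIST classification, progression times, Kaplan-Meier
## PFS, compartmental exposure AUC, and cohort-level virtual trials.

#' RECIST 1.1 classification of a tumor-size trajectory
#'
#' Percent change is computed at the final day of the trial,
#' \eqn{100 (d_{end} - d_0)/d_0}: progressive disease (PD) at
#' \eqn{\ge +20\%}, partial response (PR) at \eqn{\le -30\%}, complete
#' response (CR) when the final diameter falls below \code{cr_diameter},
#' stable disease (SD) otherwise.
#'
#' @param baseline baseline (pre-treatment) diameter, cm, > 0.
#' @param trajectory anything with numeric fields \code{time} and
#'   \code{diameter} (a \code{qsp_trajectory} or a toy trajectory).
#' @param cr_diameter complete-response threshold on the final
#'   diameter (cm, default 0.2).
#' @return list with \code{percent_change} and \code{class} (factor
#'   with levels PD, SD, PR, CR).
#' @export
recist_classify <- function(baseline, trajectory, cr_diameter = 0.2) {
  if (baseline <= 0) stop("baseline must be > 0", call. = FALSE)
  d_end <- trajectory$diameter[length(trajectory$diameter)]
  pc <- 100 * (d_end - baseline) / baseline
  cls <- if (pc >= 20) "PD"
  else if (d_end <= cr_diameter) "CR"
  else if (pc <= -30) "PR"
  else "SD"
  list(percent_change = pc,
       class = factor(cls, levels = c("PD", "SD", "PR", "CR")))
}

#' Time to progression
#'
#' First day the diameter exceeds the progression threshold: by default
#' +20\% over the running nadir (RECIST 1.1 spirit); set
#' \code{reference = "baseline"} for +20\% over the baseline diameter.
#' Censored at the end of the trajectory if progression never occurs.
#'
#' @param trajectory object with \code{time} and \code{diameter}.
#' @param baseline baseline diameter (cm).
#' @param threshold relative increase defining progression (default 0.2).
#' @param reference \code{"nadir"} (running minimum, including the
#'   baseline) or \code{"baseline"}.
#' @return list with \code{time} (days) and \code{censored} flag.
#' @export
progression_time <- function(trajectory, baseline,
                             threshold = 0.2,
                             reference = c("nadir", "baseline")) {
  reference <- match.arg(reference)
  d <- trajectory$diameter
  tt <- trajectory$time
  ref <- if (reference == "nadir") cummin(c(baseline, d))[-1] else baseline
  prog <- d > (1 + threshold) * ref
  i <- which(prog)
  if (!length(i)) list(time = tt[length(tt)], censored = TRUE)
  else list(time = tt[i[1L]], censored = FALSE)
}

#' Kaplan-Meier progression-free survival curve
#'
#' Product-limit estimate with Greenwood-variance 95\% confidence
#' intervals on the log(-log) scale, via \pkg{survival}.  The curve
#' starts at 1 at time 0.
#'
#' @param times event/censoring times (days).
#' @param censored logical, TRUE where censored.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns \code{time, n_risk, surv, lower,
#'   upper}, beginning with the (0, 1, 1, 1) anchor row.
#' @export
km_pfs <- function(times, censored, conf_level = 0.95) {
  stopifnot(length(times) >= 1, length(times) == length(censored))
  fit <- survival::survfit(
    survival::Surv(times, !censored) ~ 1,
    conf.type = "log-log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  out <- data.frame(time = s$time, n_risk = s$n.risk, surv = s$surv,
                    lower = s$lower, upper = s$upper)
  ## degenerate all-censored data: survfit leaves CI at NA; the curve
  ## is identically 1 with no events to estimate variance from
  out$lower[is.na(out$lower) & out$surv == 1] <- 1
  out$upper[is.na(out$upper) & out$surv == 1] <- 1
  rbind(data.frame(time = 0, n_risk = length(times), surv = 1,
                   lower = 1, upper = 1), out)
}

#' Exposure AUC of active antibody, %dose x day / g
#'
#' Trapezoidal integral over the trial window of the active-species
#' amount (molecules with at least one exposed active site, free or
#' target-bound) in a compartment, expressed as percent of the total
#' administered dose per gram of compartment tissue.  The tumor mass is
#' the pre-treatment tumor volume at density 1 g/mL (floored at
#' \code{min_tumor_mass_g}), so exposures of shrinking and progressing
#' tumors are reported per gram of the same baseline tissue; central,
#' peripheral and lymph-node masses are fixed configuration constants.
#'
#' @param traj a \code{qsp_trajectory} from a treated simulation.
#' @param compartment one of \code{"tumor", "central", "peripheral",
#'   "tdln"}.
#' @param masses_g named list/vector of compartment masses in grams
#'   (tumor mass is dynamic and ignored here).
#' @param min_tumor_mass_g floor on the dynamic tumor mass (default
#'   0.5 g).
#' @return AUC in percent-dose x day / g.
#' @export
exposure_auc <- function(traj, compartment,
                         masses_g = c(central = 5000, peripheral = 60000,
                                      tdln = 1),
                         min_tumor_mass_g = 0.5) {
  reg <- traj$regimen
  nd <- length(dose_times(reg, max(traj$time)))
  total_dose_mg <- nd * reg$dose_mg_per_kg * traj$params[["BW"]]
  if (total_dose_mg <= 0) return(0)
  amount_mg <- active_amount(traj, compartment) * traj$params[["MW"]]
  mass <- if (compartment == "tumor") {
    max(pi * traj$diameter[1L]^3 / 6, min_tumor_mass_g)  # 1 g/mL
  } else {
    m <- masses_g[[compartment]]
    if (is.null(m) || m <= 0)
      stop("compartment mass must be configured and > 0", call. = FALSE)
    m
  }
  pracma::trapz(traj$time, 100 * amount_mg / (total_dose_mg * mass))
}

#' Run a virtual clinical trial over a cohort
#'
#' Simulates every patient from their pre-treatment initial condition
#' for the regimen duration and assembles per-patient outcomes
#' (percent tumor-size change at trial end, RECIST class, progression
#' time, per-compartment exposure AUC), the cohort ORR
#' (\eqn{100 (\#PR + \#CR)/n}), and the Kaplan-Meier PFS curve.
#' Outcomes are deterministic given the cohort order; a patient whose
#' integration fails is flagged and excluded from the summaries.
#'
#' @param cohort a \code{qsp_cohort} (with pre-treatment states) — or a
#'   list with \code{params} data.frame and \code{init} state matrix.
#' @param regimen a [regimen()].
#' @param base baseline full parameter vector.
#' @param grid_days output grid (default 1 day).
#' @param progression_reference see [progression_time()].
#' @param keep_spider keep the per-patient percent-change time series
#'   (spider data) — default TRUE.
#' @param ... further arguments to [simulate_patient()] (e.g.
#'   \code{rtol}).
#' @return object of class \code{qsp_trial}: list with
#'   \code{outcomes} (data.frame), \code{orr_pct}, \code{pfs}
#'   (data.frame), \code{spider} (long data.frame or NULL),
#'   \code{regimen}.
#' @export
run_trial <- function(cohort, regimen, base = default_parameters(),
                      grid_days = 1,
                      progression_reference = "nadir",
                      keep_spider = TRUE, ...) {
  n <- nrow(cohort$params)
  if (!n) stop("cohort is empty", call. = FALSE)
  rows <- vector("list", n)
  spider <- if (keep_spider) vector("list", n) else NULL
  final <- matrix(NA_real_, n, length(.qsp_state_names),
                  dimnames = list(NULL, .qsp_state_names))
  for (i in seq_len(n)) {
    pp <- apply_patient_params(cohort$params[i, , drop = FALSE], base)
    init <- cohort$init[i, ]
    baseline <- tumor_diameter(init[["C"]], pp)
    tr <- try(simulate_patient(pp, init = init,
                               t_span = regimen$duration_days,
                               regimen = regimen, grid_days = grid_days,
                               ...),
              silent = TRUE)
    if (inherits(tr, "try-error")) {
      warning("patient ", i, " failed to integrate; excluded")
      rows[[i]] <- data.frame(patient = i, failed = TRUE,
                              percent_change = NA_real_, class = NA,
                              progression_days = NA_real_,
                              censored = NA,
                              auc_tumor = NA_real_, auc_central = NA_real_,
                              auc_peripheral = NA_real_)
      next
    }
    final[i, ] <- tr$state[nrow(tr$state), ]
    rc <- recist_classify(baseline, tr)
    pt <- progression_time(tr, baseline, reference = progression_reference)
    rows[[i]] <- data.frame(
      patient = i, failed = FALSE,
      percent_change = rc$percent_change,
      class = as.character(rc$class),
      progression_days = pt$time, censored = pt$censored,
      auc_tumor = exposure_auc(tr, "tumor"),
      auc_central = exposure_auc(tr, "central"),
      auc_peripheral = exposure_auc(tr, "peripheral"))
    if (keep_spider)
      spider[[i]] <- data.frame(
        patient = i, time = tr$time,
        percent_change = 100 * (tr$diameter - baseline) / baseline)
  }
  outcomes <- do.call(rbind, rows)
  ok <- !outcomes$failed
  orr <- if (any(ok))
    100 * sum(outcomes$class[ok] %in% c("PR", "CR")) / sum(ok) else NA_real_
  pfs <- if (any(ok))
    km_pfs(outcomes$progression_days[ok], outcomes$censored[ok]) else NULL
  structure(list(
    outcomes = outcomes, orr_pct = orr, pfs = pfs,
    spider = if (keep_spider) do.call(rbind, spider) else NULL,
    final_state = final,
    regimen = regimen
  ), class = "qsp_trial")
}

#' @export
print.qsp_trial <- function(x, ...) {
  ok <- !x$outcomes$failed
  cat("<qsp_trial> ", sum(ok), " patients, arm = ", x$regimen$arm,
      ", ORR = ", round(x$orr_pct, 1), "%\n", sep = "")
  print(table(x$outcomes$class[ok]))
  invisible(x)
}

#' Write trial outputs
#'
#' Waterfall-ready per-patient outcomes, spider series, PFS curve and
#' exposure AUCs as plain CSV files.
#'
#' @param trial a \code{qsp_trial}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, paste0(prefix, "_", x, ".csv"))
  utils::write.csv(trial$outcomes, f("outcomes"), row.names = FALSE)
  if (!is.null(trial$spider))
    utils::write.csv(trial$spider, f("spider"), row.names = FALSE)
  if (!is.null(trial$pfs))
    utils::write.csv(trial$pfs, f("pfs"), row.names = FALSE)
  exposure <- trial$outcomes[, c("patient", "auc_tumor", "auc_central",
                                 "auc_peripheral")]
  utils::write.csv(exposure, f("exposure"), row.names = FALSE)
  invisible(dir)
}
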