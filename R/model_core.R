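## model_core: reduced four-compartment QSP immuno-oncology ODE system
## with conditionally activated (masked, protease-cleavable) anti-PD-L1
## antibody kinetics.

#' Equilibrium binding-competent fraction of the masked antibody
#'
#' The antibody carries two masks; each independently and reversibly
#' exposes its active site with equilibrium constant \code{K_M}
#' (open/closed).  Absent cleavage, the equilibrium fraction of
#' molecules with at least one exposed active site is
#' \code{1 - (1 + K_M)^-2}: 0 when the mask never opens, approaching 1
#' as \code{K_M} grows, and strictly increasing in between.
#'
#' @param K_M non-negative masking equilibrium constant (dimensionless).
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' unmasked_fraction(c(0, 0.02, 1))
unmasked_fraction <- function(K_M) {
  if (any(!is.finite(K_M) & !is.infinite(K_M)) || any(K_M < 0))
    stop("K_M must be non-negative", call. = FALSE)
  ifelse(is.infinite(K_M), 1, 1 - (1 + K_M)^-2)
}

#' Tumor diameter from cancer-cell count
#'
#' Diameter of the sphere whose volume equals
#' \code{cells * vol_cell / packing} (cell volume in mL, packing the
#' cancer-cell volume fraction of the tumor).  Zero cells give zero
#' diameter; the map is strictly increasing and inverted exactly by
#' [cells_from_diameter()].
#'
#' @param x cancer-cell count (numeric vector), a named model state
#'   containing \code{"C"}, or a trajectory state matrix.
#' @param params model parameters (for \code{vol_cell}, \code{packing}).
#' @return diameter in cm.
#' @export
tumor_diameter <- function(x, params = default_parameters()) {
  cells <- if (is.matrix(x)) x[, "C"]
  else if (!is.null(names(x)) && "C" %in% names(x)) x[["C"]]
  else x
  if (any(cells < 0)) stop("cancer-cell count must be >= 0", call. = FALSE)
  vol <- cells * params[["vol_cell"]] / params[["packing"]]
  (6 * vol / pi)^(1 / 3)
}

#' @rdname tumor_diameter
#' @param diameter tumor diameter in cm.
#' @export
cells_from_diameter <- function(diameter, params = default_parameters()) {
  if (any(diameter < 0)) stop("diameter must be >= 0", call. = FALSE)
  (pi * diameter^3 / 6) * params[["packing"]] / params[["vol_cell"]]
}

#' Dosing regimen
#'
#' @param dose_mg_per_kg antibody dose (mg/kg), default 10.
#' @param interval_days days between boluses, default 14 (Q2W).
#' @param duration_days trial duration in days, default 400.
#' @param arm \code{"masked"} (conditionally activated antibody, bolus
#'   split between the fully masked and reversibly open states at the
#'   mask equilibrium) or \code{"unmasked"} (same molecule with zero
#'   masks: the whole bolus enters the always-active state).
#' @return object of class \code{qsp_regimen}.
#' @export
regimen <- function(dose_mg_per_kg = 10, interval_days = 14,
                    duration_days = 400, arm = c("masked", "unmasked")) {
  arm <- match.arg(arm)
  stopifnot(dose_mg_per_kg >= 0, interval_days > 0, duration_days >= 0)
  structure(list(dose_mg_per_kg = dose_mg_per_kg,
                 interval_days = interval_days,
                 duration_days = duration_days, arm = arm),
            class = "qsp_regimen")
}

no_treatment <- function(duration_days = 0) {
  regimen(dose_mg_per_kg = 0, interval_days = 14,
          duration_days = duration_days, arm = "masked")
}

#' Initial model state
#'
#' @param params model parameters.
#' @param n_cells cancer-cell inoculum (default 100 cells); all immune
#'   populations, cytokine, PD-L1 and drug start at zero and build up
#'   through the model dynamics.
#' @return named numeric state vector.
#' @export
initial_state <- function(params = default_parameters(), n_cells = 100) {
  y <- stats::setNames(numeric(length(.qsp_state_names)), .qsp_state_names)
  y[["C"]] <- n_cells
  y
}

## Quasi-static synapse occupancies.  Only PD-L1 is modeled
## out-of-synapse (it is the antibody's target); the synapse ligand
## couple occupancies are algebraic functions of the state, updated
## quasi-statically: antibody occupancy of out-of-synapse PD-L1 proxies
## the synapse PD-L1 availability.

#' Synapse ligand occupancies (quasi-static)
#'
#' Competitive-binding equilibrium occupancies of the immune-synapse
#' ligand couples, derived algebraically from the current state:
#' antibody occupancy of out-of-synapse PD-L1, PD-1 engagement by
#' PD-L1/PD-L2, CTLA4/CD28 competition for CD80, and TCR--MHC antigen
#' engagement.  All values are occupancy fractions in \[0, 1\].
#'
#' @param state named model state vector.
#' @param params model parameters.
#' @return named numeric vector of occupancy fractions.
#' @export
synapse_occupancy <- function(state, params = default_parameters()) {
  P <- max(state[["P"]], 0)
  B <- max(state[["Bo_T"]], 0) + max(state[["Bc_T"]], 0)
  theta <- if (P + B > 0) B / (P + B) else 0
  L1 <- params[["pdl1_syn"]] * (1 - theta)
  L2 <- params[["pdl2_syn"]]
  Kpd <- params[["K_pd"]]
  cd80 <- 2; K_ctla4 <- 0.4; K_cd28 <- 4  # relative synapse affinities
  c(
    pdl1_ab   = theta,
    pd1_pdl1  = L1 / (L1 + L2 + Kpd),
    pd1_pdl2  = L2 / (L1 + L2 + Kpd),
    ctla4_cd80 = cd80 / (cd80 + K_ctla4),
    cd28_cd80  = cd80 / (cd80 + K_cd28),
    tcr_mhc   = params[["K_ag"]] / (params[["K_ag"]] + params[["Kd_neo"]])
  )
}

## Reference R implementation of the right-hand side.  The compiled C
## version in src/qspvct_rhs.c is the production path; the two are
## cross-checked in the test suite.
.qsp_rhs_r <- function(t, y, p) {
  y <- pmax(y, 0)
  C <- y[[1L]]; T8 <- y[[2L]]; T4 <- y[[3L]]; Tr <- y[[4L]]
  APC <- y[[5L]]; M1 <- y[[6L]]; M2 <- y[[7L]]; Cyt <- y[[8L]]
  APC_LN <- y[[9L]]; T8_LN <- y[[10L]]; T4_LN <- y[[11L]]; Tr_LN <- y[[12L]]
  T8_C <- y[[13L]]; T4_C <- y[[14L]]; Tr_C <- y[[15L]]
  P <- y[[16L]]
  Am_T <- y[[17L]]; Ao_T <- y[[18L]]; Ac_T <- y[[19L]]
  Bo_T <- y[[20L]]; Bc_T <- y[[21L]]
  Am_C <- y[[22L]]; Ao_C <- y[[23L]]; Ac_C <- y[[24L]]
  Am_P <- y[[25L]]; Ao_P <- y[[26L]]; Ac_P <- y[[27L]]
  Am_LN <- y[[28L]]; Ao_LN <- y[[29L]]; Ac_LN <- y[[30L]]

  fC <- C / (C + p[["K_rec"]])
  Btot <- Bo_T + Bc_T
  theta <- if (P + Btot > 0) Btot / (P + Btot) else 0
  L <- p[["pdl1_syn"]] * (1 - theta) + p[["pdl2_syn"]]
  H <- L / (L + p[["K_pd"]])   # PD-1/PD-L1-mediated inhibition

  kill <- p[["k_kill"]] * T8 * C / (C + p[["K_kill"]]) * (1 - H) /
    (1 + Tr / p[["K_treg"]])
  dC <- p[["k_growth"]] * C * (1 - C / p[["C_max"]]) - kill

  infl8 <- p[["k_T_in"]] * T8_C * fC
  infl4 <- p[["k_T_in"]] * T4_C * fC
  inflR <- p[["k_T_in"]] * Tr_C * fC
  dT8 <- infl8 - p[["k_T_death"]] * T8 - p[["k_exh"]] * T8 * H * fC
  dT4 <- infl4 - p[["k_T_death"]] * T4
  dTr <- inflR - p[["k_T_death"]] * Tr

  sCyt <- Cyt / (Cyt + p[["K_cyt"]])
  dAPC <- p[["k_apc_mat"]] * p[["A_pool"]] * sCyt -
    (p[["k_apc_mig"]] + p[["k_apc_death"]]) * APC
  dM1 <- p[["k_m1_rec"]] * p[["M_pool"]] * sCyt -
    p[["k_m12"]] * M1 * fC - p[["k_m_death"]] * M1
  dM2 <- p[["k_m2_rec"]] * p[["M_pool"]] * fC +
    p[["k_m12"]] * M1 * fC - p[["k_m_death"]] * M2
  dCyt <- p[["k_cyt_prod"]] * fC +
    p[["k_cyt_kill"]] * kill / (kill + p[["K_kflux"]]) -
    p[["k_cyt_deg"]] * Cyt

  ag <- (p[["TCC"]] / (p[["TCC"]] + p[["K_TCC"]])) *
    (p[["K_ag"]] / (p[["K_ag"]] + p[["Kd_neo"]]))
  help4 <- 1 + p[["w4"]] * T4_LN / (T4_LN + p[["K4"]])
  k_out <- p[["k_ln_out"]] + p[["k_ln_death"]]
  dAPC_LN <- p[["k_apc_mig"]] * APC - p[["k_apcln_death"]] * APC_LN
  dT8_LN <- p[["k_pr8"]] * APC_LN * ag * help4 - k_out * T8_LN
  dT4_LN <- p[["k_pr4"]] * APC_LN * ag - k_out * T4_LN
  dTr_LN <- p[["k_prR"]] * APC_LN - k_out * Tr_LN

  dT8_C <- p[["k_ln_out"]] * T8_LN - p[["k_c_death"]] * T8_C - infl8
  dT4_C <- p[["k_ln_out"]] * T4_LN - p[["k_c_death"]] * T4_C - infl4
  dTr_C <- p[["k_ln_out"]] * Tr_LN - p[["k_c_death"]] * Tr_C - inflR

  k_on <- p[["k_off_ab"]] / p[["Kd_ab"]]
  bind_o <- k_on * Ao_T * P
  bind_c <- k_on * Ac_T * P
  dP <- p[["k_shed"]] * (C + p[["w_m2"]] * M2) - p[["k_p_deg"]] * P -
    bind_o - bind_c + p[["k_off_ab"]] * Btot

  kcv <- p[["k_cvg"]]
  dBo <- bind_o - (p[["k_off_ab"]] + kcv + p[["k_b_int"]]) * Bo_T
  dBc <- bind_c + kcv * Bo_T - (p[["k_off_ab"]] + p[["k_b_int"]]) * Bc_T

  ## mask exchange: masked <-> open at relaxation rate k_mask, with the
  ## equilibrium open fraction u_open = unmasked_fraction(K_M)
  ko <- p[["k_mask"]] * p[["u_open"]]
  kc <- p[["k_mask"]] * (1 - p[["u_open"]])

  QT <- p[["Q_T"]]; QP <- p[["Q_P"]]; QL <- p[["Q_LN"]]
  sT <- p[["sig_T"]]; sP <- p[["sig_P"]]; sL <- p[["sig_LN"]]
  VT <- p[["V_T"]]; VC <- p[["V_C"]]; VP <- p[["V_P"]]; VL <- p[["V_LN"]]

  ## transport fluxes (mol/day), central -> compartment
  fl_m_T <- QT * (sT * Am_C - Am_T); fl_o_T <- QT * (sT * Ao_C - Ao_T)
  fl_c_T <- QT * (sT * Ac_C - Ac_T)
  fl_m_P <- QP * (sP * Am_C - Am_P); fl_o_P <- QP * (sP * Ao_C - Ao_P)
  fl_c_P <- QP * (sP * Ac_C - Ac_P)
  fl_m_L <- QL * (sL * Am_C - Am_LN); fl_o_L <- QL * (sL * Ao_C - Ao_LN)
  fl_c_L <- QL * (sL * Ac_C - Ac_LN)

  ex_T <- ko * Am_T - kc * Ao_T
  ex_C <- ko * Am_C - kc * Ao_C
  ex_P <- ko * Am_P - kc * Ao_P
  ex_L <- ko * Am_LN - kc * Ao_LN

  ## tumor: cleavage acts here only
  dAm_T <- fl_m_T / VT - ex_T - kcv * Am_T
  dAo_T <- fl_o_T / VT + ex_T - kcv * Ao_T - bind_o + p[["k_off_ab"]] * Bo_T
  dAc_T <- fl_c_T / VT + kcv * (Am_T + Ao_T) - bind_c +
    p[["k_off_ab"]] * Bc_T

  kcl <- p[["k_cl"]]
  dAm_C <- -kcl * Am_C - ex_C - (fl_m_T + fl_m_P + fl_m_L) / VC
  dAo_C <- -kcl * Ao_C + ex_C - (fl_o_T + fl_o_P + fl_o_L) / VC
  dAc_C <- -kcl * Ac_C - (fl_c_T + fl_c_P + fl_c_L) / VC

  dAm_P <- fl_m_P / VP - ex_P
  dAo_P <- fl_o_P / VP + ex_P
  dAc_P <- fl_c_P / VP

  dAm_L <- fl_m_L / VL - ex_L
  dAo_L <- fl_o_L / VL + ex_L
  dAc_L <- fl_c_L / VL

  dQcv <- kcv * (Am_T + Ao_T + Bo_T) * VT

  list(c(dC, dT8, dT4, dTr, dAPC, dM1, dM2, dCyt,
         dAPC_LN, dT8_LN, dT4_LN, dTr_LN,
         dT8_C, dT4_C, dTr_C,
         dP,
         dAm_T, dAo_T, dAc_T, dBo, dBc,
         dAm_C, dAo_C, dAc_C,
         dAm_P, dAo_P, dAc_P,
         dAm_L, dAo_L, dAc_L,
         dQcv))
}

#' Model derivatives
#'
#' Time-derivatives of the full model state: tumor-compartment cells
#' (cancer, CD8/CD4/Treg T cells, mature APC, M1/M2 macrophages) and
#' cytokine, lymph-node APC and primed T cells, circulating T cells,
#' out-of-synapse PD-L1, and the antibody mask-state species per
#' compartment.  Antibody cleavage is nonzero only in the tumor
#' compartment; checkpoint blockade by bound antibody reduces the
#' PD-1/PD-L1-mediated inhibition of T-cell killing and exhaustion
#' monotonically with occupancy.
#'
#' @param state named non-negative state vector (see [initial_state()]).
#' @param t time (days); the system is autonomous between boluses.
#' @param params full model parameter vector.
#' @param regimen optional [regimen()]; dosing enters as bolus events in
#'   [simulate_patient()], not through the derivative.
#' @return named numeric vector of derivatives, one per state.
#' @export
qsp_derivatives <- function(state, t = 0, params = default_parameters(),
                            regimen = NULL) {
  params <- validate_params(params)
  missing <- setdiff(.qsp_state_names, names(state))
  if (length(missing))
    stop("missing state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  state <- state[.qsp_state_names]
  if (any(state < 0))
    stop("integration failure: negative state entry (",
         paste(names(state)[state < 0], collapse = ", "), ")",
         call. = FALSE)
  d <- .qsp_rhs_r(t, unname(state), as.list(params))[[1L]]
  stats::setNames(d, .qsp_state_names)
}

dose_times <- function(regimen, t_end) {
  if (regimen$dose_mg_per_kg <= 0 || regimen$duration_days <= 0)
    return(numeric(0))
  tt <- seq(0, min(regimen$duration_days, t_end),
            by = regimen$interval_days)
  tt[tt < min(regimen$duration_days, t_end)]
}

bolus_concentration <- function(regimen, params) {
  regimen$dose_mg_per_kg * params[["BW"]] /
    (params[["MW"]] * params[["V_C"]])
}

## per-state absolute tolerances: cell-scale states vs molar drug states
.qsp_atol <- function(atol_cells = 1e-10, atol_molar = 1e-22) {
  a <- rep(atol_cells, length(.qsp_state_names))
  molar <- c("P", grep("^(Am|Ao|Ac|B)", .qsp_state_names, value = TRUE),
             "Qcv")
  a[.qsp_state_names %in% molar] <- atol_molar
  a
}

#' Simulate one virtual patient
#'
#' Integrates the model with a stiff implicit solver (deSolve
#' \code{lsoda}, relative tolerance \code{1e-8}, scale-aware absolute
#' tolerances) on a fixed output grid.  Boluses are state-jump events
#' at the dosing times: the central-compartment antibody concentration
#' increases by \code{dose * body mass / (MW * V_C)}; in the masked arm
#' the bolus is split between the fully masked and reversibly open
#' states at the mask equilibrium, in the unmasked arm it enters the
#' maskless (always binding-competent) state.  Dosing times appear as
#' grid points.
#'
#' @param params full model parameter vector.
#' @param init initial state (default [initial_state()]).
#' @param t_span simulation horizon (days, > 0).
#' @param regimen a [regimen()]; default no treatment.
#' @param grid_days output grid spacing (days, default 1).
#' @param engine \code{"compiled"} (C right-hand side, default) or
#'   \code{"R"} (reference implementation).
#' @param rtol,atol_cells,atol_molar solver tolerances.
#' @return object of class \code{qsp_trajectory}: list with \code{time},
#'   state matrix \code{state}, derived \code{diameter} (cm) series,
#'   \code{params} and \code{regimen}.
#' @export
simulate_patient <- function(params, init = NULL, t_span,
                             regimen = no_treatment(),
                             grid_days = 1,
                             engine = c("compiled", "R"),
                             rtol = 1e-8, atol_cells = 1e-10,
                             atol_molar = 1e-22) {
  engine <- match.arg(engine)
  params <- validate_params(params)
  if (t_span <= 0) stop("t_span must be > 0", call. = FALSE)
  if (is.null(init)) init <- initial_state(params)
  init <- init[.qsp_state_names]
  if (anyNA(init)) stop("invalid initial state", call. = FALSE)

  dt <- dose_times(regimen, t_span)
  times <- sort(unique(c(seq(0, t_span, by = grid_days), t_span, dt)))
  conc <- bolus_concentration(regimen, params)
  u <- params[["u_open"]]

  ev <- NULL
  if (length(dt) && conc > 0) {
    if (regimen$arm == "masked") {
      ev <- data.frame(
        var = rep(c("Am_C", "Ao_C"), each = length(dt)),
        time = rep(dt, 2),
        value = rep(c((1 - u) * conc, u * conc), each = length(dt)),
        method = "add")
    } else {
      ev <- data.frame(var = "Ac_C", time = dt, value = conc,
                       method = "add")
    }
    ev <- ev[order(ev$time, ev$var), , drop = FALSE]
    ## a dose exactly at t = 0 is applied to the initial state
    at0 <- ev$time == times[1L]
    if (any(at0)) {
      for (i in which(at0)) init[[ev$var[i]]] <- init[[ev$var[i]]] + ev$value[i]
      ev <- ev[!at0, , drop = FALSE]
      if (!nrow(ev)) ev <- NULL
    }
  }

  atol <- .qsp_atol(atol_cells, atol_molar)
  events <- if (!is.null(ev)) list(data = ev) else NULL
  out <- if (engine == "compiled") {
    deSolve::ode(y = init, times = times, func = "qspvct_derivs",
                 parms = unname(params[.qsp_param_names]),
                 dllname = "qspvct", initfunc = "qspvct_initmod",
                 method = "lsoda", rtol = rtol, atol = atol,
                 events = events, maxsteps = 50000)
  } else {
    pl <- as.list(params)
    deSolve::ode(y = init, times = times,
                 func = function(t, y, parms) .qsp_rhs_r(t, y, parms),
                 parms = pl, method = "lsoda", rtol = rtol, atol = atol,
                 events = events, maxsteps = 50000)
  }
  if (nrow(out) < length(times))
    stop("solver failed to converge; last valid time = ",
         signif(out[nrow(out), 1L], 6), " days", call. = FALSE)
  state <- out[, .qsp_state_names, drop = FALSE]
  state[state < 0 & state > -1e-9] <- 0
  structure(list(
    time = out[, 1L],
    state = state,
    diameter = tumor_diameter(pmax(state[, "C"], 0), params),
    params = params,
    regimen = regimen
  ), class = "qsp_trajectory")
}

#' @export
print.qsp_trajectory <- function(x, ...) {
  cat("<qsp_trajectory> ", length(x$time), " time points over ",
      max(x$time), " days; final diameter ",
      signif(x$diameter[length(x$diameter)], 4), " cm\n", sep = "")
  invisible(x)
}

## Active (binding-competent) antibody amount in a compartment (mol):
## molecules with at least one exposed active site -- reversibly open or
## cleaved, free or target-bound.
active_amount <- function(traj, compartment) {
  s <- traj$state; p <- traj$params
  switch(compartment,
    tumor = (s[, "Ao_T"] + s[, "Ac_T"] + s[, "Bo_T"] + s[, "Bc_T"]) *
      p[["V_T"]],
    central = (s[, "Ao_C"] + s[, "Ac_C"]) * p[["V_C"]],
    peripheral = (s[, "Ao_P"] + s[, "Ac_P"]) * p[["V_P"]],
    tdln = (s[, "Ao_LN"] + s[, "Ac_LN"]) * p[["V_LN"]],
    stop("unknown compartment: ", compartment, call. = FALSE))
}

## total antibody amount across compartments and mask states (mol)
total_antibody <- function(traj) {
  s <- traj$state; p <- traj$params
  (s[, "Am_T"] + s[, "Ao_T"] + s[, "Ac_T"] + s[, "Bo_T"] + s[, "Bc_T"]) *
    p[["V_T"]] +
    (s[, "Am_C"] + s[, "Ao_C"] + s[, "Ac_C"]) * p[["V_C"]] +
    (s[, "Am_P"] + s[, "Ao_P"] + s[, "Ac_P"]) * p[["V_P"]] +
    (s[, "Am_LN"] + s[, "Ao_LN"] + s[, "Ac_LN"]) * p[["V_LN"]]
}

#' Export a trajectory
#'
#' @param traj a \code{qsp_trajectory}.
#' @return long-format data.frame (time, compartment, species, value).
#' @export
as.data.frame.qsp_trajectory <- function(x, ...) {
  comp_of <- function(nm) {
    if (grepl("_LN$", nm) || nm %in% c("APC_LN")) "tdln"
    else if (grepl("_C$", nm) || nm %in% c("T8_C", "T4_C", "Tr_C")) "central"
    else if (grepl("_P$", nm)) "peripheral"
    else "tumor"
  }
  nm <- colnames(x$state)
  do.call(rbind, lapply(seq_along(nm), function(j) {
    data.frame(time = x$time, compartment = comp_of(nm[j]),
               species = nm[j], value = unname(x$state[, j]))
  }))
}

#' @rdname as.data.frame.qsp_trajectory
#' @param traj trajectory to export.
#' @param path CSV path for the long-format table; a JSON summary
#'   (final state, final diameter, dosing) is written alongside when
#'   \code{json} is TRUE.
#' @param json write the JSON summary too.
#' @export
write_trajectory <- function(traj, path, json = TRUE) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (json) {
    jp <- paste0(tools::file_path_sans_ext(path), "_summary.json")
    n <- length(traj$time)
    jsonlite::write_json(list(
      t_end = traj$time[n],
      final_diameter_cm = traj$diameter[n],
      final_state = as.list(traj$state[n, ]),
      regimen = unclass(traj$regimen)
    ), jp, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
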