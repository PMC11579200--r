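## Canonical parameter and state ordering shared by the R and compiled
## right-hand sides.  Do not reorder without updating src/qspvct_rhs.c.

.qsp_param_names <- c(
  ## tumor geometry & growth
  "k_growth", "C_max", "vol_cell", "packing", "d0",
  ## killing & checkpoint
  "k_kill", "K_kill", "K_treg", "pdl1_syn", "pdl2_syn", "K_pd", "k_exh",
  ## trafficking
  "K_rec", "k_T_in", "k_T_death", "k_c_death", "k_ln_out", "k_ln_death",
  ## APC / priming
  "A_pool", "k_apc_mat", "K_cyt", "k_apc_mig", "k_apc_death", "k_apcln_death",
  "k_pr8", "k_pr4", "k_prR", "K_TCC", "K_ag", "w4", "K4",
  ## macrophages
  "M_pool", "k_m1_rec", "k_m2_rec", "k_m12", "k_m_death",
  ## cytokine
  "k_cyt_prod", "k_cyt_kill", "K_kflux", "k_cyt_deg",
  ## out-of-synapse PD-L1
  "k_shed", "w_m2", "k_p_deg",
  ## antibody PK / masking
  "MW", "Kd_ab", "k_off_ab", "k_cl", "k_b_int", "k_mask",
  "K_M", "k_cvg", "Kd_neo", "TCC", "BW",
  ## compartment volumes (mL) and flows (mL/day)
  "V_C", "V_P", "V_T", "V_LN",
  "Q_T", "Q_P", "Q_LN", "sig_T", "sig_P", "sig_LN",
  ## derived: equilibrium open (binding-competent) fraction of intact drug
  "u_open"
)

.qsp_state_names <- c(
  ## tumor compartment (cells, a.u. for Cyt)
  "C", "T8", "T4", "Tr", "APC", "M1", "M2", "Cyt",
  ## tumor-draining lymph node
  "APC_LN", "T8_LN", "T4_LN", "Tr_LN",
  ## central (circulating T cells)
  "T8_C", "T4_C", "Tr_C",
  ## out-of-synapse free PD-L1 in the tumor (mol/mL)
  "P",
  ## antibody species (mol/mL): m = fully masked, o = reversibly open,
  ## c = cleaved; B* = PD-L1-bound counterparts of the binding-competent
  ## states (tumor only)
  "Am_T", "Ao_T", "Ac_T", "Bo_T", "Bc_T",
  "Am_C", "Ao_C", "Ac_C",
  "Am_P", "Ao_P", "Ac_P",
  "Am_LN", "Ao_LN", "Ac_LN",
  ## cumulative cleaved antibody (mol), monitoring state
  "Qcv"
)

.qsp_compartments <- c("tumor", "tdln", "central", "peripheral")

#' Default model parameters
#'
#' Returns the reduced default parameterization of the QSP
#' immuno-oncology model: a structurally faithful, four-compartment
#' (tumor, tumor-draining lymph node, central, peripheral) system with
#' CD8/CD4/Treg T-cell dynamics, antigen-presenting cells, M1/M2
#' macrophages, a cytokine pool, out-of-synapse PD-L1, and a masked
#' (conditionally activated) anti-PD-L1 antibody with reversible
#' unmasking (equilibrium constant \code{K_M}) and irreversible
#' protease cleavage (\code{k_cvg}, tumor compartment only).  Every
#' rate is a named entry so a full external calibration table can be
#' loaded over these defaults.
#'
#' Units: first-order rates 1/day, cell pools absolute cells,
#' concentrations mol/mL, volumes mL, flows mL/day, diameters cm,
#' body mass kg, antibody molecular weight mg/mol.
#'
#' @param ... named overrides of individual parameter values.
#' @return named numeric vector of model parameters.
#' @export
#' @examples
#' p <- default_parameters(TCC = 200, k_cvg = 0.05)
#' p[["TCC"]]
default_parameters <- function(...) {
  p <- c(
    k_growth = 0.008, C_max = 3e11, vol_cell = 2.36e-9, packing = 0.375,
    d0 = 3.5,
    k_kill = 2, K_kill = 1e9, K_treg = 1e7,
    pdl1_syn = 30, pdl2_syn = 0.3, K_pd = 1, k_exh = 0.5,
    K_rec = 1e8, k_T_in = 0.3, k_T_death = 0.1, k_c_death = 0.05,
    k_ln_out = 0.5, k_ln_death = 0.05,
    A_pool = 1e7, k_apc_mat = 1.0, K_cyt = 0.5, k_apc_mig = 0.3,
    k_apc_death = 0.2, k_apcln_death = 0.5,
    k_pr8 = 4, k_pr4 = 8, k_prR = 0.05, K_TCC = 450, K_ag = 1e-11,
    w4 = 2, K4 = 1e6,
    M_pool = 5e9, k_m1_rec = 0.02, k_m2_rec = 0.03, k_m12 = 0.05,
    k_m_death = 0.2,
    k_cyt_prod = 1.0, k_cyt_kill = 1.0, K_kflux = 1e7, k_cyt_deg = 1.0,
    k_shed = 1e-21, w_m2 = 5, k_p_deg = 10,
    MW = 1.5e8, Kd_ab = 3e-14, k_off_ab = 5, k_cl = 0.15, k_b_int = 0.5,
    k_mask = 50,
    K_M = 0.01, k_cvg = 0.13, Kd_neo = 1e-11, TCC = 93, BW = 70,
    V_C = 5000, V_P = 15000, V_T = 15, V_LN = 1,
    Q_T = 2, Q_P = 500, Q_LN = 10, sig_T = 0.6, sig_P = 0.05,
    sig_LN = 0.6,
    u_open = NA_real_
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  p[["u_open"]] <- unmasked_fraction(p[["K_M"]])
  p
}

#' Validate a model parameter vector
#'
#' Checks completeness and the physical constraints (non-negative rates
#' and concentrations, \code{TCC >= 1}, \code{K_M > 0},
#' \code{d0 > 0}).  A missing parameter raises a configuration error
#' naming the parameter.
#'
#' @param params named numeric vector as from [default_parameters()].
#' @return the validated parameter vector, invisibly, with
#'   \code{u_open} refreshed from \code{K_M}.
#' @export
validate_params <- function(params) {
  missing <- setdiff(.qsp_param_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  params <- params[.qsp_param_names]
  chk <- params[setdiff(.qsp_param_names, "u_open")]
  if (anyNA(chk))
    stop("non-finite parameter(s): ",
         paste(names(chk)[is.na(chk)], collapse = ", "), call. = FALSE)
  if (any(chk < 0))
    stop("negative parameter(s): ",
         paste(names(chk)[chk < 0], collapse = ", "), call. = FALSE)
  if (params[["TCC"]] < 1) stop("TCC must be >= 1", call. = FALSE)
  if (params[["K_M"]] <= 0) stop("K_M must be > 0", call. = FALSE)
  if (params[["d0"]] <= 0) stop("d0 must be > 0", call. = FALSE)
  params[["u_open"]] <- unmasked_fraction(params[["K_M"]])
  invisible(params)
}

## Patient-level parameters are a subset of the full vector; applying a
## sampled PatientParameters row over the defaults yields the per-patient
## model parameterization.
apply_patient_params <- function(patient, base = default_parameters()) {
  patient <- unlist(patient)
  patient <- patient[names(patient) %in% .qsp_param_names]
  base[names(patient)] <- patient
  base[["u_open"]] <- unmasked_fraction(base[["K_M"]])
  base
}

#' Read / write parameter distribution tables
#'
#' Parameter distribution tables are delimited text (CSV) with columns
#' \code{name, distribution, p1, p2, lower, upper, units}.  Supported
#' families: \code{uniform} (p1 = min, p2 = max), \code{loguniform}
#' (p1 = min, p2 = max, both > 0), \code{normal} (p1 = mean, p2 = sd),
#' \code{lognormal} (p1 = meanlog, p2 = sdlog) and \code{fixed}
#' (p1 = value).  \code{lower}/\code{upper} are truncation bounds
#' (may be \code{NA} for unbounded).
#'
#' @param path CSV file path.
#' @return data.frame with the table schema above.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "distribution", "p1", "p2", "lower", "upper")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table missing column(s): ", paste(miss, collapse = ", "))
  validate_distribution_set(tab)
  tab
}

#' @rdname read_parameter_table
#' @param tab parameter distribution data.frame.
#' @param path output CSV path.
#' @export
write_parameter_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

.qsp_families <- c("uniform", "loguniform", "normal", "lognormal", "fixed")

validate_distribution_set <- function(tab) {
  bad <- setdiff(tab$distribution, .qsp_families)
  if (length(bad))
    stop("unknown distribution family: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  lo <- ifelse(is.na(tab$lower), -Inf, tab$lower)
  hi <- ifelse(is.na(tab$upper), Inf, tab$upper)
  if (any(lo >= hi & tab$distribution != "fixed"))
    stop("truncation bounds must satisfy lower < upper", call. = FALSE)
  invisible(tab)
}

#' Default patient-level parameter distributions
#'
#' The reduced default sampling distributions for the patient-level
#' parameters of the NSCLC-like virtual population: tumor growth rate
#' and initial (pre-treatment target) diameter, neoantigen binding
#' constant \code{Kd_neo}, tumor-specific T-cell clone count
#' \code{TCC} (the model's tumor-mutational-burden proxy, geometric
#' median 93), protease cleavage rate \code{k_cvg}, exhaustion rate,
#' antibody clearance, body mass, macrophage recruitment rates and
#' Treg/CD4 priming rates.  A full external calibration can be loaded
#' with [read_parameter_table()] and used anywhere this default is.
#'
#' @return data.frame with columns
#'   \code{name, distribution, p1, p2, lower, upper, units}.
#' @export
default_parameter_distributions <- function() {
  data.frame(
    name = c("k_growth", "d0", "Kd_neo", "TCC", "k_cvg", "k_exh",
             "k_cl", "BW", "k_m1_rec", "k_m2_rec", "k_prR", "k_pr4",
             "K_M"),
    distribution = c("lognormal", "uniform", "loguniform", "lognormal",
                     "loguniform", "lognormal", "lognormal", "normal",
                     "lognormal", "lognormal", "lognormal", "lognormal",
                     "fixed"),
    p1 = c(log(0.008), 2, 1e-12, log(93), 0.03, log(0.5), log(0.15),
           70, log(0.02), log(0.03), log(0.05), log(8), 0.01),
    p2 = c(0.35, 5, 1e-9, 1.0, 0.6, 0.5, 0.2, 10, 0.7, 0.7, 0.6, 0.5, NA),
    lower = c(0.002, 2, 1e-12, 1, 0.03, 0.1, 0.05, 40, 0.002, 0.003,
              0.01, 0.5, NA),
    upper = c(0.03, 5, 1e-9, 1e4, 0.6, 3, 0.5, 120, 0.2, 0.3, 2, 80,
              NA),
    units = c("1/day", "cm", "mol/mL", "clones", "1/day", "1/day",
              "1/day", "kg", "1/day", "1/day", "1/day", "1/day", "-"),
    stringsAsFactors = FALSE
  )
}
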