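## interface: run configuration, deterministic sub-seeds, stage
## orchestration in the generate -> select -> trial -> analyze order,
## and result serialization.

#' Run configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].
#' One master seed spawns named sub-seeds (synthetic data, LHS,
#' annealing, selection, trial) so stages can be re-run in isolation
#' reproducibly.  The full configuration is serialized into every
#' output directory for provenance.
#'
#' @param n_proposed proposed-cohort size.
#' @param seed master seed.
#' @param eps ratio clamp constant (default 0.01).
#' @param constraints active constraint subset.
#' @param dose_mg_per_kg,interval_days,duration_days trial regimen
#'   (defaults 10 mg/kg every 14 days for 400 days).
#' @param arms trial arms to run.
#' @param horizon_days,inoculum_cells,growth_grid_days pre-treatment
#'   growth settings.
#' @param annealing list of [calibrate_beta()] settings.
#' @param param_dists path to a parameter distribution CSV, or NULL for
#'   [default_parameter_distributions()].
#' @param omics_table path to an omics reference CSV, or NULL to
#'   generate a synthetic reference table.
#' @param omics_n synthetic reference-table size when generated.
#' @param out_dir output directory.
#' @param analyses character subset of
#'   \code{c("prcc", "biomarkers", "median_split")}.
#' @return validated list of class \code{qsp_config}.
#' @export
run_config <- function(n_proposed = 200, seed = 1L, eps = 0.01,
                       constraints = c("x1", "x2", "x3"),
                       dose_mg_per_kg = 10, interval_days = 14,
                       duration_days = 400,
                       arms = c("masked", "unmasked"),
                       horizon_days = 8000, inoculum_cells = 100,
                       growth_grid_days = 5,
                       annealing = list(iters = 300, t0 = 1,
                                        cooling = 0.99, step = 0.25),
                       param_dists = NULL, omics_table = NULL,
                       omics_n = 500,
                       out_dir = tempfile("qspvct_run_"),
                       analyses = c("prcc", "biomarkers",
                                    "median_split")) {
  cfg <- list(n_proposed = n_proposed, seed = as.integer(seed),
              eps = eps, constraints = constraints,
              dose_mg_per_kg = dose_mg_per_kg,
              interval_days = interval_days,
              duration_days = duration_days, arms = arms,
              horizon_days = horizon_days,
              inoculum_cells = inoculum_cells,
              growth_grid_days = growth_grid_days,
              annealing = annealing, param_dists = param_dists,
              omics_table = omics_table, omics_n = omics_n,
              out_dir = out_dir, analyses = analyses)
  validate_config(cfg)
}

#' @rdname run_config
#' @param cfg configuration list (e.g. parsed from YAML/JSON).
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg)
    stop("config field '", field, "': ", msg, call. = FALSE)
  num1 <- function(field, lo = -Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo)
      fail(field, paste0("must be a single number >= ", lo))
  }
  num1("n_proposed", 1); num1("seed"); num1("dose_mg_per_kg", 0)
  num1("interval_days", 1e-9); num1("duration_days", 0)
  num1("horizon_days", 1e-9); num1("inoculum_cells", 1)
  num1("growth_grid_days", 1e-9); num1("omics_n", 20)
  if (!is.numeric(cfg$eps) || cfg$eps <= 0 || cfg$eps >= 0.5)
    fail("eps", "must be in (0, 0.5)")
  if (!all(cfg$constraints %in% c("x1", "x2", "x3")) ||
      !length(cfg$constraints))
    fail("constraints", "must be a non-empty subset of x1, x2, x3")
  if (!all(cfg$arms %in% c("masked", "unmasked")) || !length(cfg$arms))
    fail("arms", "must be a non-empty subset of masked, unmasked")
  for (pth in c("param_dists", "omics_table")) {
    if (!is.null(cfg[[pth]]) && !file.exists(cfg[[pth]]))
      fail(pth, paste0("file not found: ", cfg[[pth]]))
  }
  if (!all(cfg$analyses %in% c("prcc", "biomarkers", "median_split")))
    fail("analyses", "unknown analysis name")
  structure(cfg, class = "qsp_config")
}

#' @rdname run_config
#' @param path YAML (or JSON) config file.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- run_config()
  keep <- intersect(names(cfg), names(defaults))
  full <- unclass(defaults)
  full[keep] <- cfg[keep]
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  validate_config(full)
}

#' Deterministic named sub-seeds from a master seed
#'
#' @param seed master integer seed.
#' @return named integer vector (synth, lhs, annealing, selection,
#'   trial).
#' @export
derive_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 5L),
                  c("synth", "lhs", "annealing", "selection", "trial"))
}

.log_event <- function(log_path, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  cat(line, "\n", file = log_path, append = TRUE)
  message(event, ": ",
          paste(names(list(...)), unlist(list(...)), sep = "=",
                collapse = " "))
}

#' Run the full virtual-clinical-trial pipeline
#'
#' Executes the workflow stages in order: synthesize/load inputs,
#' generate proposed and plausible patients, select virtual patients by
#' the omics-informed inclusion probability, run the trial arm(s), and
#' the configured analyses.  Every numeric figure input (waterfall,
#' spider, PFS, exposure, PRCC matrix, biomarker comparison,
#' median-split labels) is written as a machine-readable CSV/JSON file
#' under \code{cfg$out_dir}; a JSON-lines log records seeds, beta,
#' acceptance rates and runtimes.
#'
#' @param cfg a [run_config()].
#' @return list with the cohort, selection report, trials and analyses
#'   (invisibly also serialized under \code{cfg$out_dir}).
#' @export
run_pipeline <- function(cfg = run_config()) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "log.jsonl")
  jsonlite::write_json(unclass(cfg),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  seeds <- derive_seeds(cfg$seed)
  t_start <- Sys.time()

  ## inputs
  dists <- if (is.null(cfg$param_dists)) default_parameter_distributions()
  else read_parameter_table(cfg$param_dists)
  omics <- if (is.null(cfg$omics_table))
    make_omics_table(omics_spec(n = cfg$omics_n,
                                seed = seeds[["synth"]]))
  else read_omics_table(cfg$omics_table)
  utils::write.csv(omics, file.path(cfg$out_dir, "omics_reference.csv"),
                   row.names = FALSE)

  ## generate
  coh <- generate_cohort(dists, n = cfg$n_proposed,
                         seed = seeds[["lhs"]],
                         horizon = cfg$horizon_days,
                         inoculum_cells = cfg$inoculum_cells,
                         grid_days = cfg$growth_grid_days)
  write_cohort(coh, file.path(cfg$out_dir, "plausible_cohort.csv"))
  .log_event(log_path, "generate", n_proposed = coh$n_proposed,
             n_plausible = coh$n_plausible, seed = seeds[["lhs"]])
  if (coh$n_plausible < 20)
    stop("too few plausible patients (", coh$n_plausible,
         ") to fit the inclusion model", call. = FALSE)

  ## select
  ref_ratios <- ratios_from_table(omics, cfg$eps)
  pla_ratios <- ratios_from_cohort(coh, cfg$eps)
  model <- inclusion_model(ref_ratios, pla_ratios, cfg$constraints,
                           cfg$eps)
  model <- do.call(calibrate_beta,
                   c(list(model = model, pla_ratios = pla_ratios,
                          ref_ratios = ref_ratios,
                          seed = seeds[["annealing"]]),
                     cfg$annealing))
  sel <- select_vps(pla_ratios, model, seed = seeds[["selection"]],
                    n_proposed = coh$n_proposed)
  vcoh <- coh
  vcoh$params <- coh$params[sel$selected, , drop = FALSE]
  vcoh$init <- coh$init[sel$selected, , drop = FALSE]
  report <- list(seed = cfg$seed, eps = cfg$eps,
                 constraints = cfg$constraints, beta = model$beta,
                 n_proposed = coh$n_proposed,
                 n_plausible = coh$n_plausible,
                 n_virtual = sum(sel$selected),
                 acceptance_rate_pct = sel$acceptance_rate_pct)
  jsonlite::write_json(report,
                       file.path(cfg$out_dir, "selection_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_event(log_path, "select", beta = model$beta,
             n_virtual = sum(sel$selected),
             acceptance_rate_pct = round(sel$acceptance_rate_pct, 2))
  if (!nrow(vcoh$params))
    stop("selection produced an empty virtual cohort", call. = FALSE)

  ## trial arm(s)
  trials <- list()
  for (arm in cfg$arms) {
    reg <- regimen(cfg$dose_mg_per_kg, cfg$interval_days,
                   cfg$duration_days, arm)
    tl <- run_trial(vcoh, reg)
    write_trial(tl, cfg$out_dir, prefix = paste0("trial_", arm))
    trials[[arm]] <- tl
    .log_event(log_path, "trial", arm = arm,
               orr_pct = round(tl$orr_pct, 2))
  }

  ## analyses (on the first arm)
  analyses <- list()
  tl <- trials[[1L]]
  if ("prcc" %in% cfg$analyses) {
    ok <- !tl$outcomes$failed
    X <- vcoh$params[ok, , drop = FALSE]
    Y <- cbind(.biomarker_panel(tl$final_state[ok, , drop = FALSE]),
               percent_change = tl$outcomes$percent_change[ok],
               final_diameter = tumor_diameter(
                 tl$final_state[ok, "C"], default_parameters()),
               CD8_CD4 = tl$final_state[ok, "T8"] /
                 pmax(tl$final_state[ok, "T4"], 1))
    analyses$prcc <- prcc_table(X, Y)
    utils::write.csv(analyses$prcc,
                     file.path(cfg$out_dir, "prcc_matrix.csv"))
  }
  if ("biomarkers" %in% cfg$analyses) {
    analyses$biomarkers <- compare_responders(tl, vcoh$init)
    utils::write.csv(analyses$biomarkers,
                     file.path(cfg$out_dir, "biomarker_comparison.csv"),
                     row.names = FALSE)
  }
  if ("median_split" %in% cfg$analyses) {
    v_ratios <- ratios_from_cohort(vcoh, cfg$eps)
    analyses$median_split <- cbind(
      patient = seq_len(nrow(v_ratios)),
      percent_change = tl$outcomes$percent_change,
      median_split_waterfall(v_ratios))
    utils::write.csv(analyses$median_split,
                     file.path(cfg$out_dir, "median_split_waterfall.csv"),
                     row.names = FALSE)
  }
  .log_event(log_path, "done",
             runtime_s = round(as.numeric(Sys.time() - t_start,
                                          units = "secs"), 1))
  invisible(list(config = cfg, cohort = coh, virtual_cohort = vcoh,
                 selection = report, model = model, trials = trials,
                 analyses = analyses))
}

#' Command-line entry point
#'
#' Backs the \code{inst/cli/qspvct.R} script.  Commands: \code{synth}
#' (write the synthetic inputs), \code{generate}, \code{select},
#' \code{trial}, \code{analyze} (each stage reads its upstream
#' artifacts from the output directory and errors if they are
#' missing), and \code{full-run}.
#'
#' @param command one of synth, generate, select, trial, analyze,
#'   full-run.
#' @param config_path YAML/JSON config file, or NULL for defaults.
#' @param out_dir overrides the configured output directory.
#' @param seed overrides the configured master seed.
#' @return 0 on success (invisibly); errors propagate.
#' @export
cli_run <- function(command, config_path = NULL, out_dir = NULL,
                    seed = NULL) {
  command <- match.arg(command, c("synth", "generate", "select",
                                  "trial", "analyze", "full-run"))
  cfg <- if (is.null(config_path)) run_config() else
    read_config(config_path)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg <- validate_config(cfg)
  seeds <- derive_seeds(cfg$seed)
  need <- function(f) {
    p <- file.path(cfg$out_dir, f)
    if (!file.exists(p))
      stop("missing upstream artifact: ", p,
           " (run the earlier stage first)", call. = FALSE)
    p
  }
  if (command == "full-run") { run_pipeline(cfg); return(invisible(0L)) }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (command == "synth") {
    omics <- make_omics_table(omics_spec(n = cfg$omics_n,
                                         seed = seeds[["synth"]]))
    utils::write.csv(omics, file.path(cfg$out_dir, "omics_reference.csv"),
                     row.names = FALSE)
    write_parameter_table(default_parameter_distributions(),
                          file.path(cfg$out_dir, "parameter_dists.csv"))
    return(invisible(0L))
  }
  if (command == "generate") {
    dists <- if (is.null(cfg$param_dists))
      default_parameter_distributions()
    else read_parameter_table(cfg$param_dists)
    coh <- generate_cohort(dists, n = cfg$n_proposed,
                           seed = seeds[["lhs"]],
                           horizon = cfg$horizon_days,
                           inoculum_cells = cfg$inoculum_cells,
                           grid_days = cfg$growth_grid_days)
    write_cohort(coh, file.path(cfg$out_dir, "plausible_cohort.csv"))
    saveRDS_txt <- file.path(cfg$out_dir, "plausible_meta.json")
    jsonlite::write_json(list(n_proposed = coh$n_proposed,
                              n_plausible = coh$n_plausible,
                              time_to_target = coh$time_to_target),
                         saveRDS_txt, auto_unbox = TRUE, digits = NA)
    return(invisible(0L))
  }
  ## stages below need the generated cohort on disk
  coh <- .read_cohort(need("plausible_cohort.csv"),
                      need("plausible_meta.json"))
  omics_path <- file.path(cfg$out_dir, "omics_reference.csv")
  omics <- if (!is.null(cfg$omics_table)) read_omics_table(cfg$omics_table)
  else if (file.exists(omics_path)) read_omics_table(omics_path)
  else stop("missing upstream artifact: ", omics_path,
            " (run 'synth' first or set omics_table)", call. = FALSE)
  ref_ratios <- ratios_from_table(omics, cfg$eps)
  pla_ratios <- ratios_from_cohort(coh, cfg$eps)
  model <- inclusion_model(ref_ratios, pla_ratios, cfg$constraints,
                           cfg$eps)
  model <- do.call(calibrate_beta,
                   c(list(model = model, pla_ratios = pla_ratios,
                          ref_ratios = ref_ratios,
                          seed = seeds[["annealing"]]),
                     cfg$annealing))
  sel <- select_vps(pla_ratios, model, seed = seeds[["selection"]],
                    n_proposed = coh$n_proposed)
  if (command == "select") {
    jsonlite::write_json(
      list(beta = model$beta, selected = which(sel$selected),
           acceptance_rate_pct = sel$acceptance_rate_pct,
           eps = cfg$eps, seed = cfg$seed),
      file.path(cfg$out_dir, "selection_report.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(0L))
  }
  vcoh <- coh
  vcoh$params <- coh$params[sel$selected, , drop = FALSE]
  vcoh$init <- coh$init[sel$selected, , drop = FALSE]
  if (command == "trial") {
    for (arm in cfg$arms) {
      reg <- regimen(cfg$dose_mg_per_kg, cfg$interval_days,
                     cfg$duration_days, arm)
      write_trial(run_trial(vcoh, reg), cfg$out_dir,
                  prefix = paste0("trial_", arm))
    }
    return(invisible(0L))
  }
  ## analyze
  arm <- cfg$arms[1L]
  reg <- regimen(cfg$dose_mg_per_kg, cfg$interval_days,
                 cfg$duration_days, arm)
  tl <- run_trial(vcoh, reg)
  cmp <- compare_responders(tl, vcoh$init)
  utils::write.csv(cmp, file.path(cfg$out_dir,
                                  "biomarker_comparison.csv"),
                   row.names = FALSE)
  invisible(0L)
}

.read_cohort <- function(csv_path, meta_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  init <- as.matrix(utils::read.csv(
    paste0(tools::file_path_sans_ext(csv_path), "_init.csv")))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(
    params = tab[, setdiff(names(tab), "time_to_target"), drop = FALSE],
    init = init, time_to_target = tab$time_to_target,
    n_proposed = meta$n_proposed, n_plausible = nrow(tab),
    seed = NA_integer_), class = "qsp_cohort")
}
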