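#' Read and validate a run configuration
#'
#' Flat YAML configuration for the end-to-end pipeline. Recognized keys:
#' `dispensing`, `hospital`, `baseline` (input CSV paths) or `simulate_n` +
#' `simulate_seed` (generate a synthetic cohort instead); `out_dir`;
#' `n_states` (10); `horizon` (20); `first_window` (5); `hospital_credit`
#' (`union`/`sum`); `terms` (model term list, default the final model);
#' `prev_state`; `time`; `bootstrap_reps` (100); `seed`. Unknown keys are
#' rejected.
#'
#' @param path YAML file path, or a named list (validated in place).
#' @return Named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("dispensing", "hospital", "baseline", "simulate_n",
             "simulate_seed", "out_dir", "n_states", "horizon",
             "first_window", "hospital_credit", "terms", "prev_state",
             "time", "bootstrap_reps", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(n_states = 10L, horizon = 20L, first_window = 5L,
                   hospital_credit = "union", bootstrap_reps = 100L,
                   seed = 1L, out_dir = ".", prev_state = "categorical",
                   time = "linear")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$terms))
    cfg$terms <- c("rcs4:age", "rcs4:chads_vasc", "rcs4:days_w1",
                   "rcs4:days_w2", "rcs4:days_w3 * time",
                   "rcs4:days_w4 * time")
  has_files <- !is.null(cfg$dispensing) && !is.null(cfg$baseline)
  has_sim <- !is.null(cfg$simulate_n)
  if (!has_files && !has_sim)
    stop("config must provide input CSV paths or simulate_n")
  structure(cfg, class = "run_config")
}

cfg_path <- function(config, file) file.path(config$out_dir, file)

#' Generate a synthetic cohort and write its input CSVs
#'
#' Writes `dispensing.csv`, `hospital.csv`, `baseline.csv`, the ground-truth
#' window table `truth_windows.csv` and `truth.json` (the true-model
#' parameters and seed) into `out_dir`.
#'
#' @param config a [read_run_config()] list with `simulate_n` (and
#'   optionally `simulate_seed`).
#' @return The `synthetic_cohort`, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$simulate_seed)) config$simulate_seed
          else config$seed
  tm <- default_true_model()
  coh <- generate_cohort(config$simulate_n, tm = tm, seed = seed,
                         n_windows = config$horizon)
  utils::write.csv(coh$dispensing, cfg_path(config, "dispensing.csv"),
                   row.names = FALSE)
  utils::write.csv(coh$hospital, cfg_path(config, "hospital.csv"),
                   row.names = FALSE)
  utils::write.csv(coh$baseline, cfg_path(config, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(coh$truth, cfg_path(config, "truth_windows.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n = config$simulate_n, alpha = as.list(tm$alpha),
         beta = as.list(tm$beta), knots = tm$knots,
         centers = as.list(tm$centers)),
    cfg_path(config, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message("simulated ", config$simulate_n, " patients (seed ", seed, ")")
  invisible(coh)
}

#' Compute windowed adherence states (`windows.csv`)
#'
#' Reads the three input CSVs (or the ones [run_simulate()] wrote into
#' `out_dir`), runs the PDC engine and writes `windows.csv`.
#'
#' @param config a [read_run_config()] list.
#' @return The windows data.frame, invisibly.
#' @export
run_pdc <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pick <- function(key, file) {
    if (!is.null(config[[key]])) config[[key]] else cfg_path(config, file)
  }
  dispensing <- utils::read.csv(pick("dispensing", "dispensing.csv"))
  baseline <- utils::read.csv(pick("baseline", "baseline.csv"))
  hosp_path <- pick("hospital", "hospital.csv")
  hospital <- if (file.exists(hosp_path)) utils::read.csv(hosp_path) else NULL
  if (!nrow(dispensing)) {
    warning("dispensing file is empty; writing an empty windows table")
    w <- data.frame(patient_id = character(), window_index = integer(),
                    covered_days = integer(), hospital_days = integer(),
                    pdc = numeric(), state = integer())
  } else {
    w <- build_cohort_windows(dispensing, hospital, baseline,
                              n_windows = config$horizon,
                              hospital_credit = config$hospital_credit)
  }
  utils::write.csv(w, cfg_path(config, "windows.csv"), row.names = FALSE)
  message("windows.csv: ", nrow(w), " rows (",
          length(unique(w$patient_id)), " patients)")
  invisible(w)
}

#' Fit the model ladder and serialize the final model
#'
#' Builds the transition table from `windows.csv`, fits the candidate
#' ladder, writes `ladder.csv` and serializes the minimum-AIC fit to
#' `fit.json`.
#'
#' @param config a [read_run_config()] list.
#' @return The [model_ladder()] result, invisibly.
#' @export
run_fit <- function(config) {
  config <- read_run_config(config)
  windows <- utils::read.csv(cfg_path(config, "windows.csv"))
  baseline <- utils::read.csv(
    if (!is.null(config$baseline)) config$baseline
    else cfg_path(config, "baseline.csv"))
  transitions <- build_transition_table(windows, baseline,
                                        first_window = config$first_window,
                                        horizon = config$horizon)
  lad <- model_ladder(transitions, n_states = config$n_states)
  utils::write.csv(lad$table, cfg_path(config, "ladder.csv"),
                   row.names = FALSE)
  final <- lad$fits[[which(lad$table$final)]]
  write_fit_json(final, cfg_path(config, "fit.json"))
  message("final model: ", lad$table$model[lad$table$final],
          " (AIC ", round(min(lad$table$aic, na.rm = TRUE), 1), ")")
  invisible(lad)
}

#' Predict state occupancy probabilities per patient
#'
#' Loads `fit.json`, computes SOPs and mean time in state for the requested
#' patients (default: all) and/or hypothetical profiles, writes long-format
#' `sops.csv` and `mean_time.csv`, and renders one SOP chart per subject.
#'
#' @param config a [read_run_config()] list.
#' @param patients patient ids (default all in `windows.csv`). Unknown ids
#'   are listed and skipped.
#' @param profiles optional data.frame of hypothetical profiles with columns
#'   `age`, `chads_vasc`, `days_w1`..`days_w4` and optionally `initial_state`
#'   (default: the state implied by `days_w4`).
#' @param figures write PNG charts (default TRUE).
#' @return Named list of `sop_matrix` objects, invisibly.
#' @export
run_predict <- function(config, patients = NULL, profiles = NULL,
                        figures = TRUE) {
  config <- read_run_config(config)
  fit <- read_fit_json(cfg_path(config, "fit.json"))
  windows <- utils::read.csv(cfg_path(config, "windows.csv"))
  baseline <- utils::read.csv(
    if (!is.null(config$baseline)) config$baseline
    else cfg_path(config, "baseline.csv"))
  transitions <- build_transition_table(windows, baseline,
                                        first_window = config$first_window,
                                        horizon = config$horizon)
  horizon_windows <- config$first_window:config$horizon
  per_pat <- transitions[!duplicated(transitions$patient_id), , drop = FALSE]
  if (is.null(patients) && is.null(profiles)) patients <- per_pat$patient_id
  sops <- list()
  if (!is.null(patients)) {
    unknown <- setdiff(patients, per_pat$patient_id)
    if (length(unknown))
      message("unknown patient(s) skipped: ", paste(unknown, collapse = ", "))
    for (id in setdiff(patients, unknown)) {
      row <- per_pat[per_pat$patient_id == id, , drop = FALSE]
      init <- windows$state[windows$patient_id == id &
                              windows$window_index == config$first_window - 1L]
      sops[[id]] <- compute_sops(fit, row[, c("age", "chads_vasc",
                                              paste0("days_w", 1:4))],
                                 init, windows = horizon_windows)
    }
  }
  if (!is.null(profiles)) {
    for (r in seq_len(nrow(profiles))) {
      pr <- profiles[r, , drop = FALSE]
      init <- if ("initial_state" %in% names(pr)) pr$initial_state
              else map_pdc_to_state(compute_pdc(pr$days_w4, 0))
      nm <- if (!is.null(rownames(profiles))) rownames(profiles)[r]
            else paste0("profile", r)
      sops[[nm]] <- compute_sops(fit, pr[, c("age", "chads_vasc",
                                             paste0("days_w", 1:4))],
                                 init, windows = horizon_windows)
    }
  }
  long <- do.call(rbind, lapply(names(sops), function(id) {
    s <- sops[[id]]
    data.frame(patient_id = id,
               window_index = rep(attr(s, "windows"), ncol(s)),
               state = rep(seq_len(ncol(s)), each = nrow(s)),
               probability = as.numeric(unclass(s)))
  }))
  utils::write.csv(long, cfg_path(config, "sops.csv"), row.names = FALSE)
  mt <- do.call(rbind, lapply(names(sops), function(id)
    data.frame(patient_id = id, state = seq_len(ncol(sops[[id]])),
               mean_time = as.numeric(mean_time_in_state(sops[[id]])))))
  utils::write.csv(mt, cfg_path(config, "mean_time.csv"), row.names = FALSE)
  if (figures) {
    figdir <- cfg_path(config, "figures")
    dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(sops))
      ggplot2::ggsave(file.path(figdir, paste0("sop_", id, ".png")),
                      plot_sops(sops[[id]]), width = 7, height = 4, dpi = 120)
  }
  message("predicted SOPs for ", length(sops), " subject(s)")
  invisible(sops)
}

#' Run the calibration and discrimination report
#'
#' Loads `fit.json` and `windows.csv`, computes in-sample SOP-based
#' diagnostics — subject-level and time-stratified calibration, the
#' GAM-smoothed calibration curve, transition-probability calibration, SOP
#' distribution widths with the bootstrap envelope, and the mean-time
#' absolute-error summary — and writes one CSV per diagnostic plus figures.
#'
#' @param config a [read_run_config()] list (`bootstrap_reps` and `seed`
#'   control the bootstrap).
#' @param figures write PNG charts (default TRUE).
#' @return Named list of the diagnostic tables, invisibly.
#' @export
run_evaluate <- function(config, figures = TRUE) {
  config <- read_run_config(config)
  fit_path <- cfg_path(config, "fit.json")
  if (!file.exists(fit_path))
    stop("fit.json not found in out_dir; run run_fit() first")
  fit <- read_fit_json(fit_path)
  windows <- utils::read.csv(cfg_path(config, "windows.csv"))
  baseline <- utils::read.csv(
    if (!is.null(config$baseline)) config$baseline
    else cfg_path(config, "baseline.csv"))
  transitions <- build_transition_table(windows, baseline,
                                        first_window = config$first_window,
                                        horizon = config$horizon)
  horizon_windows <- config$first_window:config$horizon
  per_pat <- transitions[!duplicated(transitions$patient_id), , drop = FALSE]
  sops <- lapply(seq_len(nrow(per_pat)), function(i) {
    id <- per_pat$patient_id[i]
    init <- windows$state[windows$patient_id == id &
                            windows$window_index == config$first_window - 1L]
    compute_sops(fit, per_pat[i, c("age", "chads_vasc",
                                   paste0("days_w", 1:4))],
                 init, windows = horizon_windows)
  })
  names(sops) <- per_pat$patient_id

  obs <- windows[windows$window_index %in% horizon_windows &
                   windows$patient_id %in% per_pat$patient_id, , drop = FALSE]
  pred <- sop_prediction_table(sops, obs)
  calib <- subject_calibration(pred)
  calib_time <- subject_calibration(pred, strata = "default")
  smooth <- smoothed_calibration(pred)
  trans_cal <- transition_calibration(fit, transitions)
  widths <- sop_width(sops)
  boot <- bootstrap_widths(sops, reps = config$bootstrap_reps,
                           seed = config$seed)
  mae <- mean_time_mae(sops, obs)

  utils::write.csv(calib, cfg_path(config, "calibration_subject.csv"),
                   row.names = FALSE)
  utils::write.csv(calib_time, cfg_path(config, "calibration_time.csv"),
                   row.names = FALSE)
  utils::write.csv(smooth, cfg_path(config, "calibration_smooth.csv"),
                   row.names = FALSE)
  utils::write.csv(trans_cal, cfg_path(config, "calibration_transition.csv"),
                   row.names = FALSE)
  utils::write.csv(widths$by_window, cfg_path(config, "sop_width.csv"),
                   row.names = FALSE)
  utils::write.csv(boot$by_window, cfg_path(config, "sop_width_bootstrap.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(median = mae$median, q25 = mae$q25,
                              q75 = mae$q75),
                   cfg_path(config, "mean_time_mae.csv"), row.names = FALSE)
  if (figures) {
    figdir <- cfg_path(config, "figures")
    dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(figdir, "calibration_subject.png"),
                    plot_calibration(calib), width = 5, height = 5, dpi = 120)
    ggplot2::ggsave(file.path(figdir, "calibration_time.png"),
                    plot_calibration(calib_time), width = 9, height = 4,
                    dpi = 120)
    ggplot2::ggsave(file.path(figdir, "sop_width.png"),
                    plot_sop_width(boot), width = 7, height = 4, dpi = 120)
  }
  message("evaluation report written to ", config$out_dir)
  invisible(list(calibration = calib, calibration_time = calib_time,
                 smoothed = smooth, transition_calibration = trans_cal,
                 widths = widths, bootstrap = boot, mae = mae))
}
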