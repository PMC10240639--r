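#' Build and validate a pipeline configuration
#'
#' @param model_file planar-model defaults JSON.
#' @param mechanism_file patellar-mechanism JSON.
#' @param cohort_file cohort defaults JSON (simulation only).
#' @param stance_threshold_n stance threshold on the raw vertical force
#'   (N), default 20.
#' @param velocity_window_s approach-velocity window before contact (s),
#'   default 0.050.
#' @param marker_cutoff_hz marker low-pass cutoff (Hz); \code{NA} disables.
#' @param grf_cutoff_hz GRF low-pass cutoff for inverse dynamics (Hz);
#'   event detection always uses the raw signal. \code{NA} disables.
#' @param g gravitational acceleration (m/s^2) for BW normalisation.
#' @param seed integer seed for any simulation step.
#' @param out_dir output directory.
#' @return object of class \code{pipeline_config} with a stable
#'   \code{hash} embedded in all outputs.
#' @export
pipeline_config <- function(model_file = default_file("model"),
                            mechanism_file = default_file("mechanism"),
                            cohort_file = default_file("cohort"),
                            stance_threshold_n = 20,
                            velocity_window_s = 0.050,
                            marker_cutoff_hz = 12,
                            grf_cutoff_hz = 50,
                            g = 9.81, seed = 1, out_dir = tempdir()) {
  if (stance_threshold_n <= 0)
    stop("configuration error: stance_threshold_n must be > 0")
  if (velocity_window_s <= 0)
    stop("configuration error: velocity_window_s must be > 0")
  if (g <= 0) stop("configuration error: g must be > 0")
  for (f in c(model_file, mechanism_file, cohort_file)) {
    if (!file.exists(f))
      stop("configuration error: referenced file does not exist: ", f)
  }
  cfg <- list(model_file = model_file, mechanism_file = mechanism_file,
              cohort_file = cohort_file,
              stance_threshold_n = stance_threshold_n,
              velocity_window_s = velocity_window_s,
              marker_cutoff_hz = marker_cutoff_hz,
              grf_cutoff_hz = grf_cutoff_hz, g = g, seed = seed,
              out_dir = out_dir)
  cfg$hash <- digest::digest(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

config_provenance <- function(config, model = NULL, mech = NULL) {
  c(config_hash = config$hash,
    model_version = if (!is.null(model)) model$version else NA,
    mechanism_version = if (!is.null(mech)) mech$version else NA,
    package_version = as.character(utils::packageVersion("pfjload")))
}

cutoff_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else x

#' Analyze one trial end to end
#'
#' Chains IK, stance detection, approach velocity, inverse dynamics over
#' stance, static optimization, the PFJ model, and metric extraction.
#'
#' @param markers a \code{\link{marker_series}}.
#' @param grf native-rate GRF data.frame (\code{time, fx, fy, cop_x}).
#' @param mass_kg,height_m participant anthropometry.
#' @param config a \code{\link{pipeline_config}}.
#' @param participant_id,limb,trial labels carried into the metrics row.
#' @return list with all stage outputs and the \code{stance_metrics} row.
#' @export
analyze_signal_trial <- function(markers, grf, mass_kg, height_m,
                                 config = pipeline_config(),
                                 participant_id = NA_character_,
                                 limb = NA_character_, trial = NA_integer_) {
  model <- planar_model(mass_kg, height_m, defaults = config$model_file)
  mech <- patellar_mechanism(config$mechanism_file)
  kin <- inverse_kinematics(markers, model,
                            filter_cutoff = cutoff_or_null(config$marker_cutoff_hz))
  stance <- detect_stance(grf, config$stance_threshold_n)
  stance_idx <- which(kin$time >= stance$contact_time - 1e-9 &
                      kin$time <= stance$toe_off_time + 1e-9)
  if (length(stance_idx) < 3)
    stop("no-stance error: stance covers fewer than 3 marker frames")
  grf_mark <- align_grf_to_markers(grf, kin$time)
  moments <- inverse_dynamics(kin, grf_mark, model,
                              grf_cutoff = cutoff_or_null(config$grf_cutoff_hz))
  sol <- static_optimization(moments, kin, model)
  fq_bw <- quadriceps_force(sol, mass_kg, config$g)
  pfj <- pfj_series(fq_bw, kin, mech)
  com_xy <- t(vapply(seq_along(kin$time), function(i) {
    fk_model_com(model, kin$pose[i, ])
  }, c(0, 0)))
  com <- data.frame(time = kin$time, x = com_xy[, 1], y = com_xy[, 2])
  vel <- approach_velocity(com, stance$contact_time,
                           window = config$velocity_window_s)
  metrics <- extract_metrics(pfj, kin, stance_idx, vel,
                             feasible = sol$feasible,
                             participant_id = participant_id, limb = limb,
                             trial = trial)
  list(kinematics = kin, stance = stance, moments = moments,
       muscles = sol, f_q_bw = fq_bw, pfj = pfj, com = com,
       approach_velocity = vel, metrics = metrics)
}

#' Simulate a cohort to disk
#'
#' \code{level = "metric"} writes a per-trial metrics CSV;
#' \code{level = "signal"} additionally generates marker (TRC) and GRF
#' (MOT) files per trial plus a \code{trials.csv} manifest for
#' \code{\link{run_pipeline}}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param level \code{"metric"} or \code{"signal"}.
#' @param design optional \code{\link{cohort_design}}; defaults to the
#'   config's cohort defaults file.
#' @param n_signal_participants number of ACLR + control participants to
#'   emit at signal level (signal trials are slower; defaults small).
#' @return invisibly, the output directory.
#' @export
simulate_cohort <- function(config = pipeline_config(),
                            level = c("metric", "signal"),
                            design = NULL, n_signal_participants = 2) {
  level <- match.arg(level)
  design <- design %||% cohort_design(defaults = config$cohort_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- config_provenance(config)
  prov["cohort_version"] <- design$version
  if (level == "metric") {
    tab <- generate_metric_cohort(design, config$seed)
    write_metrics_csv(tab, file.path(config$out_dir, "metrics.csv"),
                      provenance = prov)
    return(invisible(config$out_dir))
  }
  manifest <- list()
  seeds <- derive_seeds(config$seed, 10000L)
  k <- 0L
  emit_trial <- function(pid, limb, tr) {
    k <<- k + 1L
    spec <- limb_spec_from_design(design, limb)
    sim <- generate_signal_trial(spec, seed = seeds[k])
    stem <- sprintf("%s_%s_t%d", pid, limb, tr)
    pdir <- file.path(config$out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    write_trc(sim$trial$markers, file.path(pdir, paste0(stem, "_markers.trc")))
    write_mot(sim$trial$grf, file.path(pdir, paste0(stem, "_grf.mot")),
              name = stem, in_degrees = FALSE, provenance = prov)
    data.frame(participant_id = pid, limb = limb, trial = tr,
               markers_file = file.path(pid, paste0(stem, "_markers.trc")),
               grf_file = file.path(pid, paste0(stem, "_grf.mot")),
               mass_kg = spec$mass_kg, height_m = spec$height_m,
               stringsAsFactors = FALSE)
  }
  na <- min(design$n_aclr, n_signal_participants)
  nc <- min(design$n_control, n_signal_participants)
  for (i in seq_len(na)) for (limb in c("ACLR", "contralateral"))
    for (tr in seq_len(design$trials_per_limb))
      manifest[[length(manifest) + 1L]] <- emit_trial(sprintf("A%03d", i), limb, tr)
  for (i in seq_len(nc))
    for (tr in seq_len(design$trials_per_limb))
      manifest[[length(manifest) + 1L]] <- emit_trial(sprintf("C%03d", i), "control", tr)
  utils::write.csv(do.call(rbind, manifest),
                   file.path(config$out_dir, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(config$out_dir)
}

#' Run the full pipeline over a trial directory
#'
#' Reads the \code{trials.csv} manifest in \code{input_dir}, analyzes
#' every trial, writes the per-trial metrics CSV, fits the three
#' velocity-adjusted limb comparisons, and writes full-precision JSON
#' results plus a human-readable summary. A failing trial is skipped with
#' a logged reason; the run fails only if every trial fails.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param input_dir directory containing \code{trials.csv} and trial
#'   files.
#' @return a \code{limb_report} (invisibly) with the metrics table and
#'   per-trial log attached as attributes.
#' @export
run_pipeline <- function(config, input_dir) {
  manifest_path <- file.path(input_dir, "trials.csv")
  if (!file.exists(manifest_path))
    stop("input error: no trials.csv manifest in ", input_dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  rows <- list()
  log <- list()
  for (i in seq_len(nrow(manifest))) {
    tr <- manifest[i, ]
    res <- tryCatch({
      mk <- read_trc(file.path(input_dir, tr$markers_file))
      grf <- read_mot(file.path(input_dir, tr$grf_file))
      out <- analyze_signal_trial(mk, grf, tr$mass_kg, tr$height_m, config,
                                  participant_id = tr$participant_id,
                                  limb = tr$limb, trial = tr$trial)
      rows[[length(rows) + 1L]] <- out$metrics
      list(status = "ok")
    }, error = function(e) list(status = "skipped", reason = conditionMessage(e)))
    log[[i]] <- data.frame(participant_id = tr$participant_id, limb = tr$limb,
                           trial = tr$trial, status = res$status,
                           reason = res$reason %||% "",
                           stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, log)
  if (length(rows) == 0)
    stop("pipeline error: all ", nrow(manifest), " trials failed; first: ",
         log$reason[1])
  metrics <- normalize_metrics_table(do.call(rbind, rows))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- planar_model(defaults = config$model_file)
  mech <- patellar_mechanism(config$mechanism_file)
  prov <- config_provenance(config, model, mech)
  write_metrics_csv(metrics, file.path(config$out_dir, "metrics.csv"),
                    provenance = prov)
  report <- compare_all(metrics)
  write_results_json(report, file.path(config$out_dir, "stats.json"),
                     provenance = as.list(prov))
  utils::write.csv(log, file.path(config$out_dir, "trial_log.csv"),
                   row.names = FALSE, quote = TRUE)
  con <- file(file.path(config$out_dir, "summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  attr(report, "metrics") <- metrics
  attr(report, "log") <- log
  invisible(report)
}

#' Descriptive diagnostics (normality and group t-tests)
#'
#' Optional descriptives outside the main comparison: Shapiro--Wilk
#' normality checks per limb/outcome and Welch t-tests of participant
#' means between ACLR and control groups.
#'
#' @param metrics metrics table.
#' @return data.frame of diagnostics.
#' @export
diagnostics_table <- function(metrics) {
  metrics <- normalize_metrics_table(metrics)
  out <- list()
  for (col in c("peak_pfj_bw", "knee_angle_deg", "quad_force_bw")) {
    for (l in unique(metrics$limb)) {
      y <- metrics[[col]][metrics$limb == l]
      p <- if (length(y) >= 3 && stats::sd(y) > 0)
        stats::shapiro.test(y)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        outcome = col, limb = l, test = "shapiro_wilk", p_value = p)
    }
    a <- metrics[[col]][metrics$limb == "ACLR"]
    c_ <- metrics[[col]][metrics$limb == "control"]
    if (length(a) >= 2 && length(c_) >= 2)
      out[[length(out) + 1L]] <- data.frame(
        outcome = col, limb = "ACLR_vs_control", test = "welch_t",
        p_value = stats::t.test(a, c_)$p.value)
  }
  do.call(rbind, out)
}
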