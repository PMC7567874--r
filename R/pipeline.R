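# End-to-end pipeline orchestration over the synthetic cohort, with a YAML
# config and a JSON summary of headline statistics.

#' Build a pipeline configuration
#'
#' All tunables of the end-to-end synthetic run in one structure: stimulus
#' rhythm, cohort sizes, sample rates, bands, thresholds, bootstrap sizes,
#' and the master seed from which every stage derives its own seed (see
#' [derive_seed()]). Round-trips losslessly through YAML.
#'
#' @param seed master seed.
#' @param ... overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    mod_freq_hz = 3, mod_depth = 0.8, rhythmic_dur_s = 3,
    constant_dur_s = 0.833,
    neural_fs = 400, n_trials = 15,
    n_hgtts = 8, n_pt = 6, n_stg = 4, ml_extent_mm = 16,
    snr = 3,
    epoch_window_s = c(-0.5, 4.2), baseline_window_s = c(-0.3, -0.05),
    bias_threshold = 10, magnitude_min = 10, alpha = 0.05,
    n_boot = 200, nnmf_replicates = 30,
    n_subjects = 12, n_behavior_trials = 100,
    stim_counts = list(hg_edge = c(10, 31), uniform = c(11, 18),
                       pt_edge = c(17, 21)))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$stim_counts <- lapply(cfg$stim_counts, as.numeric)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> preprocess -> spectral decomposition -> interval engagement ->
#' NNMF classification -> traveling wave -> behavioral statistics. Writes TSV
#' tables, a JSON summary of the headline statistics, and a log of seeds to
#' `out_dir`, and returns the summary invisibly.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("ecogpred")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("ecogpred pipeline, master seed %d", cfg$seed),
                 sprintf("R %s", getRversion()))
  if (cfg$n_boot < 100)
    log_lines <- c(log_lines, "WARNING: n_boot < 100; bootstrap p-values are coarse")

  # --- simulate ---------------------------------------------------------
  spec <- stimulus_spec(sample_rate_hz = 8000, mod_freq_hz = cfg$mod_freq_hz,
                        mod_depth = cfg$mod_depth,
                        rhythmic_dur_s = cfg$rhythmic_dur_s,
                        constant_dur_s = cfg$constant_dur_s,
                        seed = derive_seed(cfg$seed, "stimulus"))
  stim <- make_am_noise_stimulus(spec)
  electrodes <- make_electrode_table(cfg$n_hgtts, cfg$n_pt, cfg$n_stg,
                                     ml_extent_mm = cfg$ml_extent_mm,
                                     seed = derive_seed(cfg$seed, "electrodes"))
  truth <- make_ground_truth(electrodes, snr = cfg$snr)
  sim <- simulate_neural_response(stim, electrodes, truth,
                                  n_trials = cfg$n_trials, fs = cfg$neural_fs,
                                  seed = derive_seed(cfg$seed, "neural"))
  write_event_tsv(electrodes, file.path(out_dir, "electrodes.tsv"))
  write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))

  # --- preprocess -------------------------------------------------------
  excl <- exclude_channels(sim$listening)
  rec <- common_average_reference(excl$recording)
  write_event_tsv(excl$report, file.path(out_dir, "exclusions.tsv"))

  # --- spectral ---------------------------------------------------------
  epochs <- epoch_recording(rec, "stimulus_onset", cfg$epoch_window_s,
                            cfg$baseline_window_s)
  bands <- canonical_bands()
  hg <- analytic_signal(epochs, bands$highgamma)
  lf <- analytic_signal(epochs, bands$low)
  hg_pc <- percent_change_power(hg)

  # --- phase stats ------------------------------------------------------
  intervals <- interval_definitions(cfg$mod_freq_hz, cfg$rhythmic_dur_s,
                                    cfg$baseline_window_s)
  eng <- interval_engagement(lf$phase, hg$amplitude, epochs$time, intervals,
                             cfg$mod_freq_hz)
  utils::write.table(eng$table, file.path(out_dir, "interval_engagement.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- response classes -------------------------------------------------
  hg_mean <- apply(hg_pc, c(1, 3), mean)
  A <- rectify(hg_mean)
  model <- nnmf_fit(A, k = 2, n_replicates = cfg$nnmf_replicates,
                    seed = derive_seed(cfg$seed, "nnmf"))
  model <- assign_class_identity(normalize_archetypes(model), epochs$time,
                                 cfg$mod_freq_hz, cfg$rhythmic_dur_s)
  cb <- class_bias(model)
  classes <- classify_responses(cb$bias, threshold = cfg$bias_threshold)
  grad <- tryCatch(
    gradient_correlation(cb$bias, cb$magnitude,
                         rec$electrode_table$anteroposterior_pos_mm,
                         cfg$magnitude_min),
    error = function(e) list(rho = NA_real_, p = NA_real_, n = 0L))

  # --- traveling wave ---------------------------------------------------
  is_hg_tts <- rec$electrode_table$region == "HG/TTS"
  wave <- if (sum(is_hg_tts) >= 4) {
    pt <- peak_time_by_pulse(hg_mean[is_hg_tts, , drop = FALSE], epochs$time,
                             stim$pulse_peak_times, cfg$mod_freq_hz)
    traveling_wave_fit(pt, rec$electrode_table$mediolateral_pos_mm[is_hg_tts])
  } else list(velocity_m_per_s = NA_real_, defined = FALSE)

  # --- behavior ---------------------------------------------------------
  beh <- simulate_detection_behavior(cfg$n_subjects, cfg$n_behavior_trials,
                                     seed = derive_seed(cfg$seed, "behavior"))
  acc <- accuracy_by_condition(beh)
  pos <- position_effect_test(beh)
  sc <- cfg$stim_counts
  z_uniform <- two_proportion_z(sc$hg_edge[1], sc$hg_edge[2],
                                sc$uniform[1], sc$uniform[2])
  z_pt <- two_proportion_z(sc$hg_edge[1], sc$hg_edge[2],
                           sc$pt_edge[1], sc$pt_edge[2])

  summary <- list(
    seed = cfg$seed,
    n_electrodes = nrow(rec$data),
    interval_engagement = eng$group,
    classification_counts = as.list(table(classes)),
    gradient_rho = grad$rho, gradient_p = grad$p,
    wave_velocity_m_per_s = wave$velocity_m_per_s,
    quarter_period_delay_ms = quarter_period_delay(cfg$mod_freq_hz),
    behavior_hit_rate_by_level = acc$by_level$hit_rate,
    position2_min_p = min(pos$p_adjusted),
    stimulation_p_edge_vs_uniform = z_uniform$p,
    stimulation_p_hg_vs_pt = z_pt$p)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(summary)
}
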