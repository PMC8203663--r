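# End-to-end orchestration: simulate or load a session, run the signal
# chain, site classification, onset latency, decoding (task) or spike
# cleaning and food-specific testing (meal), and write TSV/JSON outputs
# with a reproducibility manifest.

# 12-channel demo scenario: one shaft per planted category so the Laplacian
# re-reference cannot leak a planted response into an unplanted flanking
# contact. A1-A4 inactive, B1-B4 responsive (equal gains), C1-C4 specific
# (neutral-dominant, mirroring the posterior-insula finding).
demo_task_specs <- function() {
  rbind(
    response_spec(paste0("B", 1:4), "palatable", 3, 0.3, 1, 0.1, "cue"),
    response_spec(paste0("B", 1:4), "neutral", 3, 0.3, 1, 0.1, "cue"),
    response_spec(paste0("C", 1:4), "palatable", 1, 0.3, 1, 0.1, "cue"),
    response_spec(paste0("C", 1:4), "neutral", 4, 0.3, 1, 0.1, "cue"))
}

demo_task_channels <- function() {
  shaft <- rep(c("A", "B", "C"), each = 4)
  idx <- rep(1:4, 3)
  channel_table(label = paste0(shaft, idx), shaft = shaft,
                index_on_shaft = idx,
                region = rep(c("frontal_operculum", "anterior_insula",
                               "posterior_insula"), each = 4))
}

write_manifest <- function(path, config, seed, inputs, outputs) {
  manifest <- list(
    tool = "foodcue",
    version = as.character(utils::packageVersion("foodcue")),
    seed = seed,
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full task analysis pipeline
#'
#' Either loads a session (HDF5 container with signal, channels, events) or
#' simulates the 12-channel demo scenario, then runs notch filtering,
#' Laplacian re-referencing, HFB band power, cue-locked epoching, site
#' classification for both phases, response-onset latency summaries, and
#' single-trial decoding from the condition-specific channels. Writes
#' `sites.tsv`, `rol.tsv` (+ `rol_trials.tsv`), `report.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param session path to an HDF5 session file, or `NULL` to simulate.
#' @param config [fc_config()].
#' @param n_trials trial count for the simulated session.
#' @param seed master seed (simulation, permutations, folds).
#' @return invisibly, a list with the intermediate objects (`sites_ant`,
#'   `sites_rec`, `rol`, `report`).
#' @export
run_task_pipeline <- function(out_dir, session = NULL, config = fc_config(),
                              n_trials = 40, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(session)) {
    sim <- generate_task_session(demo_task_specs(), n_trials = n_trials,
                                 channels = demo_task_channels(),
                                 config = config, seed = seed)
    rec <- sim$rec
    events <- sim$events
  } else {
    if (!file.exists(session)) stop_argument("session file not found: ", session)
    rec <- read_recording(session, "hdf5")
    events <- attr(rec, "events")
    if (is.null(events)) stop_argument("session file carries no event table")
  }
  message("stage: preprocessing")
  rec <- notch_filter(rec, config$notch_freqs, config$notch_q)
  rec <- laplacian_rereference(rec)
  hfb <- band_power(rec, "hfb", config$smooth, config)
  epochs <- epoch_and_zscore(hfb, events, config$task_window,
                             config$task_baseline, "cue")
  message("stage: site classification")
  sites_ant <- classify_all_sites(epochs, "anticipation", config,
                                  seed = child_seed(seed, 11))
  sites_rec <- classify_all_sites(epochs, "receipt", config,
                                  seed = child_seed(seed, 12))
  write_results(sites_ant, file.path(out_dir, "sites_anticipation.tsv"))
  write_results(sites_rec, file.path(out_dir, "sites_receipt.tsv"))
  message("stage: response onset latency")
  trials <- rol_by_trial(epochs, config$rol$anticipation_window, config)
  rol <- rol_summary(trials, config, seed = child_seed(seed, 13))
  write_results(rol, file.path(out_dir, "rol.tsv"))
  message("stage: decoding")
  spec_ch <- sites_ant$channel[sites_ant$category == "specific"]
  report <- NULL
  if (length(spec_ch) >= 1) {
    feats <- extract_features(epochs, spec_ch, config$feature_windows)
    report <- train_eval_knn(feats, n_folds = config$knn$n_folds,
                             k = config$knn$k,
                             var_explained = config$knn$var_explained,
                             positive = config$knn$positive,
                             seed = child_seed(seed, 14))
    write_results(report, file.path(out_dir, "report.json"))
  } else {
    message("no condition-specific channels; decoding skipped")
  }
  outputs <- list.files(out_dir)
  write_manifest(file.path(out_dir, "manifest.json"), config, seed,
                 inputs = if (is.null(session)) character(0) else session,
                 outputs = outputs)
  invisible(list(sites_ant = sites_ant, sites_rec = sites_rec,
                 rol = rol, report = report, epochs = epochs))
}

# food-specific channels on shaft A, equal-gain channels on shaft B
demo_meal_specs <- function() {
  rbind(
    response_spec(paste0("A", 1:2), "entree", 4, -0.3, 1, 0.1, "bite"),
    response_spec(paste0("A", 1:2), "non_entree", 1, -0.3, 1, 0.1, "bite"),
    response_spec(paste0("B", 1:2), "entree", 2, -0.3, 1, 0.1, "bite"),
    response_spec(paste0("B", 1:2), "non_entree", 2, -0.3, 1, 0.1, "bite"))
}

demo_meal_channels <- function() {
  channel_table(label = c("A1", "A2", "B1", "B2"),
                shaft = c("A", "A", "B", "B"), index_on_shaft = c(1, 2, 1, 2),
                region = rep("posterior_insula", 4))
}

#' Run the ad libitum meal analysis pipeline
#'
#' Loads or simulates a meal session, detects and interpolates inter-ictal
#' spikes (cleaning precedes band-power extraction and epoching), epochs
#' bite-locked HFB activity, tests each channel for food specificity
#' (entree vs non-entree), and optionally tests the association with task
#' site labels. Writes `meal_sites.tsv`, `association.json` and
#' `manifest.json`.
#'
#' @param out_dir output directory.
#' @param session HDF5 session path, or `NULL` to simulate.
#' @param task_sites optional `site_labels` (or TSV path) from the task
#'   pipeline for the association test.
#' @param config [fc_config()].
#' @param n_bites length-2 bite counts for the simulated session.
#' @param spike_rate planted spikes/min for the simulated session.
#' @param seed master seed.
#' @return invisibly, list with `meal_sites`, `association`, `spikes`.
#' @export
run_meal_pipeline <- function(out_dir, session = NULL, task_sites = NULL,
                              config = fc_config(), n_bites = c(26, 18),
                              spike_rate = 2, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(session)) {
    if (min(n_bites) < config$min_bites) {
      stop_argument("inclusion criterion: at least ", config$min_bites,
                    " bites per food type required")
    }
    sim <- generate_meal_session(demo_meal_specs(), n_bites = n_bites,
                                 spike_rate = spike_rate,
                                 channels = demo_meal_channels(),
                                 config = config, seed = seed)
    rec <- sim$rec
    events <- sim$events
  } else {
    rec <- read_recording(session, "hdf5")
    events <- attr(rec, "events")
    if (is.null(events)) stop_argument("session file carries no event table")
  }
  counts <- table(events$condition[events$phase == "bite"])
  if (length(counts) < 2 || min(counts) < config$min_bites) {
    stop_argument("inclusion criterion: at least ", config$min_bites,
                  " bites per food type required")
  }
  message("stage: spike cleaning")
  spikes <- detect_spikes(rec, config$spikes$threshold, config$spikes$band,
                          config$spikes$merge)
  rec <- interpolate_spikes(rec, spikes, config$spikes$crossfade,
                            seed = child_seed(seed, 21))
  message("stage: preprocessing")
  rec <- notch_filter(rec, config$notch_freqs, config$notch_q)
  rec <- laplacian_rereference(rec)
  hfb <- band_power(rec, "hfb", config$smooth, config)
  epochs <- epoch_and_zscore(hfb, events, config$meal_window,
                             config$meal_baseline, "bite")
  message("stage: food-specific sites")
  meal_sites <- do.call(rbind, lapply(seq_len(nrow(rec$channels)), function(ch)
    classify_meal_site(epochs, ch, config, seed = child_seed(seed, 30 + ch))))
  class(meal_sites) <- c("site_labels", "data.frame")
  write_results(meal_sites, file.path(out_dir, "meal_sites.tsv"))
  association <- NULL
  if (!is.null(task_sites)) {
    if (is.character(task_sites)) task_sites <- read_site_labels(task_sites)
    common <- intersect(task_sites$channel, meal_sites$channel)
    association <- task_meal_association(
      task_sites[task_sites$channel %in% common, ],
      meal_sites[meal_sites$channel %in% common, ])
    jsonlite::write_json(
      list(statistic = association$statistic, df = association$df,
           p = association$p),
      file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
  }
  outputs <- list.files(out_dir)
  write_manifest(file.path(out_dir, "manifest.json"), config, seed,
                 inputs = if (is.null(session)) character(0) else session,
                 outputs = outputs)
  invisible(list(meal_sites = meal_sites, association = association,
                 spikes = spikes, epochs = epochs))
}
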