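#' Analysis configuration with study defaults
#'
#' Collects every tunable constant of the pipeline in one list. Defaults are
#' the published procedure values: 1024 Hz sampling, the canonical band
#' definitions, cue-locked epochs of -2 to 6 s z-scored against the -0.6 to
#' -0.1 s pre-cue baseline, bite-locked epochs of -5 to 5 s against a -5 to
#' -4.5 s baseline, 1000-iteration cluster permutation tests at alpha 0.05,
#' the 200 ms minimum responsive span and 100 ms specific/responsive overlap,
#' a weighted 10-nearest-neighbour decoder with 5-fold cross-validation and
#' 95% PCA variance retention, the 2-SD / 100 ms / 200 ms response-onset
#' procedure, and 5-SD inter-ictal spike detection on the 20-50 Hz band with
#' 100 ms replacement.
#'
#' @param ... named overrides of any top-level entry (unknown names error).
#' @return A list of class `fc_config`.
#' @examples
#' cfg <- fc_config(n_perm = 200)
#' cfg$bands$hfb
#' @export
fc_config <- function(...) {
  cfg <- list(
    fs = 1024,
    bands = list(
      delta = band_definition("delta", 1, 4, 4),
      theta = band_definition("theta", 4, 8, 4),
      alpha = band_definition("alpha", 8, 12, 4),
      beta  = band_definition("beta", 15, 25, 4),
      gamma = band_definition("gamma", 25, 50, 4),
      hfb   = band_definition("hfb", 70, 170, 8)
    ),
    smooth = 0.2,                      # boxcar envelope smoothing (s)
    notch_freqs = c(60, 120, 180),
    notch_q = 35,
    task_window = c(-2, 6),            # cue-locked epoch (s)
    task_baseline = c(-0.6, -0.1),
    meal_window = c(-5, 5),            # bite-locked epoch (s)
    meal_baseline = c(-5, -4.5),
    cue_effect_window = c(0, 1),       # effect-size averaging windows (s)
    receipt_effect_window = c(3, 4),
    n_perm = 1000,
    cluster_alpha = 0.05,
    min_response = 0.2,                # minimum significant span (s)
    min_overlap = 0.1,                 # specific/responsive overlap (s)
    site_windows = 5,                  # consecutive 500 ms test windows
    site_window_width = 0.5,
    meal_test_window = c(-1, 1),
    min_bites = 10,
    knn = list(k = 10, n_folds = 5, var_explained = 0.95,
               n_perm = 100, positive = "neutral"),
    feature_windows = list(c(0, 0.5), c(0.5, 1), c(1, 2), c(2, 3)),
    rol = list(threshold = 2, min_supra = 0.1, window = 0.2,
               n_boot = 1000, min_n = 10,
               anticipation_window = c(0, 3), receipt_window = c(3, 6)),
    spikes = list(threshold = 5, band = c(20, 50), replace = 0.1,
                  merge = 0.1, crossfade = 0.01),
    task = list(n_trials = 80, cue_duration = 1, fixation = 2,
                receipt_onset = 3, receipt_duration = 3, trial_spacing = 9.5,
                conditions = c("palatable", "neutral")),
    meal = list(conditions = c("entree", "non_entree"), bite_spacing = 10.5),
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop_argument("unknown config entries: ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]) && nm != "bands" &&
          nm != "feature_windows") {
        cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        cfg[[nm]] <- overrides[[nm]]
      }
    }
  }
  structure(cfg, class = "fc_config")
}

#' Frequency band definition
#'
#' @param name band name.
#' @param lo,hi band edges in Hz; `0 < lo < hi`.
#' @param order effective Butterworth band-pass order (two-pass filtering
#'   doubles the magnitude roll-off on top of this).
#' @return list of class `fc_band`.
#' @export
band_definition <- function(name, lo, hi, order = 4) {
  if (!(lo > 0 && hi > lo)) stop_argument("band edges must satisfy 0 < lo < hi")
  if (order < 2 || order %% 2 != 0) stop_argument("filter order must be even and >= 2")
  structure(list(name = name, lo = lo, hi = hi, order = order), class = "fc_band")
}

resolve_band <- function(band, config = fc_config()) {
  if (inherits(band, "fc_band")) return(band)
  if (is.character(band) && band %in% names(config$bands)) return(config$bands[[band]])
  stop_argument("unknown band: ", band)
}

#' Read an analysis configuration from a YAML file
#'
#' Top-level keys override [fc_config()] defaults; absent keys keep them.
#' @param path YAML file.
#' @return `fc_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_argument("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  do.call(fc_config, raw)
}

#' @export
print.fc_config <- function(x, ...) {
  cat("<foodcue analysis config>\n")
  cat("  fs:", x$fs, "Hz; bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat("  task epoch", sprintf("[%g, %g] s, baseline [%g, %g] s\n",
      x$task_window[1], x$task_window[2], x$task_baseline[1], x$task_baseline[2]))
  cat("  cluster permutations:", x$n_perm, "at alpha", x$cluster_alpha, "\n")
  invisible(x)
}
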