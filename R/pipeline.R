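#' Full run configuration
#'
#' Bundles every stage's parameters with their canonical defaults: 2 s
#' windows stepped by 0.5 s, order-26 FIR band-pass over 0.5-10 Hz, ANOVA
#' ranking with k = 35 features, SMOTE with 5 neighbours to a 1:1 ratio, and
#' a 10-tree random forest. One master `seed` deterministically derives all
#' stage seeds.
#'
#' @param generator A [generator_config()] (used when data are simulated).
#' @param window `list(length_s, step_s)`.
#' @param filter `list(order, band)`.
#' @param selection `list(method, k, n_bins)`; `method = "none"` disables
#'   feature selection.
#' @param smote `list(k_neighbors, target_ratio)`.
#' @param model `list(n_trees)`.
#' @param channels Channel subset specification (names or site shorthands;
#'   see [channels_at()]); default: left shank accelerometer + gyroscope.
#' @param seed Master seed.
#' @return Object of class `fog_config`.
#' @export
fog_config <- function(generator = generator_config(),
                       window = list(length_s = 2, step_s = 0.5),
                       filter = list(order = 26, band = c(0.5, 10)),
                       selection = list(method = "anova", k = 35, n_bins = 10),
                       smote = list(k_neighbors = 5, target_ratio = 1),
                       model = list(n_trees = 10),
                       channels = "left_shank",
                       seed = 1) {
  structure(
    list(
      generator = generator, window = window, filter = filter,
      selection = selection, smote = smote, model = model,
      channels = channels, seed = as.integer(seed)
    ),
    class = "fog_config"
  )
}

#' Extract a cohort feature table from raw recordings
#'
#' Per subject: restrict to the requested channels, interpolate missing
#' samples, band-pass filter, segment into labelled windows and compute the
#' 13 features per channel; rows from all subjects are stacked.
#'
#' @param cohort List of `list(recording, annotations)` pairs (as returned
#'   by [simulate_cohort()] or [read_recordings()]).
#' @param config A [fog_config()].
#' @return A feature table covering the whole cohort.
#' @export
extract_cohort_features <- function(cohort, config = fog_config()) {
  channels <- resolve_channels(config$channels)
  fs <- cohort[[1]]$recording$sample_rate
  coeffs <- design_fir(fs, order = config$filter$order, band = config$filter$band)
  tables <- lapply(cohort, function(s) {
    rec <- s$recording
    rec$channels <- rec$channels[channels]
    rec$missing <- rec$missing[channels]
    rec <- bandpass(interpolate_missing(rec), coeffs)
    ws <- segment(rec, s$annotations,
      m = config$window$length_s, t = config$window$step_s
    )
    compute_features(ws)
  })
  do.call(rbind, tables)
}

#' Run the full recognition pipeline under LOSO evaluation
#'
#' Preprocess, window, featurise (see [extract_cohort_features()]), then
#' evaluate with the per-fold normalise / rank / select / SMOTE / random
#' forest procedure of [loso_evaluate()].
#'
#' @param cohort List of `list(recording, annotations)` pairs.
#' @param config A [fog_config()].
#' @return A `fog_eval` (with the channel subset recorded in its config).
#' @export
run_pipeline <- function(cohort, config = fog_config()) {
  table <- extract_cohort_features(cohort, config)
  res <- loso_evaluate(
    table,
    method = config$selection$method,
    k = config$selection$k,
    n_trees = config$model$n_trees,
    smote_k = config$smote$k_neighbors,
    target_ratio = config$smote$target_ratio,
    seed = config$seed,
    n_bins = config$selection$n_bins
  )
  res$config$channels <- resolve_channels(config$channels)
  res
}

#' Compare sensor configurations
#'
#' Runs the pipeline once per channel subset with shared folds and seeds and
#' tabulates the pooled metrics, one row per configuration.
#'
#' @param cohort List of `list(recording, annotations)` pairs.
#' @param subsets Named list of channel subsets (e.g.
#'   [single_sensor_subsets()], or site shorthands).
#' @param config A [fog_config()] providing all other parameters.
#' @return Data frame: `subset`, `n_channels`, sensitivity, specificity,
#'   accuracy, precision, f_score; with the per-subset `fog_eval`s in
#'   attribute `"evals"`.
#' @export
evaluate_sensor_subsets <- function(cohort, subsets, config = fog_config()) {
  stopifnot(length(subsets) > 0)
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, function(s) paste(s, collapse = "+"), character(1))
  }
  evals <- lapply(subsets, function(sub) {
    if (length(sub) == 0) stop("config error: empty channel subset")
    cfg <- config
    cfg$channels <- sub
    # cap k at the subset's feature count
    nf <- 13 * length(resolve_channels(sub))
    if (!is.null(cfg$selection$k)) cfg$selection$k <- min(cfg$selection$k, nf)
    run_pipeline(cohort, cfg)
  })
  rows <- lapply(names(evals), function(nm) {
    m <- evals[[nm]]$aggregate$metrics
    data.frame(
      subset = nm,
      n_channels = length(evals[[nm]]$config$channels),
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy, precision = m$precision, f_score = m$f_score,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "evals") <- evals
  out
}
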