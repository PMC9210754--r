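#' Write a recording as a wide CSV
#'
#' Column 1 is `t_s`, then one column per channel (`<location>_<sensor>_<axis>`
#' for IMU channels, `<location>_fsr` for pressure channels); masked samples
#' are written as empty cells. The file is named `<subject_id>.csv`.
#'
#' @param recording A `fog_recording`.
#' @param dir Output directory (created if needed).
#' @return The file path, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "fog_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(recording$channels[[1]])
  df <- data.frame(t_s = (seq_len(n) - 1) / recording$sample_rate)
  for (ch in names(recording$channels)) {
    x <- recording$channels[[ch]]
    x[recording$missing[[ch]]] <- NA
    df[[ch]] <- x
  }
  path <- file.path(dir, paste0(recording$subject_id, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read one recording CSV
#'
#' @param path File written by [write_recording()]; the subject id is the
#'   file name without extension.
#' @return A `fog_recording` (empty cells become masked samples).
#' @export
read_recording <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (names(df)[1] != "t_s") {
    stop("parse error in ", path, ": first column must be t_s")
  }
  chans <- names(df)[-1]
  known <- montage()$channel
  bad <- setdiff(chans, known)
  if (length(bad) > 0) {
    stop(
      "parse error in ", path, ": unknown channel column(s): ",
      paste(bad, collapse = ", ")
    )
  }
  if (nrow(df) < 2) stop("parse error in ", path, ": too few samples")
  fs <- 1 / stats::median(diff(df$t_s))
  structure(
    list(
      subject_id = sub("\\.csv$", "", basename(path)),
      sample_rate = round(fs, 6),
      channels = lapply(df[chans], function(x) {
        x <- as.numeric(x)
        x[is.na(x)] <- 0
        x
      }),
      missing = lapply(df[chans], function(x) is.na(as.numeric(x)))
    ),
    class = "fog_recording"
  )
}

#' Read all recordings in a directory
#'
#' @param dir Directory of per-subject CSV files.
#' @return List of `fog_recording`s (possibly empty, with a warning).
#' @export
read_recordings <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    warning("no recording files found in ", dir)
    return(list())
  }
  lapply(files, read_recording)
}

#' Write / read episode annotations
#'
#' One CSV for a whole cohort with columns `subject_id,start_s,end_s`.
#'
#' @param annotations List of `fog_annotations` (or a single one).
#' @param path CSV path.
#' @return `write_annotations` returns the path invisibly;
#'   `read_annotations` a named list of `fog_annotations`.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "fog_annotations")) annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    if (nrow(a$episodes) == 0) {
      return(NULL)
    }
    data.frame(subject_id = a$subject_id, a$episodes)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(
      subject_id = character(0), start_s = numeric(0), end_s = numeric(0)
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @param subject_ids Subjects to materialise (so subjects without episodes
#'   still get an empty annotation track); defaults to those present in the
#'   file.
#' @export
read_annotations <- function(path, subject_ids = NULL) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("parse error in ", path, ": need columns ", paste(need, collapse = ","))
  }
  if (is.null(subject_ids)) subject_ids <- unique(df$subject_id)
  out <- lapply(subject_ids, function(s) {
    eps <- df[df$subject_id == s, c("start_s", "end_s"), drop = FALSE]
    eps <- eps[order(eps$start_s), , drop = FALSE]
    rownames(eps) <- NULL
    structure(list(subject_id = s, episodes = eps), class = "fog_annotations")
  })
  names(out) <- subject_ids
  out
}

#' Write / read a feature table
#'
#' CSV with header `subject_id,label,start_s,<channel>__<feature>,...`.
#'
#' @param table A feature table.
#' @param path CSV path.
#' @return `write_feature_table` returns the path invisibly;
#'   `read_feature_table` the table.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(META_COLS %in% names(df))) {
    stop("parse error in ", path, ": missing metadata columns")
  }
  df
}

#' Write an evaluation result as JSON
#'
#' @param eval_result A `fog_eval`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_eval_result <- function(eval_result, path) {
  stopifnot(inherits(eval_result, "fog_eval"))
  jsonlite::write_json(
    list(
      per_fold = eval_result$per_fold,
      aggregate = eval_result$aggregate,
      config = eval_result$config
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' The round-trip is lossless for every parameter.
#'
#' @param config A [fog_config()].
#' @param path YAML path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   a `fog_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "fog_config"))
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- do.call(generator_config, x$generator)
  fog_config(
    generator = gen,
    window = x$window,
    filter = x$filter,
    selection = x$selection,
    smote = x$smote,
    model = x$model,
    channels = unlist(x$channels),
    seed = x$seed
  )
}
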