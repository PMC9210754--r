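#' Number of sliding windows in a recording
#'
#' For `l` samples at `f` Hz, window length `m` s and step `t` s, the count
#' is `floor((l/f - m)/t) + 1`, or 0 when the recording is shorter than one
#' window.
#'
#' @param l Recording length in samples.
#' @param f Sampling frequency, Hz.
#' @param m Window length, seconds.
#' @param t Step length, seconds.
#' @return Integer window count.
#' @examples
#' count_windows(1000, 100, 2, 0.5) # 17
#' @export
count_windows <- function(l, f, m, t) {
  stopifnot(t > 0, m > 0, f > 0)
  if (l / f < m) {
    return(0L)
  }
  as.integer(floor((l / f - m) / t + 1e-9) + 1)
}

#' Segment a recording into labelled sliding windows
#'
#' Windows start at 0, `t`, `2t`, ... seconds; all channels are segmented
#' with identical boundaries. A window is labelled FoG (1) iff its *start*
#' time lies inside an annotated episode, episodes taken half-open
#' `[start_s, end_s)` -- a window starting exactly at an episode's end is
#' non-FoG. The label-at-start rule reflects that human annotation of FoG
#' onset lags the physiological onset.
#'
#' @param recording A preprocessed `fog_recording` (no missing samples).
#' @param annotations A `fog_annotations` for the same subject.
#' @param m Window length, seconds.
#' @param t Step length, seconds.
#' @param channels Channel names to keep (default: all in the recording).
#' @return A `fog_window_set`: list with `data` (named list of
#'   `window_samples x n_windows` matrices), `labels` (0/1), `start_s`,
#'   `subject_id`, `sample_rate`, `window_s`, `step_s`.
#' @export
segment <- function(recording, annotations, m = 2, t = 0.5,
                    channels = names(recording$channels)) {
  stopifnot(
    inherits(recording, "fog_recording"),
    inherits(annotations, "fog_annotations")
  )
  if (any(vapply(recording$missing[channels], any, logical(1)))) {
    stop("precondition error: recording has missing samples")
  }
  fs <- recording$sample_rate
  l <- length(recording$channels[[1]])
  duration <- l / fs
  eps <- annotations$episodes
  if (nrow(eps) > 0 && (any(eps$start_s < 0) || any(eps$end_s > duration + 1e-9))) {
    stop("data error: annotations reference times beyond the recording")
  }
  n_win <- count_windows(l, fs, m, t)
  win_samples <- round(m * fs)
  starts <- (seq_len(n_win) - 1) * t
  labels <- integer(n_win)
  if (nrow(eps) > 0 && n_win > 0) {
    for (i in seq_len(nrow(eps))) {
      labels[starts >= eps$start_s[i] & starts < eps$end_s[i]] <- 1L
    }
  }
  start_idx <- round(starts * fs) + 1
  idx <- outer(seq_len(win_samples) - 1L, as.integer(start_idx), `+`)
  data <- lapply(recording$channels[channels], function(x) {
    matrix(x[idx], nrow = win_samples)
  })
  structure(
    list(
      data = data,
      labels = labels,
      start_s = starts,
      subject_id = recording$subject_id,
      sample_rate = fs,
      window_s = m,
      step_s = t
    ),
    class = "fog_window_set"
  )
}

#' @export
print.fog_window_set <- function(x, ...) {
  cat(sprintf(
    "<fog_window_set> subject %s: %d windows (%.0f%% FoG) x %d channels, %g s / step %g s @ %g Hz\n",
    x$subject_id, length(x$labels), 100 * mean(x$labels == 1),
    length(x$data), x$window_s, x$step_s, x$sample_rate
  ))
  invisible(x)
}
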