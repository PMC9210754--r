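#' Construct a recording
#'
#' Container for one subject's synchronous multichannel time series with a
#' per-channel missing-sample mask.
#'
#' @param subject_id Subject identifier.
#' @param sample_rate Sampling frequency, Hz.
#' @param channels Named list of equal-length numeric series; names must be
#'   montage channel names (see [montage()]).
#' @param missing Optional named list of logical masks (`TRUE` = sample
#'   absent), parallel to `channels`; defaults to no missing samples.
#' @return Object of class `fog_recording`.
#' @export
fog_recording <- function(subject_id, sample_rate, channels, missing = NULL) {
  stopifnot(is.list(channels), length(channels) > 0, sample_rate > 0)
  known <- montage()$channel
  bad <- setdiff(names(channels), known)
  if (length(bad) > 0) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all channel series must share one length")
  }
  if (is.null(missing)) {
    missing <- lapply(channels, function(x) rep(FALSE, length(x)))
  }
  stopifnot(
    identical(names(missing), names(channels)),
    all(vapply(missing, length, integer(1)) == lens[1])
  )
  structure(
    list(
      subject_id = subject_id, sample_rate = sample_rate,
      channels = channels, missing = missing
    ),
    class = "fog_recording"
  )
}

#' Construct an annotation track
#'
#' Non-overlapping, sorted FoG episode intervals for one subject, in seconds.
#' Intervals are half-open `[start_s, end_s)` throughout the package.
#'
#' @param subject_id Subject identifier.
#' @param start_s,end_s Episode boundaries, seconds.
#' @return Object of class `fog_annotations`.
#' @export
fog_annotations <- function(subject_id, start_s = numeric(0), end_s = numeric(0)) {
  stopifnot(length(start_s) == length(end_s))
  ord <- order(start_s)
  start_s <- start_s[ord]
  end_s <- end_s[ord]
  if (any(end_s <= start_s)) stop("episodes must have end_s > start_s")
  if (length(start_s) > 1 && any(start_s[-1] < end_s[-length(end_s)])) {
    stop("episodes must be pairwise non-overlapping")
  }
  structure(
    list(
      subject_id = subject_id,
      episodes = data.frame(start_s = start_s, end_s = end_s)
    ),
    class = "fog_annotations"
  )
}
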