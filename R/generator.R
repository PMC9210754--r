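# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject / per-stage seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1009 + as.numeric(p) * 7919 + 97) %% 2147483647
  as.integer(h)
}

#' Synthetic cohort generator configuration
#'
#' Defaults describe a 12-subject cohort (10 freezers, 2 non-freezers)
#' recorded at 100 Hz for 755 s per subject (about 2.5 h in total). Walking
#' carries a locomotor oscillation with fundamental in `step_freq_range` plus
#' one harmonic; freezing-of-gait (FoG) episodes superimpose a trembling-band
#' component while attenuating the locomotor component by
#' `fog_amplitude_ratio`. Episode durations are lognormal
#' (`episode_duration_lognormal = c(meanlog, sdlog)`), truncated to
#' `episode_duration_range`; the defaults give mean 8.1 s, sd 9.3 s and a
#' median below 6 s. Episodes arrive at `episode_rate` per minute among
#' freezers with exponential walking gaps in between. Short transmission
#' dropouts are emulated by [inject_gaps()] at `gap_rate` gaps per second
#' with lengths (in samples) uniform over `gap_length_range`.
#'
#' @param n_subjects Number of subjects.
#' @param n_freezers Number of subjects that exhibit FoG episodes
#'   (the first `n_freezers` subject indices).
#' @param sample_rate Sampling frequency in Hz.
#' @param recording_length Seconds of signal per subject.
#' @param step_freq_range Locomotor (step) fundamental frequency interval, Hz.
#' @param tremble_freq_range FoG trembling frequency interval, Hz.
#' @param fog_amplitude_ratio Attenuation of the locomotor component during
#'   FoG (0 = fully suppressed, 1 = unchanged).
#' @param episode_duration_lognormal `c(meanlog, sdlog)` of episode durations.
#' @param episode_duration_range Truncation interval for durations, seconds.
#' @param episode_rate Episodes per minute for freezer subjects.
#' @param gap_rate Expected missing-data gaps per second per channel.
#' @param gap_length_range Integer range of gap lengths, samples.
#' @param noise_sd Additive Gaussian noise level in units of each sensor's
#'   intrinsic scale (g for accelerometers, dps for gyroscopes, load units
#'   for FSRs).
#' @param seed Integer seed; all generated data are a pure function of
#'   `(seed, subject_index)`.
#' @return An object of class `fog_generator_config`.
#' @export
generator_config <- function(n_subjects = 12,
                             n_freezers = 10,
                             sample_rate = 100,
                             recording_length = 755,
                             step_freq_range = c(1.5, 2.5),
                             tremble_freq_range = c(4, 7),
                             fog_amplitude_ratio = 0.3,
                             episode_duration_lognormal = c(1.672, 0.917),
                             episode_duration_range = c(0.9, 76.9),
                             episode_rate = 2.2,
                             gap_rate = 0.02,
                             gap_length_range = c(5, 50),
                             noise_sd = 0.05,
                             seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_freezers = as.integer(n_freezers),
    sample_rate = sample_rate,
    recording_length = recording_length,
    step_freq_range = step_freq_range,
    tremble_freq_range = tremble_freq_range,
    fog_amplitude_ratio = fog_amplitude_ratio,
    episode_duration_lognormal = episode_duration_lognormal,
    episode_duration_range = episode_duration_range,
    episode_rate = episode_rate,
    gap_rate = gap_rate,
    gap_length_range = as.integer(gap_length_range),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "fog_generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1,
    cfg$n_freezers >= 0,
    cfg$sample_rate > 0,
    cfg$recording_length > 0,
    cfg$episode_rate >= 0,
    cfg$gap_rate >= 0,
    cfg$noise_sd >= 0,
    cfg$fog_amplitude_ratio >= 0, cfg$fog_amplitude_ratio <= 1
  )
  if (cfg$n_freezers > cfg$n_subjects) {
    stop("configuration error: n_freezers exceeds n_subjects")
  }
  for (rng in list(
    cfg$step_freq_range, cfg$tremble_freq_range,
    cfg$episode_duration_range, cfg$gap_length_range
  )) {
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      stop("configuration error: invalid (empty or non-finite) range")
    }
  }
  # Nyquist: the generator must not place components above sample_rate / 2.
  max_freq <- max(cfg$tremble_freq_range[2], 2 * cfg$step_freq_range[2])
  if (cfg$sample_rate <= 2 * max_freq) {
    stop("configuration error: sample_rate must exceed twice the highest generated frequency")
  }
  invisible(cfg)
}

# Per-site locomotor amplitudes (in each sensor's intrinsic unit scale).
# Leg sensors carry the largest gait signal so that leg channels are the
# most informative, mirroring where FoG detection works best in practice.
site_amplitude <- function(location) {
  base <- c(
    waist = 0.5, left_thigh = 0.9, right_thigh = 0.9,
    left_shank = 1.0, right_shank = 1.0,
    left_foot = 0.7, right_foot = 0.7
  )
  if (location %in% names(base)) base[[location]] else 1.0 # soles
}

sensor_unit_scale <- function(sensor) {
  switch(sensor, accelerometer = 1, gyroscope = 100, fsr = 1)
}

axis_multiplier <- function(axis) {
  switch(axis, x = 1, y = 0.7, z = 0.5, none = 1)
}

#' Sample truncated-lognormal FoG episode durations
#'
#' Rejection-samples the configured lognormal, truncated to
#' `config$episode_duration_range`.
#'
#' @param n Number of durations.
#' @param config A [generator_config()].
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Numeric vector of durations in seconds.
#' @export
sample_episode_durations <- function(n, config = generator_config(), seed = NULL) {
  draw <- function() {
    mu <- config$episode_duration_lognormal[1]
    sg <- config$episode_duration_lognormal[2]
    lo <- config$episode_duration_range[1]
    hi <- config$episode_duration_range[2]
    out <- numeric(0)
    while (length(out) < n) {
      d <- stats::rlnorm(n, meanlog = mu, sdlog = sg)
      out <- c(out, d[d >= lo & d <= hi])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Closed-form mean of the truncated lognormal episode-duration law.
truncated_lognormal_mean <- function(meanlog, sdlog, lower, upper) {
  a <- (log(lower) - meanlog) / sdlog
  b <- (log(upper) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Alternating walk / FoG schedule: exponential walking gaps (memoryless),
# truncated-lognormal episode durations; first and last ~2 s are always walk.
place_episodes <- function(config) {
  rate_s <- config$episode_rate / 60
  len <- config$recording_length
  episodes <- matrix(numeric(0), ncol = 2)
  if (rate_s <= 0) {
    return(episodes)
  }
  mean_dur <- truncated_lognormal_mean(
    config$episode_duration_lognormal[1], config$episode_duration_lognormal[2],
    config$episode_duration_range[1], config$episode_duration_range[2]
  )
  # Walking gaps sized so that episodes arrive at episode_rate per minute.
  gap_mean <- max(60 / config$episode_rate - mean_dur, 2)
  t <- max(2, stats::rexp(1, 1 / gap_mean))
  repeat {
    d <- sample_episode_durations(1, config)
    if (t + d > len - 2) break
    episodes <- rbind(episodes, c(t, t + d))
    t <- t + d + 2 + stats::rexp(1, 1 / gap_mean)
  }
  episodes
}

#' Simulate one subject's multi-sensor gait recording
#'
#' IMU channels carry a locomotor oscillation (subject-specific step
#' fundamental plus one harmonic at twice the frequency) during walking;
#' during FoG episodes the locomotor component is attenuated by
#' `fog_amplitude_ratio` and an additive trembling-band sinusoid (one
#' frequency per episode) appears. FSR channels carry a periodic
#' half-rectified loading pattern during walking and a near-constant load
#' during FoG. Gaussian noise is added everywhere. Only freezer subjects
#' (`subject_index <= n_freezers`) receive episodes, and the returned
#' annotations are exactly the generated FoG segments.
#'
#' @param config A [generator_config()].
#' @param subject_index Subject number, `1..n_subjects`.
#' @return A list with elements `recording` (class `fog_recording`: fields
#'   `subject_id`, `sample_rate`, `channels` -- a named list of numeric
#'   series -- and `missing` -- parallel logical masks, all `FALSE` here) and
#'   `annotations` (class `fog_annotations`: `subject_id` and an `episodes`
#'   data frame with `start_s`, `end_s`).
#' @export
simulate_subject <- function(config, subject_index) {
  validate_generator_config(config)
  stopifnot(subject_index >= 1, subject_index <= config$n_subjects)
  with_seed(derive_seed(config$seed, subject_index), {
    fs <- config$sample_rate
    n <- round(config$recording_length * fs)
    tt <- (seq_len(n) - 1) / fs
    subject_id <- sprintf("S%02d", subject_index)
    freezer <- subject_index <= config$n_freezers

    episodes <- if (freezer) place_episodes(config) else matrix(numeric(0), ncol = 2)
    fog <- rep(FALSE, n)
    ep_freqs <- numeric(nrow(episodes))
    if (nrow(episodes) > 0) {
      ep_freqs <- stats::runif(
        nrow(episodes),
        config$tremble_freq_range[1], config$tremble_freq_range[2]
      )
      for (i in seq_len(nrow(episodes))) {
        fog <- fog | (tt >= episodes[i, 1] & tt < episodes[i, 2])
      }
    }

    f_step <- stats::runif(1, config$step_freq_range[1], config$step_freq_range[2])
    m <- montage()
    channels <- vector("list", nrow(m))
    names(channels) <- m$channel
    walk_gain <- ifelse(fog, config$fog_amplitude_ratio, 1)

    for (ci in seq_len(nrow(m))) {
      loc <- m$location[ci]
      sen <- m$sensor[ci]
      amp <- site_amplitude(loc) * sensor_unit_scale(sen) * axis_multiplier(m$axis[ci])
      noise <- stats::rnorm(n, sd = config$noise_sd * sensor_unit_scale(sen))
      if (sen == "fsr") {
        phase <- stats::runif(1, 0, 2 * pi)
        walk_load <- 0.5 + amp * pmax(0, sin(2 * pi * f_step * tt + phase))
        hold_load <- 0.5 + 0.5 * amp # feet planted: near-constant load
        x <- ifelse(fog, hold_load, walk_load) + noise
      } else {
        ph <- stats::runif(3, 0, 2 * pi)
        loco <- amp * (sin(2 * pi * f_step * tt + ph[1]) +
          0.3 * sin(4 * pi * f_step * tt + ph[2]))
        tremble <- numeric(n)
        if (nrow(episodes) > 0) {
          for (i in seq_len(nrow(episodes))) {
            idx <- tt >= episodes[i, 1] & tt < episodes[i, 2]
            tremble[idx] <- 0.8 * amp * sin(2 * pi * ep_freqs[i] * tt[idx] + ph[3])
          }
        }
        x <- loco * walk_gain + tremble + noise
      }
      channels[[ci]] <- x
    }

    recording <- structure(
      list(
        subject_id = subject_id,
        sample_rate = fs,
        channels = channels,
        missing = lapply(channels, function(x) rep(FALSE, length(x)))
      ),
      class = "fog_recording"
    )
    annotations <- structure(
      list(
        subject_id = subject_id,
        episodes = data.frame(
          start_s = episodes[, 1],
          end_s = episodes[, 2]
        )[order(episodes[, 1]), , drop = FALSE]
      ),
      class = "fog_annotations"
    )
    list(recording = recording, annotations = annotations)
  })
}

#' Simulate a full cohort
#'
#' Generates `n_subjects` recordings with unique subject ids; the first
#' `n_freezers` subjects carry FoG episodes. When `gap_rate > 0`, missing-data
#' dropouts are injected via [inject_gaps()].
#'
#' @param config A [generator_config()].
#' @return A list of `n_subjects` elements, each a list with `recording` and
#'   `annotations` (see [simulate_subject()]).
#' @export
simulate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  lapply(seq_len(config$n_subjects), function(i) {
    s <- simulate_subject(config, i)
    if (config$gap_rate > 0) {
      s$recording <- inject_gaps(s$recording, config)
    }
    s
  })
}

#' Inject short missing-data gaps into a recording
#'
#' Marks contiguous runs of samples as missing in each channel's mask,
#' emulating transient transmission dropouts. Gap counts per channel are
#' Poisson with mean `gap_rate * duration`; lengths are uniform over
#' `gap_length_range` (samples). The first and last sample of a channel are
#' never masked, so linear interpolation is always interior. Deterministic
#' given `(config$seed, subject_id)`.
#'
#' @param recording A `fog_recording`.
#' @param config A [generator_config()].
#' @return The recording with an updated `missing` mask (signal values are
#'   left in place; readers/writers treat masked samples as absent).
#' @export
inject_gaps <- function(recording, config) {
  stopifnot(inherits(recording, "fog_recording"), config$gap_rate >= 0)
  n <- length(recording$channels[[1]])
  if (max(config$gap_length_range) >= n - 1) {
    stop("configuration error: gap longer than the recording")
  }
  if (config$gap_rate == 0) {
    return(recording)
  }
  duration <- n / recording$sample_rate
  with_seed(derive_seed(config$seed, sum(utf8ToInt(recording$subject_id)), 5), {
    for (ch in names(recording$channels)) {
      mask <- recording$missing[[ch]]
      n_gaps <- stats::rpois(1, config$gap_rate * duration)
      if (n_gaps > 0) {
        span <- config$gap_length_range[2] - config$gap_length_range[1] + 1L
        lens <- config$gap_length_range[1] + sample.int(span, n_gaps, replace = TRUE) - 1L
        for (g in seq_len(n_gaps)) {
          start <- 1L + sample.int(n - lens[g] - 1L, 1) # in [2, n - len]
          mask[start:(start + lens[g] - 1L)] <- TRUE
        }
        mask[c(1, n)] <- FALSE
      }
      recording$missing[[ch]] <- mask
    }
    recording
  })
}

#' @export
print.fog_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf(
    "<fog_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %.2f%% missing\n",
    x$subject_id, length(x$channels), n, x$sample_rate, n / x$sample_rate,
    100 * mean(unlist(x$missing))
  ))
  invisible(x)
}

#' @export
print.fog_annotations <- function(x, ...) {
  cat(sprintf(
    "<fog_annotations> subject %s: %d FoG episode(s), total %.1f s\n",
    x$subject_id, nrow(x$episodes),
    sum(x$episodes$end_s - x$episodes$start_s)
  ))
  invisible(x)
}
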