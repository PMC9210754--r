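# Independent oracles and small fixture builders used across the suite.

# Brute-force DFT band power by direct summation (no fft): sum over bins
# whose aliased frequency lies in [lo, hi] (closure configurable), divided
# by n -- the same normalisation band_power() documents.
dft_band_power_oracle <- function(x, lo, hi, f,
                                  lower_inclusive = TRUE,
                                  upper_inclusive = TRUE) {
  n <- length(x)
  total <- 0
  for (k in 0:(n - 1)) {
    fk <- min(k, n - k) * f / n
    in_lo <- if (lower_inclusive) fk >= lo else fk > lo
    in_hi <- if (upper_inclusive) fk <= hi else fk < hi
    if (in_lo && in_hi) {
      re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
      total <- total + (re^2 + im^2) / n
    }
  }
  total
}

# Textbook one-way ANOVA F by direct summation over classes.
anova_f_oracle <- function(values, labels) {
  labs <- unique(labels)
  grand <- sum(values) / length(values)
  ss_b <- 0
  ss_w <- 0
  for (l in labs) {
    g <- values[labels == l]
    gm <- sum(g) / length(g)
    ss_b <- ss_b + length(g) * (gm - grand)^2
    ss_w <- ss_w + sum((g - gm)^2)
  }
  (ss_b / (length(labs) - 1)) / (ss_w / (length(values) - length(labs)))
}

# One-channel recording fixture on the left shank gyroscope x axis.
make_recording <- function(x, fs = 100, subject_id = "T01",
                           channel = "left_shank_gyroscope_x",
                           missing = NULL) {
  chans <- stats::setNames(list(x), channel)
  miss <- if (is.null(missing)) NULL else stats::setNames(list(missing), channel)
  fog_recording(subject_id, fs, chans, miss)
}

no_episodes <- function(subject_id = "T01") fog_annotations(subject_id)

# Filter a bare numeric vector through bandpass() via a one-channel recording.
fir_apply_test <- function(x, co) {
  bandpass(make_recording(x), co)$channels[[1]]
}

# Toy feature table: n rows per subject, one informative column (equal to
# the label plus small noise) and `n_noise` pure-noise columns.
make_toy_table <- function(n_per_subject = 40, subjects = c("A", "B", "C"),
                           n_noise = 3, seed = 42, signal_sd = 0.1) {
  set.seed(seed)
  rows <- lapply(subjects, function(s) {
    label <- rep(c(0L, 1L), length.out = n_per_subject)
    df <- data.frame(
      subject_id = s,
      label = label,
      start_s = seq(0, by = 0.5, length.out = n_per_subject)
    )
    df$ch1__signal <- label + rnorm(n_per_subject, sd = signal_sd)
    for (j in seq_len(n_noise)) {
      df[[paste0("ch1__noise", j)]] <- rnorm(n_per_subject)
    }
    df
  })
  do.call(rbind, rows)
}

# Small imbalanced two-class table (no subject structure needed).
make_imbalanced_table <- function(n_min = 100, n_maj = 400, p = 4, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    subject_id = rep(c("A", "B"), length.out = n_min + n_maj),
    label = c(rep(1L, n_min), rep(0L, n_maj)),
    start_s = seq(0, by = 0.5, length.out = n_min + n_maj)
  )
  for (j in seq_len(p)) {
    df[[paste0("ch__f", j)]] <- c(rnorm(n_min, mean = 1), rnorm(n_maj))
  }
  df
}
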