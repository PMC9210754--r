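# The 13 per-channel window features, in canonical order.
FEATURE_NAMES <- c(
  "fi", "energy", "sum_power", "mean", "abs_mean", "zcr", "sd",
  "range", "rms", "max", "min", "pde", "entropy"
)

# Columns of a feature table that are not features.
META_COLS <- c("subject_id", "label", "start_s")

#' Feature column names of a feature table
#' @param table A feature table (data frame from [compute_features()]).
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) setdiff(names(table), META_COLS)

#' Spectral power of a window in a frequency band
#'
#' Power is the sum of squared DFT magnitudes over the bins whose frequency
#' lies in `band`, counting positive and negative frequency bins, divided by
#' the window length. The DC bin is excluded unless the band includes 0.
#' Summed over all of `(0, f/2]` plus the DC term this equals the signal
#' energy `sum(x^2)` (Parseval).
#'
#' @param window Numeric vector (one channel, one window).
#' @param band `c(low, high)` in Hz, inside `(0, f/2]`.
#' @param f Sampling frequency, Hz.
#' @param lower_inclusive,upper_inclusive Closure of the band edges. The
#'   freeze zone is the closed `[3, 8]` Hz; the motion zone `[0.5, 3)` Hz is
#'   half-open at 3 Hz so that the two zones partition the spectrum there.
#' @return Non-negative scalar.
#' @export
band_power <- function(window, band, f,
                       lower_inclusive = TRUE, upper_inclusive = TRUE) {
  n <- length(window)
  stopifnot(n >= 2)
  if (band[1] <= 0 || band[2] > f / 2 || band[1] >= band[2]) {
    stop("argument error: band must lie inside (0, f/2]")
  }
  p <- Mod(stats::fft(window))^2 / n
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) * f / n # alias each bin to its absolute frequency
  lo <- if (lower_inclusive) fk >= band[1] else fk > band[1]
  hi <- if (upper_inclusive) fk <= band[2] else fk < band[2]
  sum(p[lo & hi])
}

# Frequency-zone powers for a matrix of windows (win_samples x n_windows).
# Returns list(motion, freeze, total) with motion = [0.5, 3) Hz,
# freeze = [3, 8] Hz, total = full DFT energy sum(|X_k|^2).
zone_powers <- function(W, f) {
  n <- nrow(W)
  P <- Mod(stats::mvfft(W))^2 / n
  k <- 0:(n - 1)
  fk <- pmin(k, n - k) * f / n
  motion <- colSums(P[fk >= 0.5 & fk < 3, , drop = FALSE])
  freeze <- colSums(P[fk >= 3 & fk <= 8, , drop = FALSE])
  list(motion = motion, freeze = freeze, energy = n * colSums(P))
}

# Shannon entropy (nats) of the 16-bin amplitude histogram of each column.
window_entropy <- function(W, bins = 16) {
  apply(W, 2, function(x) {
    lo <- min(x)
    hi <- max(x)
    if (hi <= lo) {
      return(0) # constant window: single occupied bin
    }
    cnt <- tabulate(pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1), bins)
    p <- cnt / length(x)
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

# Zero-crossing count per column; a zero sample inherits the sign of the
# previous nonzero sample, so flat touches of zero are not double-counted.
zero_crossings <- function(W) {
  s <- sign(W)
  for (i in 2:nrow(s)) {
    z <- s[i, ] == 0
    if (any(z)) s[i, z] <- s[i - 1, z]
  }
  colSums(s[-1, , drop = FALSE] * s[-nrow(s), , drop = FALSE] < 0)
}

# Eigenvalues (descending) of the within-window covariance of a sensor's
# axes. W_list is a list of 1..3 matrices (win_samples x n_windows), one per
# axis; returns a matrix n_axes x n_windows. Closed-form symmetric 2x2/3x3
# solutions, vectorised over windows.
group_cov_eigenvalues <- function(W_list) {
  d <- length(W_list)
  n <- nrow(W_list[[1]])
  mu <- lapply(W_list, colMeans)
  cmom <- function(a, b) colMeans(W_list[[a]] * W_list[[b]]) - mu[[a]] * mu[[b]]
  if (d == 1) {
    return(matrix(pmax(cmom(1, 1), 0), nrow = 1))
  }
  if (d == 2) {
    a <- cmom(1, 1)
    b <- cmom(2, 2)
    c2 <- cmom(1, 2)
    tr <- a + b
    disc <- sqrt(pmax((a - b)^2 / 4 + c2^2, 0))
    return(rbind(tr / 2 + disc, tr / 2 - disc))
  }
  # 3x3: trigonometric closed form for symmetric matrices
  a11 <- cmom(1, 1)
  a22 <- cmom(2, 2)
  a33 <- cmom(3, 3)
  a12 <- cmom(1, 2)
  a13 <- cmom(1, 3)
  a23 <- cmom(2, 3)
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q
  b22 <- a22 - q
  b33 <- a33 - q
  p2 <- (b11^2 + b22^2 + b33^2) / 6 + (a12^2 + a13^2 + a23^2) / 3
  p <- sqrt(pmax(p2, 0))
  # det(B) for symmetric B with off-diagonals of A
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  rbind(e1, e2, e3)
}

#' Compute the 13 features for every window and channel
#'
#' Per (window, channel): freeze index FI (freeze-zone `[3,8]` Hz power over
#' motion-zone `[0.5,3)` Hz power, denominator guarded by `1e-12`), DFT
#' energy, sum power (freeze + motion zone), mean, absolute mean,
#' zero-crossing rate, standard deviation (population), range, RMS, maximum,
#' minimum, principal-direction eigenvalue, and Shannon entropy of the
#' 16-bin amplitude histogram (nats).
#'
#' The principal-direction eigenvalues are those of a sensor's within-window
#' covariance across its axes (3x3 for a triaxial sensor), sorted descending
#' and assigned to the axes in montage order, so each axis column carries one
#' eigenvalue; FSR channels use their scalar variance.
#'
#' Column order is deterministic: channels in montage order, the 13 features
#' per channel in the order above; names are `<channel>__<feature>`.
#'
#' @param ws A `fog_window_set`.
#' @param channels Channel subset (default: all channels in `ws`).
#' @return A feature table: data frame with `subject_id`, `label`, `start_s`,
#'   then `13 * length(channels)` feature columns (624 for the full montage).
#' @export
compute_features <- function(ws, channels = names(ws$data)) {
  stopifnot(inherits(ws, "fog_window_set"), length(channels) > 0)
  missing_ch <- setdiff(channels, names(ws$data))
  if (length(missing_ch) > 0) {
    stop("channels not present in window set: ", paste(missing_ch, collapse = ", "))
  }
  m <- montage()
  channels <- m$channel[m$channel %in% channels] # montage order
  n_win <- length(ws$labels)
  fs <- ws$sample_rate

  # principal-direction eigenvalues, grouped by (location, sensor)
  minfo <- m[match(channels, m$channel), ]
  pde <- matrix(NA_real_, nrow = n_win, ncol = length(channels))
  groups <- split(seq_along(channels), paste(minfo$location, minfo$sensor))
  for (g in groups) {
    ev <- group_cov_eigenvalues(ws$data[channels[g]])
    for (j in seq_along(g)) pde[, g[j]] <- ev[j, ]
  }

  cols <- vector("list", length(channels) * length(FEATURE_NAMES))
  cn <- character(length(cols))
  for (ci in seq_along(channels)) {
    W <- ws$data[[channels[ci]]]
    zp <- zone_powers(W, fs)
    mean_w <- colMeans(W)
    msq <- colMeans(W^2)
    mx <- apply(W, 2, max)
    mn <- apply(W, 2, min)
    vals <- list(
      fi = zp$freeze / (zp$motion + 1e-12),
      energy = zp$energy,
      sum_power = zp$freeze + zp$motion,
      mean = mean_w,
      abs_mean = colMeans(abs(W)),
      zcr = zero_crossings(W),
      sd = sqrt(pmax(msq - mean_w^2, 0)),
      range = mx - mn,
      rms = sqrt(msq),
      max = mx,
      min = mn,
      pde = pde[, ci],
      entropy = window_entropy(W)
    )
    for (fi in seq_along(FEATURE_NAMES)) {
      k <- (ci - 1) * length(FEATURE_NAMES) + fi
      cols[[k]] <- as.numeric(vals[[FEATURE_NAMES[fi]]])
      cn[k] <- paste0(channels[ci], "__", FEATURE_NAMES[fi])
    }
  }
  out <- data.frame(
    subject_id = rep(ws$subject_id, n_win),
    label = ws$labels,
    start_s = ws$start_s,
    stringsAsFactors = FALSE
  )
  out[cn] <- cols
  out
}

#' Fit a min-max normalisation model
#'
#' Records each feature's min and max over the training rows. Fit on
#' training folds only: fitting on all data would leak test information.
#'
#' @param train A feature table.
#' @return Object of class `fog_minmax` (per-feature `min`, `max`).
#' @export
fit_minmax <- function(train) {
  fc <- feature_cols(train)
  stopifnot(nrow(train) > 0, length(fc) > 0)
  structure(
    list(
      features = fc,
      min = vapply(train[fc], min, numeric(1)),
      max = vapply(train[fc], max, numeric(1))
    ),
    class = "fog_minmax"
  )
}

#' Apply a min-max normalisation model
#'
#' Maps `v` to `(v - min) / (max - min)`. A feature constant in training
#' (`max == min`) maps every value to 0. Values outside the training range
#' fall outside `[0, 1]` and are deliberately not clipped.
#'
#' @param model A `fog_minmax`.
#' @param table A feature table with the same feature columns.
#' @return The normalised table.
#' @export
apply_minmax <- function(model, table) {
  stopifnot(inherits(model, "fog_minmax"))
  if (!setequal(model$features, feature_cols(table))) {
    stop("schema error: feature columns do not match the normalisation model")
  }
  for (f in model$features) {
    span <- model$max[[f]] - model$min[[f]]
    table[[f]] <- if (span > 0) (table[[f]] - model$min[[f]]) / span else 0
  }
  table
}
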