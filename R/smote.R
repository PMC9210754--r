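#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbours (default 5).
#' @param target_ratio Minority:majority ratio after balancing, in `(0, 1]`.
#' @param seed Integer seed for neighbour choice and interpolation draws.
#' @return Object of class `fog_smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1, seed = 1) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(
    list(
      k_neighbors = as.integer(k_neighbors),
      target_ratio = target_ratio,
      seed = as.integer(seed)
    ),
    class = "fog_smote_config"
  )
}

#' Oversample the minority class by SMOTE
#'
#' For each minority sample `x_i`, its `k` nearest minority neighbours by
#' Euclidean distance are found and synthetic rows are drawn on the segments
#' `x_i + u (x_ij - x_i)` with `u ~ Uniform(0, 1)`, until the minority count
#' reaches `target_ratio` times the majority count. When the required count
#' is not a multiple of the minority size, the remainder's parent points are
#' sampled without replacement. Original rows are preserved unchanged and
#' come first; synthetic rows carry the minority label and the `subject_id`
#' of their parent `x_i` (so subject-wise leakage audits still work).
#' Applies to training data only -- never balance test rows.
#'
#' @param train A feature table (normalise first: neighbours are Euclidean).
#' @param config A [smote_config()].
#' @return The balanced feature table.
#' @export
smote <- function(train, config = smote_config()) {
  stopifnot(inherits(config, "fog_smote_config"))
  fc <- feature_cols(train)
  counts <- table(train$label)
  if (length(counts) < 2) stop("data error: training data has a single class")
  minority_label <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min == 0) stop("data error: empty minority class")
  need <- round(config$target_ratio * n_maj) - n_min
  if (need <= 0) {
    return(train)
  }

  min_idx <- which(train$label == minority_label)
  X <- as.matrix(train[min_idx, fc, drop = FALSE])
  k <- config$k_neighbors
  if (n_min <= k) {
    k <- max(n_min - 1L, 0L)
    warning(
      "minority class has <= k_neighbors samples; falling back to k = ", k
    )
  }

  # k nearest minority neighbours of each minority row (self excluded)
  if (k >= 1) {
    sq <- rowSums(X^2)
    d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }

  with_seed(config$seed, {
    base <- need %/% n_min
    rem <- need %% n_min
    parents <- c(
      rep(seq_len(n_min), base),
      if (rem > 0) sample(seq_len(n_min), rem, replace = FALSE)
    )
    if (k >= 1) {
      nb_pick <- nn[cbind(parents, sample.int(k, length(parents), replace = TRUE))]
    } else {
      nb_pick <- parents # single minority point: segments of length zero
    }
    u <- stats::runif(length(parents))
    synth <- X[parents, , drop = FALSE] +
      u * (X[nb_pick, , drop = FALSE] - X[parents, , drop = FALSE])

    new_rows <- train[min_idx[parents], , drop = FALSE]
    new_rows[, fc] <- synth
    new_rows$label <- train$label[min_idx[1]]
    rownames(new_rows) <- NULL
    out <- rbind(train, new_rows)
    rownames(out) <- NULL
    out
  })
}
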