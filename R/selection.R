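#' One-way ANOVA F statistic for a single feature
#'
#' `F = [SS_b/(M-1)] / [SS_w/(N-M)]` with `SS_b = sum_i N_i (xbar_i - xbar)^2`
#' and `SS_w = sum_i sum_j (x_ij - xbar_i)^2`, for `M` classes and `N` total
#' samples. A larger F means a larger between-class mean difference relative
#' to within-class spread, hence a more discriminative feature. When
#' `SS_w = 0` (perfect within-class constancy) the statistic is `+Inf`, which
#' ranks above every finite score.
#'
#' @param values Numeric vector.
#' @param labels Class labels (any atomic type), same length.
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' anova_f(c(1, 2, 3, 2, 3, 4), c(0, 0, 0, 1, 1, 1)) # 1.5
#' @export
anova_f <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  groups <- split(values, labels)
  M <- length(groups)
  if (M < 2) stop("argument error: need at least two classes")
  N <- length(values)
  if (N - M < 1) stop("argument error: need at least one within-class degree of freedom")
  grand <- mean(values)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ss_w == 0) {
    return(if (ss_b == 0) 0 else Inf)
  }
  (ss_b / (M - 1)) / (ss_w / (N - M))
}

#' Mutual information between a feature and the class label
#'
#' Plug-in estimate `I(X, Y) = H(Y) - H(Y|X)` (natural-log entropies) after
#' discretising the continuous feature into `n_bins` quantile bins.
#' Quantile binning makes the estimate invariant to strictly monotone
#' transformations of the feature and robust to scale and outliers.
#' Tiny negative values from finite-sample noise are clamped to 0.
#'
#' @param values Numeric vector.
#' @param labels Class labels, same length.
#' @param n_bins Number of quantile bins (>= 2).
#' @return Non-negative scalar (nats); at most `H(Y)`.
#' @export
mutual_info <- function(values, labels, n_bins = 10) {
  stopifnot(length(values) == length(labels))
  if (n_bins < 2) stop("argument error: n_bins must be >= 2")
  if (length(unique(labels)) < 2) stop("argument error: labels are degenerate")
  br <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
    names = FALSE, type = 7
  ))
  if (length(br) < 2) {
    return(0) # constant feature carries no information
  }
  x <- cut(values, breaks = br, include.lowest = TRUE)
  joint <- table(x, labels)
  p <- joint / sum(joint)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  i <- ent(rowSums(p)) + ent(colSums(p)) - ent(p)
  if (i < 0 && i > -1e-12) i <- 0
  max(i, 0)
}

#' Rank all features of a table by a filter criterion
#'
#' Scores every feature column by ANOVA F or mutual information against the
#' binary window label and sorts descending; ties (including ties at `+Inf`)
#' are broken by column order, so the ranking is deterministic.
#'
#' @param table A feature table (normalised; see [fit_minmax()]).
#' @param method `"anova"` or `"mi"`.
#' @param n_bins Quantile bins for the MI estimator.
#' @return Data frame `feature_id`, `method`, `score`, `rank` (1 = best),
#'   ordered by rank.
#' @export
rank_features <- function(table, method = c("anova", "mi"), n_bins = 10) {
  method <- match.arg(method)
  fc <- feature_cols(table)
  if (nrow(table) == 0 || length(fc) == 0) {
    stop("argument error: empty feature table")
  }
  labels <- table$label
  scores <- vapply(fc, function(f) {
    if (method == "anova") {
      anova_f(table[[f]], labels)
    } else {
      mutual_info(table[[f]], labels, n_bins = n_bins)
    }
  }, numeric(1))
  ord <- order(-scores, seq_along(scores)) # stable: column order breaks ties
  data.frame(
    feature_id = fc[ord],
    method = method,
    score = scores[ord],
    rank = seq_along(ord),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Top-k feature-count sweep
#'
#' For each `k`, evaluates the full leave-one-subject-out pipeline restricted
#' to the top-`k` features (ranked inside each training fold) and reports
#' pooled metrics plus fold-wise mean and standard deviation, reproducing
#' the feature-count experiments' design.
#'
#' @param table An (unnormalised) feature table for the chosen channels.
#' @param method Ranking method, `"anova"` or `"mi"`.
#' @param ks Integer vector of feature counts.
#' @param ... Passed on to [loso_evaluate()] (e.g. `n_trees`, `seed`).
#' @return Data frame with one row per `k`: pooled sensitivity, specificity,
#'   accuracy, precision, f_score, and fold-wise `*_mean` / `*_sd` columns.
#' @export
topk_sweep <- function(table, method = c("anova", "mi"), ks, ...) {
  method <- match.arg(method)
  nf <- length(feature_cols(table))
  if (any(ks > nf)) stop("argument error: k exceeds the number of features")
  rows <- lapply(ks, function(k) {
    res <- tryCatch(
      loso_evaluate(table, method = method, k = k, ...),
      error = function(e) stop("top-k sweep failed at k = ", k, ": ", conditionMessage(e))
    )
    agg <- res$aggregate
    data.frame(
      k = k,
      sensitivity = agg$metrics$sensitivity,
      specificity = agg$metrics$specificity,
      accuracy = agg$metrics$accuracy,
      precision = agg$metrics$precision,
      f_score = agg$metrics$f_score,
      sensitivity_mean = agg$fold_mean[["sensitivity"]],
      sensitivity_sd = agg$fold_sd[["sensitivity"]],
      specificity_mean = agg$fold_mean[["specificity"]],
      specificity_sd = agg$fold_sd[["specificity"]],
      accuracy_mean = agg$fold_mean[["accuracy"]],
      accuracy_sd = agg$fold_sd[["accuracy"]]
    )
  })
  do.call(rbind, rows)
}
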