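#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test rows are all of that subject's
#' windows, the training rows all other subjects'. Folds are ordered by
#' subject id, and every row appears in exactly one test set.
#'
#' @param table A feature table.
#' @return List of folds, each `list(subject, train, test)` with row indices.
#' @export
loso_splits <- function(table) {
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2) {
    stop("argument error: leave-one-subject-out needs at least two subjects")
  }
  lapply(subjects, function(s) {
    test <- which(table$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(table)), test), test = test)
  })
}

#' Train the random-forest window classifier
#'
#' An ensemble of `n_trees` fully grown (unpruned) decision trees with
#' bootstrap resampling and `sqrt(p)` feature subsampling per split;
#' prediction is the majority vote over trees, with an exact tie (possible
#' because the ensemble is even-sized) resolved deterministically toward the
#' FoG class -- the conservative choice for a screening tool. Backed by
#' `ranger`. Train on balanced, normalised data.
#'
#' @param train A feature table with both classes present.
#' @param n_trees Number of trees (default 10).
#' @param seed Integer seed; same data and seed give identical predictions.
#' @return Object of class `fog_rf`.
#' @export
train_classifier <- function(train, n_trees = 10, seed = 1) {
  fc <- feature_cols(train)
  if (length(unique(train$label)) < 2) {
    stop("data error: training set has a single class")
  }
  x <- train[fc]
  y <- factor(train$label, levels = sort(unique(train$label)))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees,
    mtry = max(1, floor(sqrt(length(fc)))),
    min.node.size = 1, # fully grown, no pruning
    replace = TRUE,
    probability = TRUE, # vote fractions, so ties can be broken by a fixed rule
    seed = seed,
    num.threads = 1
  )
  structure(
    list(fit = fit, features = fc, positive = max(as.integer(levels(y)))),
    class = "fog_rf"
  )
}

#' Predict window labels
#'
#' @param object A `fog_rf`.
#' @param newdata A feature table (extra columns ignored).
#' @param ... Unused.
#' @return Integer vector of predicted labels.
#' @export
predict.fog_rf <- function(object, newdata, ...) {
  p <- stats::predict(object$fit,
    data = newdata[object$features],
    num.threads = 1
  )$predictions
  pos <- as.character(object$positive)
  ifelse(p[, pos] >= 0.5, object$positive, 1L - object$positive)
}

#' Confusion counts between truth and prediction
#'
#' @param truth,pred Binary vectors (1 = FoG).
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  list(
    tp = sum(truth == 1 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)` and the F-score, the harmonic
#' mean of sensitivity and precision. A metric whose denominator is zero
#' (e.g. sensitivity for a subject with no FoG windows) is returned as `NA`
#' with a warning.
#'
#' @param counts List with `tp`, `tn`, `fp`, `fn`.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `precision`,
#'   `f_score`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp
  tn <- counts$tn
  fp <- counts$fp
  fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("argument error: all confusion counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  f <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * sens * prec / (sens + prec)
  } else if (!is.na(sens) && !is.na(prec)) {
    0
  } else {
    NA_real_
  }
  list(
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / total,
    precision = prec,
    f_score = f
  )
}

#' Leave-one-subject-out evaluation of a feature table
#'
#' The per-fold pipeline: fit min-max normalisation on the training rows,
#' rank features on the (normalised) training rows, restrict to the top-k,
#' SMOTE-balance the training rows, train the random forest, and predict the
#' held-out subject's untouched (unbalanced, train-normalised) rows. Nothing
#' derived from the held-out subject ever influences normalisation, ranking,
#' balancing or training.
#'
#' @param table A feature table (raw, unnormalised).
#' @param method Feature-ranking method, `"anova"`, `"mi"` or `"none"`
#'   (keep all features).
#' @param k Number of top-ranked features to keep (`NULL` = all).
#' @param n_trees Random-forest size.
#' @param smote_k SMOTE neighbour count.
#' @param target_ratio Post-SMOTE minority:majority ratio.
#' @param seed Master seed; per-fold SMOTE and forest seeds derive from it.
#' @param n_bins MI estimator bins.
#' @return Object of class `fog_eval`: `per_fold` data frame (subject,
#'   confusion counts, metrics), `aggregate` (pooled counts + metrics, and
#'   fold-wise mean/sd with undefined fold metrics excluded), and the
#'   configuration snapshot.
#' @export
loso_evaluate <- function(table, method = c("anova", "mi", "none"), k = NULL,
                          n_trees = 10, smote_k = 5, target_ratio = 1,
                          seed = 1, n_bins = 10) {
  method <- match.arg(method)
  fc <- feature_cols(table)
  if (!is.null(k) && k > length(fc)) {
    stop("argument error: k exceeds the number of features")
  }
  folds <- loso_splits(table)
  per_fold <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    train <- table[fold$train, , drop = FALSE]
    test <- table[fold$test, , drop = FALSE]

    norm <- fit_minmax(train)
    train <- apply_minmax(norm, train)
    test <- apply_minmax(norm, test)

    if (method != "none" && !is.null(k)) {
      ranking <- rank_features(train, method = method, n_bins = n_bins)
      keep <- fc[fc %in% ranking$feature_id[seq_len(k)]] # keep original order
      train <- train[c(META_COLS, keep)]
      test <- test[c(META_COLS, keep)]
    }

    balanced <- smote(train, smote_config(
      k_neighbors = smote_k, target_ratio = target_ratio,
      seed = derive_seed(seed, i, 11)
    ))
    model <- train_classifier(balanced,
      n_trees = n_trees,
      seed = derive_seed(seed, i, 13)
    )
    pred <- predict(model, test)
    cc <- confusion_counts(test$label, pred)
    met <- withCallingHandlers(
      compute_metrics(cc),
      warning = function(w) invokeRestart("muffleWarning") # non-freezer folds
    )
    per_fold[[i]] <- data.frame(
      subject_id = fold$subject,
      tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
      sensitivity = met$sensitivity, specificity = met$specificity,
      accuracy = met$accuracy, precision = met$precision,
      f_score = met$f_score,
      stringsAsFactors = FALSE
    )
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- list(
    tp = sum(per_fold$tp), tn = sum(per_fold$tn),
    fp = sum(per_fold$fp), fn = sum(per_fold$fn)
  )
  pooled_metrics <- withCallingHandlers(
    compute_metrics(pooled),
    warning = function(w) invokeRestart("muffleWarning")
  )
  mcols <- c("sensitivity", "specificity", "accuracy", "precision", "f_score")
  structure(
    list(
      per_fold = per_fold,
      aggregate = list(
        counts = pooled,
        metrics = pooled_metrics,
        # fold-wise summaries; folds where a metric is undefined (e.g.
        # non-freezers' sensitivity) are excluded from that metric's mean/sd
        fold_mean = vapply(per_fold[mcols], function(v) mean(v, na.rm = TRUE), numeric(1)),
        fold_sd = vapply(per_fold[mcols], function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
        n_folds_defined = vapply(per_fold[mcols], function(v) sum(!is.na(v)), numeric(1))
      ),
      config = list(
        method = method, k = k, n_trees = n_trees, smote_k = smote_k,
        target_ratio = target_ratio, seed = seed, n_bins = n_bins,
        n_features = length(fc), n_windows = nrow(table)
      )
    ),
    class = "fog_eval"
  )
}

#' @export
print.fog_eval <- function(x, ...) {
  m <- x$aggregate$metrics
  cat(sprintf(
    paste0(
      "<fog_eval> %d folds, %d windows, %s top-%s, %d trees\n",
      "  pooled: sens %.3f  spec %.3f  acc %.3f  prec %.3f  f %.3f\n"
    ),
    nrow(x$per_fold), x$config$n_windows, x$config$method,
    ifelse(is.null(x$config$k), "all", x$config$k), x$config$n_trees,
    m$sensitivity, m$specificity, m$accuracy, m$precision, m$f_score
  ))
  invisible(x)
}
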