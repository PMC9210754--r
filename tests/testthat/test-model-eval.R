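test_that("LOSO folds partition the table by subject", {
  tab <- make_toy_table(n_per_subject = 10, subjects = sprintf("S%02d", 1:12))
  folds <- loso_splits(tab)
  expect_length(folds, 12)
  test_rows <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_rows, seq_len(nrow(tab)))
  for (f in folds) {
    expect_length(intersect(
      unique(tab$subject_id[f$train]),
      unique(tab$subject_id[f$test])
    ), 0)
  }
  two <- loso_splits(make_toy_table(subjects = c("A", "B")))
  expect_length(two, 2)
  expect_equal(two[[1]]$train, two[[2]]$test)
  expect_error(loso_splits(make_toy_table(subjects = "A")), "two subjects")
})

test_that("metrics follow the printed formulas and degenerate rules", {
  m <- compute_metrics(list(tp = 8, tn = 90, fp = 10, fn = 2))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 98 / 110)
  expect_equal(m$precision, 8 / 18)
  expect_equal(m$f_score, 2 * 0.8 * (8 / 18) / (0.8 + 8 / 18))
  perfect <- compute_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))
  zero_tp <- compute_metrics(list(tp = 0, tn = 5, fp = 2, fn = 3))
  expect_equal(zero_tp$sensitivity, 0)
  expect_equal(zero_tp$f_score, 0)
  expect_warning(
    und <- compute_metrics(list(tp = 0, tn = 5, fp = 2, fn = 0)),
    "sensitivity undefined"
  )
  expect_true(is.na(und$sensitivity))
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "all confusion")
})

test_that("unpruned forests memorise separable data and are seed-deterministic", {
  set.seed(10)
  tab <- data.frame(
    subject_id = rep(c("A", "B"), 10),
    label = rep(c(0L, 1L), each = 10),
    start_s = seq(0, by = 0.5, length.out = 20)
  )
  tab$ch__x <- tab$label * 2 + rnorm(20, sd = 0.1)
  m1 <- train_classifier(tab, n_trees = 10, seed = 4)
  expect_equal(predict(m1, tab), tab$label)
  m2 <- train_classifier(tab, n_trees = 10, seed = 4)
  expect_equal(predict(m2, tab), predict(m1, tab))
  expect_error(
    train_classifier(tab[tab$label == 1, ]),
    "single class"
  )
})

test_that("pooled aggregate counts equal the sum over folds", {
  tab <- make_toy_table(n_per_subject = 50, subjects = c("A", "B", "C", "D"))
  res <- loso_evaluate(tab, method = "anova", k = 2, seed = 8)
  expect_equal(nrow(res$per_fold), 4)
  agg <- res$aggregate
  expect_equal(agg$counts$tp, sum(res$per_fold$tp))
  expect_equal(agg$counts$fn, sum(res$per_fold$fn))
  total <- with(agg$counts, tp + tn + fp + fn)
  expect_equal(total, nrow(tab))
  expect_equal(
    agg$metrics$accuracy,
    (agg$counts$tp + agg$counts$tn) / total
  )
})

test_that("no synthetic training row descends from the held-out subject", {
  tab <- make_toy_table(n_per_subject = 30, subjects = c("A", "B", "C"))
  folds <- loso_splits(tab)
  for (f in folds) {
    train <- tab[f$train, ]
    norm <- fit_minmax(train)
    bal <- smote(apply_minmax(norm, train), smote_config(seed = 1))
    expect_false(f$subject %in% bal$subject_id)
  }
})

test_that("non-freezer folds keep sensitivity undefined but pooled metrics finite", {
  tab <- rbind(
    make_toy_table(n_per_subject = 40, subjects = c("A", "B")),
    within(make_toy_table(n_per_subject = 40, subjects = "C"), label <- 0L)
  )
  res <- loso_evaluate(tab, method = "none", seed = 2)
  fold_c <- res$per_fold[res$per_fold$subject_id == "C", ]
  expect_true(is.na(fold_c$sensitivity))
  expect_false(is.na(res$aggregate$metrics$sensitivity))
  expect_equal(res$aggregate$n_folds_defined[["sensitivity"]], 2)
})

test_that("sensor-subset comparison runs shared-seed pipelines per subset", {
  cfg <- fog_config(
    generator = generator_config(
      n_subjects = 4, n_freezers = 4, recording_length = 90,
      gap_rate = 0, seed = 21
    ),
    selection = list(method = "anova", k = 10, n_bins = 10),
    seed = 21
  )
  cohort <- simulate_cohort(cfg$generator)
  res <- evaluate_sensor_subsets(
    cohort,
    list(
      shank_gyro = "left_shank_gyroscope_x",
      shank_gyro_dup = "left_shank_gyroscope_x",
      waist_acc = "waist_accelerometer_x"
    ),
    cfg
  )
  expect_equal(nrow(res), 3)
  # duplicate subsets give identical metrics
  expect_equal(
    unlist(res[res$subset == "shank_gyro", -1]),
    unlist(res[res$subset == "shank_gyro_dup", -1])
  )
  expect_error(
    evaluate_sensor_subsets(cohort, list(bad = "left_elbow_accelerometer_x"), cfg),
    "unknown channel"
  )
})

test_that("the sixteen single-sensor configurations enumerate correctly", {
  subs <- single_sensor_subsets()
  expect_length(subs, 16)
  expect_equal(sum(grepl("accelerometer", names(subs))), 7)
  expect_equal(sum(grepl("gyroscope", names(subs))), 7)
  expect_equal(sum(grepl("sole", names(subs))), 2)
  expect_true(all(vapply(subs[grepl("accelerometer|gyroscope", names(subs))], length, integer(1)) == 3))
  expect_true(all(vapply(subs[grepl("sole", names(subs))], length, integer(1)) == 3))
})
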