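test_that("the window-count formula and its edge cases hold", {
  expect_equal(count_windows(1000, 100, 2, 0.5), 17)
  expect_equal(count_windows(200, 100, 2, 0.5), 1)
  expect_equal(count_windows(199, 100, 2, 0.5), 0)
  expect_equal(count_windows(1005, 100, 2, 0.5), 17) # partial step discarded
})

test_that("windows are labelled by their start time against half-open episodes", {
  x <- rnorm(1000)
  rec <- make_recording(x)
  ann <- fog_annotations("T01", 3, 5)
  ws <- segment(rec, ann)
  expect_length(ws$labels, 17)
  expect_equal(ws$start_s[ws$labels == 1], c(3, 3.5, 4, 4.5))
  # no episodes -> all non-FoG
  ws0 <- segment(rec, no_episodes())
  expect_true(all(ws0$labels == 0))
  # a window starting exactly at the episode end is non-FoG
  ws2 <- segment(rec, fog_annotations("T01", 3, 4.5))
  expect_equal(ws2$start_s[ws2$labels == 1], c(3, 3.5, 4))
  # windows hold the right samples
  expect_equal(ws$data[[1]][, 2], x[51:250])
  expect_error(
    segment(rec, fog_annotations("T01", 8, 11)),
    "beyond the recording"
  )
})

test_that("band power matches a brute-force DFT oracle and Parseval holds", {
  fs <- 100
  tt <- (0:199) / fs
  x6 <- sin(2 * pi * 6 * tt)
  for (x in list(x6, rnorm(200))) {
    for (band in list(c(3, 8), c(0.5, 3), c(10, 20))) {
      expect_equal(
        band_power(x, band, fs),
        dft_band_power_oracle(x, band[1], band[2], fs),
        tolerance = 1e-9
      )
    }
  }
  # >= 99% of the non-DC power of a pure 6 Hz tone sits in the freeze zone
  total_nondc <- band_power(x6, c(0.005, 50), fs)
  expect_gt(band_power(x6, c(3, 8), fs) / total_nondc, 0.99)
  expect_equal(band_power(rep(0, 100), c(3, 8), fs), 0)
  # Parseval: power over (0, f/2] plus the DC term equals sum(x^2)
  x <- rnorm(256)
  dc <- sum(x)^2 / length(x)
  expect_equal(
    band_power(x, c(1e-9, 50), fs) + dc,
    sum(x^2),
    tolerance = 1e-9
  )
  expect_error(band_power(x, c(40, 60), fs), "argument error")
})

test_that("the freeze index separates trembling-band from locomotor-band tones", {
  fs <- 100
  tt <- (0:199) / fs
  ws <- segment(make_recording(c(sin(2 * pi * 6 * tt), sin(2 * pi * 6 * tt))), no_episodes())
  ft <- compute_features(ws)
  expect_gte(ft$left_shank_gyroscope_x__fi[1], 50)
  ws2 <- segment(make_recording(rep(sin(2 * pi * 1.5 * tt), 2)), no_episodes())
  ft2 <- compute_features(ws2)
  expect_lte(ft2$left_shank_gyroscope_x__fi[1], 0.02)
})

test_that("the full montage yields 13 features for each of the 48 channels", {
  cfg <- generator_config(recording_length = 10, gap_rate = 0, seed = 9)
  s <- simulate_subject(cfg, 1)
  ws <- segment(s$recording, s$annotations)
  ft <- compute_features(ws)
  expect_equal(length(feature_cols(ft)), 624)
  expect_false(anyNA(ft))
  # column order: channels in montage order, 13 features per channel
  expect_equal(
    feature_cols(ft)[1:13],
    paste0("waist_accelerometer_x__", c(
      "fi", "energy", "sum_power", "mean", "abs_mean", "zcr", "sd",
      "range", "rms", "max", "min", "pde", "entropy"
    ))
  )
  # any subset keeps 13 columns per channel
  ft_sub <- compute_features(ws, channels_at("left_shank"))
  expect_equal(length(feature_cols(ft_sub)), 13 * 6)
})

test_that("a constant window degenerates to the documented feature values", {
  ws <- segment(make_recording(rep(-2.5, 200)), no_episodes())
  ft <- compute_features(ws)
  g <- function(f) ft[[paste0("left_shank_gyroscope_x__", f)]][1]
  expect_equal(g("mean"), -2.5)
  expect_equal(g("abs_mean"), 2.5)
  expect_equal(g("sd"), 0)
  expect_equal(g("range"), 0)
  expect_equal(g("rms"), 2.5)
  expect_equal(g("max"), -2.5)
  expect_equal(g("min"), -2.5)
  expect_equal(g("zcr"), 0)
  expect_equal(g("entropy"), 0)
  expect_equal(g("pde"), 0)
})

test_that("features transform covariantly under channel scaling", {
  x <- rnorm(400)
  a <- 3
  ft1 <- compute_features(segment(make_recording(x), no_episodes()))
  ft2 <- compute_features(segment(make_recording(a * x), no_episodes()))
  g <- function(ft, f) ft[[paste0("left_shank_gyroscope_x__", f)]]
  expect_equal(g(ft2, "energy"), a^2 * g(ft1, "energy"), tolerance = 1e-9)
  expect_equal(g(ft2, "rms"), a * g(ft1, "rms"), tolerance = 1e-9)
  expect_equal(g(ft2, "sd"), a * g(ft1, "sd"), tolerance = 1e-9)
  expect_equal(g(ft2, "range"), a * g(ft1, "range"), tolerance = 1e-9)
  expect_equal(g(ft2, "fi"), g(ft1, "fi"), tolerance = 1e-6)
  expect_equal(g(ft2, "zcr"), g(ft1, "zcr"))
})

test_that("principal-direction eigenvalues agree with dense eigendecomposition", {
  cfg <- generator_config(recording_length = 12, gap_rate = 0, seed = 31)
  s <- simulate_subject(cfg, 1)
  chans <- channels_at("left_shank", "accelerometer")
  ws <- segment(s$recording, s$annotations, channels = chans)
  ft <- compute_features(ws, chans)
  n <- nrow(ws$data[[1]])
  for (w in c(1, 5, 10)) {
    mat <- cbind(ws$data[[1]][, w], ws$data[[2]][, w], ws$data[[3]][, w])
    ev <- sort(eigen(stats::cov(mat) * (n - 1) / n, symmetric = TRUE)$values,
      decreasing = TRUE
    )
    got <- c(
      ft$left_shank_accelerometer_x__pde[w],
      ft$left_shank_accelerometer_y__pde[w],
      ft$left_shank_accelerometer_z__pde[w]
    )
    expect_equal(got, ev, tolerance = 1e-8)
  }
})

test_that("zero-crossing counting is strict and ignores zero touches", {
  ws <- segment(
    make_recording(rep(c(1, 0, 1, -1), 50)), # touches zero, crosses once per cycle
    no_episodes()
  )
  ft <- compute_features(ws)
  # pattern 1,0,1,-1: zero inherits +, so crossings at 1->-1 and -1->1
  expect_equal(ft$left_shank_gyroscope_x__zcr[1], 2 * 50 - 1)
})

test_that("min-max normalisation follows the fit/apply contract", {
  tr <- data.frame(
    subject_id = "A", label = c(0L, 1L, 0L), start_s = c(0, 0.5, 1),
    ch__a = c(2, 4, 6), ch__b = c(7, 7, 7)
  )
  mod <- fit_minmax(tr)
  out <- apply_minmax(mod, tr)
  expect_equal(out$ch__a, c(0, 0.5, 1))
  expect_equal(out$ch__b, c(0, 0, 0)) # constant feature -> all zeros
  te <- tr
  te$ch__a <- c(0, 8, 4)
  out2 <- apply_minmax(mod, te)
  expect_equal(out2$ch__a, c(-0.5, 1.5, 0.5)) # outside [0,1], not clipped
  bad <- tr
  names(bad)[4] <- "ch__c"
  expect_error(apply_minmax(mod, bad), "schema error")
})

test_that("FoG-labelled shank windows carry a higher mean freeze index than walking windows", {
  cfg <- generator_config(recording_length = 240, gap_rate = 0, seed = 55)
  s <- simulate_subject(cfg, 1)
  ws <- segment(s$recording, s$annotations, channels = channels_at("left_shank", "gyroscope"))
  ft <- compute_features(ws)
  fi <- ft$left_shank_gyroscope_x__fi
  expect_gt(mean(fi[ft$label == 1]), mean(fi[ft$label == 0]))
})
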