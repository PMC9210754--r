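short_cfg <- function(...) {
  generator_config(recording_length = 60, seed = 101, ...)
}

test_that("montage enumerates 48 channels with the expected structure", {
  m <- montage()
  expect_equal(nrow(m), 48)
  expect_equal(sum(m$sensor == "accelerometer"), 21)
  expect_equal(sum(m$sensor == "gyroscope"), 21)
  expect_equal(sum(m$sensor == "fsr"), 6)
  expect_true(all(m$axis[m$sensor == "fsr"] == "none"))
  expect_equal(anyDuplicated(m$channel), 0)
  expect_equal(length(channels_at("left_shank")), 6)
})

test_that("simulated recordings are deterministic and complete", {
  cfg <- short_cfg()
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a, b)
  expect_equal(length(a$recording$channels), 48)
  lens <- vapply(a$recording$channels, length, integer(1))
  expect_true(all(lens == 60 * 100))
  # a different subject index gives different data
  c2 <- simulate_subject(cfg, 2)
  expect_false(identical(a$recording$channels[[1]], c2$recording$channels[[1]]))
})

test_that("only freezer subjects receive episodes, and cohorts have the right counts", {
  cfg <- generator_config(
    n_subjects = 4, n_freezers = 2, recording_length = 60,
    gap_rate = 0, seed = 5
  )
  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 4)
  n_eps <- vapply(cohort, function(s) nrow(s$annotations$episodes), integer(1))
  expect_true(all(n_eps[1:2] >= 1))
  expect_true(all(n_eps[3:4] == 0))
  ids <- vapply(cohort, function(s) s$recording$subject_id, character(1))
  expect_equal(anyDuplicated(ids), 0)
  # degenerate cohort: one subject, no freezers
  solo <- simulate_cohort(generator_config(
    n_subjects = 1, n_freezers = 0,
    recording_length = 30, seed = 1
  ))
  expect_length(solo, 1)
  expect_equal(nrow(solo[[1]]$annotations$episodes), 0)
})

test_that("annotations lie inside the recording and match the trembling signal", {
  cfg <- short_cfg()
  s <- simulate_subject(cfg, 1)
  eps <- s$annotations$episodes
  expect_true(nrow(eps) >= 1)
  expect_true(all(eps$start_s >= 0))
  expect_true(all(eps$end_s <= cfg$recording_length))
  expect_true(all(eps$end_s > eps$start_s))
  if (nrow(eps) > 1) {
    expect_true(all(eps$start_s[-1] >= eps$end_s[-nrow(eps)]))
  }
})

test_that("episode durations match the truncated-lognormal law", {
  cfg <- generator_config()
  d <- sample_episode_durations(10000, cfg, seed = 2024)
  expect_true(all(d >= cfg$episode_duration_range[1]))
  expect_true(all(d <= cfg$episode_duration_range[2]))
  # closed-form truncated mean as the independent oracle (defaults: ~8.1 s)
  mu <- cfg$episode_duration_lognormal[1]
  sg <- cfg$episode_duration_lognormal[2]
  a <- (log(cfg$episode_duration_range[1]) - mu) / sg
  b <- (log(cfg$episode_duration_range[2]) - mu) / sg
  m_expect <- exp(mu + sg^2 / 2) * (pnorm(b - sg) - pnorm(a - sg)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(d) - m_expect) / m_expect, 0.1)
  expect_equal(m_expect, 8.1, tolerance = 0.01)
  # more than half of episodes are shorter than 6 s
  expect_gt(mean(d < 6), 0.5)
})

test_that("gap injection respects rate, length and boundary rules", {
  cfg0 <- short_cfg(gap_rate = 0)
  rec <- simulate_subject(cfg0, 3)$recording
  expect_identical(inject_gaps(rec, cfg0), rec)

  cfg <- short_cfg(gap_rate = 0.02, gap_length_range = c(5, 50))
  g <- inject_gaps(rec, cfg)
  frac <- mean(unlist(g$missing))
  expect_gt(frac, 0)
  expect_lt(frac, 0.02) # expectation: 0.02 * 27.5 / 100 = 0.55%
  first_last <- vapply(g$missing, function(m) m[1] || m[length(m)], logical(1))
  expect_false(any(first_last))
  expect_identical(inject_gaps(rec, cfg), g) # deterministic

  # exact gap length: run lengths must lie in the configured range
  runs <- unlist(lapply(g$missing, function(m) {
    r <- rle(m)
    r$lengths[r$values]
  }))
  expect_true(all(runs >= 5))
  # overlapping gaps can merge, so only the lower bound is sharp
  expect_true(all(runs <= 100))
})

test_that("FoG segments are trembling-band dominated and walking segments locomotor-band dominated", {
  cfg <- generator_config(recording_length = 300, gap_rate = 0, seed = 77)
  band_ratio <- function(x, fs) {
    freeze <- band_power(x, c(3, 8), fs)
    motion <- band_power(x, c(0.5, 3), fs, upper_inclusive = FALSE)
    freeze / motion
  }
  n_fog <- 0
  n_walk <- 0
  fog_ok <- 0
  walk_ok <- 0
  for (subj in 1:4) {
    s <- simulate_subject(cfg, subj)
    fs <- s$recording$sample_rate
    eps <- s$annotations$episodes
    for (ch in channels_at("left_shank")) {
      x <- s$recording$channels[[ch]]
      tt <- (seq_along(x) - 1) / fs
      for (i in seq_len(nrow(eps))) {
        seg <- x[tt >= eps$start_s[i] & tt < eps$end_s[i]]
        if (length(seg) >= 100) {
          n_fog <- n_fog + 1
          fog_ok <- fog_ok + (band_ratio(seg, fs) > 1)
        }
      }
      # walking stretch before the first episode
      seg <- x[tt < eps$start_s[1] - 0.5]
      if (length(seg) >= 100) {
        n_walk <- n_walk + 1
        walk_ok <- walk_ok + (band_ratio(seg, fs) < 1)
      }
    }
  }
  expect_gte(n_fog + n_walk, 100)
  expect_equal(fog_ok, n_fog)
  expect_equal(walk_ok, n_walk)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_freezers = 13), "n_freezers")
  expect_error(generator_config(step_freq_range = c(3, 2)), "range")
  expect_error(generator_config(sample_rate = 10), "sample_rate")
  expect_error(
    inject_gaps(
      make_recording(rnorm(50)),
      generator_config(gap_length_range = c(60, 60))
    ),
    "gap longer"
  )
})
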