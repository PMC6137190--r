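oracle_counter <- function(truth) {
  function(rois, frame_id) truth[[frame_id]]$count
}

test_that("build_series pairs counts frame-by-frame and skips the first frame", {
  ds <- generate_sequence(scene_config(frame_shape = c(60, 80), n_frames = 10,
                                       day_mean = 2, error_prob = 0,
                                       seed = 51))
  ann <- classify_photoperiod(ds$annotations)
  ser <- build_series(ds$frames, ann, oracle_counter(ds$truth$frames))
  expect_identical(nrow(ser), 9L)
  expect_identical(ser$frame_id, ds$frames$frame_id[2:10])
  expect_identical(ser$timestamp, ds$frames$timestamp[2:10])
  # the oracle stub reproduces the observation exactly
  expect_equal(ser$recognized, ser$observed)
})

test_that("recognized counts do not leak from the annotations", {
  ds <- generate_sequence(scene_config(frame_shape = c(60, 80), n_frames = 8,
                                       day_mean = 2, error_prob = 0,
                                       seed = 52))
  ann <- classify_photoperiod(ds$annotations)
  ens <- make_const_ensemble(1)
  s1 <- build_series(ds$frames, ann, ens)
  ann2 <- ann
  ann2$observed_count <- rev(ann2$observed_count)
  s2 <- build_series(ds$frames, ann2, ens)
  expect_identical(s1$recognized, s2$recognized)
})

test_that("reduction drops flagged frames pairwise and commutes with strata", {
  ser <- make_series(observed = 1:10, recognized = 10:1,
                     turbidity = rep(c(0L, 2L), 5),
                     ptz_ok = c(rep(TRUE, 7), FALSE, TRUE, FALSE),
                     error_frame = c(TRUE, rep(FALSE, 9)))
  expect_identical(nrow(filter_reduced(make_series(1:4))), 4L)

  red <- filter_reduced(ser)
  expect_identical(nrow(red), 7L)
  expect_identical(red$observed, c(2L, 3L, 4L, 5L, 6L, 7L, 9L))
  expect_identical(red$recognized, c(9L, 8L, 7L, 6L, 5L, 4L, 2L))

  a <- stratify(filter_reduced(ser), turbidity = 0)
  b <- filter_reduced(stratify(ser, turbidity = 0))
  expect_identical(a, b)

  # crowding cutoff applies on top of the flags
  expect_identical(nrow(filter_reduced(ser, max_count = 5)), 4L)
})

test_that("aggregation averages per calendar day/photoperiod and per month", {
  # constant counts survive any scale unchanged
  konst <- make_series(rep(4, 96), photoperiod = rep(c("day", "night"), 48))
  for (sc in c("raw_30min", "day_night", "monthly")) {
    ag <- aggregate_series(konst, sc)
    expect_true(all(ag$observed == 4))
  }

  ser <- make_series(observed = c(2, 4, 0, 0), recognized = c(2, 4, 0, 0),
                     start = as.POSIXct("2013-05-10 08:00:00", tz = "CET"),
                     step_min = 180,   # all four samples on one calendar day
                     photoperiod = c("day", "day", "night", "night"))
  dn <- aggregate_series(ser, "day_night", tz = "CET")
  expect_equal(dn$observed[dn$photoperiod == "day"], 3.0)
  expect_equal(dn$observed[dn$photoperiod == "night"], 0.0)

  long <- make_series(observed = rep(c(1, 5), each = 40),
                      start = as.POSIXct("2013-01-15 00:00:00", tz = "CET"),
                      step_min = 60 * 24)
  mo <- aggregate_series(long, "monthly", tz = "CET")
  expect_identical(mo$month, sort(mo$month))       # chronological
  expect_gt(nrow(mo), 2)
  expect_equal(mo$observed[1], 1)
})

test_that("pearson handles exact, undefined and stochastic cases", {
  a <- c(1, 3, 2, 5, 4, 6)
  expect_equal(pearson_cor(a, a)$r, 1)
  expect_equal(pearson_cor(a, -a)$r, -1)
  expect_false(pearson_cor(rep(2, 10), 1:10)$defined)
  expect_false(pearson_cor(1:2, 2:1)$defined)
  expect_error(pearson_cor(1:5, 1:4), class = "fishcam_data_error")

  # population r = 0.9 by construction: b = 0.8 a + noise with
  # sigma^2 = (0.8 sd_a)^2 (1/r^2 - 1)
  set.seed(55)
  sd_a <- 2
  sig <- sqrt((0.8 * sd_a)^2 * (1 / 0.9^2 - 1))
  ok <- replicate(20, {
    av <- rnorm(50, 10, sd_a)
    bv <- 0.8 * av + rnorm(50, 0, sig)
    r <- pearson_cor(av, bv)$r
    ci <- tanh(atanh(0.9) + c(-1, 1) * qnorm(0.995) / sqrt(50 - 3))
    r >= ci[1] && r <= ci[2]
  })
  expect_gte(mean(ok), 0.9)   # 99% Fisher-z band should almost always hold

  expect_error(series_pearson(make_series(1:5), make_series(1:5,
    start = as.POSIXct("2014-01-01", tz = "UTC"))),
    class = "fishcam_data_error")
})

test_that("the stratified correlation grid flags sparse cells as undefined", {
  set.seed(56)
  n <- 160
  ser <- make_series(observed = rpois(n, 3),
                     turbidity = sample(0:1, n, replace = TRUE),
                     fouling = sample(0:1, n, replace = TRUE))
  ser$recognized <- ser$observed  # perfect recognizer
  g <- correlation_grid(ser, "raw_30min")
  expect_identical(nrow(g), 16L)
  expect_true(all(g$r[g$n >= 3] == 1))          # oracle closure
  expect_true(all(is.na(g$r[g$n == 0])))        # empty strata are missing
  # cells for scores never generated are empty
  expect_true(all(g$n[g$turbidity >= 2 | g$fouling >= 2] == 0))
})

test_that("with a perfect classifier all scales and strata correlate at 1", {
  set.seed(57)
  n <- 96 * 4
  ser <- make_series(observed = rpois(n, 4) + rep(c(3, 0), each = 48),
                     photoperiod = rep(rep(c("day", "night"), each = 48), 4))
  ser$recognized <- ser$observed
  for (sc in c("raw_30min", "day_night")) {
    ag <- aggregate_series(ser, sc)
    expect_equal(pearson_cor(ag$observed, ag$recognized)$r, 1)
  }
})
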