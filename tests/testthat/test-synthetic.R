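test_that("sequences are bit-reproducible from the seed", {
  cfg <- scene_config(frame_shape = c(50, 60), n_frames = 6, day_mean = 2,
                      fouling = 1, turbidity = 1, seed = 71)
  a <- generate_sequence(cfg)
  b <- generate_sequence(cfg)
  expect_identical(a$frames$pixels, b$frames$pixels)
  expect_identical(a$annotations, b$annotations)
  c_ <- generate_sequence(scene_config(frame_shape = c(50, 60), n_frames = 6,
                                       day_mean = 2, fouling = 1,
                                       turbidity = 1, seed = 72))
  expect_false(identical(a$frames$pixels, c_$frames$pixels))
})

test_that("an empty scene yields zero counts and zero RoIs", {
  ds <- generate_sequence(scene_config(frame_shape = c(60, 80), n_frames = 8,
                                       day_mean = 0, night_mean = 0,
                                       school_prob = 0, error_prob = 0,
                                       seed = 73))
  expect_true(all(ds$annotations$observed_count == 0))
  for (i in 2:8) expect_length(segment_frame(ds$frames, i), 0)
})

test_that("true counts follow the configured Poisson law", {
  ds <- generate_sequence(scene_config(frame_shape = c(50, 60), n_frames = 500,
                                       day_mean = 3, school_prob = 0,
                                       error_prob = 0, fouling = 0,
                                       force_photoperiod = "day", seed = 74))
  counts <- ds$annotations$observed_count
  se <- sqrt(3 / 500)
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("ground truth is self-consistent and matches the annotations", {
  ds <- generate_sequence(scene_config(frame_shape = c(60, 80), n_frames = 12,
                                       day_mean = 3, fouling = 0,
                                       error_prob = 0, seed = 75))
  for (i in seq_len(12)) {
    tr <- ds$truth$frames[[i]]
    # with no fouling every placed fish is fully visible and counted
    expect_identical(tr$count, length(tr$fish))
    expect_equal(ds$annotations$observed_count[i], tr$count)
    expect_length(tr$visible, length(tr$fish))
  }
})

test_that("fouling is static between frames except at growth steps", {
  cfg <- scene_config(frame_shape = c(60, 80), n_frames = 8, day_mean = 0,
                      night_mean = 0, school_prob = 0, error_prob = 0,
                      fouling = 3, growth_every = 4, seed = 76)
  fz <- fishcam:::make_fouling(c(60, 80), 3, seed = 76 + 7919L)
  m0 <- fishcam:::fouling_mask_at(fz, c(60, 80), 0)
  m0b <- fishcam:::fouling_mask_at(fz, c(60, 80), 0)
  m1 <- fishcam:::fouling_mask_at(fz, c(60, 80), 1)
  expect_identical(m0, m0b)          # static within a growth period
  expect_gt(sum(m1), sum(m0))        # growth enlarges the patches
  expect_true(all(m1[m0]))           # monotone growth

  ds <- generate_sequence(cfg)
  # frames 1..4 share growth step 0; 5..8 share step 1: differences within
  # a period contain no fouling signal (scene is otherwise empty)
  for (i in c(2, 3, 4, 6, 7, 8))
    expect_length(segment_frame(ds$frames, i), 0)
})

test_that("fish are displaced by at least one body length between frames", {
  ds <- generate_sequence(scene_config(frame_shape = c(120, 160),
                                       n_frames = 20, day_mean = 1,
                                       school_prob = 0, error_prob = 0,
                                       force_photoperiod = "day", seed = 77))
  for (i in 2:20) {
    prev <- ds$truth$frames[[i - 1]]$fish
    cur <- ds$truth$frames[[i]]$fish
    if (!length(prev) || !length(cur)) next
    for (f in cur) {
      d <- vapply(prev, function(p)
        sqrt((p$cy - f$cy)^2 + (p$cx - f$cx)^2), numeric(1))
      expect_gte(min(d), 2 * f$a)
    }
  }
})

test_that("error frames are flagged, noisy and excluded from the count truth", {
  ds <- generate_sequence(scene_config(frame_shape = c(50, 60), n_frames = 60,
                                       day_mean = 2, error_prob = 0.3,
                                       seed = 78))
  flags <- ds$annotations$error_frame
  expect_gt(sum(flags), 0)
  expect_true(all(ds$annotations$observed_count[flags] == 0))
  # a corrupted frame is white noise: enormous per-pixel spread
  i <- which(flags)[1]
  expect_gt(stats::sd(ds$frames$pixels[[i]]), 40)
})

test_that("feature-space datasets have exact class counts and separation", {
  d <- generate_feature_dataset(120, 80, 5, seed = 79)
  expect_identical(sum(d$y == 1), 120L)
  expect_identical(sum(d$y == 0), 80L)
  expect_identical(dim(d$X), c(200L, 22L))
  expect_identical(colnames(d$X), default_feature_schema())
  expect_identical(d, generate_feature_dataset(120, 80, 5, seed = 79))

  # informative features separate the classes by ~5 pooled sigma
  gap <- colMeans(d$X[d$y == 1, d$informative, drop = FALSE]) -
    colMeans(d$X[d$y == 0, d$informative, drop = FALSE])
  expect_true(all(gap > 3))

  d0 <- generate_feature_dataset(100, 100, 0, seed = 80)
  gap0 <- colMeans(d0$X[d0$y == 1, ]) - colMeans(d0$X[d0$y == 0, ])
  expect_true(all(abs(gap0) < 1))
})
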