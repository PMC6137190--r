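test_that("tree evaluation follows the protected-operator semantics", {
  # x3 - 0.5 on x3 = 0.7 -> raw 0.2 -> class 1
  tree <- list(op = "sub", kids = list(list(var = 3), list(const = 0.5)))
  X <- matrix(0, 1, 5); X[1, 3] <- 0.7
  expect_identical(evaluate_individual(tree, X), 1L)
  X[1, 3] <- 0.3
  expect_identical(evaluate_individual(tree, X), 0L)

  # protected division: x1 / 0 -> 1 -> class 1
  tree0 <- list(op = "pdiv", kids = list(list(var = 1), list(const = 0)))
  X2 <- matrix(c(-5, 0.2), 2, 1)
  expect_identical(evaluate_individual(tree0, X2), c(1L, 1L))

  # codomain is {0,1} for arbitrary random trees
  set.seed(91)
  Xr <- matrix(rnorm(200), 20, 10)
  for (i in 1:20) {
    tr <- fishcam:::random_tree(4, 10)
    out <- evaluate_individual(tr, Xr)
    expect_true(all(out %in% c(0L, 1L)))
  }
})

test_that("compiled evaluator agrees with a plain R re-evaluation", {
  ops <- list(add = `+`, sub = `-`, mul = `*`,
              pdiv = function(a, b) ifelse(b == 0, 1, a / b),
              min = pmin, max = pmax, neg = function(a) -a)
  eval_r <- function(nd, X) {
    if (!is.null(nd$op)) {
      if (nd$op == "ifgt") {
        a <- eval_r(nd$kids[[1]], X); b <- eval_r(nd$kids[[2]], X)
        cc <- eval_r(nd$kids[[3]], X); d <- eval_r(nd$kids[[4]], X)
        ifelse(a > b, cc, d)
      } else {
        vals <- lapply(nd$kids, function(k) eval_r(k, X))
        do.call(ops[[nd$op]], vals)
      }
    } else if (!is.null(nd$var)) X[, nd$var]
    else rep(nd$const, nrow(X))
  }
  set.seed(92)
  X <- matrix(runif(150), 15, 10)
  for (i in 1:30) {
    tr <- fishcam:::random_tree(5, 10)
    expect_equal(fishcam:::gp_eval_tree(tr, X), eval_r(tr, X),
                 tolerance = 1e-12)
  }
})

test_that("fitness is balanced accuracy minus the parsimony penalty", {
  # tree (x1 * 1.0) - 0.5 has 5 nodes and separates x1 around 0.5
  tree <- list(op = "sub",
               kids = list(list(op = "mul",
                                kids = list(list(var = 1),
                                            list(const = 1.0))),
                           list(const = 0.5)))
  expect_identical(fishcam:::tree_size(tree), 5L)
  X <- matrix(c(seq(0.6, 0.9, length.out = 10),
                seq(0.1, 0.4, length.out = 10)), 20, 1)
  y <- rep(c(1, 0), each = 10)
  expect_equal(gp_fitness(tree, X, y, parsimony = 0.001), 1 - 0.005)

  # constant-1 classifier: TPR 1, TNR 0 -> balanced accuracy 0.5
  one <- list(const = 1)
  expect_equal(gp_fitness(one, X, y, parsimony = 0.001), 0.5 - 0.001)

  # permutation invariance
  p <- sample(20)
  expect_equal(gp_fitness(tree, X[p, , drop = FALSE], y[p], 0.001),
               gp_fitness(tree, X, y, 0.001))
})

test_that("serialization round-trips trees and whole models", {
  set.seed(93)
  X <- matrix(runif(100), 10, 10)
  for (i in 1:10) {
    tr <- fishcam:::random_tree(5, 10)
    rt <- fishcam:::parse_gp_tokens(fishcam:::gp_tokens(tr))
    expect_equal(fishcam:::gp_eval_tree(rt, X), fishcam:::gp_eval_tree(tr, X))
  }

  d <- generate_feature_dataset(40, 40, 3, seed = 94)
  cv <- balanced_cv(d$X, d$y, k = 4, repeats = 2,
                    gp_config(pop_size = 30, generations = 3), seed = 95)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_model(cv$ensemble, path)
  back <- read_gp_model(path)
  expect_identical(length(back$individuals), length(cv$ensemble$individuals))
  pr1 <- predict_ensemble(cv$ensemble, d$X)
  pr2 <- predict_ensemble(back, d$X)
  expect_equal(pr1$fraction, pr2$fraction)
  expect_identical(pr1$label, pr2$label)
})

test_that("evolution recovers a separable concept and is seed-deterministic", {
  d <- generate_feature_dataset(100, 100, 5, seed = 96)
  X01 <- apply_normalization(d$X, feature_ranges(d$X))
  cfg <- gp_config(pop_size = 100, generations = 12)
  ind <- evolve(X01, d$y, cfg, seed = 97)
  expect_gte(ind$fitness + cfg$parsimony * ind$size, 0.9)

  ind2 <- evolve(X01, d$y, cfg, seed = 97)
  expect_identical(ind$tree, ind2$tree)

  expect_error(evolve(X01, rep(1, nrow(X01)), cfg, seed = 1),
               class = "fishcam_data_error")
})

test_that("balanced CV accounts for every example exactly once per repeat", {
  d <- generate_feature_dataset(30, 200, 2, seed = 98)
  k <- 5; repeats <- 2
  cv <- balanced_cv(d$X, d$y, k = k, repeats = repeats,
                    gp_config(pop_size = 20, generations = 2), seed = 99)
  folds <- cv$report$folds
  expect_equal(nrow(folds), k * repeats)
  for (r in seq_len(repeats)) {
    fr <- folds[folds$repeat_ == r, ]
    # every repeat draws |positives| negatives: 30 + 30 examples in k folds
    expect_identical(sum(fr$tp + fr$fp + fr$tn + fr$fn), 60L)
    # stratified folds: per-class fold sizes differ by at most 1
    expect_lte(diff(range(fr$tp + fr$fn)), 1)
    expect_lte(diff(range(fr$fp + fr$tn)), 1)
    expect_identical(sum(fr$tp + fr$fn), 30L)  # all positives validated once
  }
  # metric identities against the confusion counts
  expect_equal(folds$acc,
               (folds$tp + folds$tn) /
                 (folds$tp + folds$fp + folds$fn + folds$tn))
  expect_equal(folds$tpr, folds$tp / (folds$tp + folds$fn))
  expect_equal(folds$fpr, folds$fp / (folds$fp + folds$tn))

  cv2 <- balanced_cv(d$X, d$y, k = k, repeats = repeats,
                     gp_config(pop_size = 20, generations = 2), seed = 99)
  expect_identical(cv$report$folds, cv2$report$folds)
  expect_equal(length(cv$ensemble$individuals), repeats)
})

test_that("counting follows the ensemble votes and is bounded by the RoIs", {
  ds <- generate_sequence(scene_config(frame_shape = c(80, 100), n_frames = 5,
                                       fixed_count = 2, error_prob = 0,
                                       school_prob = 0,
                                       force_photoperiod = "day", seed = 100))
  rois <- segment_frame(ds$frames, 3)
  yes <- make_const_ensemble(1)
  no <- make_const_ensemble(-1)
  expect_identical(predict_count(yes, list()), 0L)
  expect_equal(predict_count(yes, rois), length(rois))
  expect_equal(predict_count(no, rois), 0)

  usage <- feature_usage(yes)
  expect_identical(names(usage), default_feature_schema())
  expect_true(all(usage == 0))   # a constant tree uses no features
})
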