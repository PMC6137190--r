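#' Genetic-programming hyperparameters
#'
#' Reference defaults for the evolutionary search: generational GP with
#' ramped half-and-half initialization, tournament selection, subtree
#' crossover, subtree/point mutation and elitism. Fitness is balanced
#' accuracy (mean of TPR and TNR) minus a parsimony penalty
#' `parsimony * tree size`.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param tournament tournament size for selection.
#' @param p_crossover per-offspring crossover probability.
#' @param p_mutation per-offspring mutation probability.
#' @param elitism number of best individuals copied unchanged each
#'   generation.
#' @param max_depth maximum tree depth.
#' @param max_size maximum tree node count (guards the 4-ary conditional
#'   from bloating within the depth limit).
#' @param parsimony per-node fitness penalty.
#' @param init_depth depth range for ramped half-and-half initialization.
#' @param const_range range of ephemeral constants (features are normalized
#'   to \[0, 1\], so unit-scale constants suffice).
#' @return validated list of class `gp_config`.
#' @export
gp_config <- function(pop_size = 200, generations = 30, tournament = 5,
                      p_crossover = 0.8, p_mutation = 0.15, elitism = 1,
                      max_depth = 8, max_size = 150, parsimony = 0.001,
                      init_depth = c(2, 6), const_range = c(-1, 1)) {
  if (pop_size < 2 || generations < 1 || tournament < 1 || elitism < 0)
    stop_config("invalid GP hyperparameters")
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1)
    stop_config("crossover/mutation probabilities must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = as.integer(elitism),
                 max_depth = as.integer(max_depth),
                 max_size = as.integer(max_size),
                 parsimony = parsimony, init_depth = init_depth,
                 const_range = const_range), class = "gp_config")
}

#' Binary output of one GP individual on examples
#'
#' The expression tree is evaluated on the normalized feature rows; the
#' classifier output is 1 exactly when the raw tree value is positive.
#' Protected division returns 1 on a zero denominator, so every tree is
#' total on the feature space.
#'
#' @param ind a `gp_individual` (or bare tree node).
#' @param X numeric matrix of normalized features (or a single named/plain
#'   vector, treated as one row).
#' @return integer vector of 0/1 outputs.
#' @export
evaluate_individual <- function(ind, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  tree <- if (inherits(ind, "gp_individual")) ind$tree else ind
  if (max(c(0L, flatten_tree(tree)$code)) - 100L > ncol(X))
    stop_data("feature schema mismatch: tree references feature beyond ncol(X)")
  as.integer(gp_eval_tree(tree, X) > 0)
}

#' Fitness of an individual on a labeled set
#'
#' Balanced accuracy (mean of the true positive and true negative rates)
#' minus `parsimony * tree size`; invariant to example order and robust to
#' class imbalance. Higher is better.
#'
#' @param ind tree node or `gp_individual`.
#' @param X normalized feature matrix.
#' @param y 0/1 labels.
#' @param parsimony per-node penalty.
#' @return scalar fitness.
#' @export
gp_fitness <- function(ind, X, y, parsimony = 0.001) {
  tree <- if (inherits(ind, "gp_individual")) ind$tree else ind
  if (length(y) == 0) stop_data("empty example set")
  f <- flatten_tree(tree)
  gp_fitness_batch(list(f$code), list(f$consts), X, as.integer(y),
                   parsimony, tree_size(tree))[1]
}

pop_fitness <- function(pop, X, y, parsimony) {
  flat <- lapply(pop, flatten_tree)
  sizes <- vapply(pop, tree_size, 1L)
  gp_fitness_batch(lapply(flat, `[[`, "code"), lapply(flat, `[[`, "consts"),
                   X, as.integer(y), parsimony, sizes)
}

init_population <- function(cfg, n_features) {
  depths <- rep(seq(cfg$init_depth[1], cfg$init_depth[2]),
                length.out = cfg$pop_size)
  methods <- rep(c("grow", "full"), length.out = cfg$pop_size)
  lapply(seq_len(cfg$pop_size), function(i)
    random_tree(depths[i], n_features, cfg$const_range, methods[i]))
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), k, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' Evolve a GP binary classifier on a training set
#'
#' Generational genetic programming: ramped half-and-half initialization,
#' tournament selection, depth-limited subtree crossover, subtree/point
#' mutation and elitism, for `generations` generations. Returns the
#' best-of-run individual by fitness. Fully reproducible from `seed`.
#'
#' @param X normalized feature matrix of the training examples.
#' @param y 0/1 labels; both classes must be present.
#' @param config a [gp_config()].
#' @param seed integer RNG seed.
#' @return object of class `gp_individual`: fields `tree`, `fitness`,
#'   `size`, `depth`.
#' @export
evolve <- function(X, y, config = gp_config(), seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_data("training set must contain both classes")
  nf <- ncol(X)
  withr::with_seed(seed, {
    pop <- init_population(config, nf)
    fit <- pop_fitness(pop, X, y, config$parsimony)
    best_i <- which.max(fit)
    best <- list(tree = pop[[best_i]], fitness = fit[best_i])
    for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(config$elitism)]]
      while (length(new_pop) < config$pop_size) {
        p1 <- pop[[tournament_pick(fit, config$tournament)]]
        child <- if (runif(1) < config$p_crossover) {
          p2 <- pop[[tournament_pick(fit, config$tournament)]]
          crossover_trees(p1, p2, config$max_depth, config$max_size)
        } else p1
        if (runif(1) < config$p_mutation)
          child <- mutate_tree(child, nf, config$const_range,
                               config$max_depth, config$max_size)
        new_pop[[length(new_pop) + 1L]] <- child
      }
      pop <- new_pop
      fit <- pop_fitness(pop, X, y, config$parsimony)
      gi <- which.max(fit)
      if (fit[gi] > best$fitness)
        best <- list(tree = pop[[gi]], fitness = fit[gi])
    }
    structure(list(tree = best$tree, fitness = best$fitness,
                   size = tree_size(best$tree),
                   depth = tree_depth(best$tree)),
              class = "gp_individual")
  })
}

#' @export
print.gp_individual <- function(x, ...) {
  cat(sprintf("<gp_individual> size %d, depth %d, fitness %.4f\n  %s\n",
              x$size, x$depth, x$fitness,
              paste(gp_tokens(x$tree), collapse = " ")))
  invisible(x)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated, class-balanced, stratified k-fold cross-validation of the GP
#' classifier
#'
#' Fish/non-fish example pools from fixed-camera imagery are heavily
#' imbalanced (few positives, many background regions). Each repeat draws as
#' many negatives as there are positives uniformly without replacement from
#' the negative pool, reshuffles the positives, forms class-stratified k
#' folds, and trains one GP classifier per fold rotation. Per-fold confusion
#' counts are recorded on the held-out fold, and the repeat's best individual
#' (highest held-out balanced accuracy) joins the returned ensemble.
#'
#' @param X raw (unnormalized) feature matrix of the full example pool.
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param repeats number of balanced repeats.
#' @param config a [gp_config()].
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @param theta ensemble vote-fraction threshold.
#' @return list with `ensemble` (class `gp_ensemble`) and `report`
#'   (class `cv_report`: per-fold confusion counts and summary statistics).
#' @export
balanced_cv <- function(X, y, k = 10, repeats = 10, config = gp_config(),
                        seed = 1L, theta = 0.5) {
  y <- as.integer(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) < k || length(neg) < k)
    stop_data("need at least k examples of each class")
  swap <- FALSE
  if (length(neg) < length(pos)) {
    warning("fewer negatives than positives: subsampling positives down")
    swap <- TRUE
  }
  ranges <- feature_ranges(X)
  X01 <- apply_normalization(X, ranges)
  rows <- list(); champions <- vector("list", repeats)
  withr::with_seed(seed, {
    sub_seeds <- matrix(sample.int(.Machine$integer.max - 1, repeats * k),
                        repeats, k)
    for (r in seq_len(repeats)) {
      if (!swap) {
        n_draw <- length(pos)
        samp <- c(sample(pos), sample(neg, n_draw))
      } else {
        n_draw <- length(neg)
        samp <- c(sample(pos, n_draw), sample(neg))
      }
      ys <- y[samp]
      fold <- stratified_folds(ys, k)
      best_ba <- -Inf
      for (f in seq_len(k)) {
        tr <- samp[fold != f]; va <- samp[fold == f]
        ind <- evolve(X01[tr, , drop = FALSE], y[tr], config,
                      seed = sub_seeds[r, f])
        pred <- evaluate_individual(ind, X01[va, , drop = FALSE])
        tp <- sum(pred == 1 & y[va] == 1); fp <- sum(pred == 1 & y[va] == 0)
        tn <- sum(pred == 0 & y[va] == 0); fn <- sum(pred == 0 & y[va] == 1)
        m <- confusion_metrics(tp, fp, tn, fn)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, tp = tp, fp = fp, tn = tn, fn = fn,
          acc = m[["acc"]], tpr = m[["tpr"]], fpr = m[["fpr"]])
        ba <- (m[["tpr"]] + (1 - m[["fpr"]])) / 2
        if (ba > best_ba) { best_ba <- ba; champions[[r]] <- ind }
      }
    }
  })
  folds_df <- do.call(rbind, rows)
  report <- structure(list(
    folds = folds_df,
    summary = list(
      mean_acc = mean(folds_df$acc), sd_acc = sd(folds_df$acc),
      mean_tpr = mean(folds_df$tpr), sd_tpr = sd(folds_df$tpr),
      mean_fpr = mean(folds_df$fpr), sd_fpr = sd(folds_df$fpr)),
    k = k, repeats = repeats), class = "cv_report")
  ensemble <- structure(list(
    individuals = champions,
    feature_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    ranges = ranges, theta = theta, k = k, repeats = repeats,
    config = config, seed = seed), class = "gp_ensemble")
  list(ensemble = ensemble, report = report)
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<cv_report> %d repeats x %d folds\n",
                     "  ACC %.3f (sd %.3f)  TPR %.3f (sd %.3f)  ",
                     "FPR %.3f (sd %.3f)\n"),
              x$repeats, x$k, s$mean_acc, s$sd_acc, s$mean_tpr, s$sd_tpr,
              s$mean_fpr, s$sd_fpr))
  invisible(x)
}

#' @export
print.gp_ensemble <- function(x, ...) {
  cat(sprintf("<gp_ensemble> %d individuals, theta %.2f, %d features\n",
              length(x$individuals), x$theta, length(x$feature_names)))
  invisible(x)
}

#' Ensemble vote fractions and labels on raw feature rows
#'
#' Features are normalized with the training ranges stored in the ensemble;
#' each retained individual votes and an example is positive when the vote
#' fraction exceeds `theta` (majority vote at the default 0.5).
#'
#' @param ensemble a `gp_ensemble`.
#' @param X raw feature matrix (or single row vector).
#' @return list with `fraction` (vote fractions) and `label` (0/1).
#' @export
predict_ensemble <- function(ensemble, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  X01 <- apply_normalization(X, ensemble$ranges)
  votes <- vapply(ensemble$individuals,
                  function(ind) evaluate_individual(ind, X01),
                  integer(nrow(X01)))
  if (is.null(dim(votes))) votes <- matrix(votes, 1)
  fraction <- rowMeans(votes)
  list(fraction = fraction, label = as.integer(fraction > ensemble$theta))
}

#' Count the fish-classified RoIs of one frame
#'
#' The per-image fish count is the number of RoIs whose ensemble vote
#' fraction exceeds the decision threshold. An empty RoI list counts 0.
#'
#' @param ensemble a `gp_ensemble`.
#' @param rois list of RoIs.
#' @param extractors feature extractor registry.
#' @return non-negative integer count.
#' @export
predict_count <- function(ensemble, rois,
                          extractors = default_feature_extractors()) {
  if (!length(rois)) return(0L)
  X <- feature_matrix(rois, extractors)
  sum(predict_ensemble(ensemble, X)$label)
}

#' Per-feature usage frequency across the ensemble
#'
#' Features absent from every winning tree were implicitly unselected by the
#' evolutionary search; this reports, for each schema feature, the fraction
#' of ensemble individuals whose tree references it.
#'
#' @param ensemble a `gp_ensemble`.
#' @return named numeric vector over the feature schema.
#' @export
feature_usage <- function(ensemble) {
  nf <- length(ensemble$feature_names)
  used <- vapply(ensemble$individuals, function(ind) {
    code <- flatten_tree(ind$tree)$code
    tabulate(code[code > 100] - 100L, nf) > 0
  }, logical(nf))
  setNames(rowMeans(used), ensemble$feature_names)
}

#' Write a GP ensemble model to JSON
#'
#' Stores schema version, feature names, normalization ranges, the expression
#' trees in prefix notation, the decision threshold and the training seed.
#'
#' @param ensemble a `gp_ensemble`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_gp_model <- function(ensemble, path) {
  obj <- list(
    schema_version = 1L,
    feature_names = ensemble$feature_names,
    ranges = list(min = unname(ensemble$ranges$min),
                  max = unname(ensemble$ranges$max)),
    trees = lapply(ensemble$individuals, function(i) gp_tokens(i$tree)),
    theta = ensemble$theta, k = ensemble$k, repeats = ensemble$repeats,
    seed = ensemble$seed)
  # I(17) significant digits: numeric fields survive the round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a GP ensemble model from JSON
#' @param path model file written by [write_gp_model()].
#' @return a `gp_ensemble`.
#' @export
read_gp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  inds <- lapply(obj$trees, function(tk) {
    tree <- parse_gp_tokens(vapply(tk, as.character, character(1)))
    structure(list(tree = tree, fitness = NA_real_,
                   size = tree_size(tree), depth = tree_depth(tree)),
              class = "gp_individual")
  })
  nm <- vapply(obj$feature_names, as.character, character(1))
  structure(list(individuals = inds, feature_names = nm,
                 ranges = list(
                   min = setNames(vapply(obj$ranges$min, as.numeric,
                                         numeric(1)), nm),
                   max = setNames(vapply(obj$ranges$max, as.numeric,
                                         numeric(1)), nm)),
                 theta = obj$theta, k = obj$k, repeats = obj$repeats,
                 seed = obj$seed), class = "gp_ensemble")
}

#' Write a cross-validation report (per-fold CSV + JSON summary)
#' @param report a `cv_report`.
#' @param csv_path per-fold CSV output path.
#' @param json_path optional JSON summary output path.
#' @return `csv_path`, invisibly.
#' @export
write_cv_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$folds, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
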