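#' Square-root transform of abundance data
#'
#' The mild variance-stabilising transform applied before building the
#' Euclidean resemblance matrix for PERMANOVA.
#'
#' @param values non-negative numeric vector.
#' @return element-wise square root.
#' @export
transform_abundance <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop_data("abundance values must be >= 0")
  sqrt(values)
}

permanova_ss <- function(D2, groups) {
  n <- length(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * sum(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

permanova_F <- function(D2, groups, df_b, df_w) {
  ss <- permanova_ss(D2, groups)
  msa <- ss[["among"]] / df_b
  msw <- ss[["within"]] / df_w
  if (msw == 0) { if (msa <= 1e-15) 0 else Inf } else msa / msw
}

# All permutations of 1..n (n small), matrix n x n!.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}

#' Univariate permutation PERMANOVA on the Euclidean resemblance matrix
#'
#' Partitions the sum of squared Euclidean distances between observations
#' into among- and within-group components and forms the pseudo-F statistic
#' `(SS_among / df_between) / (SS_within / df_within)`. Significance comes
#' from free permutation of the group labels:
#' `p = (#\{permuted F >= observed F\} + 1) / (n_perm + 1)`. In the
#' univariate Euclidean case the pseudo-F is identical to the classical
#' one-way ANOVA F. For very small samples (`n <= exact_limit`) all label
#' permutations are enumerated and the p-value is exact.
#'
#' @param values numeric vector (typically square-root-transformed
#'   abundances, see [transform_abundance()]).
#' @param groups group labels, at least 2 groups with at least 2
#'   observations each.
#' @param n_perm number of random permutations.
#' @param seed integer RNG seed for the permutations.
#' @param exact_limit enumerate all permutations when `length(values)` is at
#'   most this (set to 0 to force sampling).
#' @return list of class `permanova_result`: `pseudo_F`, `df_between`,
#'   `df_within`, `p_perm`, `n_permutations`, `method`.
#' @export
permanova_univariate <- function(values, groups, n_perm = 9999, seed = 1L,
                                 exact_limit = 8) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2) stop_data("need at least 2 groups")
  if (any(tab < 2)) stop_data("every group needs at least 2 observations")
  n <- length(values)
  df_b <- length(tab) - 1L
  df_w <- n - length(tab)
  D2 <- outer(values, values, "-")^2
  F_obs <- permanova_F(D2, groups, df_b, df_w)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    F_perm <- vapply(seq_len(ncol(perms)), function(j)
      permanova_F(D2, groups[perms[, j]], df_b, df_w), numeric(1))
    p <- mean(F_perm >= F_obs - 1e-12)
    n_eff <- ncol(perms)
    method <- "exact"
  } else {
    # Within-group SS for all permutations at once: for group g with
    # indicator column l, sum_{i,j in g} d2_ij = l' D2 l.
    F_perm <- withr::with_seed(seed, {
      ss_tot <- sum(D2) / (2 * n)
      ssw <- numeric(n_perm)
      perm_idx <- replicate(n_perm, sample.int(n))
      for (g in names(tab)) {
        sel <- groups == g
        L <- matrix(0, n, n_perm)
        pos <- which(sel)
        for (j in seq_len(n_perm)) L[perm_idx[pos, j], j] <- 1
        ssw <- ssw + colSums((D2 %*% L) * L) / (2 * tab[[g]])
      }
      ifelse(ssw == 0, ifelse(ss_tot - ssw <= 1e-15, 0, Inf),
             ((ss_tot - ssw) / df_b) / (ssw / df_w))
    })
    p <- (sum(F_perm >= F_obs - 1e-12) + 1) / (n_perm + 1)
    n_eff <- n_perm
    method <- "sampled"
  }
  structure(list(pseudo_F = F_obs, df_between = df_b, df_within = df_w,
                 p_perm = p, n_permutations = n_eff, method = method),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F(%d,%d) = %.3f, p = %.4g (%s, %d perms)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_perm, x$method,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA contrasts
#'
#' For every pair of groups the two-group pseudo-F is computed and converted
#' to a pseudo-t (`t = sqrt(F)`; on univariate data this equals the
#' equal-variance two-sample t in magnitude), with a permutation p-value per
#' pair. The full table is returned; `signif` marks pairs with `p < alpha`.
#'
#' @param values numeric vector.
#' @param groups group labels (e.g. month numbers).
#' @param n_perm permutations per pair.
#' @param seed integer RNG seed.
#' @param alpha significance threshold for the reporting flag.
#' @return data.frame: `group1, group2, t, p, signif`.
#' @export
pairwise_permanova <- function(values, groups, n_perm = 9999, seed = 1L,
                               alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sel <- groups %in% c(a, b)
    res <- permanova_univariate(values[sel], groups[sel], n_perm,
                                seed = seed + i, exact_limit = 0)
    data.frame(group1 = a, group2 = b, t = sqrt(res$pseudo_F),
               p = res$p_perm, signif = res$p_perm < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Greedy autocorrelation pre-filter for covariate columns
#'
#' Covariates entering downstream models should not be collinear. While any
#' pair of retained columns has `|r| >= r_max`, the worst (highest `|r|`)
#' pair is located and the member with the larger mean absolute correlation
#' against all other retained columns is dropped; ties break by column name
#' order (the alphabetically later name is dropped). Deterministic and
#' independent of input column order.
#'
#' @param covariates data.frame or matrix of named numeric columns.
#' @param r_max threshold on the absolute Pearson correlation.
#' @return character vector of retained column names.
#' @export
autocorrelation_filter <- function(covariates, r_max = 0.70) {
  X <- as.matrix(covariates)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2) stop_data("need at least 2 complete rows")
  keep <- sort(colnames(X))
  repeat {
    if (length(keep) < 2) break
    R <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) < r_max) break
    worst <- which(R == max(R), arr.ind = TRUE)
    # deterministic pick of the worst pair: earliest by (row name, col name)
    pr <- worst[order(keep[worst[, 1]], keep[worst[, 2]]), , drop = FALSE][1, ]
    a <- keep[pr[1]]; b <- keep[pr[2]]
    mean_r <- rowMeans(R)
    drop <- if (mean_r[a] > mean_r[b]) a
    else if (mean_r[b] > mean_r[a]) b
    else max(a, b)   # tie: drop the later name
    keep <- setdiff(keep, drop)
  }
  keep
}
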