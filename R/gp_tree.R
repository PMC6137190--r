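# Expression-tree primitives for the genetic-programming classifier.
# A tree node is a list: list(op = <name>, kids = list(...)) for operators,
# list(var = j) for a feature terminal (1-based schema column), or
# list(const = x) for an ephemeral real constant.

GP_OPS <- data.frame(
  name = c("add", "sub", "mul", "pdiv", "min", "max", "neg", "ifgt"),
  code = 1:8,
  arity = c(2, 2, 2, 2, 2, 2, 1, 4),
  stringsAsFactors = FALSE)

gp_op_arity <- setNames(GP_OPS$arity, GP_OPS$name)
gp_op_code <- setNames(GP_OPS$code, GP_OPS$name)

random_terminal <- function(n_features, const_range, p_var = 0.8) {
  if (runif(1) < p_var) list(var = sample.int(n_features, 1))
  else list(const = runif(1, const_range[1], const_range[2]))
}

#' Generate a random expression tree
#'
#' `grow` trees may place terminals at any depth; `full` trees place
#' operators down to `depth` and terminals only at the leaves (the two halves
#' of ramped half-and-half initialization).
#'
#' @param depth maximum depth of this tree (root has depth 1).
#' @param n_features number of feature terminals available.
#' @param const_range range of ephemeral constants.
#' @param method "grow" or "full".
#' @return a tree node.
#' @keywords internal
random_tree <- function(depth, n_features, const_range = c(-1, 1),
                        method = c("grow", "full")) {
  method <- match.arg(method)
  if (depth <= 1 || (method == "grow" && runif(1) < 0.25))
    return(random_terminal(n_features, const_range))
  op <- GP_OPS$name[sample.int(nrow(GP_OPS), 1)]
  kids <- lapply(seq_len(gp_op_arity[[op]]), function(i)
    random_tree(depth - 1, n_features, const_range, method))
  list(op = op, kids = kids)
}

tree_size <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + sum(vapply(node$kids, tree_size, 1L))
}

tree_depth <- function(node) {
  if (is.null(node$op)) return(1L)
  1L + max(vapply(node$kids, tree_depth, 1L))
}

#' Flatten a tree to prefix arrays for the compiled evaluator
#' @return list(code = integer opcodes, consts = constant values in
#'   encounter order).
#' @keywords internal
flatten_tree <- function(node) {
  code <- integer(0); consts <- numeric(0)
  rec <- function(nd) {
    if (!is.null(nd$op)) {
      code[[length(code) + 1L]] <<- gp_op_code[[nd$op]]
      for (k in nd$kids) rec(k)
    } else if (!is.null(nd$var)) {
      code[[length(code) + 1L]] <<- 100L + nd$var
    } else {
      code[[length(code) + 1L]] <<- 0L
      consts[[length(consts) + 1L]] <<- nd$const
    }
  }
  rec(node)
  list(code = code, consts = consts)
}

# Fetch / replace the i-th node in preorder (1 = root).
get_subtree <- function(node, i) {
  res <- NULL
  cnt <- 0L
  rec <- function(nd) {
    cnt <<- cnt + 1L
    if (cnt == i) { res <<- nd; return(TRUE) }
    if (!is.null(nd$op)) for (k in nd$kids) if (rec(k)) return(TRUE)
    FALSE
  }
  rec(node)
  res
}

set_subtree <- function(node, i, sub) {
  cnt <- 0L
  rec <- function(nd) {
    cnt <<- cnt + 1L
    if (cnt == i) return(sub)
    if (!is.null(nd$op))
      for (j in seq_along(nd$kids)) {
        remaining <- i - cnt
        sz <- tree_size(nd$kids[[j]])
        if (remaining <= sz) { nd$kids[[j]] <- rec(nd$kids[[j]]); return(nd) }
        cnt <<- cnt + sz
      }
    nd
  }
  rec(node)
}

#' Subtree crossover with depth/size rejection
#'
#' Swaps a uniformly chosen subtree of `a` with one of `b`; if the offspring
#' exceeds `max_depth` or `max_size`, the first parent is returned unchanged
#' (standard depth-limited crossover).
#' @keywords internal
crossover_trees <- function(a, b, max_depth = 8, max_size = 150) {
  i <- sample.int(tree_size(a), 1)
  j <- sample.int(tree_size(b), 1)
  child <- set_subtree(a, i, get_subtree(b, j))
  if (tree_depth(child) > max_depth || tree_size(child) > max_size) a
  else child
}

point_mutate_node <- function(nd, n_features, const_range) {
  if (!is.null(nd$op)) {
    same <- GP_OPS$name[GP_OPS$arity == gp_op_arity[[nd$op]]]
    nd$op <- same[sample.int(length(same), 1)]
  } else if (!is.null(nd$var)) {
    nd$var <- sample.int(n_features, 1)
  } else {
    nd$const <- nd$const + rnorm(1, 0, 0.1 * diff(const_range))
  }
  nd
}

#' Mutate a tree: subtree replacement or point mutation
#' @keywords internal
mutate_tree <- function(node, n_features, const_range = c(-1, 1),
                        max_depth = 8, max_size = 150) {
  i <- sample.int(tree_size(node), 1)
  if (runif(1) < 0.7) {
    sub <- random_tree(sample(2:3, 1), n_features, const_range, "grow")
    child <- set_subtree(node, i, sub)
    if (tree_depth(child) > max_depth || tree_size(child) > max_size) node
    else child
  } else {
    set_subtree(node, i, point_mutate_node(get_subtree(node, i),
                                           n_features, const_range))
  }
}

#' Serialize a tree to prefix notation tokens
#'
#' Operators by name, features as `x<j>`, constants as decimal literals; the
#' inverse of [parse_gp_tokens()].
#' @param node a tree node.
#' @return character vector of tokens.
#' @keywords internal
gp_tokens <- function(node) {
  if (!is.null(node$op))
    c(node$op, unlist(lapply(node$kids, gp_tokens)))
  else if (!is.null(node$var)) paste0("x", node$var)
  else format(node$const, digits = 17)
}

#' Parse prefix tokens back to a tree
#' @param tokens character vector from [gp_tokens()].
#' @return a tree node.
#' @keywords internal
parse_gp_tokens <- function(tokens) {
  pos <- 0L
  rec <- function() {
    pos <<- pos + 1L
    tk <- tokens[pos]
    if (tk %in% GP_OPS$name) {
      list(op = tk, kids = lapply(seq_len(gp_op_arity[[tk]]),
                                  function(i) rec()))
    } else if (grepl("^x[0-9]+$", tk)) {
      list(var = as.integer(sub("^x", "", tk)))
    } else list(const = as.numeric(tk))
  }
  out <- rec()
  if (pos != length(tokens)) stop_data("malformed prefix token stream")
  out
}

#' Evaluate a tree on a (normalized) feature matrix
#' @param node tree node or `gp_individual`.
#' @param X numeric matrix, one row per example.
#' @return numeric vector of raw outputs, one per row.
#' @keywords internal
gp_eval_tree <- function(node, X) {
  if (inherits(node, "gp_individual")) node <- node$tree
  f <- flatten_tree(node)
  gp_eval_prefix(f$code, f$consts, X)
}
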