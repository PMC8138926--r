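# Recursive-partitioning classifier over binary immunostain predictors.
#
# Greedy binary tree growth with the likelihood-ratio (G^2) split
# criterion, each predictor used at most once per path, a minimum leaf
# size, and no pruning — the published tree uses each of the three
# predictors once and has depth <= 3, which this criterion/stopping pair
# reproduces. Leaf class probabilities are smoothed toward the root prior
# with one pseudo-observation: (n_c + prior_c) / (N + 1).

#' Likelihood-ratio score of a candidate binary split
#'
#' `G^2 = 2 * sum O * ln(O / E)` over both children and all classes, with
#' expected counts `E` given by the parent's class proportions scaled to
#' each child's size; zero observed counts contribute zero. Larger is
#' better; a split reproducing the parent proportions in both children
#' scores 0.
#'
#' @param parent_counts,left_counts,right_counts non-negative per-class
#'   counts; `left + right` must equal `parent`, and both children must be
#'   nonempty.
#' @return The G^2 statistic.
#' @examples
#' split_score(c(50, 50), c(50, 0), c(0, 50))  # 2 * 100 * log(2)
#' @export
split_score <- function(parent_counts, left_counts, right_counts) {
  parent_counts <- as.numeric(parent_counts)
  left_counts <- as.numeric(left_counts)
  right_counts <- as.numeric(right_counts)
  if (length(left_counts) != length(parent_counts) ||
      length(right_counts) != length(parent_counts))
    stop("count vectors must have one entry per class")
  if (any(abs(left_counts + right_counts - parent_counts) > 1e-9))
    stop("left + right counts must equal parent counts")
  if (sum(left_counts) == 0 || sum(right_counts) == 0)
    stop("both children must be nonempty")
  prop <- parent_counts / sum(parent_counts)
  g2_child <- function(obs) {
    expected <- sum(obs) * prop
    keep <- obs > 0
    sum(obs[keep] * log(obs[keep] / expected[keep]))
  }
  2 * (g2_child(left_counts) + g2_child(right_counts))
}

response_counts <- function(values, levels) {
  vapply(levels, function(l) sum(values == l), numeric(1))
}

#' Fit a recursive-partitioning tree over binary predictors
#'
#' Greedy recursion: at every node the unused predictor with the maximal
#' [split_score()] is chosen (ties broken by the order of `predictors`);
#' growth stops when no candidate leaves both children with at least
#' `min_leaf` cases or improves G^2 above zero. `forced_root` overrides
#' the greedy choice: its first element forces the root's split variable,
#' and further elements force the split variable at the corresponding
#' depth in every branch (needed to reproduce a published alternate tree
#' whose spine is fixed a priori); at any node where the forced variable
#' cannot split validly, the node becomes a leaf.
#'
#' @param data `data.frame` of two-level factors (see
#'   [cohort_marker_frame()]).
#' @param predictors character vector of predictor column names.
#' @param response response column name (two-level factor).
#' @param min_leaf minimal cases per child (default 5).
#' @param forced_root optional character vector of forced split variables
#'   by depth; `NULL` for fully greedy growth.
#' @return Object of class `partition_tree`.
#' @examples
#' mk <- cohort_marker_frame(build_cohort_fixture())
#' tree <- fit_tree(mk, c("h3k27me3", "atrx", "idh1_r132h"), "oligo")
#' tree_split_sequence(tree)
#' @export
fit_tree <- function(data, predictors, response, min_leaf = 5L,
                     forced_root = NULL) {
  if (nrow(data) == 0) stop("empty cohort")
  for (v in c(predictors, response)) {
    if (!v %in% names(data)) stop("unknown variable: ", v)
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) != 2 && v != response)
      stop("predictor ", v, " is not binary")
  }
  if (nlevels(data[[response]]) > 2)
    stop("response must have at most two levels")
  classes <- levels(data[[response]])
  prior <- response_counts(data[[response]], classes) / nrow(data)
  min_leaf <- as.integer(min_leaf)

  grow <- function(idx, available, depth) {
    counts <- response_counts(data[[response]][idx], classes)
    node <- list(
      depth = depth,
      n = length(idx),
      counts = counts,
      prob = leaf_probability(counts, prior, "laplace_prior"),
      split_var = NULL,
      g2 = NA_real_,
      children = NULL
    )
    forced_var <- if (!is.null(forced_root) && depth <= length(forced_root))
      forced_root[depth] else NULL
    candidates <- if (!is.null(forced_var)) {
      if (!forced_var %in% available) character(0) else forced_var
    } else available

    best_var <- NULL; best_g2 <- 0
    for (v in candidates) {
      lv <- levels(data[[v]])
      left <- idx[data[[v]][idx] == lv[1]]
      right <- idx[data[[v]][idx] == lv[2]]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      g2 <- split_score(counts,
                        response_counts(data[[response]][left], classes),
                        response_counts(data[[response]][right], classes))
      if (g2 > best_g2) { best_g2 <- g2; best_var <- v }
    }
    if (is.null(best_var)) return(node)

    lv <- levels(data[[best_var]])
    node$split_var <- best_var
    node$g2 <- best_g2
    remaining <- setdiff(available, best_var)
    node$children <- stats::setNames(list(
      grow(idx[data[[best_var]][idx] == lv[1]], remaining, depth + 1L),
      grow(idx[data[[best_var]][idx] == lv[2]], remaining, depth + 1L)
    ), lv)
    node
  }

  structure(list(
    root = grow(seq_len(nrow(data)), predictors, 1L),
    predictors = predictors,
    response = response,
    classes = classes,
    prior = prior,
    min_leaf = min_leaf,
    forced_root = forced_root
  ), class = "partition_tree")
}

#' Smoothed per-class leaf probabilities
#'
#' `raw` returns the empirical class fractions `n_c / N`; `laplace_prior`
#' (the default used by fitted trees) shrinks toward the root prior with
#' one pseudo-observation, `(n_c + prior_c) / (N + 1)`, so pure leaves
#' report probabilities slightly below 1 (in the spirit of published
#' probability scores such as 0.9835, whose exact smoothing formula is
#' not public and is not claimed to be matched).
#'
#' @param leaf_counts non-negative per-class counts, total > 0.
#' @param prior per-class prior proportions (sums to 1).
#' @param smoothing `"laplace_prior"` or `"raw"`.
#' @return Numeric vector of probabilities summing to 1.
#' @examples
#' leaf_probability(c(10, 0), c(0.5, 0.5), "laplace_prior")  # 10.5/11, 0.5/11
#' @export
leaf_probability <- function(leaf_counts, prior,
                             smoothing = c("laplace_prior", "raw")) {
  smoothing <- match.arg(smoothing)
  leaf_counts <- as.numeric(leaf_counts)
  if (sum(leaf_counts) <= 0) stop("empty leaf")
  if (smoothing == "raw") return(leaf_counts / sum(leaf_counts))
  (leaf_counts + prior) / (sum(leaf_counts) + 1)
}

#' Predict the class of a marker profile
#'
#' Routes a complete marker profile down the fitted tree and returns the
#' leaf's majority class (argmax of the smoothed class probabilities) and
#' its probability.
#'
#' @param object a fitted [fit_tree()] tree.
#' @param profile named list / character vector (or 1-row `data.frame`)
#'   with one value per predictor the tree tests on the routed path.
#' @param ... unused.
#' @return List with `class`, `probability`, `counts` and `prob` (the full
#'   smoothed leaf distribution).
#' @export
predict.partition_tree <- function(object, profile, ...) {
  if (is.data.frame(profile)) profile <- as.list(profile[1, , drop = FALSE])
  profile <- lapply(profile, as.character)
  node <- object$root
  while (!is.null(node$split_var)) {
    v <- node$split_var
    val <- profile[[v]]
    if (is.null(val)) stop("profile is missing tested variable: ", v)
    if (!val %in% names(node$children))
      stop("unknown level '", val, "' for variable ", v)
    node <- node$children[[val]]
  }
  k <- which.max(node$prob)
  list(class = object$classes[k],
       probability = unname(node$prob[k]),
       counts = node$counts,
       prob = node$prob)
}

#' Split variables of a fitted tree in breadth-first order
#'
#' @param tree a [fit_tree()] result.
#' @return Character vector of split variables, root first, then each
#'   depth left to right (children in factor-level order).
#' @export
tree_split_sequence <- function(tree) {
  queue <- list(tree$root)
  out <- character(0)
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    if (!is.null(node$split_var)) {
      out <- c(out, node$split_var)
      queue <- c(queue, unname(node$children))
    }
  }
  out
}

#' Fetch the node reached by a sequence of split values
#'
#' Walks from the root taking the child named by each element of `path`
#' in turn; errors if a leaf is reached early or a value does not name a
#' child.
#'
#' @param tree a [fit_tree()] result.
#' @param path character vector of child names, e.g. `c("POS",
#'   "RETAINED")`.
#' @return The tree node (list with `counts`, `prob`, `n`, ...).
#' @export
tree_node <- function(tree, path) {
  node <- tree$root
  for (val in path) {
    if (is.null(node$split_var))
      stop("reached a leaf before consuming the whole path")
    if (!val %in% names(node$children))
      stop("node split on ", node$split_var, " has no child '", val, "'")
    node <- node$children[[val]]
  }
  node
}

node_to_list <- function(node, classes) {
  out <- list(
    n = node$n,
    counts = as.list(stats::setNames(node$counts, classes)),
    prob = as.list(stats::setNames(round(node$prob, 6), classes))
  )
  if (!is.null(node$split_var)) {
    out$split_var <- node$split_var
    out$g2 <- round(node$g2, 4)
    out$children <- lapply(node$children, node_to_list, classes = classes)
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' @param tree a [fit_tree()] result.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(
    response = tree$response,
    classes = tree$classes,
    predictors = tree$predictors,
    prior = as.list(stats::setNames(round(tree$prior, 6), tree$classes)),
    min_leaf = tree$min_leaf,
    forced_root = tree$forced_root,
    root = node_to_list(tree$root, tree$classes)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.partition_tree <- function(x, ...) {
  cat("Recursive-partitioning tree:", x$response, "~",
      paste(x$predictors, collapse = " + "), "\n")
  show <- function(node, prefix) {
    cat(prefix, sprintf("[%s] ", paste(node$counts, collapse = "/")))
    if (is.null(node$split_var)) {
      cat(sprintf("leaf p=%s\n",
                  paste(sprintf("%.4f", node$prob), collapse = "/")))
    } else {
      cat(sprintf("split %s (G2=%.2f)\n", node$split_var, node$g2))
      for (nm in names(node$children))
        show(node$children[[nm]], paste0(prefix, "  ", nm, ":"))
    }
  }
  show(x$root, "")
  invisible(x)
}
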