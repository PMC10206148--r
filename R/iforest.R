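#' Isolation-forest configuration
#'
#' An isolation forest scores anomalies by how quickly points isolate
#' under recursive random axis-aligned splits: anomalous feature vectors
#' separate from the bulk after few splits, so their expected path length
#' is short. `contamination` is the assumed anomaly fraction and controls
#' how many top-scoring items are flagged; it is deliberately set high
#' (0.4 by default) so that subtle, camouflaged fauna are flagged too and
#' false positives are removed in a later filtering step.
#'
#' @param n_trees number of isolation trees (>= 1).
#' @param subsample_size rows sampled per tree (psi, >= 2); the tree
#'   height limit is `ceiling(log2(psi))`.
#' @param contamination assumed anomaly fraction in (0, 0.5].
#' @param seed integer seed.
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, subsample_size = 256,
                          contamination = 0.4, seed = 1) {
  n_trees <- check_count(n_trees, "n_trees", min = 1)
  subsample_size <- check_count(subsample_size, "subsample_size", min = 2)
  check_number(contamination, "contamination", min = 0, max = 0.5,
               closed_min = FALSE)
  structure(list(n_trees = n_trees, subsample_size = subsample_size,
                 contamination = contamination, seed = as.integer(seed)),
            class = "forest_config")
}

#' Average path length of an unsuccessful BST search
#'
#' The normalising constant of the isolation-forest score:
#' `c(n) = 2 H(n-1) - 2 (n-1) / n` with `H(i) = ln(i) + gamma`
#' (Euler–Mascheroni), `c(1) = 0`. Also used as the path-length credit
#' added at truncated leaves of size `n`.
#'
#' @param n node or subsample size(s).
#' @return numeric vector of expected path lengths.
#' @export
avg_path_length <- function(n) {
  gamma <- 0.5772156649
  ifelse(n <= 1, 0, 2 * (log(n - 1) + gamma) - 2 * (n - 1) / n)
}

# Grow one isolation tree on `x[rows, ]`; returns a flat node table.
# Columns: attr, split, left, right, size, leaf (0/1). Constant attributes
# at a node are resampled up to d times before the node becomes a leaf.
grow_itree <- function(x, rows, height_limit) {
  d <- ncol(x)
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(rows, depth) {
    id <- new_node()
    nodes[[id]] <<- list(attr = 0L, split = NA_real_, left = 0L,
                         right = 0L, size = length(rows), leaf = TRUE)
    if (depth >= height_limit || length(rows) <= 1) return(id)
    attr <- NA_integer_
    for (try in seq_len(d)) {
      cand <- sample.int(d, 1)
      rng <- range(x[rows, cand])
      if (rng[2] > rng[1]) { attr <- cand; break }
    }
    if (is.na(attr)) return(id)
    split <- stats::runif(1, min(x[rows, attr]), max(x[rows, attr]))
    go_left <- x[rows, attr] < split
    if (!any(go_left) || all(go_left)) return(id)
    left <- build(rows[go_left], depth + 1)
    right <- build(rows[!go_left], depth + 1)
    nodes[[id]]$attr <<- attr
    nodes[[id]]$split <<- split
    nodes[[id]]$left <<- left
    nodes[[id]]$right <<- right
    nodes[[id]]$leaf <<- FALSE
    id
  }
  build(rows, 0)
  list(attr = vapply(nodes, `[[`, integer(1), "attr"),
       split = vapply(nodes, `[[`, numeric(1), "split"),
       left = vapply(nodes, `[[`, integer(1), "left"),
       right = vapply(nodes, `[[`, integer(1), "right"),
       size = vapply(nodes, `[[`, integer(1), "size"),
       leaf = vapply(nodes, `[[`, logical(1), "leaf"))
}

#' Fit an isolation forest
#'
#' Builds `n_trees` isolation trees, each on a uniform subsample of
#' `subsample_size` rows. At every internal node a uniformly random
#' attribute is split at a uniformly random value between that
#' attribute's minimum and maximum within the node; growth stops at the
#' height limit `ceiling(log2(psi))` or at singleton nodes.
#'
#' @param features numeric matrix (rows = patches, >= 2 rows) or the
#'   output of [encode_patches()].
#' @param config a [forest_config()]. If `subsample_size` exceeds the row
#'   count it is lowered to it with a warning.
#' @return object of class `isolation_forest`.
#' @export
fit_iforest <- function(features, config = forest_config()) {
  features <- as.matrix(features)
  if (nrow(features) < 2) {
    stop("`features` needs at least 2 rows", call. = FALSE)
  }
  if (!inherits(config, "forest_config")) {
    stop("`config` must be created by forest_config()", call. = FALSE)
  }
  psi <- config$subsample_size
  if (psi > nrow(features)) {
    warning(sprintf("subsample_size %d exceeds n = %d rows; using n",
                    psi, nrow(features)))
    psi <- nrow(features)
  }
  height_limit <- ceiling(log2(psi))
  with_seed(derive_seed(config$seed, "fit_iforest"), {
    trees <- lapply(seq_len(config$n_trees), function(i) {
      rows <- sample.int(nrow(features), psi, replace = FALSE)
      grow_itree(features, rows, height_limit)
    })
    structure(list(trees = trees, psi = psi, n_features = ncol(features),
                   config = config),
              class = "isolation_forest")
  })
}

# Vectorised tree traversal: mean depth (with c(size) leaf credit) for
# every row of x under one tree.
tree_path_length <- function(tree, x) {
  n <- nrow(x)
  depth_out <- numeric(n)
  # iterative routing: (node, depth, member rows)
  queue <- list(list(node = 1L, depth = 0, rows = seq_len(n)))
  while (length(queue)) {
    item <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    nd <- item$node
    if (tree$leaf[nd]) {
      depth_out[item$rows] <- item$depth + avg_path_length(tree$size[nd])
    } else {
      go_left <- x[item$rows, tree$attr[nd]] < tree$split[nd]
      if (any(go_left)) {
        queue[[length(queue) + 1]] <- list(node = tree$left[nd],
                                           depth = item$depth + 1,
                                           rows = item$rows[go_left])
      }
      if (any(!go_left)) {
        queue[[length(queue) + 1]] <- list(node = tree$right[nd],
                                           depth = item$depth + 1,
                                           rows = item$rows[!go_left])
      }
    }
  }
  depth_out
}

#' Score feature vectors with a fitted isolation forest
#'
#' Anomaly score `s(x) = 2^(-E[h(x)] / c(psi))` where `E[h(x)]` is the
#' mean path length over trees and `c` is [avg_path_length()]. Scores lie
#' in (0, 1) and are strictly decreasing in the mean path length; a score
#' near 1 means the point isolates almost immediately.
#'
#' @param forest a fitted [fit_iforest()] model.
#' @param features numeric matrix with the same number of columns the
#'   forest was fitted on.
#' @return tibble `patch_id, mean_depth, score` in input row order.
#' @export
score_iforest <- function(forest, features) {
  if (!inherits(forest, "isolation_forest")) {
    stop("`forest` must be a fitted isolation_forest", call. = FALSE)
  }
  features <- as.matrix(features)
  if (ncol(features) != forest$n_features) {
    stop(sprintf("feature dimension %d does not match the forest's %d",
                 ncol(features), forest$n_features), call. = FALSE)
  }
  depths <- vapply(forest$trees, tree_path_length, numeric(nrow(features)),
                   x = features)
  if (nrow(features) == 1) depths <- matrix(depths, nrow = 1)
  mean_depth <- rowMeans(depths)
  tibble::tibble(
    patch_id = rownames(features) %||%
      sprintf("p%06d", seq_len(nrow(features))),
    mean_depth = mean_depth,
    score = 2^(-mean_depth / avg_path_length(forest$psi)))
}

#' Flag the top-scoring fraction as anomalous
#'
#' Flags exactly `ceiling(contamination * n)` highest-scoring items; ties
#' are broken by `patch_id` (ascending) so the flag set is deterministic.
#'
#' @param results tibble from [score_iforest()] (non-empty, with
#'   `patch_id` and `score`).
#' @param contamination fraction in (0, 0.5].
#' @return `results` with a logical `flagged` column.
#' @export
flag_by_contamination <- function(results, contamination = 0.4) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  check_number(contamination, "contamination", min = 0, max = 0.5,
               closed_min = FALSE)
  k <- ceiling(contamination * nrow(results))
  ord <- order(-results$score, results$patch_id)
  flagged <- logical(nrow(results))
  flagged[ord[seq_len(k)]] <- TRUE
  dplyr::mutate(tibble::as_tibble(results), flagged = flagged)
}
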