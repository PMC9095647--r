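#' Exact k-nearest-neighbor graph
#'
#' Euclidean k-NN on the supplied feature columns, computed exactly
#' (blockwise all-pairs distances); self is excluded and distance ties are
#' broken by cell index (deterministic).
#'
#' @param x Numeric matrix (cells x features) or cell table.
#' @param k Number of neighbors, `k < n`.
#' @param features Feature columns when `x` is a table.
#' @param block Number of query rows per distance block.
#' @return A `neighbor_graph`: list with `indices` (n x k integer matrix)
#'   and `k`.
#' @export
build_knn <- function(x, k, features = NULL, block = 512L) {
  m <- .as_feature_matrix(x, features)$mat
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  sq <- rowSums(m^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * m[rows, , drop = FALSE] %*% t(m)
    for (i in seq_along(rows)) {
      d <- d2[i, ]
      d[rows[i]] <- Inf
      # order() is stable: equal distances resolve to the lower index
      idx[rows[i], ] <- order(d)[seq_len(k)]
    }
  }
  structure(list(indices = idx, k = as.integer(k)), class = "neighbor_graph")
}

#' kBET batch-mixing rejection rate
#'
#' For each of `n_subsets` randomly chosen cells, the batch-label counts in
#' its neighborhood (the cell plus its `k` nearest neighbors, `k + 1` cells)
#' are compared with the global batch proportions by a Pearson chi-squared
#' test with `B - 1` degrees of freedom (expected counts = global
#' proportions times `k + 1`, no continuity correction). The rejection rate
#' is the fraction of neighborhoods with `p < alpha`: 0 indicates perfect
#' batch mixing, 1 no mixing.
#'
#' @param graph A `neighbor_graph` from [build_knn()].
#' @param batch_labels Batch label per cell (>= 2 batches).
#' @param alpha Test level (default 0.05).
#' @param n_subsets Number of sampled neighborhoods (default 100).
#' @param seed Seed for neighborhood sampling.
#' @return A `kbet_result`: `rejection_rate`, `alpha`, `k`, `n_subsets`,
#'   `seed`, and the per-subset `p_values`.
#' @export
kbet_rejection_rate <- function(graph, batch_labels, alpha = 0.05,
                                n_subsets = 100L, seed = 1L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  batch_labels <- as.character(batch_labels)
  n <- nrow(graph$indices)
  if (length(batch_labels) != n)
    stop("batch_labels must have one label per cell", call. = FALSE)
  batches <- sort(unique(batch_labels))
  if (length(batches) < 2) stop("need at least 2 batches", call. = FALSE)
  if (graph$k < 10)
    warning("k < 10 gives an unstable chi-squared test", call. = FALSE)
  props <- as.vector(table(factor(batch_labels, batches))) / n
  expected <- props * (graph$k + 1)
  anchors <- with_local_seed(seed,
    sample.int(n, n_subsets, replace = n_subsets > n))
  pv <- vapply(anchors, function(a) {
    hood <- c(a, graph$indices[a, ])
    obs <- as.vector(table(factor(batch_labels[hood], batches)))
    stat <- sum((obs - expected)^2 / expected)
    pchisq(stat, df = length(batches) - 1, lower.tail = FALSE)
  }, 0)
  structure(list(rejection_rate = mean(pv < alpha), alpha = alpha,
                 k = graph$k, n_subsets = as.integer(n_subsets),
                 seed = seed, p_values = pv), class = "kbet_result")
}

#' @export
print.kbet_result <- function(x, ...) {
  cat(sprintf("<kbet_result> rejection rate %.3f (k=%d, alpha=%g, %d subsets)\n",
              x$rejection_rate, x$k, x$alpha, x$n_subsets))
  invisible(x)
}

#' Default kBET neighborhood size
#'
#' `floor(mean batch size / 4)`, capped at `n - 1`.
#'
#' @param batch_labels Batch label per cell.
#' @return Integer k.
#' @export
kbet_default_k <- function(batch_labels) {
  n <- length(batch_labels)
  k <- floor(mean(table(batch_labels)) / 4)
  as.integer(max(1, min(k, n - 1)))
}

#' Stratified cell sampling
#'
#' Samples exactly `n_per_group` cells without replacement from every
#' combination of the grouping keys (e.g. 600 cells per TMA core per batch,
#' giving 5400 cells for 3 cores x 3 batches).
#'
#' @param table Cell table.
#' @param n_per_group Cells per group (default 600).
#' @param group_keys Grouping columns (default `core_id`, `batch_id`).
#' @param seed Sampling seed.
#' @return The sampled table (row order: groups in sorted order).
#' @export
stratified_sample <- function(table, n_per_group = 600L,
                              group_keys = c("core_id", "batch_id"),
                              seed = 1L) {
  g <- interaction(table[, group_keys, drop = FALSE], sep = ":", drop = TRUE)
  sizes <- table(g)
  bad <- names(sizes)[sizes < n_per_group]
  if (length(bad))
    stop("groups with fewer than ", n_per_group, " cells: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- with_local_seed(seed, unlist(lapply(levels(g), function(lv) {
    i <- which(g == lv)
    if (length(i) == n_per_group) i else i[sample.int(length(i), n_per_group)]
  })))
  table[rows, , drop = FALSE]
}

#' Graph-based cell clustering
#'
#' Leiden community detection (modularity objective, `resolution` as in the
#' standard single-cell workflow, default 0.6) on the exact k-NN graph of
#' the feature columns. Cluster ids are 0-based and contiguous; results are
#' deterministic under a fixed seed. Run once on the pooled normalized
#' table so replicate sections share one cluster label space.
#'
#' @param x Numeric matrix (cells x features) or cell table.
#' @param resolution Leiden resolution parameter.
#' @param k Neighbors for the graph; default 15.
#' @param features Feature columns when `x` is a table.
#' @param seed Clustering seed.
#' @return Integer vector of 0-based cluster labels.
#' @export
cluster_cells <- function(x, resolution = 0.6, k = 15L, features = NULL,
                          seed = 1L) {
  m <- .as_feature_matrix(x, features)$mat
  n <- nrow(m)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (n == 2) return(c(0L, 0L))
  k <- min(k, n - 1L)
  g <- build_knn(m, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(g$indices)))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::simplify(ig)
  memb <- with_local_seed(seed, igraph::membership(
    igraph::cluster_leiden(ig, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5)))
  as.integer(factor(as.integer(memb))) - 1L
}

#' Cluster-composition correlation between replicates
#'
#' Within each unit (e.g. TMA core), the per-replicate composition vector
#' (fraction of the unit's cells in each cluster, summing to 1) is computed
#' over the shared cluster label space, and the Pearson correlation of the
#' vectors is reported for every replicate pair (3 cores x 3 sections give
#' n = 9 values).
#'
#' @param labels Cluster labels (shared space across replicates).
#' @param replicate_ids Replicate (section/batch) id per cell.
#' @param unit_ids Unit (core) id per cell.
#' @return Data frame `unit, replicate_a, replicate_b, r`.
#' @export
cluster_composition_correlation <- function(labels, replicate_ids, unit_ids) {
  labels <- as.character(labels)
  replicate_ids <- as.character(replicate_ids)
  unit_ids <- as.character(unit_ids)
  reps <- sort(unique(replicate_ids))
  if (length(reps) < 2) stop("need at least 2 replicates", call. = FALSE)
  units <- sort(unique(unit_ids))
  clus <- sort(unique(labels))
  comp <- function(u, r) {
    sel <- unit_ids == u & replicate_ids == r
    if (!any(sel)) stop(sprintf("unit %s absent from replicate %s", u, r),
                        call. = FALSE)
    as.vector(table(factor(labels[sel], clus))) / sum(sel)
  }
  out <- list()
  for (u in units) {
    vecs <- lapply(reps, comp, u = u)
    for (i in seq_len(length(reps) - 1)) for (j in (i + 1):length(reps)) {
      out[[length(out) + 1L]] <- data.frame(
        unit = u, replicate_a = reps[i], replicate_b = reps[j],
        r = cor(vecs[[i]], vecs[[j]]))
    }
  }
  do.call(rbind, out)
}
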