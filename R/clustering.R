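#' Cluster cells from a filtered UMI count matrix
#'
#' The standard graph-based pipeline: library-size log-normalization
#' ([normalize_counts()]), selection of the most variable genes, z-scaling,
#' PCA, a shared-nearest-neighbour (SNN) graph with Jaccard edge weights, and
#' modularity (Louvain) community detection. Deterministic given `seed`.
#'
#' Two hooks make the pipeline pluggable: `batch_correct` receives the PCA
#' embedding plus the cell metadata and returns a corrected embedding
#' (identity when `NULL`) — this realises the contrast between clustering
#' with and without day/night batch normalization; `variable_genes` fixes the
#' gene list instead of re-selecting it, which is how robustness replicates
#' reuse the original clustering's genes.
#'
#' @param m A filtered, non-empty [umi_counts()] object.
#' @param n_variable_genes Number of variable genes to select.
#' @param n_pcs Number of principal components.
#' @param k_neighbors Neighbourhood size of the SNN graph; must be smaller
#'   than the number of cells.
#' @param resolution Louvain modularity resolution.
#' @param max_clusters Optional cap: if community detection returns more
#'   clusters, the closest cluster centroids (in PC space) are merged
#'   hierarchically down to this many.
#' @param snn_prune SNN edges with Jaccard weight below this are dropped.
#' @param variable_genes Optional fixed character vector of genes to use.
#' @param batch_correct Optional `function(embedding, cell_meta)` returning a
#'   corrected embedding, e.g. [batch_center()].
#' @param seed Integer seed.
#' @return A `cluster_assignment`: a tibble (`cell`, `cluster`) with integer
#'   cluster labels 1..K ordered by decreasing size, carrying the variable
#'   gene list, parameters and seed as attributes.
#' @export
cluster_cells <- function(m,
                          n_variable_genes = 100,
                          n_pcs = 10,
                          k_neighbors = 20,
                          resolution = 1,
                          max_clusters = Inf,
                          snn_prune = 1 / 15,
                          variable_genes = NULL,
                          batch_correct = NULL,
                          seed = 1L) {
  stopifnot(inherits(m, "umi_counts"))
  n_cells <- nrow(m$counts)
  if (n_cells == 0) abort("Cannot cluster an empty matrix.")
  if (n_cells <= k_neighbors) {
    abort(sprintf("Fewer cells (%d) than requested neighbours (%d).",
                  n_cells, k_neighbors),
          class = "dielsc_config_error")
  }

  X <- normalize_counts(m)
  if (is.null(variable_genes)) {
    v <- apply(X, 2, var)
    variable_genes <- names(sort(v, decreasing = TRUE))[
      seq_len(min(n_variable_genes, ncol(X)))]
  } else {
    missing <- setdiff(variable_genes, colnames(X))
    if (length(missing)) {
      abort(paste0("`variable_genes` not in matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  Xv <- scale(X[, variable_genes, drop = FALSE])
  Xv[!is.finite(Xv)] <- 0

  n_pcs <- min(n_pcs, ncol(Xv), n_cells - 1L)
  emb <- prcomp(Xv, rank. = n_pcs, center = FALSE, scale. = FALSE)$x
  if (!is.null(batch_correct)) emb <- batch_correct(emb, m$cell_meta)

  g <- snn_graph(emb, k = k_neighbors, prune = snn_prune)
  membership <- with_seed(as.integer(seed), {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  labels <- as.integer(membership)

  if (is.finite(max_clusters) && max(labels) > max_clusters) {
    centroids <- rowsum(emb, labels) / as.vector(table(labels))
    merged <- cutree(hclust(dist(centroids), method = "average"),
                     k = max_clusters)
    labels <- merged[labels]
  }
  # stable relabelling: 1..K by decreasing size
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  labels <- unname(relabel[as.character(labels)])

  out <- tibble(cell = rownames(m$counts), cluster = labels)
  attr(out, "variable_genes") <- variable_genes
  attr(out, "params") <- list(n_variable_genes = n_variable_genes,
                              n_pcs = n_pcs, k_neighbors = k_neighbors,
                              resolution = resolution,
                              max_clusters = max_clusters,
                              snn_prune = snn_prune)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cluster_assignment", class(out))
  out
}

# shared-nearest-neighbour graph with Jaccard weights (Seurat-style)
snn_graph <- function(emb, k, prune = 1 / 15) {
  n <- nrow(emb)
  d <- as.matrix(dist(emb))
  # neighbour sets include the cell itself
  nb <- apply(d, 1, function(r) order(r)[seq_len(k + 1L)], simplify = FALSE)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) adj[i, nb[[i]]] <- 1L
  shared <- adj %*% t(adj)
  union <- 2L * (k + 1L) - shared
  w <- shared / union
  # only keep edges between graph neighbours, prune weak ones
  cand <- (adj + t(adj)) > 0
  w[!cand] <- 0
  w[w < prune] <- 0
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE)
}

#' Batch-centering correction hook
#'
#' A simple batch-normalization hook for [cluster_cells()]: centres the PCA
#' embedding per batch (column means subtracted within each level of
#' `batch_col`), removing the consistent global day/night shift so cells
#' cluster by tissue identity rather than harvest time.
#'
#' @param batch_col Name of the `cell_meta` column holding the batch
#'   (default `"timepoint"`).
#' @return A `function(embedding, cell_meta)` suitable for the
#'   `batch_correct` argument of [cluster_cells()].
#' @export
batch_center <- function(batch_col = "timepoint") {
  force(batch_col)
  function(emb, cell_meta) {
    b <- cell_meta[[batch_col]]
    if (is.null(b)) abort(sprintf("No `%s` column in cell metadata.", batch_col))
    for (lev in unique(b)) {
      idx <- b == lev
      emb[idx, ] <- sweep(emb[idx, , drop = FALSE], 2,
                          colMeans(emb[idx, , drop = FALSE]))
    }
    emb
  }
}

#' Coerce a cell/cluster table to a cluster assignment
#'
#' @param x A data frame with `cell` and `cluster` columns.
#' @return A `cluster_assignment` tibble.
#' @export
as_cluster_assignment <- function(x) {
  stopifnot(is.data.frame(x), all(c("cell", "cluster") %in% names(x)))
  out <- as_tibble(x[, c("cell", "cluster")])
  out$cluster <- as.integer(out$cluster)
  if (anyDuplicated(out$cell)) abort("Every cell must have exactly one label.")
  if (!inherits(out, "cluster_assignment")) {
    class(out) <- c("cluster_assignment", class(out))
  }
  out
}

#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(cell = x$cell, cluster = x$cluster)
}

#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  sizes <- table(x$cluster)
  tibble(n_cells = nrow(x), n_clusters = length(sizes),
         min_cluster_size = as.integer(min(sizes)),
         max_cluster_size = as.integer(max(sizes)),
         seed = attr(x, "seed") %||% NA_integer_)
}

#' Variable genes recorded in a cluster assignment
#' @param clusters A `cluster_assignment`.
#' @return Character vector of gene names.
#' @export
cluster_variable_genes <- function(clusters) attr(clusters, "variable_genes")
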