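#' Ground truth for a synthetic diel single-cell experiment
#'
#' Builds the planted truth that the read and count simulators realise and
#' that parameter-recovery tests check against: the cell-to-cluster map, the
#' end-of-day / end-of-night (ED/EN) batch of every cell, planted marker genes
#' per cluster, planted di-cistronic read support per gene pair, per-cluster
#' tRNA-like-sequence (TLS) read-through fractions, and designated low-depth
#' and high-plastid cells.
#'
#' Cells are identified by unique 12-nt barcodes (Drop-seq convention).
#' Marker genes use the same `G%04d` naming scheme as [simulate_counts()],
#' cluster `k` owning genes `(k-1)*n_markers_per_cluster + 1, ...`.
#'
#' @param n_cells_per_cluster Integer vector of cluster sizes (recycled to
#'   `n_clusters`).
#' @param n_clusters Number of clusters.
#' @param n_markers_per_cluster Planted marker genes per cluster.
#' @param timepoint_design `"balanced"` assigns ED/EN alternately within each
#'   cluster; `"by_cluster"` makes the harvest time drive the clusters (odd
#'   clusters ED, even clusters EN).
#' @param n_replicates Number of replicates cells are cycled through.
#' @param n_low_depth Number of cells to plant below the depth filter.
#' @param n_high_plastid Number of cells to plant above the plastid filter
#'   (disjoint from the low-depth set).
#' @param dicistronic_pairs Optional tibble `gene_a`, `gene_b`, `support`
#'   of planted read-through pairs (gene ids must exist in the annotation
#'   passed to [simulate_reads()]).
#' @param tls_fractions Optional numeric vector, one fraction in \[0, 1\] per
#'   cluster, of host-gene molecules that read through into the tRNA.
#' @param seed Integer seed; all downstream simulators derive their random
#'   streams from it.
#'
#' @return An object of class `sim_truth`: a list with elements `cells`
#'   (tibble: `cell`, `cluster`, `timepoint`, `replicate`, `low_depth`,
#'   `high_plastid`), `markers` (tibble: `gene`, `cluster`),
#'   `dicistronic_pairs`, `tls_fractions` (tibble: `cluster`,
#'   `tls_fraction`) and `seed`.
#' @export
#' @examples
#' tr <- sim_truth(n_cells_per_cluster = c(40, 40), tls_fractions = c(0.1, 0),
#'                 seed = 7)
#' head(tr$cells)
sim_truth <- function(n_cells_per_cluster = 100,
                      n_clusters = length(n_cells_per_cluster),
                      n_markers_per_cluster = 10,
                      timepoint_design = c("balanced", "by_cluster"),
                      n_replicates = 1,
                      n_low_depth = 0,
                      n_high_plastid = 0,
                      dicistronic_pairs = NULL,
                      tls_fractions = NULL,
                      seed = 1L) {
  timepoint_design <- match.arg(timepoint_design)
  n_clusters <- check_count(n_clusters, "n_clusters")
  n_markers_per_cluster <- check_count(n_markers_per_cluster,
                                       "n_markers_per_cluster")
  n_low_depth <- check_count(n_low_depth, "n_low_depth")
  n_high_plastid <- check_count(n_high_plastid, "n_high_plastid")
  sizes <- as.integer(rep_len(n_cells_per_cluster, n_clusters))
  stopifnot(all(sizes >= 0))
  n_cells <- sum(sizes)
  if (n_low_depth + n_high_plastid > n_cells) {
    abort("More planted low-depth/high-plastid cells than cells.",
          class = "dielsc_argument_error")
  }
  if (!is.null(tls_fractions)) {
    stopifnot(length(tls_fractions) == n_clusters,
              all(tls_fractions >= 0 & tls_fractions <= 1))
  }
  if (!is.null(dicistronic_pairs)) {
    stopifnot(is.data.frame(dicistronic_pairs),
              all(c("gene_a", "gene_b", "support") %in% names(dicistronic_pairs)),
              all(dicistronic_pairs$support >= 0))
  }

  with_seed(as.integer(seed), {
    cluster <- rep(seq_len(n_clusters), sizes)
    timepoint <- switch(timepoint_design,
      balanced = unlist(lapply(sizes, function(s)
        rep_len(c("ED", "EN"), s)), use.names = FALSE),
      by_cluster = ifelse(cluster %% 2L == 1L, "ED", "EN")
    )
    cells <- tibble(
      cell = unique_barcodes(n_cells),
      cluster = cluster,
      timepoint = if (n_cells) timepoint else character(),
      replicate = if (n_cells) rep_len(seq_len(max(1L, as.integer(n_replicates))),
                                       n_cells) else integer(),
      low_depth = FALSE,
      high_plastid = FALSE
    )
    special <- sample(n_cells, n_low_depth + n_high_plastid)
    cells$low_depth[special[seq_len(n_low_depth)]] <- TRUE
    if (n_high_plastid > 0) {
      cells$high_plastid[special[n_low_depth + seq_len(n_high_plastid)]] <- TRUE
    }

    markers <- tibble(
      gene = sprintf("G%04d", seq_len(n_clusters * n_markers_per_cluster)),
      cluster = rep(seq_len(n_clusters), each = n_markers_per_cluster)
    )

    structure(
      list(
        cells = cells,
        markers = markers,
        dicistronic_pairs = dicistronic_pairs,
        tls_fractions = if (is.null(tls_fractions)) NULL else
          tibble(cluster = seq_len(n_clusters),
                 tls_fraction = as.numeric(tls_fractions)),
        seed = as.integer(seed)
      ),
      class = "sim_truth"
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d cells, %d clusters, %d planted markers, seed %d\n",
    nrow(x$cells), length(unique(x$cells$cluster)), nrow(x$markers), x$seed))
  if (!is.null(x$dicistronic_pairs)) {
    cat(sprintf("  planted di-cistronic pairs: %d\n", nrow(x$dicistronic_pairs)))
  }
  if (!is.null(x$tls_fractions)) {
    cat("  TLS fractions:",
        paste(sprintf("%d:%.2f", x$tls_fractions$cluster,
                      x$tls_fractions$tls_fraction), collapse = " "), "\n")
  }
  invisible(x)
}

#' Planted cluster labels as a cluster assignment
#'
#' Convenience accessor turning the planted truth into the same tabular shape
#' [cluster_cells()] returns, so truth labels can be fed to
#' [find_markers()], [time_composition()] or [tls_cluster_enrichment()].
#'
#' @param truth A [sim_truth()] object.
#' @return A `cluster_assignment` tibble (`cell`, `cluster`).
#' @export
truth_clusters <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  as_cluster_assignment(truth$cells[, c("cell", "cluster")])
}
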