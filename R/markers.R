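#' One-vs-rest Wilcoxon marker genes
#'
#' For every cluster, each gene is compared between in-cluster cells and all
#' other cells with a two-sided Wilcoxon rank-sum test on log-normalized
#' expression ([normalize_counts()]). The reported fold change is
#' `ln(mean_in + eps) - ln(mean_out + eps)` of the counts-per-10k means. A
#' gene is only tested when it clears the pre-screen (expressed in at least
#' `min_pct` of cells on one side, and `|log_fc| >= logfc_min`); it is
#' flagged as a marker when additionally `p_adj < alpha`, `log_fc >=
#' logfc_min` and `pct_in >= min_pct`. The default thresholds are fold
#' change 0.25 (natural log), minimum expressing fraction 5% and adjusted
#' p below 0.05.
#'
#' P-values are exact (rank-sum enumeration) when both groups have at most 8
#' cells and the data are tie-free, and use the tie-corrected normal
#' approximation with continuity correction otherwise. Adjustment is
#' Bonferroni over the full gene set of `m` per cluster (`"BH"` available).
#' Clusters with fewer than 3 cells on either side are skipped with a
#' warning.
#'
#' @param m A [umi_counts()] object.
#' @param clusters A `cluster_assignment` covering the cells of `m`.
#' @param logfc_min Minimum natural-log fold change.
#' @param min_pct Minimum expressing fraction.
#' @param alpha Adjusted-p significance threshold.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @param eps Pseudocount inside the fold-change logs.
#' @return A marker tibble: `gene`, `cluster`, `log_fc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj`, `is_marker` (only pre-screened genes appear).
#' @export
find_markers <- function(m, clusters,
                         logfc_min = 0.25,
                         min_pct = 0.05,
                         alpha = 0.05,
                         p_adjust = c("bonferroni", "BH"),
                         eps = 1e-9) {
  stopifnot(inherits(m, "umi_counts"))
  p_adjust <- match.arg(p_adjust)
  lab <- setNames(clusters$cluster, clusters$cell)
  cells <- intersect(rownames(m$counts), clusters$cell)
  if (length(unique(lab[cells])) < 2) {
    abort("Need at least two clusters.", class = "dielsc_argument_error")
  }
  X <- normalize_counts(subset_cells(m, cells))
  E <- expm1(X)
  n_genes_total <- ncol(X)
  lab <- lab[cells]

  res <- lapply(sort(unique(lab)), function(k) {
    in_k <- lab == k
    if (sum(in_k) < 3 || sum(!in_k) < 3) {
      warn(sprintf("Cluster %s skipped: fewer than 3 cells on one side.", k))
      return(NULL)
    }
    pct_in <- colMeans(X[in_k, , drop = FALSE] > 0)
    pct_out <- colMeans(X[!in_k, , drop = FALSE] > 0)
    mean_in <- colMeans(E[in_k, , drop = FALSE])
    mean_out <- colMeans(E[!in_k, , drop = FALSE])
    log_fc <- log(mean_in + eps) - log(mean_out + eps)
    tested <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(log_fc) >= logfc_min
    if (!any(tested)) return(NULL)
    use_exact <- sum(in_k) <= 8 && sum(!in_k) <= 8
    p <- vapply(which(tested), function(g) {
      suppressWarnings(
        wilcox.test(X[in_k, g], X[!in_k, g], alternative = "two.sided",
                    exact = use_exact)$p.value
      )
    }, numeric(1))
    tibble(
      gene = colnames(X)[tested],
      cluster = k,
      log_fc = unname(log_fc[tested]),
      pct_in = unname(pct_in[tested]),
      pct_out = unname(pct_out[tested]),
      p = unname(p),
      p_adj = p.adjust(p, method = p_adjust, n = n_genes_total)
    )
  })
  empty <- tibble(gene = character(), cluster = integer(),
                  log_fc = numeric(), pct_in = numeric(),
                  pct_out = numeric(), p = numeric(), p_adj = numeric())
  bind_rows(empty, res) |>
    mutate(is_marker = .data$p_adj < alpha &
             .data$log_fc >= logfc_min &
             .data$pct_in >= min_pct) |>
    arrange(.data$cluster, .data$p_adj, desc(.data$log_fc))
}

#' Marker gene sets per cluster
#'
#' @param markers A marker tibble from [find_markers()] (rows with
#'   `is_marker` are used when the column exists) or a named list of
#'   character vectors, passed through.
#' @return Named list of character vectors, one per cluster.
#' @export
marker_sets <- function(markers) {
  if (is.list(markers) && !is.data.frame(markers)) {
    stopifnot(all(vapply(markers, is.character, logical(1))))
    return(markers)
  }
  stopifnot(is.data.frame(markers), all(c("gene", "cluster") %in% names(markers)))
  if ("is_marker" %in% names(markers)) markers <- filter(markers, .data$is_marker)
  split(markers$gene, markers$cluster)
}

#' Jaccard overlap of marker sets between two clusterings
#'
#' For every pair of clusters across the two clusterings, the Jaccard index
#' `J = |A intersect B| / |A union B|` of their marker gene sets, with the
#' intersection size reported alongside. A pair of two empty sets has `J`
#' defined as 0 and is flagged.
#'
#' @param markers_a,markers_b Marker tibbles from [find_markers()] or named
#'   lists of marker gene sets (see [marker_sets()]).
#' @return A long tibble: `cluster_a`, `cluster_b`, `n_a`, `n_b`,
#'   `n_intersect`, `n_union`, `jaccard`, `both_empty`.
#' @export
jaccard_overlap <- function(markers_a, markers_b) {
  a <- marker_sets(markers_a)
  b <- marker_sets(markers_b)
  if (is.null(names(a))) names(a) <- seq_along(a)
  if (is.null(names(b))) names(b) <- seq_along(b)
  grid <- expand.grid(cluster_a = names(a), cluster_b = names(b),
                      stringsAsFactors = FALSE)
  pmap(grid, function(cluster_a, cluster_b) {
    A <- unique(a[[cluster_a]])
    B <- unique(b[[cluster_b]])
    ni <- length(intersect(A, B))
    nu <- length(union(A, B))
    tibble(cluster_a = cluster_a, cluster_b = cluster_b,
           n_a = length(A), n_b = length(B),
           n_intersect = ni, n_union = nu,
           jaccard = if (nu == 0) 0 else ni / nu,
           both_empty = nu == 0)
  }) |>
    list_rbind()
}
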