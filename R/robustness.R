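#' Binomially thin a UMI count matrix
#'
#' Desk-scale surrogate for subsampling library reads before the pipeline:
#' every count `c` is replaced by a `Binomial(c, fraction)` draw, preserving
#' each molecule's inclusion probability. Cell and gene sets are unchanged.
#'
#' @param m A [umi_counts()] object.
#' @param fraction Retention probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A thinned `umi_counts` object.
#' @export
subsample_counts <- function(m, fraction, seed = 1L) {
  stopifnot(inherits(m, "umi_counts"))
  fraction <- check_fraction(fraction, "fraction")
  counts <- m$counts
  with_seed(as.integer(seed), {
    counts@x <- as.numeric(rbinom(length(counts@x), counts@x, fraction))
  })
  counts <- Matrix::drop0(counts)
  umi_counts(counts, m$cell_meta, m$gene_meta)
}

#' Per-cluster co-occurrence between two cell partitions
#'
#' For every cluster `C` of `original`, the fraction of its cells that stay
#' together in a single cluster of `replicate`. Two metrics:
#'
#' * `"best_match"` (default): `max over C' of |C intersect C'| / |C|` —
#'   best-match containment; a cluster wholly absorbed into a merged
#'   replicate cluster scores 1.
#' * `"pairwise"`: fraction of within-`C` cell pairs assigned to a common
#'   replicate cluster.
#'
#' Both are invariant to relabelling of replicate clusters.
#'
#' @param original,replicate `cluster_assignment`s (or data frames with
#'   `cell`, `cluster`) over the same cells.
#' @param method Co-occurrence metric.
#' @return Tibble with `cluster` and `co_occurrence` in \[0, 1\].
#' @export
co_occurrence <- function(original, replicate,
                          method = c("best_match", "pairwise")) {
  method <- match.arg(method)
  rep_lab <- setNames(replicate$cluster, replicate$cell)
  if (anyNA(rep_lab[original$cell])) {
    abort("`replicate` does not label every original cell.")
  }
  tab <- table(original$cluster, rep_lab[original$cell])
  sizes <- rowSums(tab)
  score <- if (method == "best_match") {
    apply(tab, 1, max) / sizes
  } else {
    pairs_together <- rowSums(tab * (tab - 1) / 2)
    pairs_total <- sizes * (sizes - 1) / 2
    ifelse(pairs_total > 0, pairs_together / pairs_total, 1)
  }
  tibble(cluster = as.integer(rownames(tab)), co_occurrence = unname(score))
}

#' Star bin of a robustness score
#'
#' Bins are closed on the left: `[75, 100]` three stars, `[50, 75)` two,
#' `[25, 50)` one, below 25 `"none"`.
#'
#' @param score Numeric scores in \[0, 100\].
#' @return Character vector of `"***"`, `"**"`, `"*"` or `"none"`.
#' @export
robustness_stars <- function(score) {
  stopifnot(all(score >= 0 & score <= 100))
  dplyr::case_when(
    score >= 75 ~ "***",
    score >= 50 ~ "**",
    score >= 25 ~ "*",
    .default = "none"
  )
}

#' Score cluster robustness by subsampled re-clustering
#'
#' For each of `n_replicates` replicates the counts are binomially thinned to
#' `fraction` and re-clustered with the original clustering's variable genes
#' and parameters; each original cluster's co-occurrence (see
#' [co_occurrence()]) is averaged over replicates and scaled to 0--100. The
#' defaults (100 replicates at 80%) are the reference subsampling protocol;
#' star bins follow [robustness_stars()].
#'
#' @param original A `cluster_assignment` computed on `m` by
#'   [cluster_cells()] (or any assignment carrying its variable genes).
#' @param m The [umi_counts()] object `original` was computed on.
#' @param n_replicates Number of subsampling replicates (>= 1).
#' @param fraction Retention fraction for thinning.
#' @param seed Integer seed; replicate `r` uses `seed + r` for both thinning
#'   and re-clustering.
#' @param method Co-occurrence metric, see [co_occurrence()].
#' @param recluster_fn Optional pluggable backend:
#'   `function(m_subsampled, replicate_index)` returning a
#'   `cluster_assignment`. Defaults to [cluster_cells()] with the original
#'   variable genes and parameters.
#' @return A `robustness_report` tibble (`cluster`, `score`, `stars`) with
#'   `n_replicates`, `fraction`, `method` and `seed` attributes.
#' @export
robustness_score <- function(original, m,
                             n_replicates = 100,
                             fraction = 0.8,
                             seed = 1L,
                             method = c("best_match", "pairwise"),
                             recluster_fn = NULL) {
  method <- match.arg(method)
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be >= 1.", class = "dielsc_argument_error")
  }
  n_replicates <- check_count(n_replicates, "n_replicates")
  fraction <- check_fraction(fraction, "fraction")
  stopifnot(inherits(m, "umi_counts"))
  if (!setequal(original$cell, rownames(m$counts))) {
    abort("`original` was not computed on `m` (cell sets differ).",
          class = "dielsc_consistency_error")
  }
  if (is.null(recluster_fn)) {
    vg <- cluster_variable_genes(original)
    if (is.null(vg)) {
      abort("`original` carries no variable-gene list; pass `recluster_fn`.")
    }
    params <- attr(original, "params") %||% list()
    recluster_fn <- function(mr, r) {
      cluster_cells(
        mr,
        n_pcs = params$n_pcs %||% 10,
        k_neighbors = params$k_neighbors %||% 20,
        resolution = params$resolution %||% 1,
        max_clusters = params$max_clusters %||% Inf,
        snn_prune = params$snn_prune %||% (1 / 15),
        variable_genes = vg,
        seed = as.integer(seed) + r
      )
    }
  }

  per_rep <- lapply(seq_len(n_replicates), function(r) {
    mr <- subsample_counts(m, fraction, seed = as.integer(seed) + r)
    co_occurrence(original, recluster_fn(mr, r), method = method)
  })
  out <- bind_rows(per_rep) |>
    group_by(.data$cluster) |>
    summarise(score = 100 * mean(.data$co_occurrence), .groups = "drop") |>
    mutate(stars = robustness_stars(.data$score)) |>
    arrange(.data$cluster)
  attr(out, "n_replicates") <- n_replicates
  attr(out, "fraction") <- fraction
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("robustness_report", class(out))
  out
}

#' @method glance robustness_report
#' @export
glance.robustness_report <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_replicates = attr(x, "n_replicates"),
    fraction = attr(x, "fraction"),
    min_score = min(x$score),
    median_score = stats::median(x$score),
    n_three_star = sum(x$stars == "***")
  )
}
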