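#' Simulate a cluster-structured UMI count matrix
#'
#' Draws negative-binomial counts for the cells in `truth` over `n_genes`
#' genes named `G0001 ...`, with per-gene baseline means drawn log-normally
#' (the standard over-dispersed scRNA-seq noise model). On top of the
#' baseline:
#'
#' * planted marker genes (`truth$markers`) sit at a fixed baseline mean
#'   (`exp(base_meanlog)`) and are elevated by `marker_logfc` (natural-log
#'   scale) in their own cluster, so the planted fold change is exact;
#' * a designated batch gene subset is shifted by `batch_shift` (natural-log
#'   scale) in end-of-night (EN) cells, creating the consistent day/night
#'   difference batch correction is meant to remove;
#' * plastid-flagged genes are inflated `plastid_boost`-fold in the planted
#'   high-plastid cells;
#' * planted low-depth cells are binomially thinned to a total below the
#'   default transcript filter.
#'
#' Expected per-cell depth is held constant across clusters and batches
#' (cell identity does not change sequencing depth), so planted fold
#' changes are the only compositional signal normalization sees. Gene
#' roles never overlap: markers come first, then batch genes, plastid
#' genes last. The realised pre-thinning depth of every cell is recorded in
#' `cell_meta$depth`, so per-cell totals of unthinned cells reconcile with it
#' exactly.
#'
#' @param truth A [sim_truth()] object.
#' @param n_genes Number of genes (must cover all planted markers plus batch
#'   and plastid genes).
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   must be > 0.
#' @param marker_logfc Natural-log fold elevation of planted markers in their
#'   cluster.
#' @param batch_shift Natural-log shift of batch genes in EN cells.
#' @param plastid_fraction Fraction of genes flagged as plastid-encoded.
#' @param batch_gene_fraction Fraction of genes responding to the time point.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-gene baseline
#'   means.
#' @param plastid_boost Fold inflation of plastid genes in high-plastid cells.
#' @param low_depth_range Range the totals of planted low-depth cells are
#'   thinned into (below the default 500-transcript cutoff).
#'
#' @return A [umi_counts()] object. `cell_meta` carries `timepoint`,
#'   `replicate`, the truth labels (`cluster`, `low_depth`, `high_plastid`)
#'   and the pre-thinning `depth`; `gene_meta` carries `biotype`, `plastid`,
#'   `batch_gene` and `marker_cluster`.
#' @export
simulate_counts <- function(truth,
                            n_genes = 400,
                            nb_dispersion = 0.5,
                            marker_logfc = 2,
                            batch_shift = 0.5,
                            plastid_fraction = 0.05,
                            batch_gene_fraction = 0.1,
                            base_meanlog = log(3),
                            base_sdlog = 1,
                            plastid_boost = 15,
                            low_depth_range = c(100, 400)) {
  stopifnot(inherits(truth, "sim_truth"))
  n_genes <- check_count(n_genes, "n_genes")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    abort("`nb_dispersion` must be > 0.", class = "dielsc_argument_error")
  }
  n_markers <- nrow(truth$markers)
  n_batch <- ceiling(batch_gene_fraction * n_genes)
  n_plastid <- ceiling(plastid_fraction * n_genes)
  if (n_markers + n_batch + n_plastid > n_genes) {
    abort("`n_genes` too small for planted markers + batch + plastid genes.",
          class = "dielsc_argument_error")
  }
  cells <- truth$cells
  n_cells <- nrow(cells)
  genes <- sprintf("G%04d", seq_len(n_genes))

  marker_cluster <- rep(NA_integer_, n_genes)
  marker_cluster[seq_len(n_markers)] <- truth$markers$cluster
  batch_gene <- seq_len(n_genes) %in% (n_markers + seq_len(n_batch))
  plastid <- seq_len(n_genes) > n_genes - n_plastid

  with_seed(truth$seed, {
    base_mu <- rlnorm(n_genes, meanlog = base_meanlog, sdlog = base_sdlog)
    # planted markers sit at a fixed, known baseline: their realised
    # fold change is then exactly marker_logfc and, together with the
    # depth matching below, background genes stay exchangeable between
    # clusters (a true null for marker false-positive checks)
    if (n_markers > 0) base_mu[seq_len(n_markers)] <- exp(base_meanlog)
    mu <- matrix(base_mu, nrow = n_cells, ncol = n_genes, byrow = TRUE)
    if (n_markers > 0 && n_cells > 0) {
      for (k in unique(truth$markers$cluster)) {
        in_k <- cells$cluster == k
        gk <- which(marker_cluster == k)
        mu[in_k, gk] <- mu[in_k, gk] * exp(marker_logfc)
      }
    }
    if (n_batch > 0 && n_cells > 0) {
      en <- cells$timepoint == "EN"
      mu[en, batch_gene] <- mu[en, batch_gene] * exp(batch_shift)
    }
    if (n_cells > 0) {
      # hold expected per-cell depth constant across clusters/batches so the
      # planted fold changes are the only compositional signal normalization
      # sees (cell identity should not change sequencing depth)
      mu <- mu * (sum(base_mu) / rowSums(mu))
    }
    if (n_plastid > 0 && any(cells$high_plastid)) {
      mu[cells$high_plastid, plastid] <- mu[cells$high_plastid, plastid] *
        plastid_boost
    }
    counts <- matrix(
      rnbinom(n_cells * n_genes, mu = as.vector(mu), size = 1 / nb_dispersion),
      nrow = n_cells, ncol = n_genes
    )
    depth <- if (n_cells) as.integer(rowSums(counts)) else integer()
    for (i in which(cells$low_depth)) {
      target <- runif(1, low_depth_range[1], low_depth_range[2])
      keep <- min(1, target / max(1L, depth[i]))
      counts[i, ] <- rbinom(n_genes, counts[i, ], keep)
    }
    dimnames(counts) <- list(cells$cell, genes)

    umi_counts(
      counts,
      cell_meta = mutate(cells, depth = depth),
      gene_meta = tibble(gene = genes, biotype = "protein_coding",
                         plastid = plastid, batch_gene = batch_gene,
                         marker_cluster = marker_cluster)
    )
  })
}
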