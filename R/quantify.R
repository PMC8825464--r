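#' Collapse tagged reads into a UMI count matrix
#'
#' Assigns each read to a gene by interval overlap (any aligned block, >= 1
#' bp) and counts, per gene and cell, the number of distinct (cell, UMI)
#' molecules. Reads whose blocks overlap two or more genes are treated as
#' read-through evidence, not expression: they are excluded here and belong
#' to [detect_dicistronic_pairs()]. With `strand_specific = TRUE` (the
#' default; antisense transcripts require it) a gene is only a candidate when
#' its strand matches the read's.
#'
#' Reads on chromosomes absent from the annotation are skipped and counted in
#' the QC report (attribute `"qc"`), as are unassigned (no overlap) and
#' ambiguous (multi-gene) reads.
#'
#' @param reads Tagged reads tibble (see [simulate_reads()] /
#'   [read_reads_tsv()]).
#' @param annotation Gene annotation tibble (see [simulate_annotation()] /
#'   [read_annotation_gff3()]).
#' @param strand_specific Require read and gene strand to match.
#' @param cell_meta Optional tibble with a `cell` column fixing the cell set
#'   and order of the result (cells observed in `reads` must be covered);
#'   extra columns are carried into the result's metadata.
#' @return A [umi_counts()] object over the full annotation gene set, with a
#'   `"qc"` attribute: `list(n_reads, n_unknown_chrom, n_unassigned,
#'   n_ambiguous)`.
#' @export
collapse_umis <- function(reads, annotation, strand_specific = TRUE,
                          cell_meta = NULL) {
  stopifnot(is.data.frame(reads), is.data.frame(annotation))
  if (nrow(annotation) == 0) {
    abort("`annotation` is empty.", class = "dielsc_argument_error")
  }

  known <- unique(annotation$chrom)
  unknown <- unique(reads$chrom[!reads$chrom %in% known])
  n_unknown <- sum(!reads$chrom %in% known)
  if (n_unknown > 0) {
    inform(sprintf("Skipping %d read(s) on unknown chromosome(s): %s",
                   n_unknown, paste(unknown, collapse = ", ")))
  }
  kept <- reads[reads$chrom %in% known, , drop = FALSE]

  assigned <- tibble(cell = character(), umi = character(), gene = character())
  n_ambiguous <- 0L
  n_unassigned <- 0L
  if (nrow(kept) > 0) {
    blocks <- flatten_blocks(kept)
    hits <- GenomicRanges::findOverlaps(blocks_granges(blocks),
                                        genes_granges(annotation),
                                        ignore.strand = TRUE)
    hit <- tibble(
      read = blocks$read[S4Vectors::queryHits(hits)],
      gene = annotation$gene_id[S4Vectors::subjectHits(hits)],
      strand_ok = blocks$strand[S4Vectors::queryHits(hits)] ==
        annotation$strand[S4Vectors::subjectHits(hits)]
    )
    if (strand_specific) hit <- filter(hit, .data$strand_ok)
    hit <- distinct(hit, .data$read, .data$gene)
    genes_per_read <- hit |> count(.data$read)
    multi <- genes_per_read$read[genes_per_read$n >= 2L]
    n_ambiguous <- length(multi)
    n_unassigned <- nrow(kept) - nrow(genes_per_read)
    uni <- filter(hit, !.data$read %in% multi)
    assigned <- tibble(cell = kept$cell[uni$read], umi = kept$umi[uni$read],
                       gene = uni$gene) |>
      distinct()
  }

  obs_cells <- sort(unique(reads$cell))
  if (!is.null(cell_meta)) {
    stopifnot("cell" %in% names(cell_meta))
    uncovered <- setdiff(obs_cells, cell_meta$cell)
    if (length(uncovered)) {
      abort(paste0("Reads carry cells missing from `cell_meta`: ",
                   paste(head(uncovered, 5), collapse = ", ")),
            class = "dielsc_consistency_error")
    }
    cells <- cell_meta$cell
  } else {
    cells <- obs_cells
    cell_meta <- tibble(cell = cells)
  }

  counts_per <- assigned |> count(.data$cell, .data$gene)
  counts <- Matrix::sparseMatrix(
    i = match(counts_per$cell, cells),
    j = match(counts_per$gene, annotation$gene_id),
    x = counts_per$n,
    dims = c(length(cells), nrow(annotation)),
    dimnames = list(cells, annotation$gene_id)
  )

  m <- umi_counts(counts, cell_meta = cell_meta,
                  gene_meta = tibble(gene = annotation$gene_id,
                                     biotype = annotation$biotype,
                                     plastid = annotation$plastid))
  attr(m, "qc") <- list(n_reads = nrow(reads), n_unknown_chrom = n_unknown,
                        n_unassigned = n_unassigned, n_ambiguous = n_ambiguous)
  m
}

#' Per-cell quality-control statistics
#'
#' The three per-cell statistics the cell filter acts on: total transcripts
#' (UMIs), detected genes, and the fraction of UMIs from plastid-flagged
#' genes, with pass/fail flags at the supplied cutoffs.
#'
#' @inheritParams filter_cells
#' @return A tibble: `cell`, `n_transcripts`, `n_genes`, `plastid_fraction`,
#'   `pass_transcripts`, `pass_genes`, `pass_plastid`, `pass`.
#' @export
cell_qc <- function(m, min_transcripts = 500, min_genes = 200,
                    max_plastid_fraction = 0.2) {
  stopifnot(inherits(m, "umi_counts"))
  totals <- Matrix::rowSums(m$counts)
  n_genes <- Matrix::rowSums(m$counts > 0)
  plastid_cols <- which(m$gene_meta$plastid)
  plastid_umis <- if (length(plastid_cols)) {
    Matrix::rowSums(m$counts[, plastid_cols, drop = FALSE])
  } else {
    rep(0, nrow(m$counts))
  }
  tibble(
    cell = rownames(m$counts) %||% character(),
    n_transcripts = as.numeric(totals),
    n_genes = as.numeric(n_genes),
    plastid_fraction = ifelse(totals > 0, plastid_umis / totals, 0)
  ) |>
    mutate(
      pass_transcripts = .data$n_transcripts >= min_transcripts,
      pass_genes = .data$n_genes >= min_genes,
      pass_plastid = .data$plastid_fraction <= max_plastid_fraction,
      pass = .data$pass_transcripts & .data$pass_genes & .data$pass_plastid
    )
}

#' Filter cells on transcript, gene and plastid cutoffs
#'
#' Retains exactly the cells with total transcripts `>= min_transcripts`,
#' detected genes `>= min_genes` and plastid UMI fraction
#' `<= max_plastid_fraction`. The defaults (500 / 200 / 0.2) are the
#' permissive cutoffs favouring discovery of rare cell types; raising them
#' retains fewer, deeper cells (the filter is monotone in its cutoffs and
#' idempotent).
#'
#' @param m A [umi_counts()] object.
#' @param min_transcripts Minimum total UMIs per cell.
#' @param min_genes Minimum detected genes per cell.
#' @param max_plastid_fraction Maximum fraction of UMIs from plastid genes.
#' @return The filtered `umi_counts` object; attribute `"qc"` holds the full
#'   per-cell QC table from [cell_qc()].
#' @export
filter_cells <- function(m, min_transcripts = 500, min_genes = 200,
                         max_plastid_fraction = 0.2) {
  stopifnot(inherits(m, "umi_counts"))
  if (nrow(m$counts) == 0) {
    warn("Filtering an empty count matrix.")
    attr(m, "qc") <- cell_qc(m, min_transcripts, min_genes,
                             max_plastid_fraction)
    return(m)
  }
  qc <- cell_qc(m, min_transcripts, min_genes, max_plastid_fraction)
  out <- subset_cells(m, qc$cell[qc$pass])
  attr(out, "qc") <- qc
  out
}
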