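#' Construct a UMI count matrix container
#'
#' Bundles a cells x genes matrix of UMI counts with per-cell and per-gene
#' metadata. Rows are cells (barcodes), columns genes; counts are stored
#' sparsely.
#'
#' @param counts A cells x genes matrix (dense or sparse) of non-negative
#'   integers with dimnames.
#' @param cell_meta Tibble with a `cell` column matching the rownames
#'   (typically also `timepoint`, `replicate`, truth labels). Generated from
#'   rownames when `NULL`.
#' @param gene_meta Tibble with a `gene` column matching the colnames
#'   (typically also `biotype`, `plastid`). Generated when `NULL`.
#' @return An object of class `umi_counts`.
#' @export
umi_counts <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  # Matrix normalizes empty dimnames to NULL; carry names explicitly
  rn <- rownames(counts) %||% character()
  cn <- colnames(counts) %||% character()
  if (length(rn) == 0 && nrow(counts) > 0) abort("`counts` needs cell rownames.")
  if (length(cn) == 0 && ncol(counts) > 0) abort("`counts` needs gene colnames.")
  if (any(counts@x < 0) || any(counts@x != floor(counts@x))) {
    abort("`counts` must hold non-negative integers.")
  }
  if (is.null(cell_meta)) cell_meta <- tibble(cell = rn)
  if (is.null(gene_meta)) {
    gene_meta <- tibble(gene = cn, biotype = "protein_coding",
                        plastid = FALSE)
  }
  cell_meta <- as_tibble(cell_meta)
  gene_meta <- as_tibble(gene_meta)
  if (!identical(cell_meta$cell, rn)) {
    cell_meta <- cell_meta[match(rn, cell_meta$cell), ]
    if (anyNA(cell_meta$cell)) abort("`cell_meta` does not cover all cells.")
  }
  if (!identical(gene_meta$gene, cn)) {
    gene_meta <- gene_meta[match(cn, gene_meta$gene), ]
    if (anyNA(gene_meta$gene)) abort("`gene_meta` does not cover all genes.")
  }
  if (!"plastid" %in% names(gene_meta)) gene_meta$plastid <- FALSE
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("<umi_counts> %d cells x %d genes, %.0f UMIs total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  extra <- setdiff(names(x$cell_meta), "cell")
  if (length(extra)) cat("  cell_meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Restrict a count matrix to a set of cells
#'
#' @param m A [umi_counts()] object.
#' @param cells Character vector of cell barcodes to keep (order preserved).
#' @return A `umi_counts` object with the selected cells.
#' @export
subset_cells <- function(m, cells) {
  stopifnot(inherits(m, "umi_counts"))
  missing <- setdiff(cells, rownames(m$counts))
  if (length(missing)) {
    abort(paste0("Unknown cells: ", paste(head(missing, 5), collapse = ", ")))
  }
  umi_counts(m$counts[cells, , drop = FALSE],
             m$cell_meta[match(cells, m$cell_meta$cell), ],
             m$gene_meta)
}

#' Library-size normalize to counts-per-10k on the natural-log scale
#'
#' Each cell's counts are scaled to a common library size of 10,000 and
#' transformed with `log1p` — the standard normalization the marker and
#' clustering stages operate on.
#'
#' @param m A [umi_counts()] object.
#' @return A dense cells x genes matrix of `ln(1 + cp10k)` values.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  totals <- Matrix::rowSums(m$counts)
  sf <- ifelse(totals > 0, 1e4 / totals, 0)
  log1p(as.matrix(m$counts * sf))
}

#' @rdname umi_counts
#' @param x A `umi_counts` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble of non-zero counts (`cell`, `gene`,
#'   `count`) joined with cell metadata. `glance()`: a one-row summary with
#'   the average transcripts and detected genes per cell.
#' @method tidy umi_counts
#' @export
tidy.umi_counts <- function(x, ...) {
  tm <- Matrix::summary(x$counts)
  tibble(cell = (rownames(x$counts) %||% character())[tm$i],
         gene = (colnames(x$counts) %||% character())[tm$j],
         count = as.integer(tm$x)) |>
    left_join(x$cell_meta, by = "cell") |>
    arrange(.data$cell, .data$gene)
}

#' @rdname umi_counts
#' @method glance umi_counts
#' @export
glance.umi_counts <- function(x, ...) {
  tibble(
    n_cells = nrow(x$counts),
    n_genes = ncol(x$counts),
    total_umis = sum(x$counts),
    mean_transcripts_per_cell = if (nrow(x$counts)) mean(Matrix::rowSums(x$counts)) else NA_real_,
    mean_genes_per_cell = if (nrow(x$counts)) mean(Matrix::rowSums(x$counts > 0)) else NA_real_
  )
}
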