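#' Read and write gene annotations as GFF3
#'
#' Genes are exported as `type = "gene"` features with `ID`, `biotype` and
#' `plastid` attributes (1-based closed intervals, strand column), and read
#' back into the annotation tibble the rest of the toolkit consumes.
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return `write_annotation_gff3()` returns `path` invisibly;
#'   `read_annotation_gff3()` returns an annotation tibble.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- genes_granges(annotation)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$biotype <- annotation$biotype
  S4Vectors::mcols(gr)$plastid <- tolower(as.character(annotation$plastid))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tibble(
    gene_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = as.character(mc$biotype),
    plastid = as.character(mc$plastid) == "true"
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Read and write tagged reads as TSV
#'
#' The documented tabular dialect for tagged alignments: columns `cell`,
#' `umi`, `chrom`, `strand`, `block_starts`, `block_ends`, with the block
#' coordinates of a read comma-joined (1-based, closed intervals).
#'
#' @param reads Tagged reads tibble.
#' @param path File path.
#' @return `write_reads_tsv()` returns `path` invisibly; `read_reads_tsv()`
#'   returns a tagged reads tibble with list-columns.
#' @export
write_reads_tsv <- function(reads, path) {
  flat <- reads |>
    mutate(block_starts = map_chr(.data$block_starts,
                                  ~ paste(.x, collapse = ",")),
           block_ends = map_chr(.data$block_ends,
                                ~ paste(.x, collapse = ",")))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell = "c", umi = "c", chrom = "c", strand = "c",
    block_starts = "c", block_ends = "c"
  )) |>
    mutate(
      block_starts = map(strsplit(.data$block_starts, ","), as.integer),
      block_ends = map(strsplit(.data$block_ends, ","), as.integer)
    )
}

#' Write and read a UMI count matrix as MTX plus metadata TSVs
#'
#' Writes `matrix.mtx` (genes are columns of the in-memory matrix but the
#' MTX is stored cells x genes exactly as held), `barcodes.tsv`,
#' `genes.tsv`, `cell_meta.tsv` and `gene_meta.tsv` into `dir`.
#'
#' @param m A [umi_counts()] object.
#' @param dir Directory (created if needed).
#' @return `write_counts_mtx()` returns `dir` invisibly;
#'   `read_counts_mtx()` returns a `umi_counts` object.
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "umi_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(m$counts), file.path(dir, "barcodes.tsv"))
  readr::write_lines(colnames(m$counts), file.path(dir, "genes.tsv"))
  readr::write_tsv(m$cell_meta, file.path(dir, "cell_meta.tsv"))
  readr::write_tsv(m$gene_meta, file.path(dir, "gene_meta.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  colnames(counts) <- readr::read_lines(file.path(dir, "genes.tsv"))
  cell_meta <- readr::read_tsv(file.path(dir, "cell_meta.tsv"),
                               show_col_types = FALSE)
  gene_meta <- readr::read_tsv(file.path(dir, "gene_meta.tsv"),
                               show_col_types = FALSE)
  umi_counts(counts, cell_meta, gene_meta)
}
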