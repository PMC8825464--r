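#' Call di-cistronic gene pairs from read--annotation overlap
#'
#' A read supports an (ordered-by-coordinate) gene pair when its aligned
#' blocks overlap both genes (any overlap, >= 1 bp; strand-agnostic at the
#' read level). A read overlapping three or more genes contributes to every
#' pair it touches. Candidate pairs are then filtered: a pair passes when it
#' is supported by at least `min_support` reads AND (both genes are
#' protein-coding on the same strand, OR at least one gene is non-coding —
#' tRNA and other non-protein-coding biotypes count as non-coding). All
#' candidates are returned with their verdict.
#'
#' @param reads Tagged reads tibble.
#' @param annotation Gene annotation tibble.
#' @param min_support Minimum number of supporting reads (default 100).
#' @return Tibble of `dicistronic_call`s: `gene_a`, `gene_b` (coordinate
#'   order), `support`, `strand_a`, `strand_b`, `biotype_a`, `biotype_b`,
#'   `passed`, `fail_reason` (`NA`, `"low_support"` or
#'   `"strand_biotype_rule"`).
#' @export
detect_dicistronic_pairs <- function(reads, annotation, min_support = 100) {
  stopifnot(is.data.frame(reads), is.data.frame(annotation))
  min_support <- check_count(min_support, "min_support")
  empty <- tibble(gene_a = character(), gene_b = character(),
                  support = integer(),
                  strand_a = character(), strand_b = character(),
                  biotype_a = character(), biotype_b = character(),
                  passed = logical(), fail_reason = character())
  if (nrow(reads) == 0 || nrow(annotation) == 0) return(empty)

  blocks <- flatten_blocks(reads)
  hits <- GenomicRanges::findOverlaps(blocks_granges(blocks),
                                      genes_granges(annotation),
                                      ignore.strand = TRUE)
  hit <- distinct(tibble(read = blocks$read[S4Vectors::queryHits(hits)],
                         gi = S4Vectors::subjectHits(hits)))
  per_read <- split(hit$gi, hit$read)
  multi <- per_read[lengths(per_read) >= 2L]
  if (length(multi) == 0) return(empty)

  pair_keys <- unlist(lapply(multi, function(gis) {
    # order pair members by genomic coordinate
    gis <- gis[order(annotation$start[gis], annotation$end[gis])]
    cmb <- combn(gis, 2L)
    paste(cmb[1, ], cmb[2, ], sep = "|")
  }), use.names = FALSE)
  tab <- table(pair_keys)
  idx <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  a <- as.integer(idx[, 1])
  b <- as.integer(idx[, 2])

  coding_a <- annotation$biotype[a] == "protein_coding"
  coding_b <- annotation$biotype[b] == "protein_coding"
  same_strand <- annotation$strand[a] == annotation$strand[b]
  rule_ok <- (coding_a & coding_b & same_strand) | !coding_a | !coding_b
  support <- as.integer(tab)

  tibble(
    gene_a = annotation$gene_id[a],
    gene_b = annotation$gene_id[b],
    support = support,
    strand_a = annotation$strand[a],
    strand_b = annotation$strand[b],
    biotype_a = annotation$biotype[a],
    biotype_b = annotation$biotype[b],
    passed = support >= min_support & rule_ok,
    fail_reason = case_when(
      support < min_support ~ "low_support",
      !rule_ok ~ "strand_biotype_rule",
      .default = NA_character_
    )
  ) |>
    arrange(desc(.data$support), .data$gene_a, .data$gene_b)
}

#' Classify host-gene molecules as mono-cistronic or tRNA read-through
#'
#' Groups reads into molecules by (cell, UMI) over the host/tRNA locus and
#' labels each molecule:
#'
#' * `tls` — at least one read block overlaps the tRNA interval (the
#'   read-through, tRNA-like-sequence isoform);
#' * `mono` — no tRNA overlap; the mono-cistronic call is clean when no read
#'   extends past the base immediately preceding the tRNA start
#'   (strand-aware). Molecules that read past the tRNA without overlapping
#'   it violate both definitions; they are labelled `mono` and `flagged`.
#'
#' Molecules with no read overlapping the host gene are excluded. Because a
#' `tls` call needs an observed junction-overlapping read, the resulting TLS
#' ratio is a lower bound on the true read-through fraction when reads are
#' short.
#'
#' @param reads Tagged reads tibble.
#' @param host_gene,trna_gene Gene ids in `annotation`; the tRNA must lie
#'   downstream of the host on the same strand.
#' @param annotation Gene annotation tibble.
#' @return Tibble of molecule classes: `cell`, `umi`, `gene`, `label`
#'   (`"mono"`/`"tls"`), `n_reads`, `trna_overlap_reads`, `flagged`.
#' @export
classify_molecules <- function(reads, host_gene, trna_gene, annotation) {
  stopifnot(is.data.frame(reads), is.data.frame(annotation))
  h <- annotation[annotation$gene_id == host_gene, ]
  tr <- annotation[annotation$gene_id == trna_gene, ]
  if (nrow(h) != 1 || nrow(tr) != 1) {
    abort("`host_gene`/`trna_gene` must each match one annotation entry.",
          class = "dielsc_argument_error")
  }
  if (h$strand != tr$strand || h$chrom != tr$chrom) {
    abort("Host and tRNA must lie on the same strand of the same chromosome.",
          class = "dielsc_argument_error")
  }
  downstream_ok <- if (h$strand == "+") tr$start > h$end else tr$end < h$start
  if (!downstream_ok) {
    abort("tRNA gene must lie downstream of the host gene.",
          class = "dielsc_argument_error")
  }

  locus_start <- min(h$start, tr$start)
  locus_end <- max(h$end, tr$end)
  blocks <- flatten_blocks(reads) |>
    filter(.data$chrom == h$chrom,
           .data$start <= locus_end + 10000L,
           .data$end >= locus_start - 10000L)
  if (nrow(blocks) == 0) {
    return(tibble(cell = character(), umi = character(), gene = character(),
                  label = character(), n_reads = integer(),
                  trna_overlap_reads = integer(), flagged = logical()))
  }
  ov <- function(s, e, gs, ge) s <= ge & e >= gs
  blocks <- blocks |>
    mutate(
      host_ov = ov(.data$start, .data$end, h$start, h$end),
      trna_ov = ov(.data$start, .data$end, tr$start, tr$end),
      # strand-aware: does the block extend past the base before the tRNA?
      past_boundary = if (h$strand == "+") .data$end > tr$start - 1L
                      else .data$start < tr$end + 1L
    )

  blocks |>
    group_by(.data$cell, .data$umi) |>
    summarise(
      n_reads = length(unique(.data$read)),
      host_reads = length(unique(.data$read[.data$host_ov])),
      trna_overlap_reads = length(unique(.data$read[.data$trna_ov])),
      any_past = any(.data$past_boundary),
      .groups = "drop"
    ) |>
    filter(.data$host_reads > 0) |>
    mutate(
      gene = host_gene,
      label = ifelse(.data$trna_overlap_reads >= 1L, "tls", "mono"),
      flagged = .data$label == "mono" & .data$any_past
    ) |>
    select("cell", "umi", "gene", "label", "n_reads",
           "trna_overlap_reads", "flagged")
}

#' Per-cluster TLS ratio and enrichment
#'
#' Builds two per-cell pseudo-gene vectors from classified molecules (counts
#' of `tls` and `mono` molecules), restricts to cells expressing the host
#' gene (at least one classified molecule), and reports per cluster the TLS
#' ratio `tls / (tls + mono)` together with the marker-style enrichment
#' verdict: a cluster is enriched when the TLS pseudo-gene is a marker for
#' it (two-tailed Wilcoxon of in-cluster vs other host-expressing cells on
#' depth-normalized pseudo-expression, unadjusted `p < alpha`, elevated
#' in-cluster) and the mono pseudo-gene is not.
#'
#' @param classes Molecule classes from [classify_molecules()].
#' @param clusters A `cluster_assignment` covering the cells.
#' @param m The [umi_counts()] object supplying per-cell library sizes for
#'   normalization.
#' @param alpha Unadjusted significance threshold (default 0.05).
#' @return Tibble: `cluster`, `n_cells` (host-expressing), `n_tls`,
#'   `n_mono`, `tls_ratio` (`NA` when no host-expressing cells), `p_tls`,
#'   `p_mono`, `enriched`.
#' @export
tls_cluster_enrichment <- function(classes, clusters, m, alpha = 0.05) {
  stopifnot(is.data.frame(classes), inherits(m, "umi_counts"))
  lab <- setNames(clusters$cluster, clusters$cell)
  per_cell <- classes |>
    count(.data$cell, .data$label) |>
    pivot_wider(names_from = "label", values_from = "n", values_fill = 0L)
  for (col in c("tls", "mono")) {
    if (!col %in% names(per_cell)) per_cell[[col]] <- 0L
  }
  per_cell <- per_cell |>
    filter(.data$tls + .data$mono > 0) |>
    mutate(cluster = unname(lab[.data$cell]))
  if (anyNA(per_cell$cluster)) {
    abort("Classified molecules in cells without a cluster label.",
          class = "dielsc_consistency_error")
  }

  totals <- Matrix::rowSums(m$counts)
  sf <- setNames(ifelse(totals > 0, 1e4 / totals, 0), rownames(m$counts))
  if (anyNA(sf[per_cell$cell])) {
    abort("Host-expressing cells missing from the count matrix.",
          class = "dielsc_consistency_error")
  }
  per_cell <- per_cell |>
    mutate(tls_norm = log1p(.data$tls * sf[.data$cell]),
           mono_norm = log1p(.data$mono * sf[.data$cell]))

  marker_p <- function(x, in_k) {
    if (sum(in_k) == 0 || sum(!in_k) == 0) return(c(p = NA_real_, up = NA))
    p <- suppressWarnings(
      wilcox.test(x[in_k], x[!in_k], alternative = "two.sided",
                  exact = FALSE)$p.value)
    c(p = p, up = as.numeric(mean(x[in_k]) > mean(x[!in_k])))
  }

  all_clusters <- sort(unique(clusters$cluster))
  map(all_clusters, function(k) {
    cells_k <- per_cell$cluster == k
    if (!any(cells_k)) {
      return(tibble(cluster = k, n_cells = 0L, n_tls = 0L, n_mono = 0L,
                    tls_ratio = NA_real_, p_tls = NA_real_,
                    p_mono = NA_real_, enriched = NA))
    }
    n_tls <- sum(per_cell$tls[cells_k])
    n_mono <- sum(per_cell$mono[cells_k])
    pt <- marker_p(per_cell$tls_norm, cells_k)
    pm <- marker_p(per_cell$mono_norm, cells_k)
    tls_is_marker <- !is.na(pt["p"]) && pt["p"] < alpha && pt["up"] == 1
    mono_is_marker <- !is.na(pm["p"]) && pm["p"] < alpha && pm["up"] == 1
    tibble(cluster = k, n_cells = sum(cells_k),
           n_tls = as.integer(n_tls), n_mono = as.integer(n_mono),
           tls_ratio = n_tls / (n_tls + n_mono),
           p_tls = unname(pt["p"]), p_mono = unname(pm["p"]),
           enriched = tls_is_marker && !mono_is_marker)
  }) |>
    list_rbind()
}
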