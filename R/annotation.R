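#' Simulate a strand-aware gene annotation with adjacent gene pairs
#'
#' Generates a compact genome annotation laid out along one chromosome:
#' `n_gene_pairs` pairs of closely adjacent genes (candidates for read-through
#' di-cistronic molecules), `n_singletons` isolated genes, and optionally one
#' protein-coding host gene with a tRNA gene a short, configurable gap
#' downstream on the same strand (the mRNA--tRNA read-through locus used for
#' tRNA-like-sequence analysis).
#'
#' Intervals are 1-based and closed, as in GFF3. Members of a pair are
#' separated by a small `pair_gap` so a single aligned block can span both;
#' unrelated genes are separated by `intergenic_gap` so background reads never
#' touch two genes.
#'
#' @param n_gene_pairs Number of adjacent gene pairs.
#' @param n_singletons Number of isolated genes.
#' @param tls_host If `TRUE`, add a host gene plus downstream tRNA gene.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param chrom Chromosome name.
#' @param gene_length Integer range (min, max) of gene lengths.
#' @param pair_gap Integer range of the gap (bp) between members of a pair.
#' @param intergenic_gap Integer range of the gap between unrelated loci.
#' @param pair_strand `"same"`, `"opposite"`, or `"random"`: strand relation
#'   within each pair.
#' @param pair_biotypes Length-2 character vector giving the biotypes of the
#'   two members of every pair (each `"protein_coding"` or `"non_coding"`).
#' @param tls_gap Gap (bp) between the host gene end and the tRNA start.
#' @param tls_strand Strand of the host/tRNA locus (`"+"` or `"-"`).
#' @param trna_length Length of the tRNA gene in bp.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `biotype` (`protein_coding`, `non_coding` or `tRNA`) and `plastid`.
#'   Attribute `"pairs"` records the planted adjacency (tibble `gene_a`,
#'   `gene_b`, coordinate-ordered); attribute `"tls"` records the host/tRNA
#'   locus (`list(host, trna, gap)`) or is `NULL`.
#' @export
#' @examples
#' ann <- simulate_annotation(3, n_singletons = 2, tls_host = TRUE, seed = 1)
#' annotation_pairs(ann)
#' annotation_tls(ann)
simulate_annotation <- function(n_gene_pairs,
                                n_singletons = 0,
                                tls_host = FALSE,
                                seed = 1L,
                                chrom = "Chr1",
                                gene_length = c(800L, 2000L),
                                pair_gap = c(20L, 80L),
                                intergenic_gap = c(3000L, 6000L),
                                pair_strand = c("same", "opposite", "random"),
                                pair_biotypes = c("protein_coding", "protein_coding"),
                                tls_gap = 20L,
                                tls_strand = "+",
                                trna_length = 75L) {
  n_gene_pairs <- check_count(n_gene_pairs, "n_gene_pairs")
  n_singletons <- check_count(n_singletons, "n_singletons")
  pair_strand <- match.arg(pair_strand)
  stopifnot(length(pair_biotypes) == 2L,
            all(pair_biotypes %in% c("protein_coding", "non_coding")),
            tls_strand %in% c("+", "-"), tls_gap >= 1L)

  with_seed(as.integer(seed), {
    rows <- list()
    pairs <- tibble(gene_a = character(), gene_b = character())
    pos <- 1000L
    rlen <- function(rng) sample(seq.int(rng[1], rng[2]), 1L)

    for (i in seq_len(n_gene_pairs)) {
      s1 <- sample(c("+", "-"), 1L)
      s2 <- switch(pair_strand,
        same = s1,
        opposite = setdiff(c("+", "-"), s1),
        random = sample(c("+", "-"), 1L)
      )
      a_start <- pos
      a_end <- a_start + rlen(gene_length) - 1L
      b_start <- a_end + rlen(pair_gap) + 1L
      b_end <- b_start + rlen(gene_length) - 1L
      ida <- sprintf("pair%02d_a", i)
      idb <- sprintf("pair%02d_b", i)
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = c(ida, idb), chrom = chrom, strand = c(s1, s2),
        start = c(a_start, b_start), end = c(a_end, b_end),
        biotype = pair_biotypes, plastid = FALSE
      )
      pairs <- bind_rows(pairs, tibble(gene_a = ida, gene_b = idb))
      pos <- b_end + rlen(intergenic_gap) + 1L
    }

    for (i in seq_len(n_singletons)) {
      g_start <- pos
      g_end <- g_start + rlen(gene_length) - 1L
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = sprintf("single%02d", i), chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        start = g_start, end = g_end,
        biotype = "protein_coding", plastid = FALSE
      )
      pos <- g_end + rlen(intergenic_gap) + 1L
    }

    tls <- NULL
    if (tls_host) {
      host_len <- rlen(gene_length)
      if (tls_strand == "+") {
        h_start <- pos
        h_end <- h_start + host_len - 1L
        t_start <- h_end + as.integer(tls_gap)
        t_end <- t_start + as.integer(trna_length) - 1L
      } else {
        # downstream of a minus-strand gene is at lower coordinates
        t_start <- pos
        t_end <- t_start + as.integer(trna_length) - 1L
        h_start <- t_end + as.integer(tls_gap)
        h_end <- h_start + host_len - 1L
      }
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = c("host01", "trna01"), chrom = chrom, strand = tls_strand,
        start = c(h_start, t_start), end = c(h_end, t_end),
        biotype = c("protein_coding", "tRNA"), plastid = FALSE
      )
      tls <- list(host = "host01", trna = "trna01", gap = as.integer(tls_gap))
    }

    ann <- if (length(rows)) bind_rows(rows) else
      tibble(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), biotype = character(),
             plastid = logical())
    ann <- arrange(ann, .data$chrom, .data$start)
    attr(ann, "pairs") <- pairs
    attr(ann, "tls") <- tls
    ann
  })
}

#' Planted adjacent gene pairs of a simulated annotation
#' @param annotation Result of [simulate_annotation()].
#' @return Tibble with `gene_a`, `gene_b`.
#' @export
annotation_pairs <- function(annotation) {
  attr(annotation, "pairs") %||%
    tibble(gene_a = character(), gene_b = character())
}

#' Host/tRNA locus of a simulated annotation
#' @param annotation Result of [simulate_annotation()].
#' @return `list(host, trna, gap)` or `NULL`.
#' @export
annotation_tls <- function(annotation) attr(annotation, "tls")
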