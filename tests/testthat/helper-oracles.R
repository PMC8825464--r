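# Brute-force oracles, deliberately independent of the package's
# GenomicRanges-based implementation paths: plain loops over reads, blocks
# and genes with 1-based closed-interval arithmetic.

make_read <- function(cell, umi, chrom, strand, starts, ends) {
  tibble::tibble(cell = cell, umi = umi, chrom = chrom, strand = strand,
                 block_starts = list(as.integer(starts)),
                 block_ends = list(as.integer(ends)))
}

iv_overlap <- function(s, e, gs, ge) s <= ge && e >= gs

# genes overlapped by any block of read i (indices into annotation rows)
read_gene_hits <- function(reads, i, annotation, strand_specific = FALSE) {
  hits <- integer()
  for (g in seq_len(nrow(annotation))) {
    if (reads$chrom[i] != annotation$chrom[g]) next
    if (strand_specific && reads$strand[i] != annotation$strand[g]) next
    ss <- reads$block_starts[[i]]
    ee <- reads$block_ends[[i]]
    for (b in seq_along(ss)) {
      if (iv_overlap(ss[b], ee[b], annotation$start[g], annotation$end[g])) {
        hits <- c(hits, g)
        break
      }
    }
  }
  hits
}

# named support counts "geneA|geneB" (coordinate order), double loop
oracle_pair_support <- function(reads, annotation) {
  tallies <- list()
  for (i in seq_len(nrow(reads))) {
    hits <- read_gene_hits(reads, i, annotation, strand_specific = FALSE)
    if (length(hits) < 2) next
    hits <- hits[order(annotation$start[hits], annotation$end[hits])]
    cmb <- utils::combn(hits, 2)
    for (p in seq_len(ncol(cmb))) {
      key <- paste(annotation$gene_id[cmb[1, p]],
                   annotation$gene_id[cmb[2, p]], sep = "|")
      tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
    }
  }
  unlist(tallies) %||% integer()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive UMI-collapsed counts: distinct (cell, umi) per uniquely
# assigned gene, as a dense cells x genes matrix
oracle_umi_counts <- function(reads, annotation, strand_specific = TRUE) {
  cells <- sort(unique(reads$cell))
  mat <- matrix(0L, length(cells), nrow(annotation),
                dimnames = list(cells, annotation$gene_id))
  seen <- character()
  for (i in seq_len(nrow(reads))) {
    if (!reads$chrom[i] %in% annotation$chrom) next
    hits <- read_gene_hits(reads, i, annotation, strand_specific)
    if (length(hits) != 1) next
    key <- paste(reads$cell[i], reads$umi[i], annotation$gene_id[hits])
    if (key %in% seen) next
    seen <- c(seen, key)
    mat[reads$cell[i], annotation$gene_id[hits]] <-
      mat[reads$cell[i], annotation$gene_id[hits]] + 1L
  }
  mat
}

# fully random tagged reads over the span of an annotation, including
# multi-block reads; stresses the overlap logic beyond simulator geometry
random_tagged_reads <- function(n, annotation, seed, n_cells = 6,
                                unknown_chrom_frac = 0) {
  withr::with_seed(seed, {
    span <- range(c(annotation$start, annotation$end))
    lo <- max(1L, span[1] - 500L)
    hi <- span[2] + 500L
    rows <- lapply(seq_len(n), function(i) {
      nb <- sample(1:2, 1, prob = c(0.8, 0.2))
      s <- sort(sample(lo:hi, nb))
      len <- sample(30:400, nb, replace = TRUE)
      e <- s + len
      if (nb == 2 && e[1] >= s[2]) e[1] <- s[2] - 1L  # keep blocks disjoint
      if (nb == 2 && e[1] < s[1]) { s <- s[2]; e <- e[2] }
      chrom <- if (runif(1) < unknown_chrom_frac) "ChrUnk"
               else annotation$chrom[1]
      make_read(
        cell = sprintf("c%02d", sample(n_cells, 1)),
        umi = paste0("u", sample(200, 1)),
        chrom = chrom,
        strand = sample(c("+", "-"), 1),
        starts = s, ends = e
      )
    })
    dplyr::bind_rows(rows)
  })
}

# exact two-sided rank-sum p by enumeration of all splits (no ties)
oracle_exact_wilcox_p <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  n1 <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(v), n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
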