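tiny_annotation <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "Chr1",
    strand = c("+", "+", "-"),
    start = c(100L, 1000L, 5000L),
    end = c(500L, 1500L, 6000L),
    biotype = "protein_coding",
    plastid = c(FALSE, FALSE, TRUE)
  )
}

test_that("reads sharing a cell and UMI collapse to one molecule", {
  ann <- tiny_annotation()
  reads <- dplyr::bind_rows(
    make_read("c1", "AAAA", "Chr1", "+", 120, 220),
    make_read("c1", "AAAA", "Chr1", "+", 300, 400),
    make_read("c1", "CCCC", "Chr1", "+", 150, 250)
  )
  m <- collapse_umis(reads, ann)
  expect_equal(as.numeric(m$counts["c1", "gA"]), 2)  # two distinct UMIs
  expect_equal(sum(m$counts), 2)
})

test_that("an empty read stream gives an all-zero matrix over the full gene set", {
  ann <- tiny_annotation()
  no_reads <- tibble::tibble(
    cell = character(), umi = character(), chrom = character(),
    strand = character(), block_starts = list(), block_ends = list())
  m <- collapse_umis(no_reads, ann)
  expect_equal(ncol(m$counts), 3)
  expect_equal(nrow(m$counts), 0)
  m2 <- collapse_umis(no_reads, ann,
                      cell_meta = tibble::tibble(cell = c("c1", "c2")))
  expect_equal(dim(m2$counts), c(2L, 3L))
  expect_equal(sum(m2$counts), 0)
})

test_that("random synthetic reads collapse to the exhaustive recount", {
  ann <- simulate_annotation(3, n_singletons = 2, seed = 31)
  reads <- random_tagged_reads(1000, ann, seed = 32)
  for (ss in c(TRUE, FALSE)) {
    m <- collapse_umis(reads, ann, strand_specific = ss)
    oracle <- oracle_umi_counts(reads, ann, strand_specific = ss)
    expect_equal(as.matrix(m$counts)[rownames(oracle), colnames(oracle)],
                 oracle * 1.0)
  }
})

test_that("collapsing is invariant to read order and duplication of identical reads", {
  ann <- simulate_annotation(2, n_singletons = 1, seed = 33)
  reads <- random_tagged_reads(300, ann, seed = 34)
  m0 <- collapse_umis(reads, ann)
  perm <- withr::with_seed(1, sample(nrow(reads)))
  m1 <- collapse_umis(reads[perm, ], ann)
  expect_equal(as.matrix(m0$counts), as.matrix(m1$counts))
  m2 <- collapse_umis(dplyr::bind_rows(reads, reads[1:50, ]), ann)
  expect_equal(as.matrix(m0$counts), as.matrix(m2$counts))
})

test_that("unknown chromosomes are skipped and reported in the QC counters", {
  ann <- tiny_annotation()
  reads <- dplyr::bind_rows(
    make_read("c1", "AAAA", "Chr1", "+", 120, 220),
    make_read("c1", "TTTT", "ChrX", "+", 120, 220),
    make_read("c2", "GGGG", "ChrY", "-", 10, 80)
  )
  expect_message(m <- collapse_umis(reads, ann), "unknown chromosome")
  qc <- attr(m, "qc")
  expect_equal(qc$n_unknown_chrom, 2)
  expect_equal(sum(m$counts), 1)
})

test_that("strand-specific assignment drops antisense reads, relaxed mode keeps them", {
  ann <- tiny_annotation()
  antisense <- make_read("c1", "AAAA", "Chr1", "-", 120, 220)  # gA is +
  m_ss <- collapse_umis(antisense, ann, strand_specific = TRUE)
  m_un <- collapse_umis(antisense, ann, strand_specific = FALSE)
  expect_equal(sum(m_ss$counts), 0)
  expect_equal(as.numeric(m_un$counts["c1", "gA"]), 1)
})

test_that("multi-gene reads are excluded from expression counts", {
  ann <- tiny_annotation()
  bridging <- make_read("c1", "AAAA", "Chr1", "+", 400, 1100)  # spans gA+gB
  m <- collapse_umis(bridging, ann)
  expect_equal(sum(m$counts), 0)
  expect_equal(attr(m, "qc")$n_ambiguous, 1)
})

test_that("the transcript cutoff flips retention between 499 and 500 total UMIs", {
  genes <- sprintf("g%03d", 1:250)
  ann_meta <- tibble::tibble(gene = genes, biotype = "protein_coding",
                             plastid = FALSE)
  counts <- rbind(
    c(rep(2L, 249), 1L),   # 499 transcripts, 250 genes
    c(rep(2L, 250))        # 500 transcripts, 250 genes
  )
  dimnames(counts) <- list(c("cell_low", "cell_ok"), genes)
  m <- umi_counts(counts, gene_meta = ann_meta)
  kept <- filter_cells(m)  # defaults: 500 / 200
  expect_equal(rownames(kept$counts), "cell_ok")
  qc <- attr(kept, "qc")
  expect_false(qc$pass_transcripts[qc$cell == "cell_low"])
  expect_true(qc$pass_genes[qc$cell == "cell_low"])  # fails depth alone
})

test_that("filtering is idempotent and identity on all-pass matrices", {
  tr <- sim_truth(n_cells_per_cluster = c(30, 30), seed = 35)
  m <- simulate_counts(tr)
  f1 <- filter_cells(m)
  expect_equal(rownames(f1$counts), rownames(m$counts))  # all pass
  f2 <- filter_cells(f1)
  expect_equal(as.matrix(f1$counts), as.matrix(f2$counts))
})

test_that("raising cutoffs shrinks the retained set and raises per-cell averages", {
  tr <- sim_truth(n_cells_per_cluster = c(60, 60), n_low_depth = 10, seed = 36)
  m <- simulate_counts(tr)
  loose <- filter_cells(m, 500, 200)
  strict <- filter_cells(m, 2000, 1000)
  expect_true(all(rownames(strict$counts) %in% rownames(loose$counts)))
  g_loose <- glance(loose)
  g_strict <- glance(strict)
  if (nrow(strict$counts) > 0) {
    expect_gte(g_strict$mean_transcripts_per_cell,
               g_loose$mean_transcripts_per_cell)
    expect_gte(g_strict$mean_genes_per_cell, g_loose$mean_genes_per_cell)
  }
})

test_that("filtering an empty matrix warns and returns it unchanged", {
  m <- umi_counts(matrix(0L, 0, 2, dimnames = list(NULL, c("g1", "g2"))))
  expect_warning(out <- filter_cells(m), "empty")
  expect_equal(nrow(out$counts), 0)
})
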