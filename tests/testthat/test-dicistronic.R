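# two adjacent genes 60 bp apart plus strand/biotype variants
pair_annotation <- function(strand_b = "+", biotype_b = "protein_coding") {
  tibble::tibble(
    gene_id = c("left", "right"),
    chrom = "Chr1",
    strand = c("+", strand_b),
    start = c(1000L, 2060L),
    end = c(2000L, 3000L),
    biotype = c("protein_coding", biotype_b),
    plastid = FALSE
  )
}

bridge_reads <- function(n) {
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    make_read(sprintf("c%02d", i %% 7), paste0("u", i), "Chr1", "+",
              1950, 2100)))
}

test_that("the support threshold flips a call between 99 and 100 reads", {
  ann <- pair_annotation()
  call100 <- detect_dicistronic_pairs(bridge_reads(100), ann)
  expect_true(call100$passed)
  expect_equal(call100$support, 100)
  expect_true(is.na(call100$fail_reason))
  call99 <- detect_dicistronic_pairs(bridge_reads(99), ann)
  expect_false(call99$passed)
  expect_equal(call99$fail_reason, "low_support")
})

test_that("the strand/biotype rule passes same-strand coding pairs and any non-coding pair", {
  reads <- bridge_reads(500)
  opp <- detect_dicistronic_pairs(reads, pair_annotation(strand_b = "-"))
  expect_false(opp$passed)
  expect_equal(opp$fail_reason, "strand_biotype_rule")
  nc <- detect_dicistronic_pairs(
    reads, pair_annotation(strand_b = "-", biotype_b = "non_coding"))
  expect_true(nc$passed)
  trna <- detect_dicistronic_pairs(
    reads, pair_annotation(strand_b = "-", biotype_b = "tRNA"))
  expect_true(trna$passed)
})

test_that("random reads reproduce the brute-force double-loop support counts", {
  for (s in 91:93) {
    ann <- simulate_annotation(3, n_singletons = 2, seed = s)
    reads <- random_tagged_reads(400, ann, seed = s + 100)
    calls <- detect_dicistronic_pairs(reads, ann, min_support = 1)
    oracle <- oracle_pair_support(reads, ann)
    got <- stats::setNames(calls$support,
                           paste(calls$gene_a, calls$gene_b, sep = "|"))
    expect_mapequal(as.list(got), as.list(oracle))
  }
})

test_that("calls are invariant to read order and monotone in the support threshold", {
  ann <- simulate_annotation(2, seed = 94)
  reads <- random_tagged_reads(500, ann, seed = 95)
  c1 <- detect_dicistronic_pairs(reads, ann, min_support = 5)
  perm <- withr::with_seed(1, sample(nrow(reads)))
  c2 <- detect_dicistronic_pairs(reads[perm, ], ann, min_support = 5)
  expect_equal(c1, c2)
  c_hi <- detect_dicistronic_pairs(reads, ann, min_support = 20)
  passed_hi <- paste(c_hi$gene_a, c_hi$gene_b)[c_hi$passed]
  passed_lo <- paste(c1$gene_a, c1$gene_b)[c1$passed]
  expect_true(all(passed_hi %in% passed_lo))
})

# host on [1000, 2000], tRNA on [2020, 2094], plus strand
tls_annotation <- function() {
  tibble::tibble(
    gene_id = c("host", "trna"),
    chrom = "Chr1", strand = "+",
    start = c(1000L, 2020L), end = c(2000L, 2094L),
    biotype = c("protein_coding", "tRNA"), plastid = FALSE
  )
}

test_that("molecule classification honours the tRNA boundary exactly", {
  ann <- tls_annotation()
  reads <- dplyr::bind_rows(
    make_read("c1", "u1", "Chr1", "+", 1900, 2020),  # 1 bp into the tRNA
    make_read("c1", "u2", "Chr1", "+", 1900, 2019),  # ends at tRNA start - 1
    make_read("c1", "u3", "Chr1", "+", 1100, 1200),  # 5' half of the host
    make_read("c1", "u4", "Chr1", "+", 1900, 2000),
    make_read("c1", "u4", "Chr1", "+", 2095, 2200)   # past the tRNA, no overlap
  )
  cls <- classify_molecules(reads, "host", "trna", ann)
  lab <- stats::setNames(cls$label, cls$umi)
  expect_equal(unname(lab[c("u1", "u2", "u3", "u4")]),
               c("tls", "mono", "mono", "mono"))
  flg <- stats::setNames(cls$flagged, cls$umi)
  expect_false(any(flg[c("u1", "u2", "u3")]))
  expect_true(flg["u4"])
})

test_that("molecules never touching the host are excluded and labels partition the rest", {
  ann <- tls_annotation()
  reads <- dplyr::bind_rows(
    make_read("c1", "u1", "Chr1", "+", 2030, 2090),  # tRNA only
    make_read("c2", "u2", "Chr1", "+", 1500, 1600)
  )
  cls <- classify_molecules(reads, "host", "trna", ann)
  expect_equal(cls$cell, "c2")
  expect_true(all(cls$label %in% c("mono", "tls")))
})

test_that("classification is strand-aware on a minus-strand locus", {
  ann <- tibble::tibble(
    gene_id = c("trna", "host"), chrom = "Chr1", strand = "-",
    start = c(500L, 1000L), end = c(574L, 2000L),
    biotype = c("tRNA", "protein_coding"), plastid = FALSE
  )
  reads <- dplyr::bind_rows(
    make_read("c1", "u1", "Chr1", "-", 560, 1100),  # into the tRNA
    make_read("c1", "u2", "Chr1", "-", 575, 1100),  # ends at base before tRNA
    make_read("c1", "u3", "Chr1", "-", 100, 400),
    make_read("c1", "u3", "Chr1", "-", 1200, 1300)  # past tRNA, no overlap
  )
  cls <- classify_molecules(reads, "host", "trna", ann)
  lab <- stats::setNames(cls$label, cls$umi)
  expect_equal(unname(lab[c("u1", "u2")]), c("tls", "mono"))
  expect_true(cls$flagged[cls$umi == "u3"])
  expect_error(classify_molecules(reads, "trna", "host", ann),
               class = "dielsc_argument_error")
})

test_that("planted per-cluster read-through fractions drive the enrichment verdict", {
  ann <- simulate_annotation(1, tls_host = TRUE, seed = 96)
  tr <- sim_truth(n_cells_per_cluster = c(250, 250),
                  tls_fractions = c(0.10, 0.03), seed = 96)
  reads <- simulate_reads(ann, tr, depth_per_cell = 15)
  m <- collapse_umis(reads, ann)
  cls <- classify_molecules(reads, "host01", "trna01", ann)
  e <- tls_cluster_enrichment(cls, truth_clusters(tr), m)
  expect_true(e$enriched[e$cluster == 1])
  expect_false(e$enriched[e$cluster == 2])
  expect_lt(abs(e$tls_ratio[1] - 0.10),
            3 * sqrt(0.1 * 0.9 / (e$n_tls + e$n_mono)[1]))
})

test_that("short-read capture makes the estimated ratio a lower bound on the planted fraction", {
  est <- vapply(97:99, function(s) {
    ann <- simulate_annotation(1, tls_host = TRUE, seed = s)
    tr <- sim_truth(n_cells_per_cluster = 300, n_clusters = 1,
                    tls_fractions = 0.3, seed = s)
    reads <- simulate_reads(ann, tr, depth_per_cell = 3, tls_capture = 0.6)
    cls <- classify_molecules(reads, "host01", "trna01", ann)
    sum(cls$label == "tls") / nrow(cls)
  }, numeric(1))
  expect_lt(mean(est), 0.3)
})
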