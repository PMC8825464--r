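two_group_counts <- function(values_a, values_b, gene = "gX", filler = 4L) {
  # one gene of interest plus a constant filler gene, two groups of cells
  n <- length(values_a) + length(values_b)
  counts <- cbind(c(values_a, values_b), rep(filler, n))
  dimnames(counts) <- list(sprintf("c%02d", seq_len(n)), c(gene, "filler"))
  list(
    m = umi_counts(counts),
    clusters = as_cluster_assignment(tibble::tibble(
      cell = rownames(counts),
      cluster = rep(1:2, c(length(values_a), length(values_b)))))
  )
}

test_that("a gene absent from a cluster is never its marker", {
  fix <- two_group_counts(rep(0L, 10), c(5L, 6L, 7L, 8L, 9L, 5L, 6L, 7L, 8L, 9L))
  mk <- find_markers(fix$m, fix$clusters)
  row <- mk[mk$gene == "gX" & mk$cluster == 1, ]
  expect_true(nrow(row) == 0 || !row$is_marker)
  # and it is a marker of the cluster that does express it
  expect_true(mk$is_marker[mk$gene == "gX" & mk$cluster == 2])
})

test_that("planted markers are recovered and flagged only in their cluster", {
  tr <- sim_truth(n_cells_per_cluster = c(100, 100),
                  n_markers_per_cluster = 10, seed = 61)
  m <- simulate_counts(tr)
  mk <- find_markers(m, truth_clusters(tr))
  truth_key <- paste(tr$markers$gene, tr$markers$cluster)
  found_key <- paste(mk$gene[mk$is_marker], mk$cluster[mk$is_marker])
  expect_gte(mean(truth_key %in% found_key), 0.9)
})

test_that("six-versus-six p-values equal the exact enumeration over all splits", {
  vals_a <- c(3L, 8L, 12L, 17L, 23L, 31L)
  vals_b <- c(5L, 9L, 14L, 40L, 55L, 70L)
  fix <- two_group_counts(vals_a, vals_b, filler = 100L)
  mk <- find_markers(fix$m, fix$clusters, logfc_min = 0, min_pct = 0)
  X <- normalize_counts(fix$m)[, "gX"]
  p_oracle <- oracle_exact_wilcox_p(X[1:6], X[7:12])
  expect_equal(mk$p[mk$gene == "gX" & mk$cluster == 1], p_oracle)
  expect_equal(mk$p[mk$gene == "gX" & mk$cluster == 2], p_oracle)
})

test_that("marker tables are invariant to cell order", {
  tr <- sim_truth(n_cells_per_cluster = c(40, 40), seed = 62)
  m <- simulate_counts(tr)
  cl <- truth_clusters(tr)
  perm <- withr::with_seed(3, sample(nrow(m$counts)))
  m_perm <- subset_cells(m, rownames(m$counts)[perm])
  cl_perm <- as_cluster_assignment(cl[perm, ])
  mk1 <- dplyr::arrange(find_markers(m, cl), cluster, gene)
  mk2 <- dplyr::arrange(find_markers(m_perm, cl_perm), cluster, gene)
  expect_equal(mk1, mk2)
})

test_that("clusters with fewer than three cells are skipped with a warning", {
  counts <- matrix(rpois(60, 5), 12, 5,
                   dimnames = list(sprintf("c%02d", 1:12), sprintf("g%d", 1:5)))
  m <- umi_counts(counts)
  cl <- as_cluster_assignment(tibble::tibble(
    cell = rownames(counts), cluster = c(rep(1L, 6), rep(2L, 4), 3L, 3L)))
  expect_warning(mk <- find_markers(m, cl), "Cluster 3 skipped")
  expect_false(any(mk$cluster == 3))
})

test_that("Jaccard overlap handles identity, disjointness and the 82/264 case", {
  a <- list(`1` = c("g1", "g2", "g3"), `2` = sprintf("x%03d", 1:150))
  b <- list(`1` = c("g1", "g2", "g3"), `2` = sprintf("y%03d", 1:196))
  j <- jaccard_overlap(a, b)
  expect_equal(j$jaccard[j$cluster_a == "1" & j$cluster_b == "1"], 1)
  expect_equal(j$jaccard[j$cluster_a == "1" & j$cluster_b == "2"], 0)
  # sets sharing 82 genes out of a union of 264
  shared <- sprintf("s%03d", 1:82)
  a2 <- list(k = c(shared, sprintf("a%03d", 1:68)))   # 150 markers
  b2 <- list(k = c(shared, sprintf("b%03d", 1:114)))  # 196 markers
  j2 <- jaccard_overlap(a2, b2)
  expect_equal(j2$n_intersect, 82)
  expect_equal(j2$n_union, 264)
  expect_equal(j2$jaccard, 82 / 264)
  expect_equal(round(j2$jaccard, 2), 0.31)
})

test_that("Jaccard is symmetric, bounded, 1 only for equal sets, and flags empty pairs", {
  sets <- withr::with_seed(64, lapply(1:4, function(i)
    sample(sprintf("g%02d", 1:40), sample(5:20, 1))))
  names(sets) <- paste0("k", 1:4)
  j_ab <- jaccard_overlap(sets, sets)
  expect_true(all(j_ab$jaccard >= 0 & j_ab$jaccard <= 1))
  wide <- matrix(j_ab$jaccard, 4, 4, byrow = FALSE)
  expect_equal(wide, t(wide))
  diag_rows <- j_ab[j_ab$cluster_a == j_ab$cluster_b, ]
  expect_equal(diag_rows$jaccard, rep(1, 4))
  off <- j_ab[j_ab$cluster_a != j_ab$cluster_b, ]
  expect_true(all(off$jaccard < 1))  # sets drawn distinct
  j_empty <- jaccard_overlap(list(a = character()), list(b = character()))
  expect_equal(j_empty$jaccard, 0)
  expect_true(j_empty$both_empty)
})

test_that("marker sets are extracted from tables and passed through as lists", {
  tbl <- tibble::tibble(gene = c("g1", "g2", "g3"), cluster = c(1, 1, 2),
                        is_marker = c(TRUE, FALSE, TRUE))
  expect_equal(marker_sets(tbl), list(`1` = "g1", `2` = "g3"))
  lst <- list(a = c("g1", "g2"))
  expect_identical(marker_sets(lst), lst)
})
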