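test_that("an all-ED experiment gives composition (1, 0) everywhere", {
  cl <- as_cluster_assignment(tibble::tibble(
    cell = sprintf("c%02d", 1:20), cluster = rep(1:2, each = 10)))
  meta <- tibble::tibble(cell = cl$cell, timepoint = "ED")
  tc <- time_composition(cl, meta)
  expect_equal(tc$frac_ed, c(1, 1))
  expect_equal(tc$frac_en, c(0, 0))
  expect_false(any(tc$mixed))
})

test_that("a balanced day/night design gives near-half fractions and mixed clusters", {
  tr <- sim_truth(n_cells_per_cluster = c(100, 100), seed = 71)
  tc <- time_composition(truth_clusters(tr), tr$cells)
  expect_true(all(abs(tc$frac_ed - 0.5) <= 3 * sqrt(0.25 / tc$n_cells)))
  expect_true(all(tc$mixed))
})

test_that("batch-driven clusters are dominated by one timepoint", {
  tr <- sim_truth(n_cells_per_cluster = c(80, 80),
                  timepoint_design = "by_cluster", seed = 72)
  tc <- time_composition(truth_clusters(tr), tr$cells)
  expect_true(all(pmax(tc$frac_ed, tc$frac_en) >= 0.95))
  expect_false(any(tc$mixed))
})

test_that("a missing timepoint is an error naming the cell", {
  cl <- as_cluster_assignment(tibble::tibble(cell = c("aa", "bb"),
                                             cluster = c(1L, 1L)))
  meta <- tibble::tibble(cell = "aa", timepoint = "ED")
  expect_error(time_composition(cl, meta), regexp = "bb",
               class = "dielsc_consistency_error")
})

test_that("identical day and night expression leaves no exclusive markers", {
  # the EN cells carry literally the same counts as the ED cells, so the
  # two time-restricted marker tables must coincide exactly
  tr <- sim_truth(n_cells_per_cluster = c(50, 50), seed = 73)
  half <- simulate_counts(tr, batch_shift = 0)
  counts <- rbind(as.matrix(half$counts), as.matrix(half$counts))
  rownames(counts) <- c(paste0(rownames(half$counts), "_ed"),
                        paste0(rownames(half$counts), "_en"))
  m <- umi_counts(counts, cell_meta = tibble::tibble(
    cell = rownames(counts),
    timepoint = rep(c("ED", "EN"), each = nrow(half$counts))))
  cl <- as_cluster_assignment(tibble::tibble(
    cell = rownames(counts), cluster = rep(half$cell_meta$cluster, 2)))
  sp <- split_markers_by_time(m, cl)
  expect_equal(nrow(sp$exclusive), 0)
  # and both time points recover the planted markers
  truth_key <- paste(tr$markers$gene, tr$markers$cluster)
  expect_gte(mean(truth_key %in%
                    paste(sp$ed$gene[sp$ed$is_marker],
                          sp$ed$cluster[sp$ed$is_marker])), 0.9)
})

test_that("a time-restricted cluster marker appears exclusive without global day/night DE", {
  withr::with_seed(74, {
    n_per <- 60  # cells per cluster x timepoint combination
    cluster <- rep(1:2, each = 2 * n_per)
    timepoint <- rep(c("ED", "EN", "ED", "EN"), each = n_per)
    cells <- sprintf("c%03d", seq_along(cluster))
    mu <- matrix(3, length(cells), 30)
    # gene 1: elevated in (cluster 1, ED) and, symmetrically, (cluster 2, EN)
    mu[cluster == 1 & timepoint == "ED", 1] <- 24
    mu[cluster == 2 & timepoint == "EN", 1] <- 24
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2),
                     nrow = nrow(mu),
                     dimnames = list(cells, sprintf("g%02d", 1:30)))
    m <- umi_counts(counts,
                    cell_meta = tibble::tibble(cell = cells,
                                               timepoint = timepoint))
    cl <- as_cluster_assignment(tibble::tibble(cell = cells, cluster = cluster))
    sp <- split_markers_by_time(m, cl)
    excl <- sp$exclusive
    expect_true(any(excl$gene == "g01" & excl$cluster == 1 &
                      excl$timepoint == "ED"))
    expect_true(any(excl$gene == "g01" & excl$cluster == 2 &
                      excl$timepoint == "EN"))
    expect_false(any(excl$global_de[excl$gene == "g01"]))
  })
})
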