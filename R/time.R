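#' Day/night composition of clusters
#'
#' Per-cluster fractions of end-of-day (ED) and end-of-night (EN) cells. A
#' cluster is classified as `mixed` when its minority time point holds at
#' least `mixed_threshold` of the cells; otherwise it is dominated by one
#' harvest time.
#'
#' @param clusters A `cluster_assignment`.
#' @param cell_meta Tibble with `cell` and `timepoint` (`"ED"`/`"EN"`)
#'   columns, e.g. the `cell_meta` of a [umi_counts()] object.
#' @param mixed_threshold Minority-fraction cutoff for calling a cluster
#'   mixed.
#' @return A `time_composition` tibble: `cluster`, `n_cells`, `frac_ed`,
#'   `frac_en`, `mixed`.
#' @export
time_composition <- function(clusters, cell_meta, mixed_threshold = 0.25) {
  stopifnot(is.data.frame(cell_meta),
            all(c("cell", "timepoint") %in% names(cell_meta)))
  tp <- setNames(cell_meta$timepoint, cell_meta$cell)[clusters$cell]
  if (anyNA(tp)) {
    missing <- clusters$cell[is.na(tp)]
    abort(paste0("No timepoint for cell(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "dielsc_consistency_error")
  }
  bad <- setdiff(unique(tp), c("ED", "EN"))
  if (length(bad)) abort(paste0("Unknown timepoint(s): ", paste(bad, collapse = ", ")))
  out <- tibble(cluster = clusters$cluster, timepoint = tp) |>
    count(.data$cluster, .data$timepoint) |>
    pivot_wider(names_from = "timepoint", values_from = "n",
                values_fill = 0L)
  for (col in c("ED", "EN")) if (!col %in% names(out)) out[[col]] <- 0L
  out <- out |>
    mutate(n_cells = .data$ED + .data$EN,
           frac_ed = .data$ED / .data$n_cells,
           frac_en = .data$EN / .data$n_cells,
           mixed = pmin(.data$frac_ed, .data$frac_en) >= mixed_threshold) |>
    select("cluster", "n_cells", "frac_ed", "frac_en", "mixed") |>
    arrange(.data$cluster)
  class(out) <- c("time_composition", class(out))
  out
}

#' Time-split marker analysis
#'
#' Runs [find_markers()] separately on the ED cells and on the EN cells
#' (same clusters, same thresholds), then reports the gene/cluster marker
#' calls exclusive to one time point. For every exclusive marker the global
#' ED-vs-EN contrast (Wilcoxon across all cells, same adjustment) is
#' attached — the interesting cases are time-specific cluster markers that
#' are *not* globally differential between day and night.
#'
#' Clusters losing one time point entirely (or falling below 3 cells) are
#' skipped within that time point by [find_markers()].
#'
#' @inheritParams find_markers
#' @param cell_meta Optional `cell`/`timepoint` table; defaults to
#'   `m$cell_meta`.
#' @return A list with elements `ed` and `en` (marker tibbles) and
#'   `exclusive`: a tibble `gene`, `cluster`, `timepoint`, `log_fc`,
#'   `p_adj`, `global_p_adj`, `global_de`.
#' @export
split_markers_by_time <- function(m, clusters,
                                  logfc_min = 0.25, min_pct = 0.05,
                                  alpha = 0.05,
                                  p_adjust = c("bonferroni", "BH"),
                                  cell_meta = NULL) {
  stopifnot(inherits(m, "umi_counts"))
  p_adjust <- match.arg(p_adjust)
  cell_meta <- cell_meta %||% m$cell_meta
  stopifnot(all(c("cell", "timepoint") %in% names(cell_meta)))
  tp <- setNames(cell_meta$timepoint, cell_meta$cell)

  one_side <- function(side) {
    cells <- clusters$cell[tp[clusters$cell] == side]
    find_markers(subset_cells(m, cells),
                 as_cluster_assignment(clusters[clusters$cell %in% cells, ]),
                 logfc_min = logfc_min, min_pct = min_pct, alpha = alpha,
                 p_adjust = p_adjust)
  }
  ed <- one_side("ED")
  en <- one_side("EN")

  key <- function(x) paste(x$gene, x$cluster)
  ed_m <- filter(ed, .data$is_marker)
  en_m <- filter(en, .data$is_marker)
  excl <- bind_rows(
    ed_m |> filter(!key(ed_m) %in% key(en_m)) |> mutate(timepoint = "ED"),
    en_m |> filter(!key(en_m) %in% key(ed_m)) |> mutate(timepoint = "EN")
  ) |>
    select("gene", "cluster", "timepoint", "log_fc", "p_adj")

  if (nrow(excl) > 0) {
    # global ED-vs-EN contrast for the exclusive genes only
    genes <- unique(excl$gene)
    mg <- m
    mg$counts <- mg$counts[, genes, drop = FALSE]
    mg$gene_meta <- mg$gene_meta[match(genes, mg$gene_meta$gene), ]
    tp_clusters <- as_cluster_assignment(
      tibble(cell = clusters$cell,
             cluster = ifelse(tp[clusters$cell] == "ED", 1L, 2L)))
    glob <- find_markers(mg, tp_clusters, logfc_min = 0, min_pct = 0,
                         alpha = alpha, p_adjust = p_adjust) |>
      group_by(.data$gene) |>
      summarise(global_p_adj = min(.data$p_adj), .groups = "drop")
    excl <- excl |>
      left_join(glob, by = "gene") |>
      mutate(global_p_adj = coalesce(.data$global_p_adj, 1),
             global_de = .data$global_p_adj < alpha)
  } else {
    excl$global_p_adj <- numeric()
    excl$global_de <- logical()
  }
  list(ed = ed, en = en, exclusive = excl)
}
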