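#' Plot a cluster robustness report
#'
#' Bar chart of per-cluster co-occurrence scores with the star bins marked
#' at 25/50/75.
#'
#' @param object A `robustness_report` from [robustness_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot robustness_report
#' @export
autoplot.robustness_report <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$cluster), y = .data$score,
                     fill = .data$stars)) +
    geom_col() +
    geom_hline(yintercept = c(25, 50, 75), linetype = "dashed",
               colour = "grey40") +
    geom_text(aes(label = ifelse(.data$stars == "none", "", .data$stars)),
              vjust = -0.4, size = 3) +
    scale_fill_manual(values = c("***" = "#1b7837", "**" = "#a6dba0",
                                 "*" = "#fdb863", "none" = "#b2182b"),
                      name = "robustness") +
    coord_cartesian(ylim = c(0, 105)) +
    labs(x = "cluster", y = "co-occurrence score (%)",
         title = "Cluster robustness under read subsampling") +
    theme_minimal()
}

#' Plot day/night cluster composition
#'
#' Stacked per-cluster bars of end-of-day vs end-of-night cell fractions;
#' mixed clusters are marked.
#'
#' @param object A `time_composition` from [time_composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot time_composition
#' @export
autoplot.time_composition <- function(object, ...) {
  long <- object |>
    pivot_longer(c("frac_ed", "frac_en"), names_to = "timepoint",
                 values_to = "fraction") |>
    mutate(timepoint = ifelse(.data$timepoint == "frac_ed", "ED", "EN"))
  ggplot(long, aes(x = factor(.data$cluster), y = .data$fraction,
                   fill = .data$timepoint)) +
    geom_col() +
    geom_point(data = filter(object, .data$mixed),
               aes(x = factor(.data$cluster), y = 1.03),
               inherit.aes = FALSE, shape = 18) +
    scale_fill_manual(values = c(ED = "#fee391", EN = "#225ea8")) +
    labs(x = "cluster", y = "fraction of cells",
         title = "ED/EN composition per cluster (mixed clusters marked)") +
    theme_minimal()
}

#' Marker dot plot
#'
#' The standard dot-plot summary for selected genes across clusters: dot
#' size is the fraction of expressing cells, colour the mean normalized
#' expression over expressing cells.
#'
#' @param m A [umi_counts()] object.
#' @param clusters A `cluster_assignment`.
#' @param genes Character vector of genes to show.
#' @param expressing_only Average expression over expressing cells only
#'   (default), as in per-cluster transcript-accumulation dot plots.
#' @return A ggplot object.
#' @export
plot_marker_dotplot <- function(m, clusters, genes, expressing_only = TRUE) {
  stopifnot(inherits(m, "umi_counts"), all(genes %in% colnames(m$counts)))
  X <- normalize_counts(subset_cells(m, clusters$cell))[, genes, drop = FALSE]
  df <- as_tibble(X) |>
    mutate(cluster = clusters$cluster) |>
    pivot_longer(-"cluster", names_to = "gene", values_to = "expr") |>
    group_by(.data$cluster, .data$gene) |>
    summarise(
      pct = mean(.data$expr > 0),
      mean_expr = if (expressing_only) {
        ifelse(any(.data$expr > 0), mean(.data$expr[.data$expr > 0]), 0)
      } else mean(.data$expr),
      .groups = "drop"
    )
  ggplot(df, aes(x = factor(.data$cluster), y = .data$gene,
                 size = .data$pct, colour = .data$mean_expr)) +
    geom_point() +
    scale_size_area(max_size = 6, name = "% cells") +
    scale_colour_viridis_c(name = "mean expr") +
    labs(x = "cluster", y = NULL) +
    theme_minimal()
}

#' Cell QC scatter plot
#'
#' Transcripts vs detected genes per cell, coloured by filter verdict, with
#' the cutoffs drawn.
#'
#' @inheritParams filter_cells
#' @return A ggplot object.
#' @export
plot_cell_qc <- function(m, min_transcripts = 500, min_genes = 200,
                         max_plastid_fraction = 0.2) {
  qc <- cell_qc(m, min_transcripts, min_genes, max_plastid_fraction)
  ggplot(qc, aes(x = .data$n_transcripts, y = .data$n_genes,
                 colour = .data$pass)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = min_transcripts, linetype = "dashed") +
    geom_hline(yintercept = min_genes, linetype = "dashed") +
    scale_x_log10() + scale_y_log10() +
    scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "#b2182b"),
                        name = "retained") +
    labs(x = "transcripts per cell (UMIs)", y = "detected genes per cell") +
    theme_minimal()
}
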