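#' Hypergeometric category enrichment of marker sets
#'
#' Upper-tail hypergeometric test of every functional category against every
#' marker set: with a universe of `N` genes of which `K` belong to the
#' category, and `n` markers of which `k` are in the category, the reported
#' p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Significance is
#' called at unadjusted `p < alpha` (the stated convention); a
#' Benjamini-Hochberg option is available.
#'
#' @param markers A marker tibble from [find_markers()] (split per cluster),
#'   a named list of gene sets, or a single character vector.
#' @param categories Two-column tibble mapping `gene` to `category` (a gene
#'   may appear in several categories).
#' @param universe Character vector of background genes. Defaults to the
#'   union of category genes and markers. Must be non-empty and cover both.
#' @param alpha Significance threshold.
#' @param p_adjust `"none"` (default, per the stated method) or `"BH"`.
#' @return Tibble: `cluster` (`NA` for a plain set), `category`, `k`, `K`,
#'   `n`, `N`, `p`, `significant`.
#' @export
hypergeom_enrichment <- function(markers, categories, universe = NULL,
                                 alpha = 0.05,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(categories),
            all(c("gene", "category") %in% names(categories)))
  sets <- if (is.character(markers)) list(markers) else marker_sets(markers)
  set_labels <- names(sets) %||% rep(NA_character_, length(sets))

  universe <- unique(universe %||% union(categories$gene,
                                         unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    abort("`universe` is empty.", class = "dielsc_argument_error")
  }
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside)) {
    abort(paste0("Marker genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")),
          class = "dielsc_argument_error")
  }
  categories <- filter(categories, .data$gene %in% universe)
  cat_sets <- split(unique(categories)$gene, unique(categories)$category)
  N <- length(universe)

  out <- pmap(
    expand.grid(set_idx = seq_along(sets), category = names(cat_sets),
                stringsAsFactors = FALSE),
    function(set_idx, category) {
      mk <- unique(sets[[set_idx]])
      cs <- cat_sets[[category]]
      k <- length(intersect(mk, cs))
      K <- length(cs)
      n <- length(mk)
      tibble(cluster = set_labels[set_idx], category = category,
             k = k, K = K, n = n, N = N,
             p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
    }
  ) |>
    list_rbind()
  if (p_adjust == "BH") out$p <- p.adjust(out$p, method = "BH")
  out |>
    mutate(significant = .data$p < alpha) |>
    arrange(.data$cluster, .data$p)
}
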