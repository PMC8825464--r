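#' Simulate barcode/UMI-tagged aligned reads with planted read-through truth
#'
#' Emulates the tagged alignments a droplet scRNA-seq pipeline produces, at
#' the level this toolkit consumes: each read carries a cell barcode, a UMI,
#' a chromosome, a strand and one or more aligned blocks (1-based, closed).
#' Three read classes are generated:
#'
#' * background molecules: `depth_per_cell` molecules per cell, each one
#'   single-block read contained entirely within one randomly chosen gene;
#' * planted di-cistronic support: for every pair in
#'   `truth$dicistronic_pairs`, exactly `support` reads whose single block
#'   spans the inter-genic junction and overlaps both genes;
#' * host/tRNA read-through molecules: if `truth$tls_fractions` is set (and
#'   the annotation carries a host/tRNA locus), each cell receives
#'   `Pois(host_mean_molecules)` host-gene molecules; a molecule reads
#'   through into the tRNA with its cluster's planted fraction. A
#'   read-through molecule yields a junction-spanning read with probability
#'   `tls_capture` (reads too short to reach the junction are the reason the
#'   observed TLS ratio underestimates the planted fraction).
#'
#' All molecules of the non-read-through classes stay strictly inside their
#' source gene, so they can never support a gene pair. Output is
#' deterministic given `truth$seed`.
#'
#' @param annotation Annotation tibble from [simulate_annotation()].
#' @param truth A [sim_truth()] object.
#' @param depth_per_cell Background molecules per cell.
#' @param read_length Read length in bp.
#' @param junction_overhang How far (bp) a junction read extends into each
#'   flanking gene.
#' @param host_mean_molecules Poisson mean of host-gene molecules per cell.
#' @param tls_capture Probability that a read-through molecule produces a
#'   junction-spanning read (see Details).
#' @param umi_length UMI length in nt.
#'
#' @return A tibble of tagged reads: `cell`, `umi`, `chrom`, `strand`,
#'   `block_starts`, `block_ends` (list-columns of integer vectors).
#'   Attribute `"tls_molecules"` records the realised per-molecule truth
#'   (`cell`, `umi`, `tls`, `captured`) when read-through is simulated.
#' @export
simulate_reads <- function(annotation, truth,
                           depth_per_cell = 30,
                           read_length = 100L,
                           junction_overhang = 30L,
                           host_mean_molecules = 3,
                           tls_capture = 1,
                           umi_length = 8L) {
  stopifnot(inherits(truth, "sim_truth"), is.data.frame(annotation))
  depth_per_cell <- check_count(depth_per_cell, "depth_per_cell")
  tls_capture <- check_fraction(tls_capture, "tls_capture")
  read_length <- check_count(read_length, "read_length")
  cells <- truth$cells
  tls <- annotation_tls(annotation)

  if (!is.null(truth$dicistronic_pairs)) {
    missing <- setdiff(
      c(truth$dicistronic_pairs$gene_a, truth$dicistronic_pairs$gene_b),
      annotation$gene_id
    )
    if (length(missing)) {
      abort(paste0("Planted di-cistronic genes absent from annotation: ",
                   paste(missing, collapse = ", ")),
            class = "dielsc_consistency_error")
    }
  }
  if (!is.null(truth$tls_fractions) && is.null(tls)) {
    abort("Truth plants TLS fractions but the annotation has no host/tRNA locus.",
          class = "dielsc_consistency_error")
  }

  ann_idx <- setNames(seq_len(nrow(annotation)), annotation$gene_id)

  with_seed(truth$seed, {
    out <- list()

    ## -- background molecules: one read strictly inside one gene ------------
    pool <- annotation
    if (!is.null(tls)) {
      pool <- filter(pool, !.data$gene_id %in% c(tls$host, tls$trna))
    }
    pool <- filter(pool, .data$biotype != "tRNA")
    n_bg <- nrow(cells) * depth_per_cell
    if (n_bg > 0 && nrow(pool) > 0) {
      gi <- sample.int(nrow(pool), n_bg, replace = TRUE)
      g_start <- pool$start[gi]
      g_end <- pool$end[gi]
      len <- g_end - g_start + 1L
      off <- floor(runif(n_bg) * pmax(1L, len - read_length + 1L))
      r_start <- g_start + as.integer(off)
      r_end <- pmin(r_start + read_length - 1L, g_end)
      out$background <- new_tagged_reads(
        cell = rep(cells$cell, each = depth_per_cell),
        umi = random_nt(n_bg, umi_length),
        chrom = pool$chrom[gi],
        strand = pool$strand[gi],
        block_starts = as.list(r_start),
        block_ends = as.list(r_end)
      )
    }

    ## -- planted di-cistronic junction reads --------------------------------
    dp <- truth$dicistronic_pairs
    if (!is.null(dp) && nrow(dp) > 0 && sum(dp$support) > 0) {
      if (nrow(cells) == 0) {
        abort("Cannot plant di-cistronic reads without cells.",
              class = "dielsc_consistency_error")
      }
      n_dc <- sum(dp$support)
      pi <- rep(seq_len(nrow(dp)), dp$support)
      a <- ann_idx[dp$gene_a[pi]]
      b <- ann_idx[dp$gene_b[pi]]
      # order by coordinate so the block spans left gene end -> right gene start
      left <- ifelse(annotation$start[a] <= annotation$start[b], a, b)
      right <- ifelse(annotation$start[a] <= annotation$start[b], b, a)
      r_start <- pmax(annotation$start[left],
                      annotation$end[left] - junction_overhang + 1L)
      r_end <- pmin(annotation$end[right],
                    annotation$start[right] + junction_overhang - 1L)
      out$dicistronic <- new_tagged_reads(
        cell = sample(cells$cell, n_dc, replace = TRUE),
        umi = random_nt(n_dc, umi_length),
        chrom = annotation$chrom[left],
        strand = annotation$strand[left],
        block_starts = as.list(as.integer(r_start)),
        block_ends = as.list(as.integer(r_end))
      )
    }

    ## -- host-gene molecules with per-cluster read-through ------------------
    tls_mol <- NULL
    if (!is.null(truth$tls_fractions) && nrow(cells) > 0) {
      h <- annotation[ann_idx[tls$host], ]
      tr <- annotation[ann_idx[tls$trna], ]
      frac <- setNames(truth$tls_fractions$tls_fraction,
                       truth$tls_fractions$cluster)
      n_per_cell <- rpois(nrow(cells), host_mean_molecules)
      n_mol <- sum(n_per_cell)
      if (n_mol > 0) {
        mol_cell <- rep(cells$cell, n_per_cell)
        mol_cluster <- rep(cells$cluster, n_per_cell)
        mol_umi <- random_nt(n_mol, umi_length)
        is_tls <- runif(n_mol) < frac[as.character(mol_cluster)]
        captured <- is_tls & (runif(n_mol) < tls_capture)

        # every molecule: one read strictly inside the host gene
        len <- h$end - h$start + 1L
        off <- floor(runif(n_mol) * pmax(1L, len - read_length + 1L))
        i_start <- h$start + as.integer(off)
        i_end <- pmin(i_start + read_length - 1L, h$end)
        internal <- new_tagged_reads(
          cell = mol_cell, umi = mol_umi, chrom = h$chrom, strand = h$strand,
          block_starts = as.list(i_start), block_ends = as.list(i_end)
        )

        # captured read-through molecules: plus one junction-spanning read
        if (any(captured)) {
          if (h$strand == "+") {
            j_start <- max(h$start, h$end - junction_overhang + 1L)
            j_end <- min(tr$end, tr$start + junction_overhang - 1L)
          } else {
            j_start <- max(tr$start, tr$end - junction_overhang + 1L)
            j_end <- min(h$end, h$start + junction_overhang - 1L)
          }
          junction <- new_tagged_reads(
            cell = mol_cell[captured], umi = mol_umi[captured],
            chrom = h$chrom, strand = h$strand,
            block_starts = as.list(rep(as.integer(j_start), sum(captured))),
            block_ends = as.list(rep(as.integer(j_end), sum(captured)))
          )
          out$tls <- bind_rows(internal, junction)
        } else {
          out$tls <- internal
        }
        tls_mol <- tibble(cell = mol_cell, umi = mol_umi,
                          tls = is_tls, captured = captured)
      }
    }

    reads <- if (length(out)) bind_rows(out) else empty_reads()
    attr(reads, "tls_molecules") <- tls_mol
    reads
  })
}
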