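# internal helpers shared across modules

# n random fixed-length nucleotide strings (Drop-seq style barcodes/UMIs)
random_nt <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# unique barcodes: resample duplicates until collision-free
unique_barcodes <- function(n, len = 12L) {
  bc <- random_nt(n, len)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- random_nt(sum(dup), len)
  }
  bc
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer, not %s.",
                  name, deparse(x)), class = "dielsc_argument_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "dielsc_argument_error")
  }
  as.numeric(x)
}

# flatten list-column read blocks into one row per aligned block
flatten_blocks <- function(reads) {
  nb <- lengths(reads$block_starts)
  tibble(
    read  = rep(seq_len(nrow(reads)), nb),
    cell  = rep(reads$cell, nb),
    umi   = rep(reads$umi, nb),
    chrom = rep(reads$chrom, nb),
    strand = rep(reads$strand, nb),
    start = as.integer(unlist(reads$block_starts, use.names = FALSE)),
    end   = as.integer(unlist(reads$block_ends, use.names = FALSE))
  )
}

genes_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id
  )
}

blocks_granges <- function(blocks) {
  GenomicRanges::GRanges(
    seqnames = blocks$chrom,
    ranges = IRanges::IRanges(start = blocks$start, end = blocks$end),
    strand = blocks$strand
  )
}

new_tagged_reads <- function(cell, umi, chrom, strand, block_starts, block_ends) {
  tibble(cell = cell, umi = umi, chrom = chrom, strand = strand,
         block_starts = block_starts, block_ends = block_ends)
}

empty_reads <- function() {
  new_tagged_reads(character(), character(), character(), character(),
                   list(), list())
}
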