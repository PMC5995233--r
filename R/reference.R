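# Toy reference genome + targeted gene panel generator. A deliberately small
# stand-in for the real capture target space: one contig carrying
# non-overlapping gene intervals separated by untargeted gaps, each gene
# assigned to the clinically actionable tier (1) or the analytic tier (2).

#' Generate a toy reference genome with a tiered gene panel
#'
#' Builds a seeded random DNA contig and lays `n_genes` non-overlapping gene
#' intervals on it, separated by `gap` untargeted bases. A fraction of genes
#' (rounded) is assigned to tier 1 — the clinically actionable gene set with
#' the lower limit of detection — and the remainder to tier 2.
#'
#' @param seed integer master seed; identical seeds give byte-identical
#'   references.
#' @param n_genes number of genes on the panel (>= 1).
#' @param gene_length length of every gene interval in bp (>= 50).
#' @param tier1_fraction fraction of genes assigned tier 1; the count is
#'   `round(tier1_fraction * n_genes)`.
#' @param gap untargeted bases between consecutive genes.
#' @param contig_name name of the single contig.
#' @return an object of class `toy_reference`: a list with `contigs` (named
#'   character vector of uppercase DNA), `genes` (data.table with columns
#'   `gene_id`, `contig`, `start` (0-based), `end` (exclusive), `tier`) and
#'   `seed`.
#' @examples
#' ref <- generate_reference(seed = 7, n_genes = 20, gene_length = 300,
#'                           tier1_fraction = 0.5)
#' sum(ref$genes$tier == 1) # 10
#' @export
generate_reference <- function(seed, n_genes = 20L, gene_length = 300L,
                               tier1_fraction = 0.5, gap = 50L,
                               contig_name = "panel_1") {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_genes, "n_genes", lo = 1)
  assert_scalar_number(gene_length, "gene_length", lo = 50)
  assert_scalar_number(tier1_fraction, "tier1_fraction", lo = 0, hi = 1)
  assert_scalar_number(gap, "gap", lo = 0)
  n_genes <- as.integer(n_genes); gene_length <- as.integer(gene_length)
  gap <- as.integer(gap)

  total_len <- gap + n_genes * (gene_length + gap)
  n_tier1 <- as.integer(round_half_up(tier1_fraction * n_genes))

  ref <- with_seed(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
                 collapse = "")
    tiers <- rep(2L, n_genes)
    if (n_tier1 > 0) tiers[sample.int(n_genes, n_tier1)] <- 1L
    start <- gap + (seq_len(n_genes) - 1L) * (gene_length + gap)
    genes <- data.table::data.table(
      gene_id = sprintf("GENE%03d", seq_len(n_genes)),
      contig = contig_name,
      start = start,
      end = start + gene_length,
      tier = tiers
    )
    list(contigs = stats::setNames(seq, contig_name), genes = genes)
  })
  out <- structure(list(contigs = ref$contigs, genes = ref$genes,
                        seed = as.integer(seed)),
                   class = "toy_reference")
  validate_reference(out)
  out
}

validate_reference <- function(ref) {
  if (!inherits(ref, "toy_reference")) stop_param("not a toy_reference")
  if (any(nchar(ref$contigs) == 0)) stop_param("empty contig sequence")
  if (any(grepl("[^ACGT]", ref$contigs))) stop_param("contig alphabet must be {A,C,G,T}")
  g <- ref$genes
  if (any(g$start >= g$end)) stop_param("gene intervals must satisfy start < end")
  if (!all(g$tier %in% c(1L, 2L))) stop_param("gene tier must be 1 or 2")
  if (any(g$end > nchar(ref$contigs[g$contig]))) {
    stop_param("gene interval exceeds contig bounds")
  }
  ov <- g[order(contig, start),
          any(start < data.table::shift(end, fill = -1L)), by = contig]$V1
  if (any(ov)) stop_param("gene intervals overlap")
  invisible(ref)
}

#' @export
print.toy_reference <- function(x, ...) {
  cat(sprintf("toy_reference: %d contig(s), %d genes (%d tier-1), seed %d\n",
              length(x$contigs), nrow(x$genes), sum(x$genes$tier == 1L),
              x$seed))
  invisible(x)
}

#' Enumerate targeted panel positions
#'
#' Expands the gene intervals of a reference into one row per targeted base,
#' with the reference base and the owning gene/tier. This is the site
#' universe over which pileups are simulated and QC is computed.
#'
#' @param reference a `toy_reference`.
#' @return data.table with columns `contig`, `pos` (1-based), `ref`
#'   (reference base), `gene_id`, `tier`.
#' @export
panel_positions <- function(reference) {
  validate_reference(reference)
  g <- reference$genes
  bases <- strsplit(reference$contigs, "", fixed = TRUE)
  out <- g[, {
    p <- (start + 1L):end
    list(pos = p, ref = bases[[contig]][p], tier = tier)
  }, by = .(gene_id, contig)]
  data.table::setcolorder(out, c("contig", "pos", "ref", "gene_id", "tier"))
  out[order(contig, pos)]
}

contig_base <- function(reference, contig_name, pos) {
  substring(reference$contigs[[contig_name]], pos, pos)
}

#' Write a toy reference as FASTA and its panel as BED
#'
#' The panel BED is 5-column (chrom, 0-based start, end-exclusive, gene_id,
#' tier), readable back with [read_panel_bed()].
#'
#' @param reference a `toy_reference`.
#' @param fasta,bed output paths.
#' @return invisibly, the paths written.
#' @export
write_reference_fasta <- function(reference, fasta) {
  validate_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$contigs),
                              fasta)
  invisible(fasta)
}

#' @rdname write_reference_fasta
#' @export
write_panel_bed <- function(reference, bed) {
  validate_reference(reference)
  g <- reference$genes[, .(contig, start, end, gene_id, tier)]
  data.table::fwrite(g, bed, sep = "\t", col.names = FALSE)
  invisible(bed)
}

#' Read a panel BED file
#'
#' @param bed path to a 5-column BED written by [write_panel_bed()].
#' @return data.table with columns `gene_id`, `contig`, `start`, `end`, `tier`.
#' @export
read_panel_bed <- function(bed) {
  g <- data.table::fread(bed, sep = "\t",
                         col.names = c("contig", "start", "end", "gene_id", "tier"))
  data.table::setcolorder(g, c("gene_id", "contig", "start", "end", "tier"))
  g[]
}

#' Read a FASTA reference back into a named character vector
#'
#' @param fasta path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_contigs <- function(fasta) {
  x <- Biostrings::readDNAStringSet(fasta)
  stats::setNames(as.character(x), names(x))
}
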