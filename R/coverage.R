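# Per-gene coverage simulation for copy-number analysis. A gene's expected
# coverage scales with the admixture-weighted copy number:
# (purity * copies + (1 - purity) * 2) / 2, i.e. a diploid gene in a pure
# sample has scale 1. Multiplicative log-normal noise models library and
# capture variability between genes.

#' Declare a copy-number ground truth for one gene
#'
#' The event label is derived from the copy count using the assay's
#' presence/absence definitions: amplification at >= 6 copies, homozygous
#' deletion at 0 copies, otherwise normal.
#'
#' @param gene_id panel gene identifier.
#' @param true_copies non-negative copy number in the tumor cells.
#' @return one-row data.table: `gene_id`, `true_copies`, `event`.
#' @export
cnv_truth <- function(gene_id, true_copies) {
  if (any(true_copies < 0)) stop_param("true_copies must be >= 0")
  event <- ifelse(true_copies >= 6, "amplification",
                  ifelse(true_copies == 0, "homozygous_deletion", "normal"))
  data.table::data.table(gene_id = gene_id, true_copies = true_copies,
                         event = event)
}

#' Simulate per-gene mean coverage under copy-number events and admixture
#'
#' Each panel gene's mean depth is `profile$mean_depth` times the admixture
#' scale factor `(purity * C + (1 - purity) * 2) / 2` (C = 2 for genes absent
#' from `cnv_truths`) times log-normal noise `exp(N(0, dispersion))`.
#'
#' @param reference a `toy_reference`.
#' @param cnv_truths data.table from [cnv_truth()] (possibly empty); every
#'   gene must exist in the reference.
#' @param profile a [sample_profile()]; `purity` and `mean_depth` are used.
#' @param dispersion standard deviation of the log-normal noise (default
#'   0.05).
#' @return data.table of gene coverage: `gene_id`, `mean_depth`, `sample_id`.
#' @examples
#' ref <- generate_reference(seed = 1)
#' cov <- simulate_gene_coverage(ref, cnv_truth("GENE001", 8),
#'                               sample_profile("T1", "tumor", purity = 0.5))
#' @export
simulate_gene_coverage <- function(reference, cnv_truths, profile,
                                   dispersion = 0.05) {
  validate_reference(reference)
  if (!inherits(profile, "sample_profile")) stop_param("`profile` must be a sample_profile")
  assert_scalar_number(dispersion, "dispersion", lo = 0)
  genes <- reference$genes$gene_id
  cnv_truths <- data.table::as.data.table(cnv_truths)
  copies <- rep(2, length(genes))
  if (nrow(cnv_truths) > 0) {
    if (!all(cnv_truths$gene_id %in% genes)) {
      stop_consistency("cnv truth names a gene absent from the reference")
    }
    copies[match(cnv_truths$gene_id, genes)] <- cnv_truths$true_copies
  }
  scale <- (profile$purity * copies + (1 - profile$purity) * 2) / 2
  with_seed(profile$seed, {
    noise <- exp(rnorm(length(genes), 0, dispersion))
    data.table::data.table(gene_id = genes,
                           mean_depth = profile$mean_depth * scale * noise,
                           sample_id = profile$sample_id)
  })
}

#' Read/write per-gene coverage tables as TSV
#'
#' @param cov coverage data.table (`gene_id`, `mean_depth`, `sample_id`).
#' @param path file path.
#' @param seed optional provenance seed.
#' @return the path (write) or the table (read).
#' @export
write_coverage <- function(cov, path, seed = NA) write_tsv(cov, path, seed)

#' @rdname write_coverage
#' @export
read_coverage <- function(path) read_tsv(path)
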