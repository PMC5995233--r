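# Purity-adjusted per-gene copy-number presence/absence calling. The
# normalized tumor/normal coverage ratio is inverted through the standard
# diploid-admixture model to an estimated copy number, then thresholded:
# amplification at >= 6 copies (boundary inclusive) and homozygous deletion
# at <= 0.5 copies. Exact copy number is estimated internally but only the
# presence/absence verdict is the reportable result.

#' Median-normalized tumor/normal coverage ratio per gene
#'
#' Each sample's per-gene depth is first divided by that sample's panel-wide
#' median depth (removing library-size differences), then the tumor value is
#' divided by the normal value.
#'
#' @param tumor,normal per-gene coverage data.tables (`gene_id`,
#'   `mean_depth`) covering the same gene set.
#' @return named numeric vector of ratios (names = gene ids).
#' @examples
#' t <- data.frame(gene_id = c("A", "B"), mean_depth = c(1000, 500))
#' n <- data.frame(gene_id = c("A", "B"), mean_depth = c(500, 500))
#' coverage_ratio(t, n)
#' @export
coverage_ratio <- function(tumor, normal) {
  tumor <- data.table::as.data.table(tumor)
  normal <- data.table::as.data.table(normal)
  if (!setequal(tumor$gene_id, normal$gene_id) ||
      nrow(tumor) != nrow(normal)) {
    stop_consistency("tumor and normal must cover the same gene set")
  }
  normal <- normal[match(tumor$gene_id, gene_id)]
  if (any(normal$mean_depth <= 0)) {
    stop_degenerate("normal mean_depth must be > 0 for every gene")
  }
  t_norm <- tumor$mean_depth / median(tumor$mean_depth)
  n_norm <- normal$mean_depth / median(normal$mean_depth)
  stats::setNames(t_norm / n_norm, tumor$gene_id)
}

#' Invert a coverage ratio to an estimated copy number
#'
#' Under the diploid-admixture model a gene at C copies in tumor cells at
#' purity p has expected normalized ratio `(p * C + 2 * (1 - p)) / 2`;
#' inversion gives `C = (2 * ratio - 2 * (1 - p)) / p`, floored at 0.
#'
#' @param ratio numeric vector of normalized coverage ratios.
#' @param purity tumor purity in (0, 1].
#' @return estimated copy numbers (same length as `ratio`).
#' @examples
#' estimate_copies(1, 0.42)    # 2: diploid fixed point at any purity
#' estimate_copies(3, 1)       # 6
#' estimate_copies(1.6, 0.3)   # 6
#' @export
estimate_copies <- function(ratio, purity) {
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    stop_param("`purity` must be in (0, 1]")
  }
  pmax(0, (2 * ratio - 2 * (1 - purity)) / purity)
}

#' Call per-gene copy-number presence/absence
#'
#' Applies [estimate_copies()] to every gene's ratio and thresholds the
#' estimate: `amplified` at `estimated_copies >= amplification_cutoff`
#' (inclusive, per the assay's ">= 6 copies" definition),
#' `homozygous_deletion` at `estimated_copies <= deletion_cutoff`, otherwise
#' `normal_equivocal`. Below 20% purity — the assay's tumor-content intake
#' floor — the call is refused as unreliable.
#'
#' @param ratios named numeric vector from [coverage_ratio()].
#' @param purity tumor purity in \[0.2, 1\].
#' @param amplification_cutoff copies at/above which a gene is amplified
#'   (default 6).
#' @param deletion_cutoff copies at/below which a gene is homozygously
#'   deleted (default 0.5, an engineering default).
#' @return data.table of calls: `gene_id`, `ratio`, `estimated_copies`,
#'   `verdict`.
#' @export
call_gene_cnv <- function(ratios, purity, amplification_cutoff = 6,
                          deletion_cutoff = 0.5) {
  if (!is.numeric(purity) || length(purity) != 1L || purity < 0.2 || purity > 1) {
    stop_param("`purity` must be in [0.2, 1]; below 20% tumor content calls are unreliable")
  }
  assert_scalar_number(amplification_cutoff, "amplification_cutoff", lo = 0)
  assert_scalar_number(deletion_cutoff, "deletion_cutoff", lo = 0)
  est <- estimate_copies(unname(ratios), purity)
  verdict <- ifelse(est >= amplification_cutoff, "amplified",
                    ifelse(est <= deletion_cutoff, "homozygous_deletion",
                           "normal_equivocal"))
  data.table::data.table(gene_id = names(ratios), ratio = unname(ratios),
                         estimated_copies = est, verdict = verdict)
}

#' Write CNV calls as TSV plus a JSON cohort summary
#'
#' @param calls data.table from [call_gene_cnv()].
#' @param path TSV output path.
#' @param json_path optional JSON summary path (verdict tallies).
#' @param seed optional provenance seed.
#' @return invisibly, `path`.
#' @export
write_cnv_calls <- function(calls, path, json_path = NULL, seed = NA) {
  write_tsv(calls, path, seed)
  if (!is.null(json_path)) {
    tab <- as.list(table(calls$verdict))
    jsonlite::write_json(
      list(panelval_version = as.character(utils::packageVersion("panelval")),
           seed = seed, n_genes = nrow(calls), verdicts = tab),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
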