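# Tiered threshold-based somatic SNV/indel calling over paired tumor/normal
# site counts. The rules mirror a clinical panel's validated operating
# points: observed-VAF limits of detection per gene tier (5% actionable /
# 10% analytic), matched-normal germline subtraction, per-locus depth QC and
# a post-hoc benign-classification reporting filter. Thresholds not fixed by
# the validated assay claims (minimum alt-read support, germline VAF cutoff)
# are engineering defaults exposed in the configuration.

#' Somatic calling configuration
#'
#' @param tier1_lod observed-VAF limit of detection for tier-1 (actionable)
#'   genes; default 0.05.
#' @param tier2_lod observed-VAF limit of detection for tier-2 genes;
#'   default 0.10. Must be >= `tier1_lod`.
#' @param min_alt_reads minimum alternate read support for a candidate;
#'   default 5 (engineering default, not an assay claim).
#' @param germline_vaf_cutoff normal-sample VAF at or above which a matching
#'   allele is treated as germline; default 0.02 (engineering default).
#' @param min_locus_depth per-locus depth below which candidates are flagged
#'   `LOW_DEPTH`; default 300, the assay's uniformity floor.
#' @param target_mean_depth required mean unique on-target depth; default
#'   500.
#' @param uniformity_fraction required fraction of panel bases at or above
#'   `min_locus_depth`; default 0.95.
#' @return object of class `tier_config`.
#' @export
tier_config <- function(tier1_lod = 0.05, tier2_lod = 0.10,
                        min_alt_reads = 5L, germline_vaf_cutoff = 0.02,
                        min_locus_depth = 300L, target_mean_depth = 500L,
                        uniformity_fraction = 0.95) {
  for (nm in c("tier1_lod", "tier2_lod", "germline_vaf_cutoff",
               "uniformity_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop_param(sprintf("`%s` must be a fraction in (0, 1)", nm))
    }
  }
  if (tier1_lod > tier2_lod) stop_param("tier1_lod must be <= tier2_lod")
  assert_scalar_number(min_alt_reads, "min_alt_reads", lo = 1)
  assert_scalar_number(min_locus_depth, "min_locus_depth", lo = 0)
  assert_scalar_number(target_mean_depth, "target_mean_depth", lo = 0)
  structure(list(tier1_lod = tier1_lod, tier2_lod = tier2_lod,
                 min_alt_reads = as.integer(min_alt_reads),
                 germline_vaf_cutoff = germline_vaf_cutoff,
                 min_locus_depth = as.integer(min_locus_depth),
                 target_mean_depth = as.integer(target_mean_depth),
                 uniformity_fraction = uniformity_fraction),
            class = "tier_config")
}

#' Coverage quality control over the targeted panel
#'
#' Computes the mean depth over all panel bases and the fraction of bases at
#' or above `min_locus_depth` (boundary inclusive). The sample passes QC when
#' that fraction reaches `uniformity_fraction` and the mean reaches
#' `target_mean_depth`; loci below the depth floor are listed for review.
#' Panel positions absent from the sample count as depth 0.
#'
#' @param sample site-count table for one sample.
#' @param panel gene annotation data.table (`gene_id`, `contig`, `start`,
#'   `end`, `tier`), e.g. `reference$genes`.
#' @param config a [tier_config()].
#' @return object of class `qc_report`: `mean_on_target_depth`,
#'   `fraction_bases_ge_min`, `passed`, `flagged_loci` (data.table of
#'   `contig`, `pos`, `depth`).
#' @export
qc_coverage <- function(sample, panel, config = tier_config()) {
  panel <- data.table::as.data.table(panel)
  if (nrow(panel) == 0L) stop_param("empty panel")
  target <- panel[, .(pos = (start + 1L):end), by = .(gene_id, contig)]
  d <- site_depths(sample)[target, on = .(contig, pos)]
  d[is.na(depth), depth := 0L]
  frac <- mean(d$depth >= config$min_locus_depth)
  mu <- mean(d$depth)
  flagged <- d[depth < config$min_locus_depth, .(contig, pos, depth)]
  structure(list(mean_on_target_depth = mu,
                 fraction_bases_ge_min = frac,
                 passed = frac >= config$uniformity_fraction &&
                   mu >= config$target_mean_depth,
                 flagged_loci = flagged),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: mean depth %.1f, %.1f%% bases >= floor, %s (%d flagged loci)\n",
              x$mean_on_target_depth, 100 * x$fraction_bases_ge_min,
              if (x$passed) "PASS" else "FAIL", nrow(x$flagged_loci)))
  invisible(x)
}

filter_string <- function(...) {
  codes <- c(...)
  paste(sort(unique(codes)), collapse = ";")
}

add_filter <- function(filters, code) {
  ifelse(filters == "", code,
         vapply(strsplit(paste(filters, code, sep = ";"), ";", fixed = TRUE),
                function(x) paste(sort(unique(x)), collapse = ";"), ""))
}

#' Call somatic SNVs and indels from paired tumor/normal site counts
#'
#' A candidate is any non-reference allele row in the tumor with at least
#' `min_alt_reads` supporting reads. Candidates then collect filters:
#' * `BELOW_LOD` — observed VAF below the limit of detection of the gene's
#'   tier (5% tier 1, 10% tier 2 by default);
#' * `GERMLINE` — the same allele in the matched normal at VAF >=
#'   `germline_vaf_cutoff` with at least 2 supporting reads (tumor/normal
#'   subtraction);
#' * `LOW_DEPTH` — tumor locus depth below `min_locus_depth`.
#' A call is reported iff its filter set is empty. Output is ordered by
#' (contig, pos, alt allele); each non-reference allele at a multi-allelic
#' site is an independent candidate.
#'
#' @param tumor,normal site-count tables over identical site sets.
#' @param panel gene annotation data.table (`gene_id`, `contig`, `start`,
#'   `end`, `tier`).
#' @param config a [tier_config()].
#' @return data.table of calls: `contig`, `pos`, `ref_allele`, `alt_allele`,
#'   `vaf`, `alt_count`, `depth`, `gene_id`, `tier`, `filters`
#'   (semicolon-joined codes, `""` when clean), `reported`.
#' @export
call_somatic <- function(tumor, normal, panel, config = tier_config()) {
  panel <- data.table::as.data.table(panel)
  tk <- unique(tumor[, .(contig, pos)]); nk <- unique(normal[, .(contig, pos)])
  if (nrow(tk) != nrow(nk) ||
      nrow(tk[nk, on = .(contig, pos), nomatch = NULL]) != nrow(tk)) {
    stop_consistency("tumor and normal must cover identical sites")
  }

  cand <- tumor[allele != ref & count >= config$min_alt_reads,
                .(contig, pos, ref_allele = ref, alt_allele = allele,
                  alt_count = count, depth)]
  empty <- data.table::data.table(
    contig = character(), pos = integer(), ref_allele = character(),
    alt_allele = character(), vaf = numeric(), alt_count = integer(),
    depth = integer(), gene_id = character(), tier = integer(),
    filters = character(), reported = logical())
  if (nrow(cand) == 0L) return(empty)
  cand[, vaf := alt_count / depth]

  # assign gene and tier by interval containment
  pan <- panel[, .(gene_id, contig, xstart = start + 1L, xend = end, tier)]
  hit <- pan[cand, on = .(contig, xstart <= pos, xend >= pos)]
  cand[, `:=`(gene_id = hit$gene_id, tier = hit$tier)]
  if (anyNA(cand$gene_id)) stop_consistency("candidate outside any panel gene")

  # germline lookup in the matched normal for the same allele row
  nrm <- normal[, .(contig, pos, ref, allele, nrm_count = count, nrm_depth = depth)]
  cand <- nrm[cand, on = c(contig = "contig", pos = "pos",
                           ref = "ref_allele", allele = "alt_allele")]
  data.table::setnames(cand, c("ref", "allele"), c("ref_allele", "alt_allele"))
  cand[is.na(nrm_count), nrm_count := 0L]
  cand[, nrm_vaf := ifelse(is.na(nrm_depth) | nrm_depth == 0, 0,
                           nrm_count / nrm_depth)]

  lod <- ifelse(cand$tier == 1L, config$tier1_lod, config$tier2_lod)
  f_lod <- cand$vaf < lod
  f_germ <- cand$nrm_vaf >= config$germline_vaf_cutoff & cand$nrm_count >= 2L
  f_depth <- cand$depth < config$min_locus_depth
  cand[, filters := mapply(function(a, b, d) {
    filter_string(if (a) "BELOW_LOD", if (b) "GERMLINE", if (d) "LOW_DEPTH")
  }, f_lod, f_germ, f_depth)]
  cand[, reported := filters == ""]
  out <- cand[, .(contig, pos, ref_allele, alt_allele, vaf, alt_count,
                  depth, gene_id, tier, filters, reported)]
  data.table::setorder(out, contig, pos, alt_allele)
  out[]
}

#' Suppress known-benign calls from reporting
#'
#' Looks every call up in a classification table keyed by
#' `(gene_id, pos, ref_allele, alt_allele)`; calls classified benign gain the
#' `BENIGN` filter and are withdrawn from reporting, mirroring the clinical
#' rule that a variant curated as benign is not reported even when detected.
#' All other calls pass through unchanged.
#'
#' @param calls data.table from [call_somatic()].
#' @param classification_table data.table with columns `gene_id`, `pos`,
#'   `ref_allele`, `alt_allele`, `classification`.
#' @return the calls table with `filters`/`reported` updated.
#' @export
apply_classification_filter <- function(calls, classification_table) {
  calls <- data.table::copy(data.table::as.data.table(calls))
  ct <- data.table::as.data.table(classification_table)
  if (nrow(ct) == 0L || nrow(calls) == 0L) return(calls[])
  m <- ct[calls, on = .(gene_id, pos, ref_allele, alt_allele)]
  benign <- !is.na(m$classification) & m$classification == "benign"
  if (any(benign)) {
    calls[benign, `:=`(filters = add_filter(filters, "BENIGN"),
                       reported = FALSE)]
  }
  calls[]
}

#' Write somatic calls as VCF 4.2 and as a call TSV
#'
#' The VCF carries filter codes in FILTER (`PASS` when clean) and
#' per-sample FORMAT fields `DP` (depth), `AD` (ref,alt depths) and `AF`
#' (observed VAF) for the single TUMOR sample, plus INFO keys `GENE` and
#' `TIER`.
#'
#' @param calls data.table from [call_somatic()].
#' @param path output path.
#' @param seed optional provenance seed.
#' @return invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path, seed = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=panelval_v%s", as.character(utils::packageVersion("panelval"))),
    sprintf("##panelval_seed=%s", ifelse(is.na(seed), "NA", format(seed))),
    '##FILTER=<ID=BELOW_LOD,Description="Observed VAF below the tier limit of detection">',
    '##FILTER=<ID=GERMLINE,Description="Allele present in the matched normal">',
    '##FILTER=<ID=LOW_DEPTH,Description="Locus depth below the QC floor">',
    '##FILTER=<ID=BENIGN,Description="Variant classified benign; not reported">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Panel gene">',
    '##INFO=<ID=TIER,Number=1,Type=Integer,Description="Panel gene tier">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Observed allele fraction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR")
  body <- if (nrow(calls) == 0L) character() else calls[, sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tGENE=%s;TIER=%d\tDP:AD:AF\t%d:%d,%d:%.4f",
    contig, pos, ref_allele, alt_allele,
    ifelse(filters == "", "PASS", filters), gene_id, tier,
    depth, depth - alt_count, alt_count, vaf)]
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_calls_vcf
#' @export
write_calls_tsv <- function(calls, path, seed = NA) write_tsv(calls, path, seed)

#' @rdname write_calls_vcf
#' @export
read_calls_tsv <- function(path) read_tsv(path)
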