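# End-to-end study recipes reproducing the three validation experiments the
# simulator can restate at desk scale: the in silico spike-in titration of
# the somatic caller, the amplified/diploid CNV cohort, and the
# fusion-replicate concordance run. Each recipe is driven by one master seed
# (sub-seeded per sample via derive_seed) and returns a serializable report
# embedding the seed, a configuration hash and the package version.

config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((h * 16777619) + ch) %% 2^32
  format(as.hexmode(as.integer(h %% 2^31)), width = 8)
}

report_stub <- function(name, seed, config) {
  list(study = name, seed = seed,
       panelval_version = as.character(utils::packageVersion("panelval")),
       config = config, config_hash = config_hash(config))
}

#' Run the in silico spike-in titration study
#'
#' Generates a toy reference and, per titer, a truth set of `n_variants`
#' somatic variants whose nominal VAF equals the titer; simulates a matched
#' normal (no spike-ins) and a synthetic tumor (spike-ins at purity 1, so
#' that the expected observed VAF equals the titer); calls somatic variants
#' with tumor/normal subtraction and summarises per-titer sensitivity and
#' PPV. All variants are placed in tier-1 genes, the actionable tier a
#' hotspot-derived spike-in set represents.
#'
#' @param seed master seed.
#' @param titers nominal VAF titers, default `c(0.25, 0.15, 0.05)`.
#' @param n_variants truth variants per titer (default 110).
#' @param depth mean unique on-target depth (default 500).
#' @param n_genes,gene_length toy panel dimensions (default 20 x 300 bp =
#'   6 kb of targeted sequence).
#' @param indel_fraction indel share of each truth set (default 0.1).
#' @param error_rate per-base substitution error (default 0.001).
#' @param config a [tier_config()].
#' @param outdir optional directory; when given, reference FASTA/BED, truth
#'   VCFs, call VCF/TSVs and the JSON/TSV report are written there.
#' @return report list; `$results` is the [titration_summary()] table.
#' @export
run_titration_study <- function(seed, titers = c(0.25, 0.15, 0.05),
                                n_variants = 110L, depth = 500L,
                                n_genes = 20L, gene_length = 300L,
                                indel_fraction = 0.1, error_rate = 0.001,
                                config = tier_config(), outdir = NULL) {
  if (length(titers) < 1L || any(titers <= 0 | titers > 1)) {
    stop_param("titers must be fractions in (0, 1]")
  }
  ref <- generate_reference(derive_seed(seed, "reference"), n_genes = n_genes,
                            gene_length = gene_length, tier1_fraction = 1.0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_reference_fasta(ref, file.path(outdir, "reference.fa"))
    write_panel_bed(ref, file.path(outdir, "panel.bed"))
  }
  per_titer <- lapply(titers, function(titer) {
    tag <- sprintf("titer_%g", titer)
    truth <- generate_truth_variants(ref, n_variants, vaf = titer,
                                     indel_fraction = indel_fraction,
                                     seed = derive_seed(seed, paste0("truth_", tag)))
    normal <- simulate_site_counts(ref, truth[0],
      sample_profile(paste0("normal_", tag), "normal", mean_depth = depth,
                     error_rate = error_rate,
                     seed = derive_seed(seed, paste0("normal_", tag))))
    tumor <- simulate_site_counts(ref, truth,
      sample_profile(paste0("tumor_", tag), "tumor", purity = 1,
                     mean_depth = depth, error_rate = error_rate,
                     seed = derive_seed(seed, paste0("tumor_", tag))))
    calls <- call_somatic(tumor, normal, ref$genes, config)
    if (!is.null(outdir)) {
      write_truth_vcf(truth, file.path(outdir, paste0(tag, "_truth.vcf")),
                      ref, seed)
      write_calls_vcf(calls, file.path(outdir, paste0(tag, "_calls.vcf")), seed)
      write_calls_tsv(calls, file.path(outdir, paste0(tag, "_calls.tsv")), seed)
    }
    list(titer = titer, calls = calls, truth = truth)
  })
  summary <- titration_summary(per_titer)
  report <- report_stub("titration", seed, list(
    titers = titers, n_variants = n_variants, depth = depth,
    n_genes = n_genes, gene_length = gene_length,
    indel_fraction = indel_fraction, error_rate = error_rate,
    tier1_lod = config$tier1_lod, tier2_lod = config$tier2_lod,
    min_alt_reads = config$min_alt_reads))
  report$results <- summary
  if (!is.null(outdir)) {
    write_validation_report(report, file.path(outdir, "titration_report.json"),
                            file.path(outdir, "titration_report.tsv"), seed)
  }
  report
}

#' Run a simulated CNV validation cohort
#'
#' Simulates `n_positive` tumor/normal pairs carrying a high-level
#' amplification of one target gene (`true_copies`, default 8, at the given
#' purity) and `n_negative` diploid pairs, computes median-normalized
#' coverage ratios, calls presence/absence per gene, and tallies the target
#' gene's verdict per group.
#'
#' @param seed master seed.
#' @param n_positive,n_negative group sizes (default 6 and 16).
#' @param true_copies amplified copy number (default 8).
#' @param purity tumor purity of every tumor sample (default 0.5).
#' @param dispersion log-normal coverage noise sd (default 0.05).
#' @param depth mean panel depth (default 500).
#' @param target_gene gene carrying the amplification; defaults to the first
#'   panel gene.
#' @param outdir optional output directory.
#' @return report list; `$results` has one row per sample with the target
#'   gene's verdict, `$positive_amplified` / `$negative_amplified` /
#'   `$negative_normal` the group tallies, and `$counts` the cohort
#'   [confusion_counts()].
#' @export
run_cnv_cohort <- function(seed, n_positive = 6L, n_negative = 16L,
                           true_copies = 8, purity = 0.5, dispersion = 0.05,
                           depth = 500L, target_gene = NULL, outdir = NULL) {
  if (n_positive + n_negative < 1L) stop_param("cohort must contain >= 1 sample")
  ref <- generate_reference(derive_seed(seed, "cnv_reference"))
  target_gene <- target_gene %||% ref$genes$gene_id[1L]
  truth_pos <- cnv_truth(target_gene, true_copies)

  one_sample <- function(i, group) {
    sid <- sprintf("%s%02d", group, i)
    truths <- if (group == "pos") truth_pos else truth_pos[0]
    tumor <- simulate_gene_coverage(ref, truths,
      sample_profile(paste0(sid, "_T"), "tumor", purity = purity,
                     mean_depth = depth,
                     seed = derive_seed(seed, paste0(sid, "_T"))),
      dispersion = dispersion)
    normal <- simulate_gene_coverage(ref, truth_pos[0],
      sample_profile(paste0(sid, "_N"), "normal", mean_depth = depth,
                     seed = derive_seed(seed, paste0(sid, "_N"))),
      dispersion = dispersion)
    calls <- call_gene_cnv(coverage_ratio(tumor, normal), purity)
    data.table::data.table(sample_id = sid, group = group,
                           gene_id = target_gene,
                           verdict = calls[gene_id == target_gene, verdict],
                           estimated_copies = calls[gene_id == target_gene,
                                                    estimated_copies])
  }
  rows <- c(lapply(seq_len(n_positive), one_sample, group = "pos"),
            lapply(seq_len(n_negative), one_sample, group = "neg"))
  results <- data.table::rbindlist(rows)

  pos_amp <- results[group == "pos" & verdict == "amplified", .N]
  neg_amp <- results[group == "neg" & verdict == "amplified", .N]
  neg_norm <- results[group == "neg" & verdict == "normal_equivocal", .N]
  counts <- confusion_counts(tp = pos_amp, fp = neg_amp,
                             fn = n_positive - pos_amp, tn = neg_norm,
                             context = "cnv_cohort")
  report <- report_stub("cnv_cohort", seed, list(
    n_positive = n_positive, n_negative = n_negative,
    true_copies = true_copies, purity = purity, dispersion = dispersion,
    depth = depth, target_gene = target_gene))
  report$results <- results
  report$positive_amplified <- pos_amp
  report$negative_amplified <- neg_amp
  report$negative_normal <- neg_norm
  report$counts <- unclass(counts)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_validation_report(report, file.path(outdir, "cnv_cohort_report.json"),
                            file.path(outdir, "cnv_cohort_report.tsv"), seed)
  }
  report
}

#' Run the fusion replicate-concordance study
#'
#' Simulates `n_replicates` RNA libraries, each carrying one actionable
#' truth fusion at `truth_spanning` junction-spanning reads plus
#' sub-threshold background noise; calls fusions per replicate and reports
#' the per-fusion detection count and the aggregate PPV over all replicate
#' calls.
#'
#' @param seed master seed.
#' @param n_replicates number of libraries (default 12).
#' @param truth_spanning spanning reads carried by the truth fusion
#'   (default 30).
#' @param truth_discordant discordant mates carried (default 10).
#' @param noise_events background gene pairs per library (default 50).
#' @param noise_max_reads cap on background spanning counts (default 15,
#'   one below the calling threshold).
#' @param min_spanning positivity threshold (default 16).
#' @param gene5,gene3 truth fusion partners (default ESR1--CCDC170, an
#'   actionable pair in the bundled tier list).
#' @param outdir optional output directory.
#' @return report list; `$results` is the [replicate_detection()] table,
#'   `$ppv` the aggregate PPV, `$counts` the pooled [confusion_counts()].
#' @export
run_fusion_replicates <- function(seed, n_replicates = 12L,
                                  truth_spanning = 30L, truth_discordant = 10L,
                                  noise_events = 50L, noise_max_reads = 15L,
                                  min_spanning = 16L,
                                  gene5 = "ESR1", gene3 = "CCDC170",
                                  outdir = NULL) {
  if (n_replicates < 1L) stop_param("need >= 1 replicate")
  truth <- fusion_truth(gene5, gene3, truth_spanning, truth_discordant,
                        actionable = TRUE)
  pairs <- default_actionable_pairs()
  replicates <- lapply(seq_len(n_replicates), function(i) {
    simulate_fusion_library(truth, n_noise_events = noise_events,
                            noise_max_reads = noise_max_reads,
                            seed = derive_seed(seed, sprintf("rep%02d", i)))
  })
  det <- replicate_detection(replicates, truth, pairs, min_spanning)

  tp <- 0L; fp <- 0L; fn <- 0L
  for (ev in replicates) {
    calls <- call_fusions(ev, pairs, min_spanning)
    cc <- match_events(calls, truth, mode = "fusion")
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  counts <- confusion_counts(tp, fp, fn, context = "fusion_replicates")
  report <- report_stub("fusion_replicates", seed, list(
    n_replicates = n_replicates, truth_spanning = truth_spanning,
    truth_discordant = truth_discordant, noise_events = noise_events,
    noise_max_reads = noise_max_reads, min_spanning = min_spanning,
    fusion = paste(gene5, gene3, sep = "--")))
  report$results <- det
  report$ppv <- if (tp + fp > 0) ppv(counts) else NA_real_
  report$counts <- unclass(counts)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_validation_report(report,
                            file.path(outdir, "fusion_replicates_report.json"),
                            file.path(outdir, "fusion_replicates_report.tsv"),
                            seed)
  }
  report
}
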