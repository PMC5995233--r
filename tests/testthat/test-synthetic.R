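# Generators: toy reference, truth variants, pileup simulation, titration
# mixing, gene coverage and fusion libraries.

test_that("generate_reference is seeded-deterministic down to file bytes", {
  r1 <- generate_reference(seed = 7, n_genes = 20, gene_length = 300,
                           tier1_fraction = 0.5)
  r2 <- generate_reference(seed = 7, n_genes = 20, gene_length = 300,
                           tier1_fraction = 0.5)
  expect_identical(r1$contigs, r2$contigs)
  expect_identical(r1$genes, r2$genes)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  b1 <- tempfile(fileext = ".bed"); b2 <- tempfile(fileext = ".bed")
  write_reference_fasta(r1, f1); write_reference_fasta(r2, f2)
  write_panel_bed(r1, b1); write_panel_bed(r2, b2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(b1), readLines(b2))
  expect_false(identical(r1$contigs,
                         generate_reference(seed = 8, n_genes = 20)$contigs))
})

test_that("reference tier assignment and degenerate single-gene case", {
  r <- generate_reference(seed = 7, n_genes = 20, gene_length = 300,
                          tier1_fraction = 0.5)
  expect_identical(sum(r$genes$tier == 1L), 10L)
  expect_identical(nrow(r$genes), 20L)

  one <- generate_reference(seed = 7, n_genes = 1, gene_length = 50,
                            tier1_fraction = 1.0, gap = 0)
  expect_identical(one$genes$start, 0L)
  expect_identical(one$genes$end, 50L)
  expect_identical(one$genes$tier, 1L)

  expect_error(generate_reference(seed = 1, n_genes = 0),
               class = "panelval_parameter_error")
  expect_error(generate_reference(seed = 1, gene_length = 10),
               class = "panelval_parameter_error")
})

test_that("generate_truth_variants honours counts, VAF, indel share and capacity", {
  ref <- generate_reference(seed = 7)
  tv <- generate_truth_variants(ref, n_variants = 110, vaf = 0.25, seed = 1)
  expect_identical(nrow(tv), 110L)
  expect_identical(anyDuplicated(tv[, .(contig, pos)]), 0L)
  expect_true(all(tv$true_vaf == 0.25))
  expect_true(all(tv$ref_allele != tv$alt_allele))

  expect_identical(nrow(generate_truth_variants(ref, 0, vaf = 0.25)), 0L)

  tv10 <- generate_truth_variants(ref, 10, vaf = 0.1, indel_fraction = 0.3,
                                  seed = 3)
  expect_identical(sum(tv10$vtype %in% c("INS", "DEL")), 3L)
  expect_identical(sum(tv10$vtype == "SNV"), 7L)
  # anchored indel representation
  ins <- tv10[vtype == "INS"]
  if (nrow(ins)) expect_true(all(nchar(ins$alt_allele) > nchar(ins$ref_allele)))
  del <- tv10[vtype == "DEL"]
  if (nrow(del)) expect_true(all(nchar(del$ref_allele) > nchar(del$alt_allele)))

  small <- tiny_reference(n_genes = 1, gene_length = 50)
  expect_error(generate_truth_variants(small, 51, vaf = 0.2),
               class = "panelval_capacity_error")
  expect_error(generate_truth_variants(ref, 10, vaf = 0),
               class = "panelval_parameter_error")
  expect_identical(generate_truth_variants(ref, 110, vaf = 0.25, seed = 1),
                   tv)
})

test_that("simulate_site_counts conserves allele counts and is deterministic", {
  ref <- tiny_reference(n_genes = 3, gene_length = 80)
  tv <- generate_truth_variants(ref, 12, vaf = 0.3, indel_fraction = 0.25,
                                seed = 2)
  prof <- sample_profile("T", "tumor", purity = 1, mean_depth = 200,
                         error_rate = 0.002, seed = 11)
  sc1 <- simulate_site_counts(ref, tv, prof)
  sc2 <- simulate_site_counts(ref, tv, prof)
  expect_identical(sc1, sc2)
  # sum over alleles equals depth at every site (validator enforces too)
  sums <- sc1[, .(s = sum(count), d = depth[1]), by = .(contig, pos)]
  expect_true(all(sums$s == sums$d))
  # every panel position present
  expect_identical(nrow(unique(sc1[, .(contig, pos)])),
                   nrow(panel_positions(ref)))

  outside <- data.table::copy(tv)[1, pos := 1L]  # gap position
  expect_error(simulate_site_counts(ref, outside, prof),
               class = "panelval_consistency_error")
})

test_that("spike-in mean VAF recovers purity * true_vaf (Monte-Carlo vs binomial)", {
  ref <- generate_reference(seed = 3, n_genes = 20, gene_length = 300)
  tv <- generate_truth_variants(ref, 1000, vaf = 0.25, seed = 4)
  prof <- sample_profile("T", "tumor", purity = 1, mean_depth = 500,
                         error_rate = 0, seed = 5)
  sc <- simulate_site_counts(ref, tv, prof)
  vafs <- observed_vaf(sc, tv)
  # oracle: binomial mean p = 0.25, se of the mean over 1000 sites at n ~ 500
  se <- sqrt(0.25 * 0.75 / 500) / sqrt(1000)
  expect_lt(abs(mean(vafs) - 0.25), 3 * se)
  expect_lt(abs(mean(vafs) - 0.25), 0.01)

  # half purity halves the expected observed VAF
  prof50 <- sample_profile("T", "tumor", purity = 0.5, mean_depth = 500,
                           error_rate = 0, seed = 6)
  v50 <- observed_vaf(simulate_site_counts(ref, tv, prof50), tv)
  se50 <- sqrt(0.125 * 0.875 / 500) / sqrt(1000)
  expect_lt(abs(mean(v50) - 0.125), 3 * se50)
})

test_that("purity 0 erases the tumor signal at truth sites", {
  ref <- generate_reference(seed = 9, n_genes = 10, gene_length = 300)
  tv <- generate_truth_variants(ref, 500, vaf = 0.4, seed = 1)
  prof <- sample_profile("N", "normal", purity = 0, mean_depth = 400,
                         error_rate = 0.003, seed = 2)
  sc <- simulate_site_counts(ref, tv, prof)
  truth_vaf <- observed_vaf(sc, tv)
  # error-only expectation per non-reference allele is error_rate / 3
  expect_lt(abs(mean(truth_vaf) - 0.001), 5 * sqrt(0.001 / 400 / 500))
})

test_that("mix_titration: identity mixtures and mixing linearity", {
  ref <- tiny_reference(n_genes = 5, gene_length = 200)
  tv <- generate_truth_variants(ref, 500, vaf = 0.5, seed = 3)
  tumor <- simulate_site_counts(ref, tv,
    sample_profile("T", "tumor", purity = 1, mean_depth = 500,
                   error_rate = 0, seed = 7))
  normal <- simulate_site_counts(ref, tv[0],
    sample_profile("N", "normal", mean_depth = 500, error_rate = 0,
                   seed = 8))

  expect_identical(mix_titration(tumor, normal, 1.0, seed = 1)[, .(contig, pos, ref, allele, count)],
                   tumor[, .(contig, pos, ref, allele, count)])
  expect_identical(mix_titration(tumor, normal, 0.0, seed = 1)[, .(contig, pos, ref, allele, count)],
                   normal[, .(contig, pos, ref, allele, count)])

  mixed <- mix_titration(tumor, normal, 0.25, seed = 9)
  sums <- mixed[, .(s = sum(count), d = depth[1]), by = .(contig, pos)]
  expect_true(all(sums$s == sums$d))
  vafs <- observed_vaf(mixed, tv)
  # oracle: E[VAF] = f * 0.5; mixture thinning roughly preserves depth 500
  se <- sqrt(0.125 * 0.875 / 500) / sqrt(500)
  expect_lt(abs(mean(vafs) - 0.125), 3 * se)

  bad <- normal[pos != min(pos)]
  expect_error(mix_titration(tumor, bad, 0.5), class = "panelval_consistency_error")
})

test_that("simulate_gene_coverage applies the admixture scale factor", {
  ref <- generate_reference(seed = 2, n_genes = 20)
  # dispersion 0 exposes the closed-form scale factors
  cov <- simulate_gene_coverage(
    ref, cnv_truth(c("GENE001", "GENE002"), c(6, 0)),
    sample_profile("T", "tumor", purity = 0.3, mean_depth = 500, seed = 1),
    dispersion = 0)
  expect_equal(cov[gene_id == "GENE001", mean_depth], 500 * 1.6)  # (0.3*6+0.7*2)/2
  expect_equal(cov[gene_id == "GENE002", mean_depth], 500 * 0.7)  # (0.3*0+0.7*2)/2
  expect_equal(cov[gene_id == "GENE003", mean_depth], 500)        # untouched gene

  pure <- simulate_gene_coverage(
    ref, cnv_truth(c("GENE001", "GENE002"), c(2, 0)),
    sample_profile("T", "tumor", purity = 1, mean_depth = 500, seed = 1),
    dispersion = 0)
  expect_equal(pure[gene_id == "GENE001", mean_depth], 500)  # diploid, scale 1
  expect_equal(pure[gene_id == "GENE002", mean_depth], 0)    # homozygous deletion

  expect_error(simulate_gene_coverage(ref, cnv_truth("NOPE", 6),
                                      sample_profile("T", "tumor")),
               class = "panelval_consistency_error")

  # with noise, the mean scale factor across many genes matches the model
  big <- generate_reference(seed = 5, n_genes = 200, gene_length = 50)
  noisy <- simulate_gene_coverage(
    big, cnv_truth(big$genes$gene_id, rep(6, 200)),
    sample_profile("T", "tumor", purity = 0.5, mean_depth = 500, seed = 3),
    dispersion = 0.05)
  expect_lt(abs(mean(noisy$mean_depth) / 500 - 2), 4 * 2 * 0.05 / sqrt(200) + 0.01)
})

test_that("simulate_fusion_library emits truth verbatim and bounded noise", {
  tr <- fusion_truth("A", "B", n_spanning = 20, n_discordant = 3)
  ev0 <- simulate_fusion_library(tr, n_noise_events = 0)
  expect_identical(nrow(ev0), 1L)
  expect_identical(ev0$n_spanning, 20L)

  ev <- simulate_fusion_library(tr, n_noise_events = 50, noise_max_reads = 15,
                                seed = 4)
  expect_identical(nrow(ev), 51L)
  expect_true(all(ev[-1]$n_spanning <= 15L & ev[-1]$n_spanning >= 1L))
  expect_true(all(ev$n_discordant >= 0L))
  expect_true(all(ev$gene5 != ev$gene3))
  expect_identical(simulate_fusion_library(tr, 50, 15, seed = 4), ev)

  # 12 replicate libraries under distinct seeds all carry the truth pair
  for (i in 1:12) {
    evi <- simulate_fusion_library(tr, 30, 15, seed = 100 + i)
    expect_true(any(evi$gene5 == "A" & evi$gene3 == "B" & evi$n_spanning == 20L))
  }

  expect_error(fusion_truth("A", "A", 5), class = "panelval_parameter_error")
})
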