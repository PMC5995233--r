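# panelval

Simulation and scoring toolkit for the **analytic validation of a targeted
tumor/normal NGS oncology panel**. It is aimed at bioinformaticians who need
to restate a clinical panel's validation experiments — in silico variant
spike-in titrations, purity-admixture dilution series, copy-number cohorts,
fusion replicate runs — as reproducible, seeded desk-scale studies, and to
recompute the validation statistics (sensitivity, specificity, PPV, VAF
concordance) from first principles.

## What it implements

* **Synthetic genomics** — a toy reference + tiered gene panel
  (FASTA/BED), ground-truth somatic variant sets at a nominal VAF
  (VCF 4.2), count-level tumor/normal pileups with digital spike-ins
  (`depth ~ Pois(μ)`, `alt ~ Binom(depth, p·v + (1 − p·v)·e/3)`), binomial
  purity mixing, per-gene coverage under the admixture scale factor
  `(p·C + 2(1 − p))/2`, and chimeric-read evidence tables with
  sub-threshold noise.
* **Somatic SNV/indel caller** — observed-VAF limits of detection per gene
  tier (5% actionable / 10% analytic), ≥5 alt reads, matched-normal
  germline subtraction (normal VAF ≥ 2% and ≥2 reads), 300× locus-depth QC
  with 95% uniformity, and a benign-classification reporting filter.
* **CNV caller** — median-normalized tumor/normal coverage ratio inverted
  through `C = (2r − 2(1 − p))/p`; presence/absence verdicts: amplified at
  `C ≥ 6` (inclusive), homozygous deletion at `C ≤ 0.5`, validated down to
  30% tumor purity.
* **Fusion caller** — positivity at ≥16 junction-spanning reads
  (inclusive); discordant mates carried for reporting; actionable tier by
  unordered pair lookup; replicate-concordance summaries.
* **Validation metrics** — mode-aware event matching into TP/FP/FN/TN,
  `sensitivity = TP/(TP+FN)`, `PPV = TP/(TP+FP)`,
  `specificity = TN/(TN+FP)`, Pearson VAF concordance (r and r² kept
  distinct), half-up presentation rounding ("98.4%", "0.99").
* **Study recipes + CLI** — `run_titration_study()`, `run_cnv_cohort()`,
  `run_fusion_replicates()`, and a `panelval` command-line front end
  (`simulate`, `call-snv`, `call-cnv`, `call-fusion`, `validate`,
  `study …`).

## Worked example

```r
library(panelval)

r <- run_titration_study(seed = 42)   # 110 spike-ins per titer, depth 500
r$results
#>    titer    tp    fp    fn sensitivity   ppv sensitivity_exact ppv_exact
#> 1:  0.25   110     0     0         1.0     1               1.0         1
#> 2:  0.15   110     0     0         1.0     1               1.0         1
#> 3:  0.05    55     0    55         0.5     1               0.5         1
```

Read: at the 25% and 15% titers every one of the 110 spiked-in variants is
recovered with zero false positives (sensitivity 1.00, PPV 1.00); at the 5%
titer — exactly on the actionable tier's limit of detection — about half the
variants fall below the observed-VAF cutoff, the expected behaviour of a
hard threshold sitting on the LOD (see the methods vignette for why the
production pipeline's higher published value is not reproducible from
disclosed rules). Sensitivity is monotone in the titer, PPV stays 1.00.

```r
c <- run_cnv_cohort(seed = 42)        # 6 amplified (C=8, purity 0.5) + 16 diploid
c(c$positive_amplified, c$negative_amplified, c$negative_normal)
#> [1]  6  0 16

f <- run_fusion_replicates(seed = 42) # 12 replicate RNA libraries
f$results
#>    gene5   gene3 n_detected n_replicates
#> 1:  ESR1 CCDC170         12           12
f$ppv
#> [1] 1

fmt_percent(sensitivity(confusion_counts(tp = 63, fp = 0, fn = 1)))
#> [1] "98.4%"
```

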