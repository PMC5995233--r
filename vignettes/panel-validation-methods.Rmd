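---
title: "Methods: simulating and scoring a tumor/normal panel validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring a tumor/normal panel validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

## The problem

Clinical targeted oncology panels are validated by demonstrating analytic
sensitivity, specificity and positive predictive value (PPV) against ground
truth: digitally spiked-in variants at known allele fractions, cell-line
purity admixtures, FISH-confirmed copy-number states, and replicate RNA
libraries carrying known fusions. panelval reimplements that analytic layer
at desk scale: seeded generators that restate each validation experiment,
rule-based callers implementing the assay's published operating points, and
the confusion-matrix arithmetic that turns matched calls into the printed
rates.

Everything operates on evidence summaries — per-site allele counts, per-gene
mean depths, per-pair chimeric read counts — not on reads. Every published
validation statistic of this kind of assay is a function of such counts, so
count-level simulation preserves the quantities under test while avoiding
alignment entirely.

## The pileup model

A sample is a `sample_profile` (purity $p$, mean depth $\mu$, error rate
$e$). At every targeted position, depth $D \sim \mathrm{Pois}(\mu)$. At a
truth site with nominal allele fraction $v$ the alternate count is

$$A \sim \mathrm{Binom}\!\left(D,\; p\,v + (1 - p\,v)\,\tfrac{e}{3}\right),$$

i.e. the somatic signal diluted by purity, plus the chance that a
non-variant read is mis-read as the alternate base. Background sites
accumulate substitution errors at rate $e$, split multinomially over the
three non-reference bases so that allele counts always sum exactly to depth.
Truth sites carry only reference/alternate rows: the binomial above already
folds the error contribution into the alternate allele, and modelling the
residual two error alleles there would change no tested quantity. There is
no indel error process at background sites.

Defaults state the assay's world: $\mu = 500$ (the minimum unique on-target
depth), $e = 0.001$ (a typical post-dedup substitution rate for hybrid
capture), log-normal per-gene coverage noise with $\sigma = 0.05$.

Purity admixtures (`mix_titration`) thin each allele row of the tumor
binomially with probability $f$ and of the normal with $1-f$, then sum —
exactly "each read is drawn from the tumor with probability $f$", preserving
depth in expectation and degenerating to the pure inputs at $f \in \{0,1\}$.

### Titer semantics

The in silico dilution series is stated at 25%, 15% and 5%. We treat these
as nominal observed VAFs: variants are inserted with `true_vaf = titer` at
purity 1. The alternative reading (titer = purity on a fixed-VAF truth set)
is inconsistent with a 5% series showing high sensitivity on an assay whose
actionable-tier limit of detection is 5% VAF. Purity-based dilution remains
available, explicitly, through `mix_titration`.

The titration recipe places all 110 variants in tier-1 genes
(`tier1_fraction = 1`): a hotspot-derived spike-in set emulates recurrent
actionable variants, which the actionable tier targets by construction. The
variant composition of the original set is unpublished; the recipe defaults
to a 10% indel share, an SNV-dominant mix typical of hotspot catalogues.

## The callers

**SNV/indel.** A candidate is any non-reference allele with at least
`min_alt_reads` (default 5) supporting reads in the tumor. Filters:
`BELOW_LOD` when observed VAF (alt/depth, not a modelled truth) is under the
gene tier's cutoff — 0.05 for tier 1, 0.10 for tier 2; `GERMLINE` when the
same allele sits in the matched normal at VAF ≥ 0.02 with ≥ 2 reads;
`LOW_DEPTH` under 300× locus depth. A call is reported iff unfiltered.
`min_alt_reads` and the germline cutoff are engineering defaults (the
published validation does not state them) chosen so that 500× depth at 0.1%
error yields essentially zero false positives while 5% VAF events are
retained; both are configuration-exposed. A separate classification filter
withdraws calls curated as benign — the mechanism behind the well-known
worked example where 42 externally confirmed variants yield 41 reported.

Note a structural consequence of thresholding observed VAF *at* the limit of
detection: a spike-in sitting exactly at the cutoff is detected with
probability ≈ 0.5 (half its binomial VAF draws fall below it). The
package's 5%-titer sensitivity is therefore ≈ 0.5, not the published 0.93 —
the production pipeline evidently detects below its claimed LOD ("5% VAF or
lower"), but its decision statistic is undisclosed. The sensitivity curve
remains monotone across titers, which is what the acceptance criterion
checks; the exact 5% value is documented as unreproducible.

**CNV.** Per-gene depths are median-normalized within each sample, ratioed
tumor/normal, and inverted through the diploid admixture model
$C = (2r - 2(1 - p))/p$ (floored at 0). Verdicts are presence/absence only:
`amplified` at $C \ge 6$ (inclusive), `homozygous_deletion` at $C \le 0.5$,
otherwise `normal_equivocal`. The inversion formula and median
normalization are our choices — the production algorithm's statistic is
undisclosed — but they are the standard diploid-admixture model. Purity is
an input (known for simulated material); below the 20% tumor-content intake
floor the caller refuses. At exactly $C = 6$ the estimate is centred on the
inclusive boundary, so symmetric noise detects ~50% of the time; validation
cohorts therefore probe detection at $C = 8$, where detection at 30% purity
exceeds 0.99 under default dispersion.

**Fusions.** Evidence tables carry junction-spanning and discordant-mate
counts per gene pair. Positivity is decided on spanning reads alone with the
validated inclusive threshold of 16; discordant mates feed candidate
generation and reporting but not the decision. Tier assignment matches the
unordered pair against the actionable list (a bundled synthetic 40-pair
stand-in). Simulated noise is capped below threshold by construction,
mirroring how the threshold was chosen to leave background sub-threshold —
so PPV 1.0 on clean simulation is a design property being verified, not a
discovery.

## Metrics and rounding

`match_events` builds TP/FP/FN(/TN) with mode-specific identity: exact
`(contig, pos, ref, alt)` for small variants (left-aligned anchored indels,
no realignment), `(gene, verdict class)` for CNV, unordered gene pair for
fusions. True negatives require an explicit negative universe (genes or
pairs assayed); SNV/indel TN is undefined by design. Sensitivity, PPV and
specificity error loudly on empty denominators rather than returning NaN.
Presentation rounding is half-up — two decimals for rates, one for
percentages — because that is how the printed numbers (98.4%, 0.99, 94.7%)
behave; banker's rounding would disagree on ties. VAF concordance reports
Pearson r and r² as distinct numbers (concordance write-ups sometimes
conflate them) plus a mean per-pair coefficient of variation.

## What a green test establishes — and what it does not

The generator emulates: Poisson depth, binomial allele sampling, admixture
arithmetic, log-normal coverage noise, sub-threshold chimeric background,
and seeded determinism (one master seed, per-sample streams via stable
hashing, so study outputs are byte-reproducible). It does not emulate: FFPE
chemistry (deamination artifacts), mapping and alignment error, GC and
capture bias, base-quality structure, overlapping-mate double counting, or
real germline variation. Green acceptance tests therefore establish that
the calling rules and validation arithmetic reproduce the published
operating characteristics *under the stated statistical model* — they are
not a re-validation of any laboratory assay.

Quantities depending on unpublished clinical data are out of reach and are
covered by property tests instead: the 0.884 inter-laboratory VAF
correlation, cell-line consensus fusion sensitivity, spike-in reference PPV
(0.95), and control-sample concordances.

## Numerical and degenerate-input choices

Ties in call ordering break by (contig, pos, alt allele); fusion calls by
descending spanning count then lexicographic pair. Zero-depth sites get VAF
0 via explicit guards. Coverage ratios refuse zero normal depth
(degenerate-input error) rather than returning Inf. Capacity (more variants
than positions), site-set mismatches between paired samples, and truth
events outside the panel each raise typed conditions
(`panelval_*_error`) that callers can test for. Seeds are kept inside
32-bit range by hashing modulo $2^{31}-1$.

## Running the studies

```{r, eval = FALSE}
run_titration_study(seed = 42)          # 3 titers x 110 spike-ins, ~1 s
run_cnv_cohort(seed = 42)               # 6 amplified + 16 diploid samples
run_fusion_replicates(seed = 42)        # 12 MCF-7-style replicate libraries
```

Each returns a serializable report embedding the seed, a configuration hash
and the package version; with `outdir=` the inputs (FASTA/BED/VCF/TSV) and
reports (JSON/TSV) are written with provenance headers. The same recipes
back `scripts/acceptance.R` and the command-line interface
(`panelval study titration`, etc.).
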