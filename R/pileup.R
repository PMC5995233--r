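# Count-level pileup simulation. The simulator operates on per-site allele
# count summaries rather than reads: depth is Poisson around the profile's
# mean, spike-in alt counts are binomial at the purity-scaled effective
# allele fraction, and background substitution errors are multinomial over
# the three non-reference bases. Site counts are stored long: one row per
# (site, allele) with the per-site total depth repeated on each row.

#' Describe a simulated sequencing sample
#'
#' A sample profile bundles the knobs of the count-level simulator: tumor
#' purity (fraction of reads of tumor origin), mean unique on-target depth,
#' and the per-base substitution error rate.
#'
#' @param sample_id character label; also salts the RNG stream.
#' @param role `"tumor"` or `"normal"`.
#' @param purity tumor fraction in \[0, 1\] (0 for a normal sample).
#' @param mean_depth mean unique on-target depth (default 500, the assay's
#'   minimum requirement).
#' @param error_rate per-base substitution probability in \[0, 0.05\]
#'   (default 0.001).
#' @param seed integer seed for this sample's stream.
#' @return an object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, role = c("tumor", "normal"),
                           purity = if (match.arg(role) == "tumor") 1 else 0,
                           mean_depth = 500L, error_rate = 0.001,
                           seed = 1L) {
  role <- match.arg(role)
  assert_scalar_number(purity, "purity", lo = 0, hi = 1)
  assert_scalar_number(mean_depth, "mean_depth", lo = 1)
  assert_scalar_number(error_rate, "error_rate", lo = 0, hi = 0.05)
  assert_scalar_number(seed, "seed")
  structure(list(sample_id = as.character(sample_id), role = role,
                 purity = purity, mean_depth = as.integer(mean_depth),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sample_profile")
}

# split a vector of error totals evenly (multinomially) over 3 alleles
split_errors3 <- function(total) {
  e1 <- rbinom(length(total), total, 1 / 3)
  e2 <- rbinom(length(total), total - e1, 1 / 2)
  cbind(e1, e2, total - e1 - e2)
}

#' Simulate per-site allele counts for one sample
#'
#' Every targeted position receives a Poisson depth around the profile's
#' `mean_depth`. At a truth-variant site the alternate count is
#' `Binomial(depth, effective_vaf)` with
#' `effective_vaf = purity * true_vaf + (1 - purity * true_vaf) * error_rate / 3`,
#' i.e. the spike-in signal diluted by purity plus the chance that a
#' non-variant read is mis-read as the alternate base. At all other sites,
#' substitution errors accumulate at `error_rate`, split evenly over the
#' three non-reference bases. No indel error process is simulated at
#' non-truth sites, and truth sites carry only reference/alternate rows.
#'
#' @param reference a `toy_reference`.
#' @param truths truth variants from [generate_truth_variants()] (possibly
#'   empty); all must fall on targeted positions.
#' @param profile a [sample_profile()].
#' @return data.table of site counts: `contig`, `pos`, `ref` (the anchored
#'   reference allele for that row), `allele`, `count`, `depth` (per-site
#'   total; the sum of `count` within a site equals `depth`).
#' @examples
#' ref <- generate_reference(seed = 1, n_genes = 2, gene_length = 60)
#' nrm <- simulate_site_counts(ref, generate_truth_variants(ref, 0, 0.1),
#'                             sample_profile("N1", "normal", seed = 5))
#' @export
simulate_site_counts <- function(reference, truths, profile) {
  validate_reference(reference)
  if (!inherits(profile, "sample_profile")) stop_param("`profile` must be a sample_profile")
  sites <- panel_positions(reference)
  truths <- data.table::as.data.table(truths)
  if (nrow(truths) > 0) {
    validate_truth_variants(truths)
    hit <- sites[truths, on = .(contig, pos), which = TRUE]
    if (anyNA(hit)) stop_consistency("truth variant outside the targeted panel")
  }

  bases <- c("A", "C", "G", "T")
  with_seed(profile$seed, {
    n <- nrow(sites)
    depth <- rpois(n, profile$mean_depth)
    is_truth <- rep(FALSE, n)
    if (nrow(truths) > 0) {
      is_truth[sites[truths, on = .(contig, pos), which = TRUE]] <- TRUE
    }

    # background sites: errors over the 3 non-reference bases
    bg <- sites[!is_truth]
    bg_depth <- depth[!is_truth]
    etot <- rbinom(nrow(bg), bg_depth, profile$error_rate)
    esplit <- split_errors3(etot)
    other <- vapply(bg$ref, function(b) setdiff(bases, b),
                    FUN.VALUE = character(3))
    bg_rows <- data.table::data.table(
      contig = rep(bg$contig, 4L),
      pos = rep(bg$pos, 4L),
      ref = rep(bg$ref, 4L),
      allele = c(bg$ref, other[1, ], other[2, ], other[3, ]),
      count = c(bg_depth - etot, esplit[, 1], esplit[, 2], esplit[, 3]),
      depth = rep(bg_depth, 4L))
    bg_rows <- bg_rows[count > 0 | allele == ref]

    out <- bg_rows
    if (any(is_truth)) {
      idx <- sites[truths, on = .(contig, pos), which = TRUE]
      t_depth <- depth[idx]
      eff <- profile$purity * truths$true_vaf +
        (1 - profile$purity * truths$true_vaf) * profile$error_rate / 3
      alt <- rbinom(nrow(truths), t_depth, eff)
      t_rows <- data.table::data.table(
        contig = rep(truths$contig, 2L),
        pos = rep(truths$pos, 2L),
        ref = rep(truths$ref_allele, 2L),
        allele = c(truths$ref_allele, truths$alt_allele),
        count = c(t_depth - alt, alt),
        depth = rep(t_depth, 2L))
      t_rows <- t_rows[count > 0 | allele == ref]
      out <- rbind(bg_rows, t_rows)
    }
    data.table::setorder(out, contig, pos, allele)
    validate_site_counts(out)
    out[]
  })
}

validate_site_counts <- function(sc) {
  bad <- sc[, .(ok = sum(count) == depth[1L],
                one_depth = data.table::uniqueN(depth) == 1L),
            by = .(contig, pos)]
  if (!all(bad$ok & bad$one_depth)) {
    stop_param("site counts violate sum(allele counts) == depth")
  }
  if (any(sc$count < 0) || any(sc$depth < 0)) stop_param("negative counts")
  invisible(sc)
}

site_depths <- function(sc) {
  unique(sc[, .(contig, pos, depth)])
}

#' Mix a tumor and a normal pileup into a purity titration
#'
#' Emulates the cell-line admixture series: every tumor read is retained
#' with probability `tumor_fraction` and every normal read with probability
#' `1 - tumor_fraction` (independent binomial thinning per allele row), and
#' the thinned counts are summed per site. Total depth is preserved in
#' expectation; at `tumor_fraction` 0 or 1 the thinning is degenerate and the
#' output equals one input exactly.
#'
#' @param tumor,normal site-count tables over the identical site set.
#' @param tumor_fraction probability a read originates from the tumor sample.
#' @param seed integer seed.
#' @return mixed site-count table.
#' @export
mix_titration <- function(tumor, normal, tumor_fraction, seed = 1L) {
  assert_scalar_number(tumor_fraction, "tumor_fraction", lo = 0, hi = 1)
  tk <- unique(tumor[, .(contig, pos)]); nk <- unique(normal[, .(contig, pos)])
  if (nrow(tk) != nrow(nk) || nrow(tk[nk, on = .(contig, pos), nomatch = NULL]) != nrow(tk)) {
    stop_consistency("tumor and normal must cover identical sites")
  }
  with_seed(seed, {
    t2 <- data.table::copy(tumor)[, count := rbinom(.N, count, tumor_fraction)]
    n2 <- data.table::copy(normal)[, count := rbinom(.N, count, 1 - tumor_fraction)]
    mix <- rbind(t2, n2)[, .(count = sum(count)),
                         by = .(contig, pos, ref, allele)]
    mix[, depth := sum(count), by = .(contig, pos)]
    mix <- mix[count > 0 | allele == ref]
    data.table::setorder(mix, contig, pos, allele)
    validate_site_counts(mix)
    mix[]
  })
}

#' Read/write site-count tables as TSV
#'
#' Plain TSV with a `##` provenance header (package version and seed).
#'
#' @param sc site-count data.table.
#' @param path file path.
#' @param seed optional seed recorded for provenance.
#' @return the path (write) or the table (read).
#' @export
write_site_counts <- function(sc, path, seed = NA) write_tsv(sc, path, seed)

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  sc <- read_tsv(path)
  validate_site_counts(sc)
  sc
}

#' Observed variant allele fraction at truth sites
#'
#' Convenience accessor: joins a site-count table against a truth set and
#' returns the observed `count / depth` of each truth alternate allele
#' (0 when the allele was not observed).
#'
#' @param sc site-count table.
#' @param truths truth variant table.
#' @return numeric vector of observed VAFs, one per truth row.
#' @export
observed_vaf <- function(sc, truths) {
  d <- site_depths(sc)
  j <- sc[truths, on = c(contig = "contig", pos = "pos", allele = "alt_allele")]
  dep <- d[truths, on = .(contig, pos)]$depth
  vaf <- j$count / dep
  vaf[is.na(vaf)] <- 0
  vaf
}
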