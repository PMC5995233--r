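# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

tiny_reference <- function(seed = 1, n_genes = 2, gene_length = 60,
                           tier1_fraction = 0.5) {
  generate_reference(seed = seed, n_genes = n_genes,
                     gene_length = gene_length,
                     tier1_fraction = tier1_fraction)
}

# Build a site-count table by hand from per-row (contig, pos, ref, allele,
# count); depth is the per-site count sum.
make_site_counts <- function(contig, pos, ref, allele, count) {
  sc <- data.table::data.table(contig = contig, pos = as.integer(pos),
                               ref = ref, allele = allele,
                               count = as.integer(count))
  sc[, depth := sum(count), by = .(contig, pos)]
  data.table::setorder(sc, contig, pos, allele)
  sc[]
}

# A flat background site-count table: every panel position homozygous
# reference at the given depth.
flat_counts <- function(reference, depth) {
  sites <- panel_positions(reference)
  make_site_counts(sites$contig, sites$pos, sites$ref, sites$ref,
                   rep(as.integer(depth), nrow(sites)))
}

# One-gene panel annotation for hand-built calling fixtures.
one_gene_panel <- function(contig = "panel_1", start = 0L, end = 1000L,
                           tier = 1L, gene_id = "GENEX") {
  data.table::data.table(gene_id = gene_id, contig = contig,
                         start = as.integer(start), end = as.integer(end),
                         tier = as.integer(tier))
}

# Minimal reported-call table for metric tests.
fake_calls <- function(pos, reported = TRUE, contig = "c1",
                       ref_allele = "A", alt_allele = "T") {
  data.table::data.table(contig = contig, pos = as.integer(pos),
                         ref_allele = ref_allele, alt_allele = alt_allele,
                         reported = rep_len(reported, length(pos)))
}

fake_truth <- function(pos, contig = "c1", ref_allele = "A",
                       alt_allele = "T") {
  data.table::data.table(contig = contig, pos = as.integer(pos),
                         ref_allele = ref_allele, alt_allele = alt_allele)
}
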