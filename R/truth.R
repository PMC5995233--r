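# Ground-truth somatic variant sets: the digital spike-in material. Variants
# are placed at distinct targeted positions, all at one nominal allele
# fraction (the titer), with a configurable indel share and a configurable
# share of benign annotations that the downstream classification filter is
# expected to suppress.

#' Generate a ground-truth somatic variant set for digital spike-in
#'
#' Samples `n_variants` distinct targeted positions and creates hotspot-like
#' somatic events, all with the same `true_vaf` (the titer of the in silico
#' dilution series). Indels use VCF-style anchored representation: an
#' insertion has `ref = base`, `alt = base + inserted`; a deletion has
#' `ref = base + deleted`, `alt = base`, anchored at the left.
#'
#' @param reference a `toy_reference`.
#' @param n_variants number of variants (may be 0).
#' @param vaf nominal variant allele fraction in (0, 1] carried by every
#'   variant.
#' @param indel_fraction fraction of variants emitted as indels
#'   (`round(indel_fraction * n_variants)`; alternating insertion/deletion).
#' @param benign_fraction fraction annotated as benign; the remainder is
#'   split pathogenic/VUS.
#' @param seed integer seed; identical seeds give identical truth sets.
#' @return data.table of truth variants: `contig`, `pos` (1-based anchor),
#'   `ref_allele`, `alt_allele`, `vtype` (`SNV`/`INS`/`DEL`), `true_vaf`,
#'   `gene_id`, `classification`.
#' @examples
#' ref <- generate_reference(seed = 7)
#' tv <- generate_truth_variants(ref, n_variants = 110, vaf = 0.25, seed = 1)
#' nrow(tv); all(tv$true_vaf == 0.25)
#' @export
generate_truth_variants <- function(reference, n_variants, vaf,
                                    indel_fraction = 0, benign_fraction = 0,
                                    seed = 1L) {
  validate_reference(reference)
  assert_scalar_number(n_variants, "n_variants", lo = 0)
  if (!is.numeric(vaf) || length(vaf) != 1L || vaf <= 0 || vaf > 1) {
    stop_param("`vaf` must be in (0, 1]")
  }
  assert_scalar_number(indel_fraction, "indel_fraction", lo = 0, hi = 1)
  assert_scalar_number(benign_fraction, "benign_fraction", lo = 0, hi = 1)
  n_variants <- as.integer(n_variants)

  empty <- data.table::data.table(
    contig = character(), pos = integer(), ref_allele = character(),
    alt_allele = character(), vtype = character(), true_vaf = numeric(),
    gene_id = character(), classification = character())
  if (n_variants == 0L) return(empty)

  sites <- panel_positions(reference)
  if (n_variants > nrow(sites)) {
    stop_capacity(sprintf("requested %d variants but panel has %d positions",
                          n_variants, nrow(sites)))
  }
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    picked <- sites[sample.int(nrow(sites), n_variants)]
    n_indel <- as.integer(round_half_up(indel_fraction * n_variants))
    vtype <- rep("SNV", n_variants)
    if (n_indel > 0) {
      idx <- sample.int(n_variants, n_indel)
      vtype[idx] <- rep_len(c("INS", "DEL"), n_indel)
    }
    # deletions need a following base inside the same gene
    gene_end <- reference$genes[match(picked$gene_id, gene_id), end]
    vtype[vtype == "DEL" & picked$pos >= gene_end] <- "INS"

    ref_allele <- picked$ref
    alt_allele <- character(n_variants)
    for (i in seq_len(n_variants)) {
      b <- picked$ref[i]
      alt_allele[i] <- switch(vtype[i],
        SNV = sample(setdiff(bases, b), 1L),
        INS = paste0(b, sample(bases, 1L)),
        DEL = {
          nxt <- contig_base(reference, picked$contig[i], picked$pos[i] + 1L)
          ref_allele[i] <- paste0(b, nxt)
          b
        })
    }

    classification <- sample(c("pathogenic", "VUS"), n_variants,
                             replace = TRUE, prob = c(0.7, 0.3))
    n_benign <- as.integer(round_half_up(benign_fraction * n_variants))
    if (n_benign > 0) {
      classification[sample.int(n_variants, n_benign)] <- "benign"
    }

    out <- data.table::data.table(
      contig = picked$contig, pos = picked$pos, ref_allele = ref_allele,
      alt_allele = alt_allele, vtype = vtype, true_vaf = vaf,
      gene_id = picked$gene_id, classification = classification)
    validate_truth_variants(out)
    out[order(contig, pos)]
  })
}

validate_truth_variants <- function(tv) {
  if (nrow(tv) == 0L) return(invisible(tv))
  if (any(tv$ref_allele == tv$alt_allele)) stop_param("ref_allele == alt_allele")
  snv <- tv$vtype == "SNV"
  if (any(nchar(tv$ref_allele[snv]) != 1L | nchar(tv$alt_allele[snv]) != 1L)) {
    stop_param("SNV alleles must have length 1")
  }
  if (any(tv$true_vaf <= 0 | tv$true_vaf > 1)) stop_param("true_vaf must be in (0, 1]")
  if (anyDuplicated(tv[, .(contig, pos)])) stop_param("truth positions must be distinct")
  invisible(tv)
}

#' Write a truth variant set as VCF 4.2
#'
#' INFO keys: `TRUE_VAF` (nominal spike-in fraction), `CLASS` (classification)
#' and `GENE`. Positions are 1-based, indels left-anchored, matching the VCF
#' convention used throughout the package.
#'
#' @param truth data.table from [generate_truth_variants()].
#' @param path output path.
#' @param reference optional `toy_reference` used to emit contig headers.
#' @param seed optional seed recorded in the header for provenance.
#' @return invisibly, `path`.
#' @export
write_truth_vcf <- function(truth, path, reference = NULL, seed = NA) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=panelval_v%s", as.character(utils::packageVersion("panelval"))),
    sprintf("##panelval_seed=%s", ifelse(is.na(seed), "NA", format(seed))),
    '##INFO=<ID=TRUE_VAF,Number=1,Type=Float,Description="Nominal spike-in allele fraction">',
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Variant classification">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Panel gene">')
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(reference$contigs),
                                nchar(reference$contigs)))
  }
  header <- c(header, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(truth) == 0L) character() else truth[, sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tTRUE_VAF=%g;CLASS=%s;GENE=%s",
    contig, pos, ref_allele, alt_allele, true_vaf, classification, gene_id)]
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load the bundled synthetic hotspot template catalogue
#'
#' A small static stand-in for a somatic hotspot database: recurrent-looking
#' variant templates with curated classifications (pathogenic / VUS /
#' benign). It backs worked examples of the benign-variant reporting filter;
#' it is synthetic and carries no real catalogue coordinates.
#'
#' @return data.table with columns `gene`, `protein_change`, `ref`, `alt`,
#'   `classification`.
#' @export
load_hotspot_templates <- function() {
  read_tsv(system.file("extdata", "hotspot_templates_synthetic.tsv",
                       package = "panelval", mustWork = TRUE))
}
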