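# RNA fusion evidence simulation. Libraries are represented as chimeric
# evidence tables (gene pair, junction-spanning read count, discordant mate
# count). Truth fusions carry their stated counts verbatim; background noise
# rows model spurious chimeric alignments and are capped below the calling
# threshold by construction, matching how the positivity threshold was
# chosen to leave background sub-threshold.

#' Declare a ground-truth fusion
#'
#' @param gene5,gene3 5' and 3' partner gene symbols (must differ).
#' @param n_spanning junction-spanning read count the library will carry.
#' @param n_discordant discordant mate-pair count.
#' @param actionable whether the pair belongs to the clinically actionable
#'   rearrangement tier.
#' @return one-row data.table: `gene5`, `gene3`, `n_spanning`,
#'   `n_discordant`, `actionable`.
#' @export
fusion_truth <- function(gene5, gene3, n_spanning, n_discordant = 0L,
                         actionable = TRUE) {
  if (any(gene5 == gene3)) stop_param("gene5 and gene3 must differ")
  if (any(n_spanning < 0) || any(n_discordant < 0)) stop_param("counts must be >= 0")
  data.table::data.table(gene5 = gene5, gene3 = gene3,
                         n_spanning = as.integer(n_spanning),
                         n_discordant = as.integer(n_discordant),
                         actionable = as.logical(actionable))
}

#' Simulate a chimeric-evidence table for one RNA library
#'
#' Emits one evidence row per truth fusion with its stated counts, plus
#' `n_noise_events` random background gene pairs whose spanning counts are
#' uniform on `[1, noise_max_reads]` (discordant counts uniform on
#' `[0, spanning]`). With `noise_max_reads` below the caller's threshold the
#' noise stays sub-threshold by construction.
#'
#' @param fusion_truths data.table from [fusion_truth()] (possibly empty).
#' @param n_noise_events number of background rows.
#' @param noise_max_reads cap on background spanning counts (>= 1 when noise
#'   is requested).
#' @param seed integer seed.
#' @return chimeric evidence data.table: `gene5`, `gene3`, `n_spanning`,
#'   `n_discordant`.
#' @export
simulate_fusion_library <- function(fusion_truths, n_noise_events = 0L,
                                    noise_max_reads = 15L, seed = 1L) {
  assert_scalar_number(n_noise_events, "n_noise_events", lo = 0)
  assert_scalar_number(noise_max_reads, "noise_max_reads", lo = 1)
  fusion_truths <- data.table::as.data.table(fusion_truths)
  truth_rows <- if (nrow(fusion_truths) > 0) {
    fusion_truths[, .(gene5, gene3, n_spanning, n_discordant)]
  } else {
    data.table::data.table(gene5 = character(), gene3 = character(),
                           n_spanning = integer(), n_discordant = integer())
  }
  n_noise_events <- as.integer(n_noise_events)
  if (n_noise_events == 0L) return(truth_rows[])
  with_seed(seed, {
    pool <- sprintf("BKGD%04d", sample.int(5000L, 2L * n_noise_events))
    g5 <- pool[seq_len(n_noise_events)]
    g3 <- pool[n_noise_events + seq_len(n_noise_events)]
    swap <- g5 == g3  # distinct ids by construction of the pool, but guard
    g3[swap] <- paste0(g3[swap], "B")
    noise <- data.table::data.table(
      gene5 = g5, gene3 = g3,
      n_spanning = sample.int(as.integer(noise_max_reads), n_noise_events,
                              replace = TRUE))
    noise[, n_discordant := as.integer(floor(stats::runif(.N) * (n_spanning + 1L)))]
    rbind(truth_rows, noise)[]
  })
}

#' Read/write chimeric-evidence tables as TSV
#'
#' @param ev evidence data.table (`gene5`, `gene3`, `n_spanning`,
#'   `n_discordant`).
#' @param path file path.
#' @param seed optional provenance seed.
#' @return the path (write) or the table (read).
#' @export
write_evidence <- function(ev, path, seed = NA) write_tsv(ev, path, seed)

#' @rdname write_evidence
#' @export
read_evidence <- function(path) read_tsv(path)

#' Bundled synthetic actionable-rearrangement tier
#'
#' A 40-pair stand-in for the assay's clinically actionable fusion tier,
#' assembled from fusion partners recurrently described in the oncology
#' literature. Synthetic in the sense that the list is illustrative, not a
#' clinical artifact.
#'
#' @return data.table with columns `gene_a`, `gene_b`.
#' @export
default_actionable_pairs <- function() {
  read_tsv(system.file("extdata", "actionable_fusions_synthetic.tsv",
                       package = "panelval", mustWork = TRUE))
}
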