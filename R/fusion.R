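# Threshold-based fusion calling over chimeric-evidence tables. Candidates
# come from junction-spanning and discordant-mate evidence; positivity is
# decided on junction-spanning reads alone, with 16 spanning reads (boundary
# inclusive) the validated operating point. Discordant-mate counts are
# carried through for reporting but do not enter the decision. Tier
# assignment matches the unordered gene pair against the clinically
# actionable rearrangement list.

pair_key_of <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "--")

#' Call fusions from a chimeric-evidence table
#'
#' @param evidence data.table of `gene5`, `gene3`, `n_spanning`,
#'   `n_discordant`.
#' @param actionable_pairs data.frame of gene pairs (first two columns used;
#'   unordered matching), e.g. [default_actionable_pairs()].
#' @param min_spanning junction-spanning reads required for positivity
#'   (default 16, inclusive).
#' @return data.table of calls sorted by descending `n_spanning` then pair:
#'   `gene5`, `gene3`, `n_spanning`, `n_discordant`, `tier`
#'   (`actionable`/`secondary`), `reported`.
#' @examples
#' ev <- data.frame(gene5 = "ESR1", gene3 = "CCDC170",
#'                  n_spanning = 20, n_discordant = 4)
#' call_fusions(ev, data.frame(a = "ESR1", b = "CCDC170"))
#' @export
call_fusions <- function(evidence, actionable_pairs, min_spanning = 16L) {
  assert_scalar_number(min_spanning, "min_spanning", lo = 1)
  ev <- data.table::as.data.table(evidence)
  if (any(ev$n_spanning < 0) || any(ev$n_discordant < 0)) {
    stop_param("evidence counts must be >= 0")
  }
  ap <- data.table::as.data.table(actionable_pairs)
  akeys <- if (nrow(ap) > 0) pair_key_of(ap[[1]], ap[[2]]) else character()
  out <- ev[, .(gene5, gene3, n_spanning, n_discordant)]
  out[, pair_key := pair_key_of(gene5, gene3)]
  out[, `:=`(tier = ifelse(pair_key %in% akeys, "actionable", "secondary"),
             reported = n_spanning >= min_spanning)]
  data.table::setorder(out, -n_spanning, pair_key)
  out[, pair_key := NULL]
  out[]
}

#' Count replicate libraries in which each truth fusion is reported
#'
#' Inter-run concordance summary: calls every replicate evidence table and,
#' for each truth fusion, counts the replicates in which the (unordered)
#' pair is reported.
#'
#' @param replicates list of chimeric-evidence tables, one per replicate.
#' @param truth data.table from [fusion_truth()].
#' @param actionable_pairs actionable rearrangement list.
#' @param min_spanning positivity threshold (default 16).
#' @return data.table: `gene5`, `gene3`, `n_detected`, `n_replicates`.
#' @export
replicate_detection <- function(replicates, truth, actionable_pairs,
                                min_spanning = 16L) {
  if (length(replicates) < 1L) stop_param("need at least one replicate")
  truth <- data.table::as.data.table(truth)
  tkeys <- pair_key_of(truth$gene5, truth$gene3)
  detected <- integer(length(tkeys))
  for (ev in replicates) {
    calls <- call_fusions(ev, actionable_pairs, min_spanning)
    rkeys <- pair_key_of(calls$gene5, calls$gene3)[calls$reported]
    detected <- detected + (tkeys %in% rkeys)
  }
  data.table::data.table(gene5 = truth$gene5, gene3 = truth$gene3,
                         n_detected = detected,
                         n_replicates = length(replicates))
}
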