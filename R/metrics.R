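# Validation metrics: event matching into confusion counts and the rate
# arithmetic behind every printed validation number — sensitivity
# TP/(TP+FN), PPV TP/(TP+FP), specificity TN/(TN+FP) — plus VAF concordance
# between laboratories and per-titer summaries of the in silico dilution
# series. Presentation helpers round half-up: rates to 2 decimals,
# percentages to 1 decimal.

#' Construct confusion counts
#'
#' @param tp,fp,fn non-negative integers.
#' @param tn non-negative integer, or `NA` when no negative universe is
#'   defined (SNV/indel matching, where true negatives are the untested
#'   remainder of the genome).
#' @param context free-text label carried through reports.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = NA_integer_, context = "") {
  for (v in list(tp, fp, fn)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_param("tp, fp, fn must be single non-negative numbers")
    }
  }
  if (!is.na(tn) && tn < 0) stop_param("tn must be >= 0 or NA")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 tn = if (is.na(tn)) NA_integer_ else as.integer(tn),
                 context = context),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts%s: TP=%d FP=%d FN=%d TN=%s\n",
              if (nzchar(x$context)) paste0(" [", x$context, "]") else "",
              x$tp, x$fp, x$fn,
              if (is.na(x$tn)) "NA" else format(x$tn)))
  invisible(x)
}

#' Match calls against truth into confusion counts
#'
#' Event identity depends on the mode:
#' * `snv_indel`: `(contig, pos, ref_allele, alt_allele)`; only reported
#'   calls count; TN is undefined (`NA`).
#' * `cnv`: `(gene_id, verdict class)` — an amplification truth is matched
#'   by an `amplified` verdict, a homozygous-deletion truth by a
#'   `homozygous_deletion` verdict. TN counts genes of the negative universe
#'   (defaults to the called gene set) that are negative in truth and not
#'   called positive.
#' * `fusion`: unordered gene pair of reported calls vs. truth pairs. TN
#'   requires an explicit `universe` of assayed pairs, else `NA`.
#'
#' @param calls caller output of the respective module.
#' @param truth truth table of the respective module.
#' @param mode one of `"snv_indel"`, `"cnv"`, `"fusion"`.
#' @param universe optional negative universe (character vector of gene ids
#'   for `cnv`; 2-column data.frame of pairs for `fusion`).
#' @return [confusion_counts()].
#' @export
match_events <- function(calls, truth,
                         mode = c("snv_indel", "cnv", "fusion"),
                         universe = NULL) {
  mode <- tryCatch(match.arg(mode), error = function(e) {
    stop_param("unknown matching mode")
  })
  calls <- data.table::as.data.table(calls)
  truth <- data.table::as.data.table(truth)

  if (mode == "snv_indel") {
    tkey <- if (nrow(truth)) {
      unique(truth[, paste(contig, pos, ref_allele, alt_allele)])
    } else character()
    ckey <- if (nrow(calls)) {
      unique(calls[reported == TRUE,
                   paste(contig, pos, ref_allele, alt_allele)])
    } else character()
    return(confusion_counts(tp = sum(tkey %in% ckey),
                            fn = sum(!tkey %in% ckey),
                            fp = sum(!ckey %in% tkey),
                            context = mode))
  }

  if (mode == "cnv") {
    verdict_event <- c(amplified = "amplification",
                       homozygous_deletion = "homozygous_deletion")
    pos_truth <- if (nrow(truth)) truth[event != "normal"] else truth
    tkey <- if (nrow(pos_truth)) paste(pos_truth$gene_id, pos_truth$event) else character()
    pos_calls <- if (nrow(calls)) calls[verdict != "normal_equivocal"] else calls
    ckey <- if (nrow(pos_calls)) {
      paste(pos_calls$gene_id, verdict_event[pos_calls$verdict])
    } else character()
    uni <- universe %||% unique(calls$gene_id)
    neg_genes <- setdiff(uni, pos_truth$gene_id)
    tn <- sum(!neg_genes %in% pos_calls$gene_id)
    return(confusion_counts(tp = sum(tkey %in% ckey),
                            fn = sum(!tkey %in% ckey),
                            fp = sum(!ckey %in% tkey),
                            tn = tn, context = mode))
  }

  # fusion
  tkey <- if (nrow(truth)) unique(pair_key_of(truth$gene5, truth$gene3)) else character()
  rep_calls <- if (nrow(calls)) calls[reported == TRUE] else calls
  ckey <- if (nrow(rep_calls)) {
    unique(pair_key_of(rep_calls$gene5, rep_calls$gene3))
  } else character()
  tn <- NA_integer_
  if (!is.null(universe)) {
    uni <- data.table::as.data.table(universe)
    ukey <- unique(pair_key_of(uni[[1]], uni[[2]]))
    tn <- sum(!setdiff(ukey, tkey) %in% ckey)
  }
  confusion_counts(tp = sum(tkey %in% ckey), fn = sum(!tkey %in% ckey),
                   fp = sum(!ckey %in% tkey), tn = tn, context = mode)
}

#' Validation rates from confusion counts
#'
#' `sensitivity()` = TP/(TP+FN); `ppv()` = TP/(TP+FP); `specificity()` =
#' TN/(TN+FP). Each errors (class `panelval_undefined_metric_error`) when its
#' denominator is zero or, for specificity, when TN is undefined.
#'
#' @param counts a [confusion_counts()].
#' @return numeric rate in \[0, 1\].
#' @examples
#' sensitivity(confusion_counts(tp = 63, fp = 0, fn = 1))  # 0.984375
#' ppv(confusion_counts(tp = 107, fp = 6, fn = 0))         # 0.9469...
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    stop_undefined_metric("sensitivity undefined: tp + fn == 0")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
ppv <- function(counts) {
  if (counts$tp + counts$fp == 0) {
    stop_undefined_metric("ppv undefined: tp + fp == 0")
  }
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if (is.na(counts$tn)) {
    stop_undefined_metric("specificity undefined: no negative universe (tn is NA)")
  }
  if (counts$tn + counts$fp == 0) {
    stop_undefined_metric("specificity undefined: tn + fp == 0")
  }
  counts$tn / (counts$tn + counts$fp)
}

#' Inter-laboratory VAF concordance
#'
#' Pearson product-moment correlation of paired variant allele fractions,
#' reported both as `pearson_r` and as `r_squared` (kept explicitly distinct,
#' since concordance write-ups often conflate the two), plus the mean
#' per-pair coefficient of variation (sd of the two measurements divided by
#' their mean).
#'
#' @param pairs data.frame with columns `vaf_a`, `vaf_b` in \[0, 1\].
#' @return list with `pearson_r`, `r_squared`, `cv`.
#' @export
vaf_concordance <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) < 2L) stop_undefined_metric("need at least 2 VAF pairs")
  a <- pairs$vaf_a; b <- pairs$vaf_b
  if (any(a < 0 | a > 1 | b < 0 | b > 1)) stop_param("VAFs must be in [0, 1]")
  if (sd(a) == 0 || sd(b) == 0) {
    stop_undefined_metric("degenerate variance: VAF vectors are constant")
  }
  r <- cor(a, b)
  m <- (a + b) / 2
  cvs <- ifelse(m > 0, abs(a - b) / sqrt(2) / m, NA_real_)
  list(pearson_r = r, r_squared = r^2, cv = mean(cvs, na.rm = TRUE))
}

#' Summarise an in silico titration series
#'
#' For each titer, matches calls against truth (`snv_indel` mode) and
#' reports the confusion counts with sensitivity and PPV, both exact and
#' rounded to the 2-decimal presentation format. Rows are ordered by
#' descending titer.
#'
#' @param per_titer list of lists, each with elements `titer`, `calls`,
#'   `truth`.
#' @return data.table: `titer`, `tp`, `fp`, `fn`, `sensitivity`, `ppv`
#'   (rounded half-up to 2 decimals), `sensitivity_exact`, `ppv_exact`.
#' @export
titration_summary <- function(per_titer) {
  titers <- vapply(per_titer, function(x) x$titer, numeric(1))
  if (anyDuplicated(titers)) stop_param("titers must be distinct")
  rows <- lapply(per_titer, function(x) {
    cc <- match_events(x$calls, x$truth, mode = "snv_indel")
    se <- sensitivity(cc); pv <- ppv(cc)
    data.table::data.table(titer = x$titer, tp = cc$tp, fp = cc$fp,
                           fn = cc$fn,
                           sensitivity = round_half_up(se, 2),
                           ppv = round_half_up(pv, 2),
                           sensitivity_exact = se, ppv_exact = pv)
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -titer)
  out[]
}

#' Write a validation report as JSON and TSV
#'
#' @param report named list (JSON side) containing a `results` data.frame
#'   (TSV side).
#' @param json_path,tsv_path output paths (either may be NULL).
#' @param seed optional provenance seed.
#' @return invisibly, the report.
#' @export
write_validation_report <- function(report, json_path = NULL, tsv_path = NULL,
                                    seed = NA) {
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path) && !is.null(report$results)) {
    write_tsv(data.table::as.data.table(report$results), tsv_path, seed)
  }
  invisible(report)
}
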