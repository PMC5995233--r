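# Shared numeric helpers, error conditions, seeded-RNG plumbing and
# provenance-aware TSV IO used across all modules.

#' Round half away from zero
#'
#' Decimal rounding with ties rounded away from zero ("half-up"), matching
#' the convention used when clinical validation reports print rates such as
#' 98.4% or 0.99. Base R's `round()` uses IEEE banker's rounding, which
#' rounds 0.985 to 0.98; reporting helpers must not.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.984375 * 100, 1) # 98.4
#' round_half_up(0.985, 2)          # 0.99
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a rate or a percentage the way validation reports print them
#'
#' `fmt_rate()` prints a proportion with two decimals ("0.99"); `fmt_percent()`
#' prints a percentage with one decimal ("98.4%"). Both round half-up.
#'
#' @param x numeric proportion in \[0, 1\].
#' @return character scalar/vector.
#' @examples
#' fmt_percent(63 / 64)  # "98.4%"
#' fmt_rate(109 / 110)   # "0.99"
#' @export
fmt_rate <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' @rdname fmt_rate
#' @export
fmt_percent <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))

# --- error conditions ------------------------------------------------------

condition_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "panelval_error")))
}
stop_param <- function(msg) condition_stop(msg, "panelval_parameter_error")
stop_capacity <- function(msg) condition_stop(msg, "panelval_capacity_error")
stop_consistency <- function(msg) condition_stop(msg, "panelval_consistency_error")
stop_degenerate <- function(msg) condition_stop(msg, "panelval_degenerate_input_error")
stop_undefined_metric <- function(msg) condition_stop(msg, "panelval_undefined_metric_error")

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_param(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# --- seeds -----------------------------------------------------------------

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' One master seed drives a whole study; per-sample streams use sub-seeds
#' derived by a stable polynomial hash of `(master_seed, id)` so that adding
#' or reordering samples does not perturb other samples' data. The result is
#' always a valid 32-bit integer seed.
#'
#' @param master_seed single integer-like number.
#' @param id character label of the stream (e.g. a sample id).
#' @return integer seed in \[0, 2^31 - 2\].
#' @examples
#' derive_seed(42, "tumor_A") != derive_seed(42, "tumor_B")
#' @export
derive_seed <- function(master_seed, id) {
  assert_scalar_number(master_seed, "master_seed")
  h <- abs(as.numeric(master_seed)) %% 2147483647
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# --- provenance-aware TSV IO ----------------------------------------------

provenance_lines <- function(seed = NA) {
  c(sprintf("## panelval v%s", as.character(utils::packageVersion("panelval"))),
    sprintf("## seed=%s", ifelse(is.na(seed), "NA", format(seed))))
}

write_tsv <- function(dt, path, seed = NA) {
  writeLines(provenance_lines(seed), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
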