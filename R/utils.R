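#' @importFrom rlang abort %||% is_string
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Condition helpers -----------------------------------------------------------
#
# All user-facing failures carry a condition class so callers (and the CLI)
# can map them to exit codes without string matching:
#   lp_validation_error -> malformed inputs, bad config, bad expressions
#   lp_io_error         -> filesystem / workbook / network problems
#   lp_offline_miss     -> cache miss while offline (subclass of io)

lp_stop <- function(msg, class = "lp_validation_error", ...) {
  abort(msg, class = c(class, "lp_error"), ...)
}

lp_stop_io <- function(msg, class = NULL, ...) {
  abort(msg, class = c(class, "lp_io_error", "lp_error"), ...)
}

lp_assert <- function(cond, msg, class = "lp_validation_error") {
  if (!isTRUE(cond)) lp_stop(msg, class = class)
  invisible(TRUE)
}

# Integer percentage, rounding half away from zero (so 28.57 -> 29 and
# -0.5 -> -1), unlike base round()'s round-half-even.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Integer percentage of a part over a whole
#'
#' Computes `100 * part / whole` rounded to an integer percentage using
#' round-half-away-from-zero (28.57 becomes 29). A zero or missing
#' denominator yields `NA` rather than an error, so summary tables can
#' report empty loci gracefully.
#'
#' @param part Numerator count (vectorised).
#' @param whole Denominator count.
#' @return Integer percentage vector; `NA` where `whole` is 0 or missing.
#' @examples
#' percent_of(950, 2149) # 44
#' percent_of(6, 21)     # 29
#' @export
percent_of <- function(part, whole) {
  out <- round_half_away(100 * part / whole)
  out[!is.finite(out)] <- NA_real_
  as.integer(out)
}

# Deterministic RNG scope: evaluates expr with the given seed and restores
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Find a column by case-insensitive candidate names; returns the actual
# column name or NA.
match_column <- function(tbl, candidates) {
  nms <- names(tbl)
  hit <- nms[tolower(nms) %in% tolower(candidates)]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

# Collapse a character vector to a stable ";"-joined string of distinct
# sorted values (used for reducers and sheet rendering of list columns).
concat_distinct <- function(x) {
  x <- unique(as.character(x[!is.na(x)]))
  if (length(x) == 0) NA_character_ else paste(sort(x), collapse = ";")
}

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & x == floor(x)
}

# Format a bp coordinate in Mb for locus slugs: 131000000 -> "131",
# 131500000 -> "131.5" (2 dp max, trailing zeros trimmed).
fmt_mb <- function(bp) {
  v <- sprintf("%.2f", bp / 1e6)
  v <- sub("0+$", "", v)
  sub("\\.$", "", v)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
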