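#' @keywords internal
"_PACKAGE"

#' Normalize a food or procedure name for matching
#'
#' Lowercases, trims, and collapses internal whitespace so that lookups are
#' insensitive to case and spacing. The bundled reference table keeps verbatim
#' display labels in a separate column.
#'
#' @param x Character vector of names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' normalize_name("  Gouda   CHEESE ")
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Size of one unit in the last printed decimal digit of a value, e.g.
# 9.7 -> 0.1, 16 -> 1, 0.0076 -> 1e-4. Used by the table validators to
# translate "within one unit of the last printed digit" into a numeric
# tolerance. Values are capped at 6 decimals to stay clear of binary
# representation noise.
unit_last_digit <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_real_)
    for (k in 0:6) {
      if (abs(v * 10^k - round(v * 10^k)) < 1e-8) return(10^-k)
    }
    10^-6
  }, numeric(1))
}

# Round to n significant figures, the convention used for printed-table
# comparisons (internal math is kept at full precision).
round_sig <- function(x, digits = 2) signif(x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_prcf <- function(msg, class) {
  stop(structure(
    class = c(class, "prcf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
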