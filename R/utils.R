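#' Percentage at a fixed printed precision
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places to round to (the precision the value is
#'   reported at).
#' @return Numeric percentage, rounded.
#' @examples
#' format_percent(145, 3949, 1)  # 3.7
#' @export
format_percent <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  round(100 * num / den, digits)
}

# plain markdown table from a data.frame (no extra dependencies)
md_table <- function(df) {
  df[] <- lapply(df, function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "-", formatC(x, format = "fg", digits = 4))
    else ifelse(is.na(x), "-", as.character(x))
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
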