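#' Normalize free text for dictionary matching
#'
#' Canonical text form used throughout the package: Unicode NFC, lowercase
#' folding (a no-op for Hangul and romanized-Korean hyphenated forms, which
#' carry no case distinction that matters), runs of whitespace collapsed to a
#' single space, and leading/trailing whitespace trimmed. All term lookup,
#' stop-phrase masking and keyword detection operate on this form, so surface
#' variants that differ only in case or spacing are treated as identical.
#'
#' @param x Character vector.
#' @return Character vector of the same length in normalized form.
#' @examples
#' normalize_text("  Colon   CANCER ")
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# Mask placeholder: a character that survives normalization unchanged and can
# never occur inside a term surface form, so masked runs cannot take part in
# any later match.
MASK_CHAR <- "█"

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention used for the
#' percentages this package reports), as opposed to base R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
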