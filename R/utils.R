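`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

# Whitespace-normalize and apply Unicode NFC; all parsing starts from this.
str_norm <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- gsub("\ufeff", "", x, fixed = TRUE)
  trimws(gsub("[[:space:]]+", " ", x))
}

casefold_lower <- function(x) stringi::stri_trans_tolower(x)

# Case-fold + strip diacritics; used for region-name keys.
fold_key <- function(x) {
  casefold_lower(str_norm(stringi::stri_trans_general(x, "Latin-ASCII")))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

abort_tm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "taxonmatch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
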