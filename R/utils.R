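#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize surface text
#'
#' Applies NFC unicode normalization and collapses runs of whitespace to a
#' single space. Case is preserved: lowercasing happens only inside
#' tokenization and noun extraction, so the surface form stays available to
#' the sentence encoder.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(text) {
  text <- stringi::stri_trans_nfc(enc2utf8(as.character(text)))
  text <- gsub("\\s+", " ", text, perl = TRUE)
  trimws(text)
}

# Lowercased word tokens (runs of letters/digits). Shared by the encoder,
# the baselines and noun extraction so their vocabularies agree.
tokenize_words <- function(text) {
  text <- tolower(normalize_text(text))
  toks <- stringi::stri_extract_all_regex(text, "[a-z0-9]+")[[1]]
  if (length(toks) == 1L && is.na(toks[1L])) character(0) else toks
}

# Deterministic 31/37 polynomial string hashes mod 2^31 - 1. All
# intermediates stay below 2^36, exact in doubles, so results are identical
# across platforms. Used for feature hashing and cache keys.
poly_hash <- function(s, mult = 31) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * mult + x) %% 2147483647
  h
}

# Stable digest for cache keys: two independent polynomial hashes of the
# normalized text, hex-joined. Collisions at corpus scale are negligible.
text_digest <- function(text) {
  text <- normalize_text(text)
  vapply(text, function(s) {
    sprintf("%08x%08x", poly_hash(s, 31), poly_hash(s, 37))
  }, character(1), USE.NAMES = FALSE)
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_sm <- function(...) stop(..., call. = FALSE)
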