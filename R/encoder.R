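# Sentence embeddings behind a uniform contract. The comparator never sees
# the backend, only fixed-width vectors, so a pretrained transformer encoder
# can be slotted in without touching the matching model. The default "hash"
# backend is a deterministic feature-hashed lexical embedder that needs no
# model files: stopwords are removed, and the remaining content words
# contribute unigram features plus unordered within-sentence co-occurrence
# pairs ("blue & wing"), all hashed into `dim` signed buckets, pooled over
# the sentence and l2-normalized. The pair features matter: they expose
# attribute conjunctions order-invariantly, so "a blue wing" and "the wing
# is blue" share mass even though no word bigram survives the rephrasing.
# Sentences sharing more content words get higher cosine similarity.

# Function words carrying no matching signal; removed before hashing.
.stop_words <- c(
  "a", "an", "the", "this", "that", "these", "those", "is", "are", "was",
  "were", "be", "been", "has", "have", "had", "with", "and", "or", "but",
  "of", "in", "on", "at", "to", "from", "by", "for", "as", "its", "it",
  "his", "her", "their", "there", "here", "you", "we", "they", "i", "can",
  "will", "would", "may", "also", "very", "most", "some", "any", "all"
)

.backend_registry <- new.env(parent = emptyenv())

#' Register an embedding backend
#'
#' A backend is a function `function(texts, spec) -> matrix` returning one
#' row per input text with `spec$dim` columns. It must be a pure function of
#' `(spec, text)`.
#'
#' @param backend_id backend name.
#' @param fun embedding function.
#' @return `backend_id`, invisibly.
#' @export
register_backend <- function(backend_id, fun) {
  stopifnot(is.function(fun))
  assign(backend_id, fun, envir = .backend_registry)
  invisible(backend_id)
}

#' Encoder specification
#'
#' @param backend_id registered backend name (default `"hash"`).
#' @param dim embedding dimensionality (fixed per backend instance).
#' @param version free-form version tag; part of the cache identity.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(backend_id = "hash", dim = 256L, version = "1") {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 1L, dim >= 1L)
  structure(list(backend_id = backend_id, dim = dim, pooling = "mean",
                 version = as.character(version)),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf("<encoder_spec backend='%s' dim=%d pooling=%s v%s>\n",
              x$backend_id, x$dim, x$pooling, x$version))
  invisible(x)
}

# memo of gram -> c(bucket, sign) per dim, to avoid re-hashing hot tokens
.hash_memo <- new.env(parent = emptyenv())

.gram_bucket <- function(gram, dim) {
  key <- paste0(dim, "\r", gram)
  hit <- .hash_memo[[key]]
  if (!is.null(hit)) return(hit)
  idx <- poly_hash(gram, 31) %% dim + 1
  sgn <- if (poly_hash(gram, 37) %% 2 == 0) 1 else -1
  val <- c(idx, sgn)
  assign(key, val, envir = .hash_memo)
  val
}

.hash_embed_one <- function(text, dim) {
  toks <- setdiff(tokenize_words(text), .stop_words)
  v <- numeric(dim)
  if (length(toks)) {
    grams <- toks
    uniq <- sort(unique(toks))
    if (length(uniq) > 1L) {
      cmb <- utils::combn(uniq, 2L)
      grams <- c(grams, paste(cmb[1L, ], cmb[2L, ], sep = "&"))
    }
    for (g in grams) {
      bs <- .gram_bucket(g, dim)
      v[bs[1L]] <- v[bs[1L]] + bs[2L]
    }
    v <- v / length(grams)           # mean pooling over lexical features
    nrm <- sqrt(sum(v * v))
    if (nrm > 0) v <- v / nrm
  }
  v
}

.hash_backend <- function(texts, spec) {
  out <- matrix(0, nrow = length(texts), ncol = spec$dim)
  for (i in seq_along(texts)) out[i, ] <- .hash_embed_one(texts[i], spec$dim)
  out
}

#' Embed texts
#'
#' Deterministic per `(spec, text)`: the same text always maps to the same
#' vector, and batched calls equal per-item calls. Rows are the embeddings,
#' row names the input digests.
#'
#' @param texts character vector of non-empty strings.
#' @param spec an [encoder_spec()].
#' @return numeric matrix `length(texts) x spec$dim`.
#' @export
embed_texts <- function(texts, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (!length(texts)) return(matrix(0, 0L, spec$dim))
  if (any(!nzchar(normalize_text(texts))))
    stop_sm("embed_texts: texts must be non-empty")
  fun <- .backend_registry[[spec$backend_id]]
  if (is.null(fun))
    stop_sm("unknown backend '", spec$backend_id, "'; registered: ",
            paste(ls(.backend_registry), collapse = ", "))
  M <- fun(texts, spec)
  if (!is.matrix(M) || nrow(M) != length(texts) || ncol(M) != spec$dim)
    stop_sm("backend '", spec$backend_id, "' returned wrong shape")
  if (any(!is.finite(M))) stop_sm("backend produced non-finite embeddings")
  rownames(M) <- text_digest(texts)
  M
}

# ---- embedding cache ------------------------------------------------------

#' Precompute an embedding cache
#'
#' Embeds every sentence of every document (for a corpus) or every caption
#' (for caption sets) once, keyed by a digest of the normalized text, so the
#' encoder is frozen for stage-2 training and corpus scoring.
#'
#' @param x a [corpus()], a list of [caption_set()], or a character vector.
#' @param spec an [encoder_spec()].
#' @return an object of class `embedding_cache` with fields `spec`,
#'   `vectors` (matrix, one row per unique text) and `index` (digest -> row).
#' @export
precompute_cache <- function(x, spec = encoder_spec()) {
  texts <- cache_texts(x)
  texts <- unique(normalize_text(texts))
  M <- embed_texts(texts, spec)
  idx <- seq_along(texts)
  names(idx) <- rownames(M)
  structure(list(spec = spec, vectors = M, index = idx, texts = texts),
            class = "embedding_cache")
}

cache_texts <- function(x) {
  if (inherits(x, "corpus"))
    return(unlist(lapply(x$documents, `[[`, "sentences")))
  if (inherits(x, "caption_set")) return(x$captions)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "caption_set")))
    return(unlist(lapply(x, `[[`, "captions")))
  if (is.character(x)) return(x)
  stop_sm("cannot extract texts from object of class ",
          paste(class(x), collapse = "/"))
}

#' Look up cached embeddings
#'
#' @param cache an `embedding_cache`.
#' @param texts character vector; every normalized text must be present.
#' @return numeric matrix of embeddings, rows parallel to `texts`.
#' @export
cache_lookup <- function(cache, texts) {
  keys <- text_digest(texts)
  rows <- cache$index[keys]
  if (anyNA(rows))
    stop_sm("embedding cache miss for: ",
            paste(utils::head(texts[is.na(rows)], 3L), collapse = " | "))
  cache$vectors[rows, , drop = FALSE]
}

#' @export
print.embedding_cache <- function(x, ...) {
  cat(sprintf("<embedding_cache: %d texts, dim=%d, backend='%s'>\n",
              nrow(x$vectors), x$spec$dim, x$spec$backend_id))
  invisible(x)
}

#' Persist / reload an embedding cache
#'
#' The cache is written as a plain-text TSV of vectors plus a JSON header
#' carrying the encoder spec and the digest index; reloading under a spec
#' with a different dimensionality is an error.
#'
#' @param cache an `embedding_cache`.
#' @param path output path (a `.json` header; vectors go to `<path>.tsv`).
#' @return `path`, invisibly.
#' @export
save_cache <- function(cache, path) {
  hdr <- list(spec = unclass(cache$spec), keys = names(cache$index),
              texts = cache$texts)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE), path, useBytes = TRUE)
  # 17 significant digits makes the double -> text -> double trip exact
  txt <- apply(cache$vectors, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, paste0(path, ".tsv"), useBytes = TRUE)
  invisible(path)
}

#' @rdname save_cache
#' @param spec optional [encoder_spec()] the cache must match.
#' @return for `load_cache`, the reloaded `embedding_cache`.
#' @export
load_cache <- function(path, spec = NULL) {
  hdr <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cached_spec <- do.call(encoder_spec, hdr$spec[c("backend_id", "dim", "version")])
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "encoder_spec"))
    if (spec$dim != cached_spec$dim)
      stop_sm("cache dim ", cached_spec$dim, " != spec dim ", spec$dim)
    if (spec$backend_id != cached_spec$backend_id)
      stop_sm("cache backend '", cached_spec$backend_id,
              "' != spec backend '", spec$backend_id, "'")
  }
  M <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(M) <- list(hdr$keys, NULL)
  idx <- seq_along(hdr$keys)
  names(idx) <- hdr$keys
  structure(list(spec = cached_spec, vectors = M, index = idx,
                 texts = hdr$texts),
            class = "embedding_cache")
}
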