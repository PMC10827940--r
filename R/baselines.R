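# Classical retrieval baselines sharing the caption-set/corpus containers
# and the ranking type with the comparator path, so the four methods are
# drop-in comparable. No R package in the installed stack provides TF-IDF
# or BM25, so both are implemented here directly from their standard
# formulas and pinned to hand-computed oracles in the tests.

word_ngrams <- function(toks, n_lo, n_hi) {
  out <- character(0)
  for (n in n_lo:n_hi) {
    if (length(toks) < n) next
    if (n == 1L) { out <- c(out, toks); next }
    idx <- seq_len(length(toks) - n + 1L)
    grams <- toks[idx]
    for (k in seq_len(n - 1L)) grams <- paste(grams, toks[idx + k], sep = "_")
    out <- c(out, grams)
  }
  out
}

#' TF-IDF baseline configuration
#'
#' @param ngram_range integer pair `c(low, high)` of word n-gram orders;
#'   default `c(2, 3)` (unigrams excluded).
#' @param sublinear_tf use `1 + log(tf)` instead of raw counts?
#' @return an object of class `tfidf_config`.
#' @export
tfidf_config <- function(ngram_range = c(2L, 3L), sublinear_tf = FALSE) {
  ngram_range <- as.integer(ngram_range)
  stopifnot(length(ngram_range) == 2L, ngram_range[1L] >= 1L,
            ngram_range[1L] <= ngram_range[2L])
  structure(list(ngram_range = ngram_range, sublinear_tf = sublinear_tf,
                 similarity = "cosine"),
            class = "tfidf_config")
}

#' Okapi BM25 configuration
#'
#' @param k1 term-frequency saturation (default 1.5).
#' @param b length normalization in `[0, 1]` (default 0.75).
#' @return an object of class `bm25_config`.
#' @export
bm25_config <- function(k1 = 1.5, b = 0.75) {
  stopifnot(k1 >= 0, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "bm25_config")
}

.term_counts <- function(terms, vocab) {
  v <- numeric(length(vocab))
  if (length(terms)) {
    tb <- table(terms)
    hit <- match(names(tb), vocab)
    ok <- !is.na(hit)
    v[hit[ok]] <- as.numeric(tb[ok])
  }
  v
}

#' Rank documents by TF-IDF cosine similarity
#'
#' Each document is its sentences pooled into one bag of word n-grams;
#' each image's query is its captions pooled likewise. Weights are
#' `tf * idf` with the smoothed inverse document frequency
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, vectors l2-normalized, and
#' documents ranked by cosine similarity to the query. A query with no
#' in-vocabulary n-gram gets uniform scores (tie rank by class id) with a
#' warning.
#'
#' @param caption_sets a [caption_set()] or list of them.
#' @param corp a [corpus()].
#' @param config a [tfidf_config()].
#' @return a `ranking`.
#' @export
tfidf_rank <- function(caption_sets, corp, config = tfidf_config()) {
  if (inherits(caption_sets, "caption_set")) caption_sets <- list(caption_sets)
  lo <- config$ngram_range[1L]; hi <- config$ngram_range[2L]
  doc_terms <- lapply(corp$documents, function(d)
    word_ngrams(tokenize_words(paste(d$sentences, collapse = " ")), lo, hi))
  vocab <- sort(unique(unlist(doc_terms)))
  if (!length(vocab)) stop_sm("degenerate corpus vocabulary")
  N <- length(doc_terms)
  TF <- t(vapply(doc_terms, .term_counts, numeric(length(vocab)),
                 vocab = vocab))
  df <- colSums(TF > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  weigh <- function(tf) {
    if (config$sublinear_tf) tf[tf > 0] <- 1 + log(tf[tf > 0])
    w <- tf * idf
    nrm <- sqrt(sum(w * w))
    if (nrm > 0) w / nrm else w
  }
  D <- t(apply(TF, 1L, weigh))
  z <- t(vapply(caption_sets, function(cs) {
    q_terms <- word_ngrams(tokenize_words(paste(cs$captions, collapse = " ")),
                           lo, hi)
    q <- weigh(.term_counts(q_terms, vocab))
    if (all(q == 0)) {
      warning("tfidf_rank: query for image '", cs$image_id,
              "' has no in-vocabulary n-grams; uniform scores")
      return(numeric(N))
    }
    drop(D %*% q)
  }, numeric(N)))
  Z <- score_matrix(vapply(caption_sets, `[[`, character(1), "image_id"),
                    corpus_class_ids(corp), z)
  rank_documents(Z, method = "tfidf")
}

#' Rank documents by Okapi BM25
#'
#' Pooled caption tokens (word unigrams) form the query; each document is
#' scored with the classic Okapi formula: per query term `t`,
#' `idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / avgdl))` with
#' `idf(t) = ln((N - df + 0.5) / (df + 0.5))`. Negative-idf terms (those in
#' more than half the documents) are kept, not floored.
#'
#' @inheritParams tfidf_rank
#' @param config a [bm25_config()].
#' @return a `ranking`.
#' @export
bm25_rank <- function(caption_sets, corp, config = bm25_config()) {
  if (inherits(caption_sets, "caption_set")) caption_sets <- list(caption_sets)
  doc_toks <- lapply(corp$documents, function(d)
    tokenize_words(paste(d$sentences, collapse = " ")))
  N <- length(doc_toks)
  dl <- vapply(doc_toks, length, integer(1))
  avgdl <- mean(dl)
  vocab <- sort(unique(unlist(doc_toks)))
  TF <- t(vapply(doc_toks, .term_counts, numeric(length(vocab)),
                 vocab = vocab))
  df <- colSums(TF > 0)
  idf <- log((N - df + 0.5) / (df + 0.5))
  k1 <- config$k1; b <- config$b
  z <- t(vapply(caption_sets, function(cs) {
    q <- tokenize_words(paste(cs$captions, collapse = " "))
    q <- q[q %in% vocab]
    if (!length(q)) return(numeric(N))
    scores <- numeric(N)
    # repeated query terms count once per occurrence, as in Okapi
    for (t in unique(q)) {
      j <- match(t, vocab)
      tf <- TF[, j]
      denom <- tf + k1 * (1 - b + b * dl / avgdl)
      scores <- scores + sum(q == t) * idf[j] * tf * (k1 + 1) / denom
    }
    scores
  }, numeric(N)))
  Z <- score_matrix(vapply(caption_sets, `[[`, character(1), "image_id"),
                    corpus_class_ids(corp), z)
  rank_documents(Z, method = "bm25")
}

#' Rank documents by mean embedding cosine similarity
#'
#' Document score = mean over all (caption, sentence) pairs of the cosine
#' similarity of their embeddings; a zero-norm embedding contributes
#' similarity 0 with a warning.
#'
#' @inheritParams tfidf_rank
#' @param spec an [encoder_spec()]; or pass `cache` with precomputed
#'   embeddings.
#' @param cache optional embedding cache(s).
#' @return a `ranking`.
#' @export
cosine_embedding_rank <- function(caption_sets, corp, spec = encoder_spec(),
                                  cache = NULL) {
  if (inherits(caption_sets, "caption_set")) caption_sets <- list(caption_sets)
  cap_counts <- vapply(caption_sets, function(x) length(x$captions), integer(1))
  doc_counts <- vapply(corp$documents, function(d) length(d$sentences),
                       integer(1))
  Ea <- .resolve_embeddings(unlist(lapply(caption_sets, `[[`, "captions")),
                            cache, spec)
  Eb <- .resolve_embeddings(unlist(lapply(corp$documents, `[[`, "sentences")),
                            cache, spec)
  norm_rows <- function(M) {
    n <- sqrt(rowSums(M * M))
    if (any(n == 0)) warning("zero-norm embedding; cosine taken as 0")
    n[n == 0] <- Inf
    M / n
  }
  CS <- norm_rows(Ea) %*% t(norm_rows(Eb))
  gi <- rep(seq_along(caption_sets), cap_counts)
  gj <- rep(seq_along(corp$documents), doc_counts)
  z <- t(rowsum(t(rowsum(CS, gi)), gj)) / outer(cap_counts, doc_counts)
  Z <- score_matrix(vapply(caption_sets, `[[`, character(1), "image_id"),
                    corpus_class_ids(corp), z)
  rank_documents(Z, method = "cosine")
}
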