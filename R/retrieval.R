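# Aggregating pair scores into document scores, posteriors and rankings.
# The document score z[i, j] is the mean comparator score over all caption x
# sentence pairs between image i's caption set and document j; the class of
# the top-ranked document labels the image.

#' Score one document against one caption set
#'
#' `z = mean over all (caption, sentence) pairs of f(caption, sentence)`,
#' the caption always the first argument.
#'
#' @param cs a [caption_set()].
#' @param doc a [document()].
#' @param model a trained `comparator`.
#' @param cache embedding cache(s); `spec` used for misses.
#' @param spec optional [encoder_spec()].
#' @return numeric scalar.
#' @export
score_document <- function(cs, doc, model, cache = NULL, spec = NULL) {
  if (!length(cs$captions)) stop_sm("empty caption set")
  if (!length(doc$sentences)) stop_sm("empty document")
  Ea <- .resolve_embeddings(cs$captions, cache, spec)
  Eb <- .resolve_embeddings(doc$sentences, cache, spec)
  mean(comparator_score_matrix(model, Ea, Eb))
}

#' Score a whole corpus against caption sets
#'
#' @param caption_sets list of [caption_set()].
#' @param corp a [corpus()].
#' @inheritParams score_document
#' @return an object of class `score_matrix`: fields `image_ids`,
#'   `class_ids`, and `z` (images x documents).
#' @export
score_corpus <- function(caption_sets, corp, model, cache = NULL,
                         spec = NULL) {
  image_ids <- vapply(caption_sets, `[[`, character(1), "image_id")
  class_ids <- corpus_class_ids(corp)
  cap_counts <- vapply(caption_sets, function(x) length(x$captions), integer(1))
  if (any(cap_counts == 0L)) stop_sm("empty caption set")
  doc_counts <- vapply(corp$documents, function(d) length(d$sentences), integer(1))
  Ea <- .resolve_embeddings(unlist(lapply(caption_sets, `[[`, "captions")),
                            cache, spec)
  Eb <- .resolve_embeddings(unlist(lapply(corp$documents, `[[`, "sentences")),
                            cache, spec)
  FS <- comparator_score_matrix(model, Ea, Eb)
  gi <- rep(seq_along(caption_sets), cap_counts)
  gj <- rep(seq_along(corp$documents), doc_counts)
  Z <- t(rowsum(t(rowsum(FS, gi)), gj)) / outer(cap_counts, doc_counts)
  score_matrix(image_ids, class_ids, Z)
}

#' Construct a score matrix
#'
#' @param image_ids,class_ids axis labels.
#' @param z numeric matrix, images x documents, finite.
#' @return an object of class `score_matrix`.
#' @export
score_matrix <- function(image_ids, class_ids, z) {
  z <- as.matrix(z)
  if (nrow(z) != length(image_ids) || ncol(z) != length(class_ids))
    stop_sm("score matrix shape mismatch")
  if (any(!is.finite(z))) stop_sm("score matrix has non-finite entries")
  dimnames(z) <- list(image_ids, class_ids)
  structure(list(image_ids = as.character(image_ids),
                 class_ids = as.character(class_ids), z = z),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix: %d images x %d documents>\n",
              length(x$image_ids), length(x$class_ids)))
  invisible(x)
}

#' Per-image document posteriors
#'
#' Row-wise softmax of the document scores: `p(D_j | x_i) = exp(z_ij) /
#' sum_k exp(z_ik)`. Adding a constant to a row of z leaves its posterior
#' unchanged. `sign = "literal"` instead applies the softmax to `-z`
#' (an audit option preserving the alternative sign convention, under which
#' the highest-scoring document would get the *lowest* posterior).
#'
#' @param Z a [score_matrix()].
#' @param sign `"positive"` (default) or `"literal"`.
#' @return an object of class `prob_matrix` with rows summing to 1.
#' @export
document_posteriors <- function(Z, sign = c("positive", "literal")) {
  sign <- match.arg(sign)
  z <- if (sign == "positive") Z$z else -Z$z
  P <- .softmax_rows(z)
  structure(list(image_ids = Z$image_ids, class_ids = Z$class_ids, p = P),
            class = "prob_matrix")
}

#' @export
print.prob_matrix <- function(x, ...) {
  cat(sprintf("<prob_matrix: %d images x %d documents>\n",
              length(x$image_ids), length(x$class_ids)))
  invisible(x)
}

#' Batch-level score-distribution regularizer
#'
#' For per-image posterior rows `p_x` over the corpus,
#' `R = sum_x ( -<p_x, p_x> + sum_{x' != x} <p_x, p_{x'}> )`.
#' The first term rewards concentrating each image's posterior on a single
#' document; the second pushes different images' posteriors towards
#' orthogonality, spreading images uniformly across documents. Closed
#' forms: all-uniform rows give `B(B-2)/K`; one-hot rows on distinct
#' documents give `-B`.
#'
#' @param P a `prob_matrix` (or a plain numeric matrix of rows summing
#'   to 1) for a batch of B images.
#' @return numeric scalar.
#' @export
regularizer <- function(P) {
  M <- if (inherits(P, "prob_matrix")) P$p else as.matrix(P)
  if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-9))
    stop_sm("regularizer: rows must be probability distributions")
  S <- colSums(M)
  sum(S * S) - 2 * sum(M * M)
}

#' Rank documents for every image
#'
#' Descending score, ties broken by ascending class id (stable).
#'
#' @param Z a [score_matrix()] (from the comparator or any baseline).
#' @param method label recorded on the ranking (e.g. "fgsm", "tfidf").
#' @return an object of class `ranking`: `ord[i, ]` lists class indices
#'   best-first, `ranks[i, j]` is the 1-based rank of class j for image i.
#' @export
rank_documents <- function(Z, method = "fgsm") {
  n <- length(Z$image_ids); K <- length(Z$class_ids)
  ord <- matrix(0L, n, K)
  ranks <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    o <- order(-Z$z[i, ], Z$class_ids, method = "radix")
    ord[i, ] <- o
    ranks[i, o] <- seq_len(K)
  }
  dimnames(ranks) <- list(Z$image_ids, Z$class_ids)
  structure(list(image_ids = Z$image_ids, class_ids = Z$class_ids,
                 ord = ord, ranks = ranks, z = Z$z, method = method),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking (%s): %d images over %d classes>\n", x$method,
              length(x$image_ids), length(x$class_ids)))
  invisible(x)
}

#' 1-based rank of a class for an image
#'
#' @param ranking a [rank_documents()] result.
#' @param image_id,class_id identifiers.
#' @return integer rank (1 = best).
#' @export
rank_of <- function(ranking, image_id, class_id) {
  i <- match(image_id, ranking$image_ids)
  j <- match(class_id, ranking$class_ids)
  if (is.na(i)) stop_sm("unknown image_id: ", image_id)
  if (is.na(j)) stop_sm("unknown class_id: ", class_id)
  ranking$ranks[i, j]
}

#' Top class per image
#'
#' @param ranking a [rank_documents()] result.
#' @return named character vector image_id -> predicted class_id.
#' @export
top_class <- function(ranking) {
  out <- ranking$class_ids[ranking$ord[, 1L]]
  names(out) <- ranking$image_ids
  out
}

#' Export a ranking as a long-format data.frame (image, rank, class, z)
#'
#' @param ranking a [rank_documents()] result.
#' @param top keep only the best `top` ranks per image (default all).
#' @return data.frame with columns `image_id`, `rank`, `class_id`, `z`.
#' @export
ranking_table <- function(ranking, top = ncol(ranking$ord)) {
  K <- ncol(ranking$ord)
  top <- min(top, K)
  do.call(rbind, lapply(seq_along(ranking$image_ids), function(i) {
    sel <- ranking$ord[i, seq_len(top)]
    data.frame(image_id = ranking$image_ids[i], rank = seq_len(top),
               class_id = ranking$class_ids[sel], z = ranking$z[i, sel],
               row.names = NULL)
  }))
}

#' Write / read score and probability matrices as TSV
#'
#' Rows are image ids, columns class ids.
#'
#' @param x a `score_matrix` or `prob_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  M <- if (inherits(x, "prob_matrix")) x$p else x$z
  utils::write.table(cbind(image_id = rownames(M), as.data.frame(M)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
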