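# Synthesizing labelled sentence pairs for comparator training. No expert
# labels are used anywhere: positives are two descriptions of the same
# image, negatives pair descriptions of different images (almost surely
# different classes at fine granularity), and neutrals pair a caption with a
# sentence -- from the corpus or from another image's captions -- sharing no
# nouns with it.

PAIR_LABELS <- c("negative", "neutral", "positive")

new_pairs <- function(a, b, label, source) {
  data.frame(a = a, b = b, label = label, source = source,
             stringsAsFactors = FALSE)
}

#' Positive pairs: two captions of the same image
#'
#' For each image, every unordered pair of distinct captions becomes one
#' positive example (C(n,2) per image, emitted in canonical caption order).
#' Identical duplicate caption strings within an image are collapsed first.
#' With `both_orders = TRUE` each pair is additionally emitted swapped, as
#' an augmentation for the order-sensitive comparator input.
#'
#' @param caption_sets list of [caption_set()].
#' @param both_orders emit both orders of each unordered pair?
#' @return data.frame of pairs with columns `a`, `b`, `label`, `source`.
#' @export
make_positive_pairs <- function(caption_sets, both_orders = FALSE) {
  out <- lapply(caption_sets, function(cs) {
    caps <- unique(cs$captions)
    n <- length(caps)
    if (n < 2L) return(NULL)
    idx <- utils::combn(n, 2L)
    new_pairs(caps[idx[1L, ]], caps[idx[2L, ]], "positive", "cap-cap")
  })
  if (all(vapply(out, is.null, logical(1))))
    warning("no image has >= 2 distinct captions; 0 positive pairs")
  out <- do.call(rbind, out) %||% new_pairs(character(0), character(0),
                                            character(0), character(0))
  if (both_orders && nrow(out))
    out <- rbind(out, new_pairs(out$b, out$a, out$label, out$source))
  rownames(out) <- NULL
  out
}

#' Negative pairs: captions of two different images
#'
#' For every caption, `n_per_caption` partners are sampled uniformly (with
#' replacement) from the complement -- the captions of all other images.
#' Class identity is deliberately ignored: no filtering rules beyond
#' "different image" are applied.
#'
#' @inheritParams make_positive_pairs
#' @param n_per_caption partners sampled per caption.
#' @param seed integer seed; the sample is reproducible from it.
#' @return data.frame of pairs.
#' @export
make_negative_pairs <- function(caption_sets, n_per_caption = 1L, seed = 0L) {
  if (length(caption_sets) < 2L)
    stop_sm("negative pairs need >= 2 images (no complement)")
  caps <- unlist(lapply(caption_sets, `[[`, "captions"))
  owner <- rep(vapply(caption_sets, `[[`, character(1), "image_id"),
               vapply(caption_sets, function(x) length(x$captions), integer(1)))
  with_seed(seed, {
    a <- rep(caps, each = n_per_caption)
    a_owner <- rep(owner, each = n_per_caption)
    b <- character(length(a))
    for (i in seq_along(a)) {
      pool <- which(owner != a_owner[i])
      b[i] <- caps[pool[sample.int(length(pool), 1L)]]
    }
    new_pairs(a, b, "negative", "cap-cap")
  })
}

#' Neutral pairs: no nouns in common
#'
#' Each neutral pairs a caption with either (pool 1) a caption of a
#' different image or (pool 2) a corpus sentence, subject to the two texts
#' sharing no nouns (see [neutral_eligible()]). The pool is chosen by a fair
#' coin per pair when both pools are available; candidates violating the
#' predicate are rejected and redrawn, up to `max_attempts` total draws.
#'
#' @inheritParams make_negative_pairs
#' @param corp optional [corpus()] supplying the document pool.
#' @param n number of neutral pairs to mine.
#' @param tagger optional noun tagger (see [extract_nouns()]).
#' @param max_attempts rejection-sampling budget (default `100 * n`).
#' @return data.frame of pairs; `source` records the pool used.
#' @export
make_neutral_pairs <- function(caption_sets, corp = NULL, n, seed = 0L,
                               tagger = NULL, max_attempts = 100L * n) {
  tagger <- tagger %||% default_noun_tagger()
  caps <- unlist(lapply(caption_sets, `[[`, "captions"))
  owner <- rep(seq_along(caption_sets),
               vapply(caption_sets, function(x) length(x$captions), integer(1)))
  doc_sents <- if (is.null(corp)) character(0)
               else unlist(lapply(corp$documents, `[[`, "sentences"))
  has_cap_pool <- length(caption_sets) >= 2L
  has_doc_pool <- length(doc_sents) > 0L
  if (!has_cap_pool && !has_doc_pool)
    stop_sm("no pool available for neutral pairs")
  if (!has_cap_pool || !has_doc_pool)
    message("make_neutral_pairs: only one pool available; sampling from it")
  noun_memo <- new.env(parent = emptyenv())
  nouns_of <- function(txt) {
    key <- text_digest(txt)
    hit <- noun_memo[[key]]
    if (is.null(hit)) {
      hit <- tagger(txt)
      assign(key, hit, envir = noun_memo)
    }
    hit
  }
  with_seed(seed, {
    a <- b <- src <- character(n)
    got <- 0L
    attempts <- 0L
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_sm("no neutral-eligible pair found within max_attempts = ",
                max_attempts, " (", got, "/", n, " mined)")
      use_doc <- if (has_cap_pool && has_doc_pool) stats::runif(1) < 0.5
                 else has_doc_pool
      ai <- sample.int(length(caps), 1L)
      if (use_doc) {
        cand <- doc_sents[sample.int(length(doc_sents), 1L)]
        source <- "cap-doc"
      } else {
        pool <- which(owner != owner[ai])
        cand <- caps[pool[sample.int(length(pool), 1L)]]
        source <- "cap-cap"
      }
      if (length(intersect(nouns_of(caps[ai]), nouns_of(cand))) == 0L) {
        got <- got + 1L
        a[got] <- caps[ai]; b[got] <- cand; src[got] <- source
      }
    }
    new_pairs(a, b, "neutral", src)
  })
}

#' Build a balanced, shuffled pair dataset
#'
#' Assembles `size_per_label` pairs per label (2-class: positive/negative;
#' 3-class adds neutral), shuffles them reproducibly and attaches a manifest
#' (seed, counts, mode) so a run is self-describing.
#'
#' @inheritParams make_neutral_pairs
#' @param mode `"2-class"` or `"3-class"` (neutrals require a corpus or a
#'   multi-image caption pool).
#' @param size_per_label pairs per label.
#' @param both_orders augment positives with both argument orders (the
#'   comparator input is order-sensitive)?
#' @return an object of class `pair_dataset`: the pair data.frame plus
#'   attributes `seed`, `label_counts`, `manifest`.
#' @export
build_pair_dataset <- function(caption_sets, corp = NULL,
                               mode = c("2-class", "3-class"),
                               size_per_label = 100L, seed = 0L,
                               tagger = NULL, both_orders = FALSE) {
  mode <- match.arg(mode)
  pos <- make_positive_pairs(caption_sets, both_orders = both_orders)
  if (nrow(pos) < size_per_label)
    stop_sm("size_per_label = ", size_per_label, " exceeds available ",
            "positives; attainable maximum is ", nrow(pos))
  neg <- make_negative_pairs(
    caption_sets,
    n_per_caption = max(1L, ceiling(size_per_label /
      length(unlist(lapply(caption_sets, `[[`, "captions"))))),
    seed = seed + 1L
  )
  parts <- with_seed(seed + 2L, list(
    pos[sample.int(nrow(pos), size_per_label), ],
    neg[sample.int(nrow(neg), size_per_label), ]
  ))
  if (mode == "3-class") {
    neu <- make_neutral_pairs(caption_sets, corp, n = size_per_label,
                              seed = seed + 3L, tagger = tagger)
    parts <- c(parts, list(neu))
  }
  pairs <- do.call(rbind, parts)
  pairs <- with_seed(seed, pairs[sample.int(nrow(pairs)), ])
  rownames(pairs) <- NULL
  counts <- table(factor(pairs$label, levels = PAIR_LABELS))
  counts <- counts[counts > 0L]
  structure(pairs,
            class = c("pair_dataset", "data.frame"),
            seed = as.integer(seed),
            label_counts = counts,
            manifest = list(seed = as.integer(seed), mode = mode,
                            size_per_label = as.integer(size_per_label),
                            counts = as.list(counts),
                            generator = "sentmatch pair_synthesis v1"))
}

#' @export
print.pair_dataset <- function(x, ...) {
  cts <- attr(x, "label_counts")
  cat(sprintf("<pair_dataset: %d pairs (%s), seed=%d>\n", nrow(x),
              paste(names(cts), as.integer(cts), sep = "=", collapse = ", "),
              attr(x, "seed")))
  invisible(x)
}

#' Serialize / reload a pair dataset (JSONL + manifest JSON)
#'
#' @param pairs a [build_pair_dataset()] result (or plain pair data.frame).
#' @param path output JSONL path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
save_pair_dataset <- function(pairs, path) {
  lines <- vapply(seq_len(nrow(pairs)), function(i) {
    jsonlite::toJSON(list(a = pairs$a[i], b = pairs$b[i],
                          label = pairs$label[i], source = pairs$source[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  manifest <- attr(pairs, "manifest")
  if (!is.null(manifest))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               paste0(path, ".manifest.json"), useBytes = TRUE)
  invisible(path)
}

#' @rdname save_pair_dataset
#' @export
load_pair_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- new_pairs(vapply(recs, `[[`, character(1), "a"),
                   vapply(recs, `[[`, character(1), "b"),
                   vapply(recs, `[[`, character(1), "label"),
                   vapply(recs, `[[`, character(1), "source"))
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath)) {
    manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
    attr(out, "manifest") <- manifest
    attr(out, "seed") <- manifest$seed
    class(out) <- c("pair_dataset", "data.frame")
  }
  out
}
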