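# Attribute parsing used as an independent oracle: pull (color, part)
# mentions out of generated text by plain token matching, undoing the
# injective jargon lexicon when asked.
parse_mentions <- function(sentences, config, translate_jargon = FALSE) {
  jp <- sentmatch:::.part_jargon; jc <- sentmatch:::.color_jargon
  out <- character(0)
  for (s in sentences) {
    tk <- sentmatch:::tokenize_words(s)
    if (translate_jargon) {
      tk[tk %in% jp] <- names(jp)[match(tk[tk %in% jp], jp)]
      tk[tk %in% jc] <- names(jc)[match(tk[tk %in% jc], jc)]
    }
    tk <- sub("s$", "", tk)
    cols <- which(tk %in% config$colors)
    for (ci in cols) {
      nxt <- tk[-seq_len(ci)]
      part <- nxt[nxt %in% config$parts][1]
      prev <- rev(tk[seq_len(ci - 1L)])
      if (is.na(part)) part <- prev[prev %in% config$parts][1]
      if (!is.na(part)) out <- c(out, paste(tk[ci], part))
    }
  }
  out
}

separable_config <- function(...) {
  synth_config(attribute_dropout = 0, color_confusion = list(),
               jargon_rate = 0, ...)
}

test_that("species signatures are distinct, exhaustive at the bound, and seeded", {
  cfg <- synth_config(K = 4L, parts = c("wing", "tail"),
                      colors = c("red", "blue"), seed = 2L)
  sp <- generate_species(cfg)
  sigs <- vapply(sp, function(s) paste(s$signature, collapse = "-"),
                 character(1))
  expect_length(unique(sigs), 4L)   # all 2^2 signatures, each once
  expect_error(synth_config(K = 5L, parts = c("wing", "tail"),
                            colors = c("red", "blue")),
               "distinct signatures")
  expect_identical(generate_species(cfg), sp)
  expect_length(unique(vapply(sp, `[[`, character(1), "name")), 4L)
})

test_that("noise-free captions are signature-consistent", {
  cfg <- separable_config(K = 6L, seed = 9L)
  sp <- generate_species(cfg)
  sets <- generate_captions(sp, cfg)
  sig_of <- stats::setNames(lapply(sp, `[[`, "signature"),
                            vapply(sp, `[[`, character(1), "class_id"))
  for (cs in sets) {
    sig <- sig_of[[cs$true_class_id]]
    men <- parse_mentions(cs$captions, cfg)
    expect_gt(length(men), 0L)
    expect_true(all(men %in% paste(sig, names(sig))))
  }
})

test_that("a certain color confusion removes the color entirely", {
  cfg <- synth_config(K = 4L, attribute_dropout = 0, jargon_rate = 0,
                      color_confusion = list(blue = c(black = 1)), seed = 3L)
  sets <- generate_captions(generate_species(cfg), cfg)
  expect_false(any(grepl("\\bblue\\b",
                         unlist(lapply(sets, `[[`, "captions")))))
})

test_that("the observed confusion rate matches the configured probability", {
  cfg <- synth_config(K = 2L, parts = c("wing", "tail"),
                      colors = c("blue", "red"),
                      images_per_species = 40L, captions_per_image = 10L,
                      parts_per_caption = 2L, attribute_dropout = 0,
                      jargon_rate = 0,
                      color_confusion = list(blue = c(black = 0.3)),
                      seed = 4L)
  sets <- generate_captions(generate_species(cfg), cfg)
  # "black" is not in the palette, so every "black" token is a swapped
  # "blue"; the swap rate is black / (black + blue)
  toks <- unlist(lapply(unlist(lapply(sets, `[[`, "captions")),
                        sentmatch:::tokenize_words))
  n_black <- sum(toks == "black"); n_blue <- sum(toks == "blue")
  n_slots <- n_black + n_blue
  expect_gt(n_slots, 300L)
  rate <- n_black / n_slots
  se <- sqrt(0.3 * 0.7 / n_slots)
  expect_lt(abs(rate - 0.3), 4 * se)
})

test_that("documents mix filler and visual sentences as configured", {
  cfg <- synth_config(K = 3L, filler_fraction = 0.5, doc_sentences = 10L,
                      seed = 6L)
  corp <- generate_documents(generate_species(cfg), cfg)
  for (d in corp$documents) {
    expect_length(d$sentences, 10L)
    expect_equal(sum(d$section_labels == "filler"), 5L)
    expect_equal(sum(d$section_labels == "visual"), 5L)
  }
})

test_that("with no jargon, document visual sentences share caption vocabulary", {
  cfg <- separable_config(K = 4L, seed = 8L)
  sp <- generate_species(cfg)
  corp <- generate_documents(sp, cfg)
  for (i in seq_along(sp)) {
    d <- corp$documents[[i]]
    men <- parse_mentions(d$sentences[d$section_labels == "visual"], cfg)
    expect_true(all(men %in% paste(sp[[i]]$signature,
                                   names(sp[[i]]$signature))))
    expect_setequal(unique(men), paste(sp[[i]]$signature,
                                       names(sp[[i]]$signature)))
  }
})

test_that("masking removes every species name from the corpus", {
  world <- generate_benchmark(synth_config(K = 8L, seed = 10L))
  for (i in seq_along(world$species)) {
    nm <- world$species[[i]]$name
    txt <- unlist(lapply(world$corpus$documents, `[[`, "sentences"))
    expect_false(any(grepl(nm, txt, ignore.case = TRUE)))
  }
  # unmasked corpora do contain the names
  raw <- generate_benchmark(synth_config(K = 8L, seed = 10L), mask = FALSE)
  own <- vapply(seq_along(raw$species), function(i)
    any(grepl(raw$species[[i]]$name,
              raw$corpus$documents[[i]]$sentences, fixed = TRUE)),
    logical(1))
  expect_true(all(own))
})

test_that("benchmark worlds are sized and keyed consistently", {
  world <- generate_benchmark(synth_config(K = 10L, images_per_species = 5L,
                                           seed = 12L))
  expect_length(world$caption_sets, 50L)
  expect_length(world$corpus, 10L)
  expect_length(world$truth, 50L)
  expect_setequal(unique(world$truth), corpus_class_ids(world$corpus))
})

test_that("worlds serialize byte-identically from the same seed", {
  cfg <- synth_config(K = 5L, seed = 33L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_benchmark(generate_benchmark(cfg), d1)
  save_benchmark(generate_benchmark(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  # and the reloaded world equals the in-memory one
  back <- load_captions(file.path(d1, "captions.jsonl"))
  expect_identical(back, generate_benchmark(cfg)$caption_sets)
})

test_that("separable worlds are identifiable and solved by attribute overlap", {
  cfg <- separable_config(K = 10L, images_per_species = 3L, seed = 21L)
  world <- generate_benchmark(cfg)
  sig_of <- stats::setNames(
    lapply(world$species, function(s) paste(s$signature, names(s$signature))),
    vapply(world$species, `[[`, character(1), "class_id"))
  # injectivity: attribute multisets identify the species
  keys <- vapply(world$caption_sets, function(cs)
    paste(sort(unique(parse_mentions(cs$captions, cfg))), collapse = "|"),
    character(1))
  split_cls <- split(world$truth, keys)
  expect_true(all(vapply(split_cls, function(v) length(unique(v)) == 1L,
                         logical(1))))
  # brute-force overlap scorer labels every image correctly
  ok <- vapply(world$caption_sets, function(cs) {
    men <- unique(parse_mentions(cs$captions, cfg))
    scores <- vapply(world$corpus$documents, function(d)
      length(intersect(men,
                       unique(parse_mentions(d$sentences, cfg,
                                             translate_jargon = TRUE)))),
      numeric(1))
    corpus_class_ids(world$corpus)[which.max(scores)] ==
      world$truth[[cs$image_id]]
  }, logical(1))
  expect_equal(mean(ok), 1)
})

test_that("filler sentences are neutral-eligible against every caption", {
  world <- generate_benchmark(synth_config(K = 5L, seed = 14L))
  caps <- unlist(lapply(world$caption_sets, `[[`, "captions"))
  cap_nouns <- unique(unlist(lapply(caps, extract_nouns)))
  for (d in world$corpus$documents) {
    fillers <- d$sentences[d$section_labels == "filler"]
    for (f in fillers)
      expect_length(intersect(extract_nouns(f), cap_nouns), 0L)
  }
})

test_that("retrieval degrades monotonically as attribute dropout grows", {
  top1_at <- function(dropout) {
    cfg <- synth_config(K = 8L, images_per_species = 3L,
                        attribute_dropout = dropout,
                        color_confusion = list(), jargon_rate = 0.1,
                        seed = 55L)
    w <- generate_benchmark(cfg)
    spec <- fast_spec(256L)
    cap_cache <- precompute_cache(w$caption_sets, spec)
    doc_cache <- precompute_cache(w$corpus, spec)
    pd <- build_pair_dataset(w$caption_sets, mode = "2-class",
                             size_per_label = 200L, seed = 56L,
                             both_orders = TRUE)
    m <- train_stage1(pd, spec, fast_stage1_config(epochs = 10L, seed = 57L),
                      cache = cap_cache)
    r <- rank_documents(score_corpus(w$caption_sets, w$corpus, m,
                                     cache = list(cap_cache, doc_cache)))
    unname(evaluate_ranking(r, w$truth)$topk["top1"])
  }
  accs <- vapply(c(0, 0.2, 0.4), top1_at, numeric(1))
  expect_true(all(diff(accs) <= 0))
})
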