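# The standard desk-scale benchmark study: full two-stage pipeline plus
# ablation arms and baselines on independently seeded synthetic worlds.
# Both the acceptance script and the acceptance tests run this one
# function, so the numbers they report come from the same computation.

#' Run the standard synthetic benchmark study
#'
#' For each seed: generate a K-species attribute world, train the stage-1
#' binary comparator and the stage-2 3-class + regularizer comparator on a
#' frozen hash encoder, and evaluate retrieval. With `arms = TRUE` the
#' ablation arms (stage-2 with `lambda = 0`; stage-2 on positive/negative
#' pairs only, i.e. without the neutral class) and the TF-IDF, BM25 and
#' embedding-cosine baselines are evaluated as well.
#'
#' Default problem sizes (dim-512 embeddings, 700 pairs per label, 20
#' epochs per stage, learning rate 1e-3) are the package's standard
#' desk-scale schedule; see the methods vignette for the rationale.
#'
#' @param seeds integer vector; one world + training run per seed.
#' @param K species count per world.
#' @param dim hash-encoder dimensionality.
#' @param size_per_label training pairs per label.
#' @param epochs epochs per training stage.
#' @param lr Adam learning rate for both stages.
#' @param lambda regularizer weight for the main stage-2 arm.
#' @param arms also run ablation arms and baselines?
#' @param config a [synth_config()] template; its seed is replaced by each
#'   study seed in turn.
#' @return named list (one entry per seed) of lists of `eval_report`
#'   objects: `stage1`, `stage2`, and with `arms = TRUE` also
#'   `stage2_lam0`, `stage2_2cls`, `tfidf`, `bm25`, `cosine`; each entry
#'   also carries `n_images` and `K`.
#' @export
run_pipeline_study <- function(seeds = c(101L, 102L, 103L), K = 20L,
                               dim = 512L, size_per_label = 700L,
                               epochs = 20L, lr = 1e-3, lambda = 10,
                               arms = TRUE, config = synth_config(K = K)) {
  out <- lapply(as.integer(seeds), function(seed) {
    config$K <- as.integer(K)
    config$seed <- seed
    w <- generate_benchmark(config)
    spec <- encoder_spec(dim = dim)
    cap_cache <- precompute_cache(w$caption_sets, spec)
    doc_cache <- precompute_cache(w$corpus, spec)
    caches <- list(cap_cache, doc_cache)
    ev <- function(m) {
      r <- rank_documents(score_corpus(w$caption_sets, w$corpus, m,
                                       cache = caches))
      evaluate_ranking(r, w$truth)
    }
    pd2 <- build_pair_dataset(w$caption_sets, mode = "2-class",
                              size_per_label = size_per_label,
                              seed = seed + 1000L, both_orders = TRUE)
    m1 <- train_stage1(pd2, spec,
                       comparator_config(stage = 1L, lr = lr,
                                         epochs = epochs, seed = seed + 1L),
                       cache = cap_cache)
    pd3 <- build_pair_dataset(w$caption_sets, w$corpus, mode = "3-class",
                              size_per_label = size_per_label,
                              seed = seed + 1000L, both_orders = TRUE)
    cfg2 <- function(lam) comparator_config(stage = 2L, lr = lr,
                                            epochs = epochs,
                                            seed = seed + 2L,
                                            lambda_reg = lam)
    m2 <- train_stage2(pd3, w$caption_sets, w$corpus, cfg2(lambda),
                       cap_cache, doc_cache)
    res <- list(stage1 = ev(m1), stage2 = ev(m2),
                n_images = length(w$caption_sets), K = length(w$corpus))
    if (arms) {
      m0 <- train_stage2(pd3, w$caption_sets, w$corpus, cfg2(0),
                         cap_cache, doc_cache)
      pdc <- pd3[pd3$label != "neutral", ]
      mc <- train_stage2(pdc, w$caption_sets, w$corpus, cfg2(lambda),
                         cap_cache, doc_cache)
      res$stage2_lam0 <- ev(m0)
      res$stage2_2cls <- ev(mc)
      res$tfidf <- evaluate_ranking(
        suppressWarnings(tfidf_rank(w$caption_sets, w$corpus)), w$truth)
      res$bm25 <- evaluate_ranking(bm25_rank(w$caption_sets, w$corpus),
                                   w$truth)
      res$cosine <- evaluate_ranking(
        cosine_embedding_rank(w$caption_sets, w$corpus, spec), w$truth)
    }
    res
  })
  names(out) <- paste0("seed", seeds)
  out
}

#' Summarize a study as a metric table
#'
#' @param study a [run_pipeline_study()] result.
#' @return data.frame with one row per (seed, method): top1, top5,
#'   mean_rank.
#' @export
study_table <- function(study) {
  do.call(rbind, lapply(names(study), function(s) {
    arms <- setdiff(names(study[[s]]), c("n_images", "K"))
    do.call(rbind, lapply(arms, function(a) {
      e <- study[[s]][[a]]
      data.frame(seed = s, method = a, top1 = unname(e$topk["top1"]),
                 top5 = unname(e$topk["top5"]), mean_rank = e$mean_rank)
    }))
  }))
}
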