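test_that("configurations enforce the stage/head pairing and defaults", {
  c1 <- comparator_config(stage = 1)
  expect_equal(c1$phi_dims, c(256L, 64L))
  expect_equal(c1$head_classes, 2L)
  expect_equal(c1$lr, 1e-5)
  c2 <- comparator_config(stage = 2)
  expect_equal(c2$phi_dims, c(256L, 64L, 32L))
  expect_equal(c2$head_classes, 3L)
  expect_equal(c2$lambda_reg, 10)
  expect_error(comparator_config(stage = 1, head_classes = 3), "2-class")
  expect_error(comparator_config(stage = 2, head_classes = 2), "3-class")
})

test_that("projection dimensions follow the stage architecture", {
  for (stage in 1:2) {
    cfg <- comparator_config(stage = stage)
    model <- withr::with_seed(1, sentmatch:::init_comparator(512L, cfg))
    out <- project(matrix(stats::rnorm(512), 1), model)
    expect_equal(ncol(out), if (stage == 1) 64L else 32L)
    expect_true(all(is.finite(out)))
  }
  cfg <- comparator_config(stage = 1, phi_dims = c(8L, 4L))
  model <- withr::with_seed(1, sentmatch:::init_comparator(16L, cfg))
  # zero weights map zero input to zero
  for (l in seq_along(model$phi)) {
    model$phi[[l]]$W[] <- 0; model$phi[[l]]$b[] <- 0
  }
  expect_equal(unname(project(rep(0, 16L), model)[1, ]), rep(0, 4L))
  expect_error(project(rep(0, 5L), model), "dim")
})

test_that("pair features are [p1; p2; |p1 - p2|]", {
  p <- c(0.3, -0.2, 0.5)
  expect_equal(compose_features(p, p), c(p, p, rep(0, 3)))
  withr::with_seed(2, {
    p1 <- matrix(stats::rnorm(2 * 64), 2)
    p2 <- matrix(stats::rnorm(2 * 64), 2)
  })
  U <- compose_features(p1, p2)
  expect_equal(ncol(U), 192L)
  expect_equal(U[, 129:192], abs(p1 - p2), ignore_attr = TRUE)
  # swap exchanges the first two blocks and fixes the third
  V <- compose_features(p2, p1)
  expect_equal(V[, 1:64], U[, 65:128], ignore_attr = TRUE)
  expect_equal(V[, 129:192], U[, 129:192], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(U, V)))
  expect_error(compose_features(p1, p2[, 1:10]), "shapes")
})

test_that("the scalar score is the positive-negative logit gap, shift-invariant", {
  expect_equal(score_from_logits(c(2, 2)), 0)
  expect_equal(score_from_logits(c(-1, 0, 1)), 2)
  expect_equal(score_from_logits(c(-1, 0, 1) + 5), 2)
  withr::with_seed(3, {
    L <- matrix(stats::rnorm(30), 10)
    expect_equal(score_from_logits(L + 7), score_from_logits(L))
  })
})

test_that("score_pair works from cache and fails cleanly on cache-only misses", {
  spec <- fast_spec(64L)
  cache <- precompute_cache(c("a blue wing", "a black tail"), spec)
  cfg <- comparator_config(stage = 1, phi_dims = c(16L, 8L))
  model <- withr::with_seed(4, sentmatch:::init_comparator(64L, cfg))
  s <- score_pair("a blue wing", "a black tail", model, cache = cache)
  expect_true(is.finite(s))
  expect_equal(s, score_pair("a blue wing", "a black tail", model,
                             spec = spec))
  expect_error(score_pair("a blue wing", "unseen text", model, cache = cache),
               "cache miss")
})

test_that("analytic gradients of the stage-2 objective match finite differences", {
  dim0 <- 12L
  cfg <- comparator_config(stage = 2, phi_dims = c(8L, 6L, 4L))
  model <- withr::with_seed(5, sentmatch:::init_comparator(dim0, cfg))
  withr::with_seed(6, {
    Ea <- matrix(stats::rnorm(4 * dim0), 4)
    Eb <- matrix(stats::rnorm(4 * dim0), 4)
    y <- c(1L, 2L, 3L, 1L)
    rb <- list(Ecap = matrix(stats::rnorm(5 * dim0), 5),
               cap_image = c(1L, 1L, 2L, 2L, 2L),
               Edoc = matrix(stats::rnorm(7 * dim0), 7),
               sent_doc = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
               n_img = 2L, n_doc = 3L)
  })
  res <- sentmatch:::.stage2_objective(model, Ea, Eb, y, rb, lambda = 10)
  flat <- function(g) c(unlist(lapply(g$phi, function(l) c(l$W, l$b))),
                        g$head$W, g$head$b)
  set_params <- function(m, vec) {
    i <- 1L
    for (l in seq_along(m$phi)) {
      nw <- length(m$phi[[l]]$W)
      m$phi[[l]]$W[] <- vec[i:(i + nw - 1L)]; i <- i + nw
      nb <- length(m$phi[[l]]$b)
      m$phi[[l]]$b[] <- vec[i:(i + nb - 1L)]; i <- i + nb
    }
    nw <- length(m$head$W); m$head$W[] <- vec[i:(i + nw - 1L)]; i <- i + nw
    m$head$b[] <- vec[i:(i + length(m$head$b) - 1L)]
    m
  }
  v0 <- flat(model); g_an <- flat(res$grads)
  h <- 1e-5
  idx <- withr::with_seed(7, sample(length(v0), 50L))
  g_num <- vapply(idx, function(j) {
    vp <- v0; vm <- v0; vp[j] <- vp[j] + h; vm[j] <- vm[j] - h
    (sentmatch:::.stage2_objective(set_params(model, vp), Ea, Eb, y, rb, 10,
                                   want_grads = FALSE)$value -
     sentmatch:::.stage2_objective(set_params(model, vm), Ea, Eb, y, rb, 10,
                                   want_grads = FALSE)$value) / (2 * h)
  }, numeric(1))
  rel <- abs(g_num - g_an[idx]) /
    pmax(1e-8, abs(g_num) + abs(g_an[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("with lambda = 0 the stage-2 objective is plain cross entropy", {
  dim0 <- 12L
  cfg <- comparator_config(stage = 2, phi_dims = c(8L, 4L, 4L))
  model <- withr::with_seed(8, sentmatch:::init_comparator(dim0, cfg))
  withr::with_seed(9, {
    Ea <- matrix(stats::rnorm(6 * dim0), 6)
    Eb <- matrix(stats::rnorm(6 * dim0), 6)
    y <- rep(1:3, 2)
    rb <- list(Ecap = matrix(stats::rnorm(3 * dim0), 3),
               cap_image = c(1L, 1L, 2L),
               Edoc = matrix(stats::rnorm(4 * dim0), 4),
               sent_doc = c(1L, 1L, 2L, 2L), n_img = 2L, n_doc = 2L)
  })
  full <- sentmatch:::.stage2_objective(model, Ea, Eb, y, rb, lambda = 0)
  ce <- sentmatch:::.ce_objective(model, Ea, Eb, y, want_grads = FALSE)
  # the stage-2 loss is the batch cross entropy (summed over pairs)
  expect_equal(full$value, nrow(Ea) * ce$value, tolerance = 1e-12)
  # and it equals the sum of independently computed per-pair losses
  per_pair <- vapply(seq_len(nrow(Ea)), function(i)
    sentmatch:::.ce_objective(model, Ea[i, , drop = FALSE],
                              Eb[i, , drop = FALSE], y[i],
                              want_grads = FALSE)$value, numeric(1))
  expect_equal(full$value, sum(per_pair), tolerance = 1e-12)
})

test_that("stage-1 training learns a separable planted-token world", {
  sets <- planted_world(n_images = 40L, captions_per_image = 5L, seed = 31L)
  spec <- fast_spec(512L)
  pd <- build_pair_dataset(sets, mode = "2-class",
                           size_per_label = 300L, seed = 32L)
  model <- train_stage1(pd, spec, fast_stage1_config(epochs = 25L, seed = 33L))
  expect_gte(utils::tail(model$report$accuracy, 1L), 0.95)
  # held-out pairs: freshly drawn pairs over the same caption pool, minus
  # anything seen in training
  pd_held <- build_pair_dataset(sets, mode = "2-class",
                                size_per_label = 150L, seed = 34L)
  seen <- paste(pd$a, pd$b, pd$label)
  pd_held <- pd_held[!paste(pd_held$a, pd_held$b, pd_held$label) %in% seen, ]
  expect_gt(nrow(pd_held), 50L)
  correct <- vapply(seq_len(nrow(pd_held)), function(i) {
    s <- score_pair(pd_held$a[i], pd_held$b[i], model, spec = spec)
    (s > 0) == (pd_held$label[i] == "positive")
  }, logical(1))
  expect_gte(mean(correct), 0.9)
})

test_that("label-shuffled training generalizes at chance (permutation control)", {
  sets <- planted_world(n_images = 60L, captions_per_image = 5L, seed = 41L)
  spec <- fast_spec(256L)
  pd <- build_pair_dataset(sets, mode = "2-class", size_per_label = 500L,
                           seed = 42L)
  pd$label <- withr::with_seed(43L, sample(pd$label))
  model <- train_stage1(pd, spec, fast_stage1_config(epochs = 10L, seed = 44L))
  # with labels destroyed there is nothing to learn: unseen shuffled pairs
  # are classified at chance, and the model fits far less of the training
  # noise than it fits real labels in the separable test above
  pd_held <- build_pair_dataset(sets, mode = "2-class", size_per_label = 300L,
                                seed = 45L)
  pd_held$label <- withr::with_seed(46L, sample(pd_held$label))
  pd_held <- pd_held[!paste(pd_held$a, pd_held$b) %in% paste(pd$a, pd$b), ]
  correct <- vapply(seq_len(nrow(pd_held)), function(i) {
    s <- score_pair(pd_held$a[i], pd_held$b[i], model, spec = spec)
    (s > 0) == (pd_held$label[i] == "positive")
  }, logical(1))
  se <- sqrt(0.25 / length(correct))
  expect_lt(abs(mean(correct) - 0.5), 3 * se + 0.02)
})

test_that("training is bit-reproducible from its seed", {
  sets <- planted_world(n_images = 20L, captions_per_image = 3L, seed = 51L)
  pd <- build_pair_dataset(sets, mode = "2-class", size_per_label = 50L,
                           seed = 52L)
  spec <- fast_spec(128L)
  m1 <- train_stage1(pd, spec, fast_stage1_config(epochs = 4L, seed = 53L))
  m2 <- train_stage1(pd, spec, fast_stage1_config(epochs = 4L, seed = 53L))
  expect_identical(m1$report, m2$report)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$head, m2$head)
})

test_that("stage-2 validates its inputs", {
  world <- generate_benchmark(synth_config(K = 4, seed = 61L))
  spec <- fast_spec(64L)
  cap_cache <- precompute_cache(world$caption_sets, spec)
  doc_cache <- precompute_cache(world$corpus, spec)
  pd <- build_pair_dataset(world$caption_sets, world$corpus, mode = "3-class",
                           size_per_label = 30L, seed = 62L)
  expect_error(train_stage2(pd, world$caption_sets, world$corpus,
                            fast_stage2_config()),
               "caches")
  expect_error(train_stage2(pd, world$caption_sets, world$corpus,
                            fast_stage2_config(lambda_reg = -1),
                            cap_cache, doc_cache),
               "lambda_reg")
  expect_error(train_stage1(pd, spec, fast_stage1_config()), "neutral")
})

test_that("stage-2 runs deterministically and reports its objective parts", {
  world <- generate_benchmark(synth_config(K = 4, images_per_species = 3L,
                                           seed = 63L))
  spec <- fast_spec(64L)
  cap_cache <- precompute_cache(world$caption_sets, spec)
  doc_cache <- precompute_cache(world$corpus, spec)
  pd <- build_pair_dataset(world$caption_sets, world$corpus, mode = "3-class",
                           size_per_label = 40L, seed = 64L)
  cfg <- comparator_config(stage = 2, phi_dims = c(32L, 16L, 8L), lr = 1e-3,
                           epochs = 3L, seed = 65L)
  m1 <- train_stage2(pd, world$caption_sets, world$corpus, cfg,
                     cap_cache, doc_cache)
  m2 <- train_stage2(pd, world$caption_sets, world$corpus, cfg,
                     cap_cache, doc_cache)
  expect_identical(m1$report, m2$report)
  expect_identical(m1$phi, m2$phi)
  expect_named(m1$report, c("epoch", "objective", "ce", "reg", "accuracy"))
})

test_that("the regularizer lowers per-image posterior entropy at convergence", {
  world <- generate_benchmark(synth_config(K = 10L, images_per_species = 3L,
                                           seed = 71L))
  spec <- fast_spec(256L)
  cap_cache <- precompute_cache(world$caption_sets, spec)
  doc_cache <- precompute_cache(world$corpus, spec)
  pd <- build_pair_dataset(world$caption_sets, world$corpus, mode = "3-class",
                           size_per_label = 250L, seed = 72L)
  entropy_of <- function(lambda_reg) {
    cfg <- comparator_config(stage = 2, phi_dims = c(64L, 32L, 16L),
                             lr = 1e-3, epochs = 15L, seed = 73L,
                             lambda_reg = lambda_reg)
    m <- train_stage2(pd, world$caption_sets, world$corpus, cfg,
                      cap_cache, doc_cache)
    P <- document_posteriors(score_corpus(world$caption_sets, world$corpus,
                                          m, cache = list(cap_cache,
                                                          doc_cache)))$p
    mean(-rowSums(P * log(pmax(P, 1e-12))))
  }
  expect_lt(entropy_of(10), entropy_of(0))
})

test_that("comparators round-trip through their checkpoint format", {
  cfg <- comparator_config(stage = 2, phi_dims = c(8L, 4L, 4L))
  model <- withr::with_seed(81L, sentmatch:::init_comparator(16L, cfg))
  model$report <- data.frame(epoch = 1L, objective = 0.5, ce = 0.4,
                             reg = 0.1, accuracy = 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  save_comparator(model, path)
  back <- load_comparator(path)
  expect_equal(back$phi, model$phi, tolerance = 1e-14)
  expect_equal(back$head, model$head, tolerance = 1e-14)
  expect_equal(back$config$phi_dims, model$config$phi_dims)
  withr::with_seed(82L, {
    E <- matrix(stats::rnorm(32L), 2L)
    expect_equal(project(E, back), project(E, model), tolerance = 1e-12)
  })
})
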