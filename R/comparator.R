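# The fine-grained sentence matching (FGSM) comparator. A Siamese model
# over frozen sentence embeddings: a shared projection MLP phi maps each
# embedding to a compact space, the pair feature is [phi1; phi2; |phi1 -
# phi2|], and a linear head h turns it into class logits (negative/positive,
# or negative/neutral/positive in stage 2). The scalar retrieval score of a
# pair is logit(positive) - logit(negative), which is invariant to shifting
# all logits and reduces to the binary logit difference in the 2-class case.
#
# Stage 1 trains phi and h on balanced positive/negative caption pairs with
# (2-logit softmax) cross entropy. Stage 2 re-initializes phi and h, adds
# the neutral class, and augments the loss with a batch-level regularizer on
# the per-image document posteriors (see regularizer()), computed against
# the full corpus. Both stages keep the encoder frozen, so all gradients
# here are hand-derived matrix algebra: phi/h are small enough that an
# explicit backward pass is simpler and more auditable than an autodiff
# dependency.

head_class_names <- function(C) {
  if (C == 2L) c("negative", "positive")
  else if (C == 3L) c("negative", "neutral", "positive")
  else stop_sm("head_classes must be 2 or 3")
}

#' Comparator configuration
#'
#' Defaults follow the reference architecture: stage 1 uses a two-layer
#' projection (256, 64) with tanh on hidden layers and a 2-class head;
#' stage 2 uses a three-layer projection (256, 64, 32), a 3-class head and
#' regularizer weight `lambda = 10`. The final projection layer is linear;
#' tanh is applied on hidden layers only.
#'
#' @param stage 1 or 2.
#' @param phi_dims integer vector of projection layer widths; default
#'   `c(256, 64)` (stage 1) or `c(256, 64, 32)` (stage 2).
#' @param head_classes 2 (stage 1) or 3 (stage 2); derived from `stage`.
#' @param lr Adam learning rate for phi and h (default `1e-5`).
#' @param lambda_reg regularizer weight (stage 2; default 10).
#' @param epochs,batch_size training schedule (pairs per minibatch).
#' @param images_per_batch images per regularizer batch (stage 2).
#' @param seed integer seed governing initialization and shuffling.
#' @return an object of class `comparator_config`.
#' @export
comparator_config <- function(stage = 1L, phi_dims = NULL, head_classes = NULL,
                              lr = 1e-5, lambda_reg = if (stage == 2L) 10 else 0,
                              epochs = 20L, batch_size = 32L,
                              images_per_batch = 8L, seed = 0L) {
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop_sm("stage must be 1 or 2")
  phi_dims <- as.integer(phi_dims %||% if (stage == 1L) c(256L, 64L)
                                       else c(256L, 64L, 32L))
  head_classes <- as.integer(head_classes %||% if (stage == 1L) 2L else 3L)
  if (stage == 1L && head_classes != 2L)
    stop_sm("stage 1 uses a 2-class head")
  if (stage == 2L && head_classes != 3L)
    stop_sm("stage 2 uses a 3-class head")
  structure(list(stage = stage, phi_dims = phi_dims,
                 head_classes = head_classes, activation = "tanh",
                 lr = lr, lambda_reg = lambda_reg,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 images_per_batch = as.integer(images_per_batch),
                 seed = as.integer(seed)),
            class = "comparator_config")
}

# Uniform fan-in initialization; biases start at zero. Call inside a seeded
# RNG context.
init_comparator <- function(input_dim, config) {
  dims <- c(input_dim, config$phi_dims)
  phi <- lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    lim <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(dims[l + 1L] * fan_in, -lim, lim),
                    nrow = dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
  d <- utils::tail(config$phi_dims, 1L)
  lim <- 1 / sqrt(3L * d)
  head <- list(W = matrix(stats::runif(config$head_classes * 3L * d, -lim, lim),
                          nrow = config$head_classes),
               b = numeric(config$head_classes))
  structure(list(phi = phi, head = head, config = config,
                 input_dim = as.integer(input_dim), report = NULL),
            class = "comparator")
}

#' @export
print.comparator <- function(x, ...) {
  cat(sprintf("<comparator: stage %d, phi %s -> head %d-class%s>\n",
              x$config$stage,
              paste(c(x$input_dim, x$config$phi_dims), collapse = "-"),
              x$config$head_classes,
              if (is.null(x$report)) " (untrained)" else ""))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# Forward pass through phi for a matrix of embeddings (rows). Returns the
# per-layer post-activations; acts[[1]] is the input, acts[[L+1]] the
# projection output (final layer linear, hidden layers tanh).
.phi_forward <- function(E, model) {
  L <- length(model$phi)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- E
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% t(model$phi[[l]]$W)
    Z <- sweep(Z, 2L, model$phi[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  acts
}

# Backward through phi given the gradient at the projection output and the
# stored activations; returns per-layer W/b gradients.
.phi_backward <- function(dOut, acts, model) {
  L <- length(model$phi)
  grads <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    grads[[l]] <- list(W = t(delta) %*% acts[[l]], b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% model$phi[[l]]$W
      delta <- delta * (1 - acts[[l]]^2)   # tanh'
    }
  }
  grads
}

.zero_grads <- function(model) {
  list(phi = lapply(model$phi, function(ly)
         list(W = ly$W * 0, b = ly$b * 0)),
       head = list(W = model$head$W * 0, b = model$head$b * 0))
}

.add_grads <- function(g1, g2, w = 1) {
  list(phi = Map(function(a, b) list(W = a$W + w * b$W, b = a$b + w * b$b),
                 g1$phi, g2$phi),
       head = list(W = g1$head$W + w * g2$head$W,
                   b = g1$head$b + w * g2$head$b))
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Project embeddings through the comparator's phi MLP
#'
#' @param e numeric vector (one embedding) or matrix (one per row) with
#'   `model$input_dim` columns.
#' @param model a `comparator`.
#' @return matrix of projections, `nrow(e)` x last phi dimension.
#' @export
project <- function(e, model) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1L)
  if (ncol(e) != model$input_dim)
    stop_sm("embedding dim ", ncol(e), " != comparator input dim ",
            model$input_dim)
  acts <- .phi_forward(e, model)
  acts[[length(acts)]]
}

#' Compose the Siamese pair feature
#'
#' `[p1; p2; |p1 - p2|]`: the two projections concatenated with their
#' elementwise absolute difference. The third block is symmetric under
#' argument swap; the full feature is not (the head sees argument order).
#'
#' @param p1,p2 numeric vectors or matrices of equal width.
#' @return vector/matrix of width `3 * ncol(p1)`.
#' @export
compose_features <- function(p1, p2) {
  v1 <- is.null(dim(p1))
  if (v1) { p1 <- matrix(p1, 1L); p2 <- matrix(p2, 1L) }
  if (ncol(p1) != ncol(p2) || nrow(p1) != nrow(p2))
    stop_sm("compose_features: shapes differ")
  out <- cbind(p1, p2, abs(p1 - p2))
  if (v1) out[1L, ] else out
}

.head_forward <- function(U, model) {
  sweep(U %*% t(model$head$W), 2L, model$head$b, "+")
}

# Pair logits for embedding matrices Ea, Eb (rows aligned).
.pair_logits <- function(model, Ea, Eb) {
  P <- .phi_forward(rbind(Ea, Eb), model)
  P <- P[[length(P)]]
  n <- nrow(Ea)
  .head_forward(compose_features(P[seq_len(n), , drop = FALSE],
                                 P[n + seq_len(n), , drop = FALSE]), model)
}

#' Scalar comparator score of a text pair
#'
#' `logit(positive) - logit(negative)`; the neutral logit (stage 2) absorbs
#' irrelevant sentences without contributing sign. Higher means the two
#' texts are more compatible descriptions of the same object.
#'
#' @param text_a,text_b character scalars (caption first by convention).
#' @param model a trained `comparator`.
#' @param cache an `embedding_cache`, or a list of caches searched in order;
#'   with `spec = NULL` every text must be cached (cache-only mode).
#' @param spec optional [encoder_spec()] used to embed cache misses.
#' @return numeric scalar.
#' @export
score_pair <- function(text_a, text_b, model, cache = NULL, spec = NULL) {
  E <- .resolve_embeddings(c(text_a, text_b), cache, spec)
  L <- .pair_logits(model, E[1L, , drop = FALSE], E[2L, , drop = FALSE])
  unname(score_from_logits(L)[1L])
}

#' Scalar score from pair logits
#'
#' @param logits numeric vector of length 2/3 or a matrix with one pair per
#'   row, classes ordered (negative[, neutral], positive).
#' @return numeric vector of `logit(positive) - logit(negative)`.
#' @export
score_from_logits <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1L)
  logits[, ncol(logits)] - logits[, 1L]
}

.resolve_embeddings <- function(texts, cache = NULL, spec = NULL) {
  if (is.null(cache)) {
    if (is.null(spec)) stop_sm("need an embedding cache or an encoder spec")
    return(embed_texts(texts, spec))
  }
  caches <- if (inherits(cache, "embedding_cache")) list(cache) else cache
  keys <- text_digest(texts)
  dim <- caches[[1L]]$spec$dim
  E <- matrix(NA_real_, length(texts), dim)
  for (cc in caches) {
    rows <- cc$index[keys]
    hit <- !is.na(rows)
    if (any(hit)) E[hit, ] <- cc$vectors[rows[hit], , drop = FALSE]
  }
  miss <- !stats::complete.cases(E)
  if (any(miss)) {
    if (is.null(spec))
      stop_sm("embedding cache miss (cache-only mode) for: ",
              paste(utils::head(texts[miss], 3L), collapse = " | "))
    E[miss, ] <- embed_texts(texts[miss], spec)
  }
  E
}

# ---- cross-entropy objective on a pair batch ------------------------------

# Mean softmax cross entropy over pairs; y are 1-based class indices in
# head class order. Returns value, accuracy, and gradients if asked.
.ce_objective <- function(model, Ea, Eb, y, want_grads = TRUE) {
  n <- nrow(Ea)
  acts <- .phi_forward(rbind(Ea, Eb), model)
  P <- acts[[length(acts)]]
  Pa <- P[seq_len(n), , drop = FALSE]
  Pb <- P[n + seq_len(n), , drop = FALSE]
  U <- compose_features(Pa, Pb)
  logits <- .head_forward(U, model)
  S <- .softmax_rows(logits)
  loss <- -mean(log(pmax(S[cbind(seq_len(n), y)], 1e-300)))
  acc <- mean(max.col(logits, ties.method = "first") == y)
  if (!want_grads) return(list(value = loss, accuracy = acc))
  dlogits <- S
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  gH <- list(W = t(dlogits) %*% U, b = colSums(dlogits))
  dU <- dlogits %*% model$head$W
  d <- ncol(Pa)
  sg <- sign(Pa - Pb)
  dPa <- dU[, seq_len(d), drop = FALSE] +
    dU[, 2L * d + seq_len(d), drop = FALSE] * sg
  dPb <- dU[, d + seq_len(d), drop = FALSE] -
    dU[, 2L * d + seq_len(d), drop = FALSE] * sg
  gPhi <- .phi_backward(rbind(dPa, dPb), acts, model)
  list(value = loss, accuracy = acc, grads = list(phi = gPhi, head = gH))
}

# ---- Adam -----------------------------------------------------------------

.adam_init <- function(model) {
  list(m = .zero_grads(model), v = .zero_grads(model), t = 0L)
}

.adam_step <- function(model, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(model$phi)) {
    uW <- upd(model$phi[[l]]$W, grads$phi[[l]]$W,
              state$m$phi[[l]]$W, state$v$phi[[l]]$W)
    ub <- upd(model$phi[[l]]$b, grads$phi[[l]]$b,
              state$m$phi[[l]]$b, state$v$phi[[l]]$b)
    model$phi[[l]]$W <- uW$w; state$m$phi[[l]]$W <- uW$m; state$v$phi[[l]]$W <- uW$v
    model$phi[[l]]$b <- ub$w; state$m$phi[[l]]$b <- ub$m; state$v$phi[[l]]$b <- ub$v
  }
  uW <- upd(model$head$W, grads$head$W, state$m$head$W, state$v$head$W)
  ub <- upd(model$head$b, grads$head$b, state$m$head$b, state$v$head$b)
  model$head$W <- uW$w; state$m$head$W <- uW$m; state$v$head$W <- uW$v
  model$head$b <- ub$w; state$m$head$b <- ub$m; state$v$head$b <- ub$v
  list(model = model, state = state)
}

# ---- stage 1 --------------------------------------------------------------

#' Train the comparator, stage 1 (binary)
#'
#' Trains phi and h from scratch on a balanced positive/negative pair
#' dataset with softmax cross entropy (the 2-logit form of binary cross
#' entropy), Adam, and per-epoch reshuffling. Fully reproducible from
#' `config$seed`. A training report (per-epoch loss and accuracy) is
#' attached to the returned model.
#'
#' @param pairs a pair dataset (data.frame with columns `a`, `b`, `label`)
#'   containing only positive/negative labels.
#' @param spec an [encoder_spec()] (ignored for cached texts).
#' @param config a [comparator_config()] with `stage = 1`.
#' @param cache optional `embedding_cache` (or list of caches).
#' @param verbose print per-epoch progress?
#' @return a trained `comparator` with a `report` field.
#' @export
train_stage1 <- function(pairs, spec = encoder_spec(),
                         config = comparator_config(stage = 1L),
                         cache = NULL, verbose = FALSE) {
  if (config$stage != 1L) stop_sm("train_stage1 needs a stage-1 config")
  if (any(pairs$label == "neutral"))
    stop_sm("stage 1 is binary: dataset contains neutral pairs")
  bad <- setdiff(unique(pairs$label), c("positive", "negative"))
  if (length(bad)) stop_sm("unknown labels: ", paste(bad, collapse = ", "))
  texts <- unique(c(pairs$a, pairs$b))
  E <- .resolve_embeddings(texts, cache, spec)
  key <- seq_along(texts); names(key) <- text_digest(texts)
  ia <- key[text_digest(pairs$a)]
  ib <- key[text_digest(pairs$b)]
  y <- ifelse(pairs$label == "positive", 2L, 1L)
  n <- length(y)
  with_seed(config$seed, {
    model <- init_comparator(ncol(E), config)
    state <- .adam_init(model)
    report <- data.frame(epoch = integer(0), loss = numeric(0),
                         accuracy = numeric(0))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, n)]
        res <- .ce_objective(model, E[ia[sel], , drop = FALSE],
                             E[ib[sel], , drop = FALSE], y[sel])
        st <- .adam_step(model, res$grads, state, config$lr)
        model <- st$model; state <- st$state
        losses <- c(losses, res$value)
      }
      full <- .ce_objective(model, E[ia, , drop = FALSE],
                            E[ib, , drop = FALSE], y, want_grads = FALSE)
      report <- rbind(report, data.frame(epoch = ep, loss = full$value,
                                         accuracy = full$accuracy))
      if (verbose)
        message(sprintf("stage1 epoch %d: loss %.4f acc %.3f",
                        ep, full$value, full$accuracy))
    }
    model$report <- report
    model
  })
}

# ---- stage 2 --------------------------------------------------------------

# Value (and gradients) of the full stage-2 objective on one step's data:
# 3-class cross entropy summed over the pair minibatch plus lambda times
# the batch-level regularizer R computed from the image batch's posteriors
# over the whole corpus. Both terms are batch sums (R is a sum over the
# image batch by definition), so lambda weighs regularizer against
# cross entropy on a common per-batch scale. reg_batch carries: Ecap
# (embeddings of the batch images' captions), cap_image (image index per
# caption row), Edoc (all corpus sentence embeddings), sent_doc (document
# index per sentence row), n_img, n_doc.
.stage2_objective <- function(model, Ea, Eb, y, reg_batch, lambda,
                              want_grads = TRUE) {
  n <- nrow(Ea)
  ce <- .ce_objective(model, Ea, Eb, y, want_grads = want_grads)
  reg <- .regularizer_objective(model, reg_batch, want_grads = want_grads)
  out <- list(value = n * ce$value + lambda * reg$value,
              ce = n * ce$value, reg = reg$value, accuracy = ce$accuracy)
  if (want_grads)
    out$grads <- .add_grads(.scale_grads(ce$grads, n), reg$grads, w = lambda)
  out
}

.scale_grads <- function(g, w) {
  list(phi = lapply(g$phi, function(l) list(W = w * l$W, b = w * l$b)),
       head = list(W = w * g$head$W, b = w * g$head$b))
}

# Regularizer term: z[i, j] = mean comparator score over (caption of image
# i) x (sentence of document j); p = row softmax(z); R = |colSums(p)|^2 -
# 2 * sum(p^2). Gradients flow through the softmax and the score average
# back into phi and h.
.regularizer_objective <- function(model, rb, want_grads = TRUE) {
  nc <- nrow(rb$Ecap); ns <- nrow(rb$Edoc)
  acts <- .phi_forward(rbind(rb$Ecap, rb$Edoc), model)
  P <- acts[[length(acts)]]
  Pc <- P[seq_len(nc), , drop = FALSE]
  Pd <- P[nc + seq_len(ns), , drop = FALSE]
  d <- ncol(Pc)
  Wh <- model$head$W; bh <- model$head$b
  pos <- nrow(Wh); neg <- 1L
  wv <- Wh[pos, ] - Wh[neg, ]
  w1 <- wv[seq_len(d)]; w2 <- wv[d + seq_len(d)]; w3 <- wv[2L * d + seq_len(d)]
  b0 <- bh[pos] - bh[neg]
  FS <- matrix(drop(Pc %*% w1), nc, ns) +
    matrix(drop(Pd %*% w2), nc, ns, byrow = TRUE) + b0
  for (k in seq_len(d))
    FS <- FS + w3[k] * abs(outer(Pc[, k], Pd[, k], "-"))
  # average into z over captions-of-image x sentences-of-document
  n_cap <- tabulate(rb$cap_image, rb$n_img)
  n_sent <- tabulate(rb$sent_doc, rb$n_doc)
  Z <- rowsum(t(rowsum(FS, rb$cap_image)), rb$sent_doc)
  Z <- t(Z) / outer(n_cap, n_sent)
  Pmat <- .softmax_rows(Z)
  S <- colSums(Pmat)
  R <- sum(S * S) - 2 * sum(Pmat * Pmat)
  if (!want_grads) return(list(value = R, z = Z, p = Pmat))
  dP <- 2 * matrix(S, rb$n_img, rb$n_doc, byrow = TRUE) - 4 * Pmat
  dZ <- Pmat * (dP - rowSums(Pmat * dP))
  dF <- (dZ / outer(n_cap, n_sent))[rb$cap_image, rb$sent_doc, drop = FALSE]
  rs <- rowSums(dF); cs <- colSums(dF)
  gW <- matrix(0, nrow(Wh), ncol(Wh))
  gb <- numeric(length(bh))
  gwv <- c(drop(t(Pc) %*% rs), drop(t(Pd) %*% cs), numeric(d))
  dPc <- matrix(0, nc, d); dPd <- matrix(0, ns, d)
  for (k in seq_len(d)) {
    Dk <- outer(Pc[, k], Pd[, k], "-")
    Sk <- sign(Dk)
    gwv[2L * d + k] <- sum(dF * abs(Dk))
    dFS <- dF * Sk
    dPc[, k] <- w1[k] * rs + w3[k] * rowSums(dFS)
    dPd[, k] <- w2[k] * cs - w3[k] * colSums(dFS)
  }
  gW[pos, ] <- gwv; gW[neg, ] <- -gwv
  gb[pos] <- sum(dF); gb[neg] <- -sum(dF)
  gPhi <- .phi_backward(rbind(dPc, dPd), acts, model)
  list(value = R, z = Z, p = Pmat,
       grads = list(phi = gPhi, head = list(W = gW, b = gb)))
}

#' Train the comparator, stage 2 (3-class + regularizer)
#'
#' Re-initializes phi and h from scratch (no warm start), then minimizes the
#' 3-class cross entropy on positive/neutral/negative pairs plus
#' `lambda_reg` times the batch-level score-distribution regularizer. Each
#' optimization step pairs one minibatch of labelled pairs with one batch of
#' `images_per_batch` images whose posteriors over the full corpus feed the
#' regularizer; batches are organized per image, i.e. all of an image's
#' captions enter its posterior. The encoder is frozen: caption and corpus
#' embeddings must be precomputed (see [precompute_cache()]).
#'
#' @param pairs a 3-class pair dataset.
#' @param caption_sets list of [caption_set()] (training images).
#' @param corp the target [corpus()].
#' @param config a [comparator_config()] with `stage = 2`.
#' @param cap_cache,doc_cache `embedding_cache` objects for captions and
#'   corpus sentences; both are required.
#' @param verbose print per-epoch progress?
#' @return a trained `comparator` with a `report` field (per-epoch
#'   objective, cross entropy, regularizer value, pair accuracy).
#' @export
train_stage2 <- function(pairs, caption_sets, corp,
                         config = comparator_config(stage = 2L),
                         cap_cache = NULL, doc_cache = NULL,
                         verbose = FALSE) {
  if (config$stage != 2L) stop_sm("train_stage2 needs a stage-2 config")
  if (is.null(cap_cache) || is.null(doc_cache))
    stop_sm("stage 2 requires prebuilt caption and corpus embedding caches ",
            "(frozen encoder); see precompute_cache()")
  if (config$lambda_reg < 0) stop_sm("lambda_reg must be >= 0")
  bad <- setdiff(unique(pairs$label), PAIR_LABELS)
  if (length(bad)) stop_sm("unknown labels: ", paste(bad, collapse = ", "))
  caches <- list(cap_cache, doc_cache)
  class_order <- head_class_names(3L)
  y <- match(pairs$label, class_order)
  Ea <- .resolve_embeddings(pairs$a, caches)
  Eb <- .resolve_embeddings(pairs$b, caches)
  # image-major caption embeddings for the regularizer
  cap_counts <- vapply(caption_sets, function(x) length(x$captions), integer(1))
  Ecap_all <- .resolve_embeddings(unlist(lapply(caption_sets, `[[`, "captions")),
                                  caches)
  cap_owner <- rep(seq_along(caption_sets), cap_counts)
  doc_counts <- vapply(corp$documents, function(d) length(d$sentences), integer(1))
  Edoc <- .resolve_embeddings(unlist(lapply(corp$documents, `[[`, "sentences")),
                              caches)
  sent_doc <- rep(seq_along(corp$documents), doc_counts)
  n_images <- length(caption_sets)
  B <- min(config$images_per_batch, n_images)
  n <- nrow(Ea)
  with_seed(config$seed, {
    model <- init_comparator(ncol(Ea), config)
    state <- .adam_init(model)
    report <- data.frame(epoch = integer(0), objective = numeric(0),
                         ce = numeric(0), reg = numeric(0),
                         accuracy = numeric(0))
    img_order <- sample.int(n_images)
    img_pos <- 1L
    next_image_batch <- function() {
      if (img_pos + B - 1L > n_images) {
        img_order <<- sample.int(n_images)
        img_pos <<- 1L
      }
      sel <- img_order[img_pos:(img_pos + B - 1L)]
      img_pos <<- img_pos + B
      sel
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      obj_ep <- ce_ep <- reg_ep <- acc_ep <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, n)]
        imgs <- next_image_batch()
        rows <- which(cap_owner %in% imgs)
        rb <- list(Ecap = Ecap_all[rows, , drop = FALSE],
                   cap_image = match(cap_owner[rows], imgs),
                   Edoc = Edoc, sent_doc = sent_doc,
                   n_img = length(imgs), n_doc = length(corp$documents))
        res <- .stage2_objective(model, Ea[sel, , drop = FALSE],
                                 Eb[sel, , drop = FALSE], y[sel],
                                 rb, config$lambda_reg)
        st <- .adam_step(model, res$grads, state, config$lr)
        model <- st$model; state <- st$state
        obj_ep <- c(obj_ep, res$value); ce_ep <- c(ce_ep, res$ce)
        reg_ep <- c(reg_ep, res$reg); acc_ep <- c(acc_ep, res$accuracy)
      }
      report <- rbind(report, data.frame(
        epoch = ep, objective = mean(obj_ep), ce = mean(ce_ep),
        reg = mean(reg_ep), accuracy = mean(acc_ep)))
      if (verbose)
        message(sprintf("stage2 epoch %d: obj %.4f ce %.4f R %.4f acc %.3f",
                        ep, mean(obj_ep), mean(ce_ep), mean(reg_ep),
                        mean(acc_ep)))
    }
    model$report <- report
    model
  })
}

# ---- (de)serialization ----------------------------------------------------

#' Save / load a comparator checkpoint (JSON, full double precision)
#'
#' @param model a `comparator`.
#' @param path output path.
#' @return `path` invisibly; `load_comparator` returns the model.
#' @export
save_comparator <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    input_dim = model$input_dim,
    phi = lapply(model$phi, function(ly)
      list(W = as.vector(ly$W), dims = dim(ly$W), b = ly$b)),
    head = list(W = as.vector(model$head$W), dims = dim(model$head$W),
                b = model$head$b),
    report = model$report
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_comparator
#' @export
load_comparator <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(comparator_config, obj$config[
    c("stage", "phi_dims", "head_classes", "lr", "lambda_reg", "epochs",
      "batch_size", "images_per_batch", "seed")])
  phi <- if (is.data.frame(obj$phi)) {
    lapply(seq_len(nrow(obj$phi)), function(l)
      list(W = matrix(obj$phi$W[[l]], obj$phi$dims[[l]][1L]),
           b = obj$phi$b[[l]]))
  } else {
    lapply(obj$phi, function(ly) list(W = matrix(ly$W, ly$dims[1L]), b = ly$b))
  }
  structure(list(phi = phi,
                 head = list(W = matrix(obj$head$W, obj$head$dims[1L]),
                             b = obj$head$b),
                 config = cfg, input_dim = as.integer(obj$input_dim),
                 report = obj$report),
            class = "comparator")
}

# Full comparator score matrix for caption embeddings (rows of Ea) against
# sentence embeddings (rows of Eb): F[i, j] = f(caption i, sentence j) with
# the caption always the first argument. Shared by retrieval scoring and
# the stage-2 regularizer forward pass.
comparator_score_matrix <- function(model, Ea, Eb) {
  Pa <- project(Ea, model)
  Pb <- project(Eb, model)
  d <- ncol(Pa)
  Wh <- model$head$W; bh <- model$head$b
  pos <- nrow(Wh); neg <- 1L
  wv <- Wh[pos, ] - Wh[neg, ]
  b0 <- bh[pos] - bh[neg]
  FS <- matrix(drop(Pa %*% wv[seq_len(d)]), nrow(Pa), nrow(Pb)) +
    matrix(drop(Pb %*% wv[d + seq_len(d)]), nrow(Pa), nrow(Pb), byrow = TRUE) +
    b0
  w3 <- wv[2L * d + seq_len(d)]
  for (k in seq_len(d))
    FS <- FS + w3[k] * abs(outer(Pa[, k], Pb[, k], "-"))
  FS
}
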