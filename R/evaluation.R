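# Retrieval metrics. With exactly one relevant document per class,
# retrieval accuracy equals classification accuracy; metrics are computed
# per class over that class's images and macro-averaged, with a micro
# (per-image) variant behind a flag.

#' Evaluate a ranking against ground truth
#'
#' @param ranking a `ranking` covering all K classes for every image.
#' @param truth named character vector `image_id -> class_id`, or a
#'   data.frame with columns `image_id`, `class_id`.
#' @param topk integer vector of k values for top-k accuracy (default 1, 5;
#'   values above K are capped at K).
#' @param average `"macro"` (per-class means, then mean over classes; the
#'   default) or `"micro"` (over images).
#' @return an object of class `eval_report`: `topk` (named percentages),
#'   `mean_rank`, `per_class` (data.frame), `n_images`, `K`.
#' @export
evaluate_ranking <- function(ranking, truth, topk = c(1L, 5L),
                             average = c("macro", "micro")) {
  average <- match.arg(average)
  if (is.data.frame(truth)) {
    tr <- as.character(truth$class_id)
    names(tr) <- as.character(truth$image_id)
    truth <- tr
  }
  miss <- setdiff(ranking$image_ids, names(truth))
  if (length(miss))
    stop_sm("images missing truth labels: ",
            paste(utils::head(miss, 3L), collapse = ", "))
  truth <- truth[ranking$image_ids]
  bad <- setdiff(unique(truth), ranking$class_ids)
  if (length(bad))
    stop_sm("truth classes absent from corpus: ", paste(bad, collapse = ", "))
  K <- length(ranking$class_ids)
  topk <- pmin(as.integer(topk), K)
  r <- ranking$ranks[cbind(seq_along(truth), match(truth, ranking$class_ids))]
  per_class <- do.call(rbind, lapply(sort(unique(truth)), function(cl) {
    rc <- r[truth == cl]
    row <- data.frame(class_id = cl, n = length(rc), mean_rank = mean(rc))
    for (k in topk) row[[paste0("top", k)]] <- 100 * mean(rc <= k)
    row
  }))
  agg <- function(col) {
    if (average == "macro") mean(per_class[[col]])
    else stats::weighted.mean(per_class[[col]], per_class$n)
  }
  tk <- vapply(paste0("top", topk), agg, numeric(1))
  names(tk) <- paste0("top", topk)
  structure(list(topk = tk, mean_rank = agg("mean_rank"),
                 per_class = per_class, n_images = length(r), K = K,
                 average = average, method = ranking$method),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report (%s, %s): %s | MR %.2f | %d images, K=%d>\n",
              x$method, x$average,
              paste(names(x$topk), sprintf("%.1f%%", x$topk), collapse = ", "),
              x$mean_rank, x$n_images, x$K))
  invisible(x)
}

#' Convert an evaluation report to a one-row data.frame
#'
#' @param report an `eval_report`.
#' @return one-row data.frame (method, top-k columns, mean_rank, n, K).
#' @export
report_row <- function(report) {
  out <- data.frame(method = report$method)
  for (nm in names(report$topk)) out[[nm]] <- report$topk[[nm]]
  out$mean_rank <- report$mean_rank
  out$n_images <- report$n_images
  out$K <- report$K
  out
}

#' Analytic random-guess reference
#'
#' Expected top-k accuracy of a uniformly random ranking over K classes:
#' `100 * k / K` percent. The companion expected 1-based mean rank of the
#' target is `(K + 1) / 2`.
#'
#' @param K number of classes.
#' @param k cutoff, `1 <= k <= K`.
#' @return list with `accuracy` (percentage) and `expected_mean_rank`.
#' @export
random_guess_expectation <- function(K, k = 1L) {
  K <- as.integer(K); k <- as.integer(k)
  if (k < 1L || k > K) stop_sm("need 1 <= k <= K")
  list(accuracy = 100 * k / K, expected_mean_rank = (K + 1) / 2)
}
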