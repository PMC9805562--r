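# Task metrics for relation extraction: micro and per-class P/R/F over the
# positive classes, confusion matrices, and the approximate-randomization
# (randomized shuffle) significance test.

.check_labels <- function(x, labelset, what) {
  bad <- setdiff(unique(x), labelset$labels)
  if (length(bad)) stopf("unknown %s label: %s", what, bad[1])
}

#' Confusion matrix with a fixed class order
#'
#' Rows are gold labels, columns predicted labels, ordered as in the label
#' set (negative last).
#'
#' @param gold,pred equal-length label vectors.
#' @param labelset a [ddi_labelset()].
#' @return A c x c integer matrix.
#' @export
confusion_matrix <- function(gold, pred, labelset = ddi_labelset()) {
  if (length(gold) != length(pred))
    stopf("gold and pred lengths differ (%d vs %d)", length(gold),
          length(pred))
  .check_labels(gold, labelset, "gold"); .check_labels(pred, labelset, "pred")
  table(factor(gold, levels = labelset$labels),
        factor(pred, levels = labelset$labels))
}

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F = f)
}

#' Micro precision / recall / F over the positive classes
#'
#' True/false positives and false negatives are pooled over the positive
#' classes only; the negative class is excluded, following the
#' DDIExtraction-2013 convention of one overall F over the four
#' interaction types.
#'
#' @param gold,pred equal-length label vectors.
#' @param labelset a [ddi_labelset()].
#' @return Named numeric vector `c(P, R, F)`.
#' @export
micro_prf <- function(gold, pred, labelset = ddi_labelset()) {
  if (length(gold) != length(pred))
    stopf("gold and pred lengths differ (%d vs %d)", length(gold),
          length(pred))
  .check_labels(gold, labelset, "gold"); .check_labels(pred, labelset, "pred")
  pos <- labelset$positives
  gp <- gold %in% pos; pp <- pred %in% pos
  tp <- sum(gp & pp & gold == pred)
  fp <- sum(pp) - tp
  fn <- sum(gp) - tp
  .prf(tp, fp, fn)
}

#' Per-class precision / recall / F (one-vs-rest)
#'
#' @param gold,pred equal-length label vectors.
#' @param labelset a [ddi_labelset()].
#' @return data.frame with one row per positive class: `class`, `P`, `R`,
#'   `F`, `support`, and `absent` flagging classes missing from both gold
#'   and predictions (reported as 0).
#' @export
per_class_prf <- function(gold, pred, labelset = ddi_labelset()) {
  if (length(gold) != length(pred))
    stopf("gold and pred lengths differ (%d vs %d)", length(gold),
          length(pred))
  .check_labels(gold, labelset, "gold"); .check_labels(pred, labelset, "pred")
  rows <- lapply(labelset$positives, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(gold == cl & pred != cl)
    v <- .prf(tp, fp, fn)
    data.frame(class = cl, P = v[["P"]], R = v[["R"]], F = v[["F"]],
               support = sum(gold == cl),
               absent = (tp + fp + fn) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-instance pooled-count contributions (tp, fp, fn) for fast shuffling.
.micro_contrib <- function(gold, pred, labelset) {
  gp <- gold %in% labelset$positives
  pp <- pred %in% labelset$positives
  tp <- as.integer(gp & pp & gold == pred)
  cbind(tp = tp, fp = as.integer(pp) - tp, fn = as.integer(gp) - tp)
}

.micro_f_from_counts <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Randomized shuffle test on the micro-F difference of two systems
#'
#' Approximate-randomization test: per instance, the two systems'
#' predictions are swapped with probability one half; the two-sided
#' p-value is `(1 + #{|delta_shuffled| >= |delta_observed|}) / (1 +
#' n_shuffles)`. Reproducible under `seed`.
#'
#' @param gold gold labels.
#' @param pred_a,pred_b the two systems' predictions, aligned with `gold`.
#' @param n_shuffles number of random shuffles (default 10000).
#' @param seed integer seed.
#' @param labelset a [ddi_labelset()].
#' @return A list with `p_value`, `delta_observed` (micro-F of A minus B),
#'   and `n_shuffles`.
#' @export
shuffle_test <- function(gold, pred_a, pred_b, n_shuffles = 10000, seed = 1,
                         labelset = ddi_labelset()) {
  stopifnot(n_shuffles >= 1)
  if (length(gold) != length(pred_a) || length(gold) != length(pred_b))
    stopf("gold, pred_a and pred_b must be aligned")
  fa <- micro_prf(gold, pred_a, labelset)[["F"]]
  fb <- micro_prf(gold, pred_b, labelset)[["F"]]
  delta <- fa - fb
  ca <- .micro_contrib(gold, pred_a, labelset)
  cb <- .micro_contrib(gold, pred_b, labelset)
  n <- length(gold)
  count <- with_seed(seed, {
    hits <- 0L
    for (s in seq_len(n_shuffles)) {
      swap <- stats::runif(n) < 0.5
      A <- ca; A[swap, ] <- cb[swap, , drop = FALSE]
      B <- cb; B[swap, ] <- ca[swap, , drop = FALSE]
      sa <- colSums(A); sb <- colSums(B)
      ds <- .micro_f_from_counts(sa[1], sa[2], sa[3]) -
        .micro_f_from_counts(sb[1], sb[2], sb[3])
      if (abs(ds) >= abs(delta)) hits <- hits + 1L
    }
    hits
  })
  list(p_value = (1 + count) / (1 + n_shuffles), delta_observed = delta,
       n_shuffles = n_shuffles)
}
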