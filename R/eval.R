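# Base-pair level scoring: precision, recall and F1 over unordered pairs
# (i < j), exact index matching, with the 0/0 -> 0 convention.

#' Score a predicted structure against the truth
#'
#' TP is the number of predicted pairs that occur in the truth, FP the
#' number that do not, FN the number of true pairs missed; matching is
#' exact (no one-position slippage tolerance). Precision, recall and F1
#' follow, with any 0/0 defined as 0.
#'
#' @param pred,truth `secondary_structure` objects of equal length.
#' @return an `eval_result` list with fields `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @examples
#' truth <- secondary_structure(9, rbind(c(0, 8), c(1, 7)))
#' evaluate_structure(truth, truth)$f1 # 1
#' @export
evaluate_structure <- function(pred, truth) {
  if (pred$L != truth$L)
    stop("prediction and truth have different lengths (", pred$L, " vs ",
         truth$L, ")")
  key <- function(ss) if (nrow(ss$pairs)) paste(ss$pairs[, 1L],
                                                ss$pairs[, 2L]) else
    character(0)
  kp <- key(pred); kt <- key(truth)
  tp <- sum(kp %in% kt)
  fp <- length(kp) - tp
  fn <- length(kt) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP=%d FP=%d FN=%d  P=%.3f R=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score a set of predictions
#'
#' Per-record precision/recall/F1 plus the macro average (mean of the
#' per-sequence metrics). Optionally written as TSV.
#'
#' @param preds,truths lists of `secondary_structure` objects, matched by
#'   position.
#' @param ids optional record identifiers.
#' @param path optional TSV output file for the per-record table.
#' @return `list(per_record = data.frame, macro = named numeric vector)`.
#' @export
evaluate_dataset <- function(preds, truths, ids = NULL, path = NULL) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  if (is.null(ids)) ids <- sprintf("record_%04d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(r) {
    e <- evaluate_structure(preds[[r]], truths[[r]])
    data.frame(id = ids[r], tp = e$tp, fp = e$fp, fn = e$fn,
               precision = e$precision, recall = e$recall, f1 = e$f1)
  })
  per_record <- do.call(rbind, rows)
  macro <- c(precision = mean(per_record$precision),
             recall = mean(per_record$recall),
             f1 = mean(per_record$f1))
  if (!is.null(path))
    write.table(per_record, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(per_record = per_record, macro = macro)
}

#' Weighted binary cross-entropy between a score map and a contact map
#'
#' Computed over upper-triangle cells with `|j - i| >= min_sep` (the cells
#' the decoder can ever set); positive cells are weighted by `pos_weight`
#' to counter the ~1/L density of pairs among L^2 cells; mean-reduced over
#' the counted cells.
#'
#' @param pred numeric matrix of probabilities (clipped to
#'   `[eps, 1 - eps]`).
#' @param truth binary contact map of the same shape.
#' @param pos_weight weight (>= 1) on positive cells.
#' @param min_sep minimum pair separation defining the counted cells.
#' @param eps clipping constant.
#' @return nonnegative scalar loss.
#' @export
contact_loss <- function(pred, truth, pos_weight = 1, min_sep = 4L,
                         eps = 1e-7) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth shapes differ")
  stopifnot(pos_weight >= 1)
  L <- nrow(pred)
  sel <- upper.tri(pred) & abs(row(pred) - col(pred)) >= min_sep
  if (!any(sel)) return(0)
  p <- pmin(pmax(pred[sel], eps), 1 - eps)
  y <- truth[sel]
  w <- ifelse(y == 1, pos_weight, 1)
  mean(-w * (y * log(p) + (1 - y) * log1p(-p)))
}
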