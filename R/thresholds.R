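#' Optimize per-group decision thresholds on training scores
#'
#' After training, each functional group receives its own decision cutoff:
#' the value on the grid 0.01, 0.02, ..., 0.99 that maximizes that group's
#' F1 score on the training rows, with ties broken toward the smallest
#' threshold. Groups absent from the training labels fall back to 0.5 with
#' a warning. By construction the thresholded training F1 of every group is
#' at least its F1 at the fixed cutoff 0.5.
#'
#' @param model an \code{fg_mlp}.
#' @param features training feature matrix.
#' @param labels training 0/1 label matrix.
#' @param grid candidate thresholds (default \code{seq(0.01, 0.99, 0.01)}).
#' @return the model with its \code{thresholds} replaced.
#' @export
optimize_thresholds <- function(model, features, labels,
                                grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(model, "fg_mlp"))
  labels <- as.matrix(labels)
  scores <- predict_scores(model, features)
  th <- stats::setNames(numeric(length(model$groups)), model$groups)
  for (g in seq_along(model$groups)) {
    y <- labels[, g]
    if (sum(y) == 0L) {
      warning("optimize_thresholds: group '", model$groups[g],
              "' absent from training labels; keeping threshold 0.5")
      th[g] <- 0.5
      next
    }
    th[g] <- best_threshold(scores[, g], y, grid)
  }
  model$thresholds <- th
  model
}

#' Best F1 threshold for one group by grid search
#'
#' The single-group search behind [optimize_thresholds()]: scans the
#' candidate grid in ascending order and returns the first (i.e. smallest)
#' cutoff attaining the maximal F1 of \code{scores >= t} against \code{y}.
#'
#' @param scores numeric score vector in [0, 1].
#' @param y 0/1 truth vector.
#' @param grid ascending candidate thresholds.
#' @return the selected threshold.
#' @export
best_threshold <- function(scores, y, grid = seq(0.01, 0.99, by = 0.01)) {
  f1s <- vapply(grid, function(t) f1_binary(y, as.integer(scores >= t)),
                numeric(1))
  grid[which.max(f1s)]   # first max = smallest threshold on ties
}

# F1 from binary truth/prediction vectors; 0 when no TP but some FP/FN,
# 1 for the all-negative degenerate case.
f1_binary <- function(y, p) {
  tp <- sum(y == 1L & p == 1L)
  fp <- sum(y == 0L & p == 1L)
  fn <- sum(y == 1L & p == 0L)
  if (tp + fp + fn == 0L) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Apply per-group thresholds to a score matrix
#'
#' A group is called present when its score is greater than or equal to its
#' threshold (scores exactly at the cutoff count as present).
#'
#' @param scores matrix of per-group scores (columns in group order).
#' @param thresholds numeric vector, one cutoff per group.
#' @return integer 0/1 matrix of predictions, same shape as \code{scores}.
#' @export
apply_thresholds <- function(scores, thresholds) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) != length(thresholds))
    stop("apply_thresholds: ", ncol(scores), " score columns but ",
         length(thresholds), " thresholds")
  pred <- matrix(as.integer(sweep(scores, 2, thresholds, ">=")),
                 nrow(scores), ncol(scores))
  dimnames(pred) <- dimnames(scores)
  pred
}

#' Predicted label matrix for new spectra
#' @param model an \code{fg_mlp} (ideally after [optimize_thresholds()]).
#' @param features feature matrix.
#' @return 0/1 matrix, one column per group.
#' @export
predict_labels <- function(model, features) {
  apply_thresholds(predict_scores(model, features), model$thresholds)
}
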