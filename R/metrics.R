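#' Molecular F1 score of one (truth, prediction) pair
#'
#' Counts true positives, false positives and false negatives over the
#' functional groups of a single molecule and returns the harmonic mean of
#' molecular precision \code{TP/(TP+FP)} and molecular recall
#' \code{TP/(TP+FN)}. Conventions for empty sets: both sets empty scores
#' 1.0 (a perfect prediction of "no groups"); one empty and the other not
#' scores 0.0. Under these conventions a pair is perfect (predicted set
#' identical to the true set) exactly when its molecular F1 equals 1.
#'
#' @param true_set,pred_set [label_vector()]s over the same catalogue, or
#'   plain 0/1 vectors of equal length.
#' @return the molecular F1 in [0, 1].
#' @examples
#' g <- c("arene", "alkyl_halide", "amide")
#' molecular_f1(label_from_set(g, g), label_from_set(g[1:2], g))  # 0.8
#' @export
molecular_f1 <- function(true_set, pred_set) {
  check_same_catalogue(true_set, pred_set)
  y <- as.integer(true_set); p <- as.integer(pred_set)
  tp <- sum(y == 1L & p == 1L)
  fp <- sum(y == 0L & p == 1L)
  fn <- sum(y == 1L & p == 0L)
  if (tp + fp + fn == 0L) return(1)        # both sets empty
  if (tp == 0L) return(0)                  # no overlap (covers one-empty cases)
  pr <- tp / (tp + fp)
  re <- tp / (tp + fn)
  2 * pr * re / (pr + re)
}

check_same_catalogue <- function(a, b) {
  if (length(a) != length(b))
    stop("metrics: label vectors have different lengths (",
         length(a), " vs ", length(b), ")")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("metrics: label vectors use different group catalogues")
  invisible(TRUE)
}

#' Molecular F1 for every row of paired label matrices
#' @param truth,pred 0/1 matrices of identical shape (rows = molecules).
#' @return numeric vector of per-molecule molecular F1 scores.
#' @export
molecular_f1_rows <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(identical(dim(truth), dim(pred)))
  tp <- rowSums(truth == 1L & pred == 1L)
  fp <- rowSums(truth == 0L & pred == 1L)
  fn <- rowSums(truth == 1L & pred == 0L)
  out <- numeric(nrow(truth))
  empty <- (tp + fp + fn) == 0L
  out[empty] <- 1
  ok <- !empty & tp > 0L
  out[ok] <- 2 * tp[ok] / (2 * tp[ok] + fp[ok] + fn[ok])
  out
}

#' Molecular perfection rate
#'
#' The fraction of molecules whose predicted functional-group set exactly
#' equals the true set; each molecule contributes a perfection of 1 if the
#' sets match and 0 otherwise. Equivalently, the fraction of molecules with
#' a molecular F1 of 1.0.
#'
#' @param truth,pred 0/1 matrices of identical shape (rows = molecules), or
#'   a list of \code{(true, pred)} pairs in \code{truth} with
#'   \code{pred} missing.
#' @return the perfection rate in [0, 1].
#' @export
molecular_perfection_rate <- function(truth, pred = NULL) {
  if (is.null(pred)) {
    if (!is.list(truth) || length(truth) == 0L)
      stop("molecular_perfection_rate: need a non-empty list of pairs")
    perfect <- vapply(truth, function(pair) {
      check_same_catalogue(pair[[1]], pair[[2]])
      all(as.integer(pair[[1]]) == as.integer(pair[[2]]))
    }, logical(1))
    return(mean(perfect))
  }
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(identical(dim(truth), dim(pred)))
  if (nrow(truth) == 0L)
    stop("molecular_perfection_rate: no molecules")
  mean(rowSums(truth != pred) == 0L)
}

#' Per-group precision, recall and F1
#'
#' Standard per-class scores pooled over molecules: for one functional
#' group, TP/FP/FN are counted across all molecules and precision, recall
#' and F1 computed from the pooled counts. F1 is 0 when the group occurs
#' (or is predicted) somewhere but never correctly; when a group neither
#' occurs nor is predicted anywhere the score is reported as 1.0 with
#' \code{degenerate = TRUE}.
#'
#' @param truth,pred 0/1 matrices (rows = molecules, columns = groups).
#' @param group column name or index; if missing, all groups are scored.
#' @return data frame with columns \code{group}, \code{precision},
#'   \code{recall}, \code{f1}, \code{support}, \code{degenerate}.
#' @export
group_f1 <- function(truth, pred, group = NULL) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(identical(dim(truth), dim(pred)))
  cols <- if (is.null(group)) seq_len(ncol(truth))
          else if (is.character(group)) match(group, colnames(truth))
          else as.integer(group)
  if (any(is.na(cols))) stop("group_f1: unknown group")
  out <- lapply(cols, function(g) {
    y <- truth[, g]; p <- pred[, g]
    tp <- sum(y == 1L & p == 1L)
    fp <- sum(y == 0L & p == 1L)
    fn <- sum(y == 1L & p == 0L)
    degenerate <- (tp + fp + fn) == 0L
    prec <- if (tp + fp == 0L) (if (degenerate) 1 else 0) else tp / (tp + fp)
    rec <- if (tp + fn == 0L) (if (degenerate) 1 else 0) else tp / (tp + fn)
    f1 <- if (degenerate) 1 else if (tp == 0L) 0
          else 2 * prec * rec / (prec + rec)
    data.frame(group = colnames(truth)[g] %||% as.character(g),
               precision = prec, recall = rec, f1 = f1,
               support = sum(y), degenerate = degenerate)
  })
  do.call(rbind, out)
}

#' Full evaluation report for a prediction matrix
#'
#' Bundles the per-group precision/recall/F1 table with the two
#' molecule-level summaries: overall molecular F1 (arithmetic mean of the
#' per-molecule molecular F1 scores) and the molecular perfection rate.
#'
#' @param truth,pred 0/1 matrices (rows = molecules, columns = groups).
#' @return object of class \code{fg_metrics}: list with \code{per_group}
#'   (data frame), \code{macro_f1}, \code{overall_mf1}, \code{mpr},
#'   \code{n_molecules}.
#' @export
metrics_report <- function(truth, pred) {
  per_group <- group_f1(truth, pred)
  mf1 <- molecular_f1_rows(truth, pred)
  structure(list(per_group = per_group,
                 macro_f1 = mean(per_group$f1),
                 overall_mf1 = mean(mf1),
                 mpr = molecular_perfection_rate(truth, pred),
                 n_molecules = nrow(as.matrix(truth))),
            class = "fg_metrics")
}

#' @export
print.fg_metrics <- function(x, ...) {
  cat(sprintf("<fg_metrics> %d molecules\n", x$n_molecules))
  print(x$per_group, row.names = FALSE, digits = 3)
  cat(sprintf("macro FG F1 %.3f | molecular F1 %.3f | perfection rate %.3f\n",
              x$macro_f1, x$overall_mf1, x$mpr))
  invisible(x)
}

#' Aggregate per-fold metric reports into fold means and SDs
#' @param reports list of \code{fg_metrics}, one per fold.
#' @return object of class \code{fg_cv_metrics} with per-fold values and
#'   mean +/- SD for macro F1, overall MF1 and MPR, plus the fold-averaged
#'   per-group F1 table.
#' @export
aggregate_folds <- function(reports) {
  stopifnot(length(reports) >= 1L)
  pull <- function(f) vapply(reports, `[[`, numeric(1), f)
  per_group <- Reduce(function(a, b) {
    a$f1 <- a$f1 + b$f1; a$precision <- a$precision + b$precision
    a$recall <- a$recall + b$recall; a
  }, lapply(reports, `[[`, "per_group"))
  k <- length(reports)
  per_group$f1 <- per_group$f1 / k
  per_group$precision <- per_group$precision / k
  per_group$recall <- per_group$recall / k
  per_group$support <- NULL; per_group$degenerate <- NULL
  structure(list(
    folds = data.frame(fold = seq_len(k) - 1L,
                       macro_f1 = pull("macro_f1"),
                       overall_mf1 = pull("overall_mf1"),
                       mpr = pull("mpr")),
    macro_f1_mean = mean(pull("macro_f1")), macro_f1_sd = stats::sd(pull("macro_f1")),
    overall_mf1_mean = mean(pull("overall_mf1")), overall_mf1_sd = stats::sd(pull("overall_mf1")),
    mpr_mean = mean(pull("mpr")), mpr_sd = stats::sd(pull("mpr")),
    per_group = per_group),
    class = "fg_cv_metrics")
}

#' @export
print.fg_cv_metrics <- function(x, ...) {
  k <- nrow(x$folds)
  cat(sprintf("<fg_cv_metrics> %d folds\n", k))
  cat(sprintf("macro FG F1 %.3f +/- %.3f | molecular F1 %.3f +/- %.3f | MPR %.3f +/- %.3f\n",
              x$macro_f1_mean, x$macro_f1_sd, x$overall_mf1_mean,
              x$overall_mf1_sd, x$mpr_mean, x$mpr_sd))
  invisible(x)
}

#' Serialize a metrics report
#' @param report an \code{fg_metrics} or \code{fg_cv_metrics}.
#' @param json_path,csv_path optional output paths.
#' @return the report, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  if (!is.null(csv_path)) {
    pg <- report$per_group
    summary_rows <- if (inherits(report, "fg_cv_metrics"))
      data.frame(group = c("macro_f1", "overall_mf1", "mpr"),
                 precision = NA, recall = NA,
                 f1 = c(report$macro_f1_mean, report$overall_mf1_mean,
                        report$mpr_mean))
    else
      data.frame(group = c("macro_f1", "overall_mf1", "mpr"),
                 precision = NA, recall = NA,
                 f1 = c(report$macro_f1, report$overall_mf1, report$mpr))
    common <- intersect(names(pg), names(summary_rows))
    utils::write.csv(rbind(pg[common], summary_rows[common]), csv_path,
                     row.names = FALSE)
  }
  invisible(report)
}
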