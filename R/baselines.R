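#' Accuracy-matched synthetic prediction model
#'
#' A probabilistic baseline that contextualizes the molecular perfection
#' rate: each functional-group bit of each molecule is copied from the truth
#' with that group's accuracy \code{a_g} and flipped otherwise,
#' independently across groups and molecules. Because every bit must be
#' right for a molecule to be perfect, the expected perfection rate is the
#' product of the per-group accuracies — it decays as groups are added even
#' when every individual accuracy is high.
#'
#' The symmetric bit-copy form treats errors on present and absent groups
#' alike; an asymmetric variant taking per-group
#' \code{(sensitivity, specificity)} is available through the two-column
#' form of \code{accuracies}.
#'
#' @param true_labels 0/1 matrix of ground-truth labels.
#' @param accuracies either a numeric vector of per-group accuracies
#'   \code{a_g} (symmetric form), or a two-column matrix
#'   \code{cbind(sensitivity, specificity)} with one row per group.
#' @param seed integer seed.
#' @return 0/1 matrix of simulated predictions, same shape as
#'   \code{true_labels}.
#' @export
synthetic_predict <- function(true_labels, accuracies, seed = 1L) {
  true_labels <- as.matrix(true_labels)
  G <- ncol(true_labels)
  asym <- is.matrix(accuracies)
  acc_names <- if (asym) rownames(accuracies) else names(accuracies)
  if (!is.null(acc_names) && !is.null(colnames(true_labels))) {
    missing <- setdiff(colnames(true_labels), acc_names)
    if (length(missing))
      stop("synthetic_predict: no accuracy for group(s): ",
           paste(missing, collapse = ", "))
    accuracies <- if (asym) accuracies[colnames(true_labels), , drop = FALSE]
                  else accuracies[colnames(true_labels)]
  }
  nacc <- if (asym) nrow(accuracies) else length(accuracies)
  if (nacc != G)
    stop("synthetic_predict: ", nacc, " accuracies for ", G, " groups")
  vals <- if (asym) as.numeric(accuracies) else as.numeric(accuracies)
  if (any(vals < 0 | vals > 1))
    stop("synthetic_predict: accuracies must lie in [0, 1]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  p_correct <- if (asym) {
    # sensitivity applies where the bit is 1, specificity where it is 0
    se <- matrix(accuracies[, 1], nrow(true_labels), G, byrow = TRUE)
    sp <- matrix(accuracies[, 2], nrow(true_labels), G, byrow = TRUE)
    ifelse(true_labels == 1L, se, sp)
  } else {
    matrix(accuracies, nrow(true_labels), G, byrow = TRUE)
  }
  correct <- matrix(stats::runif(length(true_labels)) < p_correct,
                    nrow(true_labels), G)
  pred <- ifelse(correct, true_labels, 1L - true_labels)
  dimnames(pred) <- dimnames(true_labels)
  pred
}

#' Expected molecular perfection rate of the synthetic model
#'
#' Closed form for the symmetric synthetic model: with independent per-group
#' copy probabilities, a molecule is perfect only if every bit is copied
#' correctly, so the expected perfection rate is \code{prod(a_g)} —
#' monotone non-increasing in the number of groups whenever any
#' \code{a_g < 1}.
#'
#' @param accuracies numeric vector of per-group accuracies.
#' @return the expected perfection rate \code{prod(accuracies)}.
#' @export
expected_mpr <- function(accuracies) {
  stopifnot(is.numeric(accuracies), all(accuracies >= 0 & accuracies <= 1))
  prod(accuracies)
}

#' Random-forest comparison baseline
#'
#' One probability forest per functional group (the standard one-vs-rest
#' reduction for ensembles of decision trees), provided solely as a
#' comparison point for the MLP. Groups that are constant in the training
#' labels are predicted constant.
#'
#' @param train_features,train_labels training matrices.
#' @param test_features matrix of rows to score.
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed.
#' @return list with \code{scores} (per-group probability matrix, same
#'   shape contract as [predict_scores()]) and \code{pred} (0/1 matrix at
#'   the fixed 0.5 cutoff).
#' @export
tree_ensemble_baseline <- function(train_features, train_labels,
                                   test_features, n_trees = 100L,
                                   seed = 1L) {
  train_features <- as.matrix(train_features)
  train_labels <- as.matrix(train_labels)
  test_features <- as.matrix(test_features)
  G <- ncol(train_labels)
  scores <- matrix(0, nrow(test_features), G,
                   dimnames = list(NULL, colnames(train_labels)))
  df_tr <- as.data.frame(train_features)
  names(df_tr) <- paste0("f", seq_len(ncol(train_features)))
  df_te <- as.data.frame(test_features)
  names(df_te) <- names(df_tr)
  for (g in seq_len(G)) {
    y <- train_labels[, g]
    if (length(unique(y)) < 2L) {
      scores[, g] <- y[1]
      next
    }
    fit <- ranger::ranger(x = df_tr, y = factor(y, levels = c(0, 1)),
                          num.trees = n_trees, probability = TRUE,
                          seed = seed + g, num.threads = 1L)
    scores[, g] <- stats::predict(fit, data = df_te,
                                  num.threads = 1L)$predictions[, "1"]
  }
  list(scores = scores, pred = apply_thresholds(scores, rep(0.5, G)))
}
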