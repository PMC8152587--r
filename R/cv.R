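#' Cross-validated training and evaluation of the multi-label classifier
#'
#' For each fold: trains the MLP on the other folds, optimizes the
#' per-group thresholds on those same training rows, then evaluates the
#' thresholded predictions on the held-out fold. When \code{latent = TRUE}
#' an autoencoder is first fitted on the pooled training folds only (so no
#' validation spectra leak into the encoder) and the classifier is trained
#' on its 256-dimensional codes.
#'
#' @param dataset a \code{labeled_dataset} with folds assigned
#'   ([assign_folds()]).
#' @param config an [mlp_config()]; each fold derives its own seed from
#'   \code{config$seed} so folds are independent but reproducible.
#' @param latent train on autoencoder codes instead of raw features.
#' @param latent_dim autoencoder embedding width (default 256).
#' @param ae_epochs autoencoder training epochs (default 30).
#' @param keep_models keep the per-fold model objects (default TRUE).
#' @param verbose print per-fold progress.
#' @return object of class \code{fg_cv}: list with \code{metrics}
#'   (an \code{fg_cv_metrics}), \code{fold_reports}, \code{models},
#'   \code{encoders}, \code{predictions} (0/1 matrix of out-of-fold
#'   predictions, aligned with the dataset rows), \code{scores}.
#' @export
crossvalidate <- function(dataset, config = mlp_config(), latent = FALSE,
                          latent_dim = 256L, ae_epochs = 30L,
                          keep_models = TRUE, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(dataset$folds))
    stop("crossvalidate: assign folds first (assign_folds)")
  folds <- sort(unique(dataset$folds))
  n <- nrow(dataset$features)
  pred_all <- matrix(NA_integer_, n, ncol(dataset$labels),
                     dimnames = dimnames(dataset$labels))
  score_all <- matrix(NA_real_, n, ncol(dataset$labels),
                      dimnames = dimnames(dataset$labels))
  reports <- list(); models <- list(); encoders <- list()
  for (f in folds) {
    tr <- which(dataset$folds != f)
    va <- which(dataset$folds == f)
    cfg <- config
    cfg$seed <- config$seed + f
    Xtr <- dataset$features[tr, , drop = FALSE]
    Ytr <- dataset$labels[tr, , drop = FALSE]
    Xva <- dataset$features[va, , drop = FALSE]
    if (latent) {
      ae <- train_autoencoder(Xtr, latent_dim = latent_dim,
                              epochs = ae_epochs, seed = cfg$seed)
      encoders[[as.character(f)]] <- ae
      Xtr_in <- encode_spectra(ae, Xtr)
      Xva_in <- encode_spectra(ae, Xva)
    } else {
      Xtr_in <- Xtr; Xva_in <- Xva
    }
    model <- train_mlp(Xtr_in, Ytr, cfg)
    model <- optimize_thresholds(model, Xtr_in, Ytr)
    sc <- predict_scores(model, Xva_in)
    pr <- apply_thresholds(sc, model$thresholds)
    pred_all[va, ] <- pr
    score_all[va, ] <- sc
    reports[[as.character(f)]] <-
      metrics_report(dataset$labels[va, , drop = FALSE], pr)
    if (keep_models) models[[as.character(f)]] <- model
    if (verbose)
      message(sprintf("fold %d: macro F1 %.3f, MF1 %.3f, MPR %.3f", f,
                      reports[[as.character(f)]]$macro_f1,
                      reports[[as.character(f)]]$overall_mf1,
                      reports[[as.character(f)]]$mpr))
  }
  structure(list(metrics = aggregate_folds(reports),
                 fold_reports = reports,
                 models = if (keep_models) models,
                 encoders = if (latent) encoders,
                 predictions = pred_all, scores = score_all),
            class = "fg_cv")
}

#' @export
print.fg_cv <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}
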