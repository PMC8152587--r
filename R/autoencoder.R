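#' Train the single-layer spectral autoencoder
#'
#' Compresses a standardized spectrum into a 256-dimensional latent code
#' through a single rectified embedding layer, and decodes it back with a
#' linear output layer, minimizing mean squared reconstruction error with
#' Adam. The latent code can replace the raw spectrum as classifier input
#' (see [train_on_latent()]); a useful encoder must reconstruct held-out
#' spectra better than the trivial predictor that always emits the training
#' mean spectrum.
#'
#' @param features numeric matrix of standardized spectra.
#' @param latent_dim embedding width (default 256); must be smaller than the
#'   feature dimension.
#' @param learning_rate,batch_size,epochs Adam hyperparameters.
#' @param seed integer seed; training is deterministic given the seed.
#' @param verbose print per-epoch reconstruction loss.
#' @return object of class \code{fg_autoencoder} with weight matrices and a
#'   \code{training_log} of per-epoch MSE.
#' @export
train_autoencoder <- function(features, latent_dim = 256L,
                              learning_rate = 1e-3, batch_size = 64L,
                              epochs = 30L, seed = 42L, verbose = FALSE) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (latent_dim >= p)
    stop("train_autoencoder: latent_dim (", latent_dim,
         ") must be below the feature dimension (", p, ")")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # inputs are centered by the training mean spectrum: without centering the
  # common baseline dominates every pre-activation and whole rectifier units
  # start (and stay) dead, letting the encoder collapse onto the decoder bias
  center <- colMeans(features)
  Xc <- sweep(features, 2, center, "-")
  W1 <- matrix(stats::rnorm(p * latent_dim, sd = sqrt(2 / p)), p, latent_dim)
  b1 <- numeric(latent_dim)
  W2 <- matrix(stats::rnorm(latent_dim * p, sd = sqrt(1 / latent_dim)),
               latent_dim, p)
  # decoder bias starts at the mean spectrum, so the initial reconstruction
  # already matches the variance baseline and training can only improve on it
  b2 <- center
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  st <- adam_init(params)
  t_adam <- 0L
  log_mse <- numeric(0)
  n <- nrow(features)
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep <- 0
    for (bi in batches) {
      X <- features[bi, , drop = FALSE]
      Xb <- Xc[bi, , drop = FALSE]
      Z <- sweep(Xb %*% params$W1, 2, params$b1, "+")
      H <- pmax(Z, 0)
      Xh <- sweep(H %*% params$W2, 2, params$b2, "+")
      E <- Xh - X
      loss <- mean(E^2)
      if (!is.finite(loss))
        stop("train_autoencoder: non-finite loss at epoch ", epoch)
      dXh <- 2 * E / length(E)
      grads <- list(
        W2 = crossprod(H, dXh), b2 = colSums(dXh),
        W1 = NULL, b1 = NULL)
      dH <- tcrossprod(dXh, params$W2) * (Z > 0)
      grads$W1 <- crossprod(Xb, dH)
      grads$b1 <- colSums(dH)
      t_adam <- t_adam + 1L
      upd <- adam_step(params, grads, st, t_adam, learning_rate)
      params <- upd$params; st <- upd$state
      ep <- ep + loss * nrow(X)
    }
    log_mse <- c(log_mse, ep / n)
    if (verbose) message(sprintf("epoch %3d  MSE %.6f", epoch, ep / n))
  }
  structure(list(W1 = params$W1, b1 = params$b1,
                 W2 = params$W2, b2 = params$b2, center = center,
                 latent_dim = as.integer(latent_dim), input_dim = p,
                 training_log = data.frame(epoch = seq_along(log_mse),
                                           mse = log_mse)),
            class = "fg_autoencoder")
}

#' @export
print.fg_autoencoder <- function(x, ...) {
  cat(sprintf("<fg_autoencoder> %d -> %d -> %d; final MSE %.5f\n",
              x$input_dim, x$latent_dim, x$input_dim,
              utils::tail(x$training_log$mse, 1)))
  invisible(x)
}

#' Encode spectra into the latent space
#' @param ae an \code{fg_autoencoder}.
#' @param features feature matrix (training dimension).
#' @return matrix with \code{latent_dim} columns.
#' @export
encode_spectra <- function(ae, features) {
  stopifnot(inherits(ae, "fg_autoencoder"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != ae$input_dim)
    stop("encode_spectra: feature dimension mismatch")
  Xc <- sweep(as.matrix(features), 2, ae$center, "-")
  pmax(sweep(Xc %*% ae$W1, 2, ae$b1, "+"), 0)
}

#' Decode latent codes back to spectra
#' @param ae an \code{fg_autoencoder}.
#' @param codes latent matrix with \code{latent_dim} columns.
#' @return reconstructed feature matrix.
#' @export
decode_spectra <- function(ae, codes) {
  stopifnot(inherits(ae, "fg_autoencoder"))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  sweep(as.matrix(codes) %*% ae$W2, 2, ae$b2, "+")
}

#' Train the classifier on autoencoder latent codes
#'
#' Encodes the feature rows with a trained autoencoder and fits the same
#' multi-label MLP on the latent codes; the training contract is identical
#' to [train_mlp()] on 256-dimensional inputs.
#'
#' @param ae a trained \code{fg_autoencoder}.
#' @param features raw feature matrix.
#' @param labels 0/1 label matrix.
#' @param config an [mlp_config()].
#' @return an \code{fg_mlp} whose input dimension is \code{ae$latent_dim}.
#' @export
train_on_latent <- function(ae, features, labels, config = mlp_config()) {
  train_mlp(encode_spectra(ae, features), labels, config)
}
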