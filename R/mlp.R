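#' Configuration for the multi-label MLP
#'
#' Defaults are the package's own desk-scale choices: three hidden layers of
#' 512/256/128 rectified units with batch normalization, dropout 0.3, Adam
#' at learning rate 1e-3, batches of 64, up to 50 epochs with early stopping
#' on a held-out slice of the training rows (patience 5).
#'
#' @param hidden_sizes integer vector of hidden layer widths (the standard
#'   model uses 3 layers; \code{integer(0)} yields a plain logistic model,
#'   useful as a linear surrogate).
#' @param dropout_rate dropout probability in [0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param seed integer seed; training is deterministic given the seed.
#' @param patience early-stopping patience in epochs; 0 disables early
#'   stopping.
#' @param validation_fraction fraction of training rows held out to monitor
#'   early stopping (ignored when \code{patience == 0}).
#' @return list of class \code{mlp_config}.
#' @export
mlp_config <- function(hidden_sizes = c(512L, 256L, 128L),
                       dropout_rate = 0.3,
                       learning_rate = 1e-3,
                       batch_size = 64L,
                       epochs = 50L,
                       seed = 42L,
                       patience = 5L,
                       validation_fraction = 0.1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))
.bn_eps <- 1e-5
.bn_momentum <- 0.9

init_mlp <- function(input_dim, output_dim, hidden_sizes) {
  dims <- c(input_dim, hidden_sizes)
  layers <- list()
  for (l in seq_along(hidden_sizes)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1]),
      gamma = rep(1, dims[l + 1]), beta = numeric(dims[l + 1]),
      rm = numeric(dims[l + 1]), rv = rep(1, dims[l + 1]))
  }
  fan_in <- dims[length(dims)]
  out <- list(W = matrix(stats::rnorm(fan_in * output_dim, sd = sqrt(1 / fan_in)),
                         fan_in, output_dim),
              b = numeric(output_dim))
  list(layers = layers, out = out)
}

# Inference-mode forward pass (running batch-norm statistics, no dropout).
# Returns the per-layer post-BN pre-activations when keep_intermediate.
mlp_forward_inference <- function(net, X, keep_intermediate = FALSE) {
  H <- X
  pre <- if (keep_intermediate) vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- H %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    A <- sweep(sweep(Z, 2, ly$rm, "-"), 2, sqrt(ly$rv + .bn_eps), "/")
    A <- sweep(sweep(A, 2, ly$gamma, "*"), 2, ly$beta, "+")
    if (keep_intermediate) pre[[l]] <- A
    H <- pmax(A, 0)
  }
  logits <- sweep(H %*% net$out$W, 2, net$out$b, "+")
  if (keep_intermediate) list(logits = logits, pre = pre) else logits
}

bce_loss <- function(P, Y) {
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}
adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * grads[[k]]
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * grads[[k]]^2
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

flatten_net <- function(net) {
  p <- list()
  for (l in seq_along(net$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      p[[paste0("h", l, "_", nm)]] <- net$layers[[l]][[nm]]
  p$out_W <- net$out$W
  p$out_b <- net$out$b
  p
}
unflatten_net <- function(net, p) {
  for (l in seq_along(net$layers))
    for (nm in c("W", "b", "gamma", "beta"))
      net$layers[[l]][[nm]] <- p[[paste0("h", l, "_", nm)]]
  net$out$W <- p$out_W
  net$out$b <- p$out_b
  net
}

# One minibatch of forward + backward; returns loss, gradients and updated
# running statistics.
mlp_batch_grad <- function(net, X, Y, dropout_rate) {
  L <- length(net$layers)
  m <- nrow(X)
  keep <- 1 - dropout_rate
  Hs <- vector("list", L + 1L); Hs[[1]] <- X
  cache <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    Z <- sweep(H %*% ly$W, 2, ly$b, "+")
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
    zn <- sweep(sweep(Z, 2, mu, "-"), 2, sqrt(v + .bn_eps), "/")
    A <- sweep(sweep(zn, 2, ly$gamma, "*"), 2, ly$beta, "+")
    R <- pmax(A, 0)
    if (dropout_rate > 0) {
      mask <- matrix(stats::runif(length(R)) < keep, nrow(R), ncol(R)) / keep
      D <- R * mask
    } else { mask <- NULL; D <- R }
    cache[[l]] <- list(zn = zn, v = v, mu = mu, A = A, mask = mask)
    net$layers[[l]]$rm <- .bn_momentum * ly$rm + (1 - .bn_momentum) * mu
    net$layers[[l]]$rv <- .bn_momentum * ly$rv + (1 - .bn_momentum) * v
    H <- D
    Hs[[l + 1L]] <- H
  }
  logits <- sweep(H %*% net$out$W, 2, net$out$b, "+")
  P <- sigmoid(logits)
  loss <- bce_loss(P, Y)

  grads <- list()
  dS <- (P - Y) / length(Y)
  grads$out_W <- crossprod(Hs[[L + 1L]], dS)
  grads$out_b <- colSums(dS)
  dH <- tcrossprod(dS, net$out$W)
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dA <- dH * (cc$A > 0)
    grads[[paste0("h", l, "_gamma")]] <- colSums(dA * cc$zn)
    grads[[paste0("h", l, "_beta")]] <- colSums(dA)
    dzn <- sweep(dA, 2, net$layers[[l]]$gamma, "*")
    inv_sd <- 1 / sqrt(cc$v + .bn_eps)
    s1 <- colSums(dzn)
    s2 <- colSums(dzn * cc$zn)
    dZ <- sweep(m * dzn - matrix(s1, m, length(s1), byrow = TRUE) -
                  cc$zn * matrix(s2, m, length(s2), byrow = TRUE),
                2, inv_sd / m, "*")
    grads[[paste0("h", l, "_W")]] <- crossprod(Hs[[l]], dZ)
    grads[[paste0("h", l, "_b")]] <- colSums(dZ)
    dH <- tcrossprod(dZ, net$layers[[l]]$W)
  }
  list(loss = loss, grads = grads, net = net)
}

#' Train the multi-label MLP classifier
#'
#' A feed-forward network mapping a standardized spectrum vector to one
#' sigmoid output per functional group: each hidden layer is dense ->
#' batch-norm -> ReLU -> dropout, trained with the Adam optimizer on the
#' binary cross-entropy loss, which treats every group as an independent
#' (but jointly learned) binary decision and so supports multi-label output.
#' Training is deterministic for a given \code{config$seed}.
#'
#' @param features numeric matrix (rows = compounds, values in [0, 1]).
#' @param labels 0/1 matrix with one column per functional group.
#' @param config an [mlp_config()].
#' @param verbose print per-epoch losses.
#' @return object of class \code{fg_mlp} with elements \code{net} (weights),
#'   \code{config}, \code{groups}, \code{thresholds} (0.5 until
#'   [optimize_thresholds()] is run), and \code{training_log}
#'   (per-epoch training and monitoring loss).
#' @export
train_mlp <- function(features, labels, config = mlp_config(),
                      verbose = FALSE) {
  features <- as.matrix(features); labels <- as.matrix(labels)
  stopifnot(nrow(features) == nrow(labels))
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("g", seq_len(ncol(labels)))
  if (nrow(unique(labels)) < 2L)
    warning("train_mlp: all training rows share one label pattern; ",
            "the fitted model is degenerate")
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  n <- nrow(features)
  use_es <- config$patience > 0L && config$validation_fraction > 0 &&
    n >= 20L
  if (use_es) {
    n_val <- max(1L, floor(config$validation_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    tr_idx <- seq_len(n); val_idx <- integer(0)
  }
  Xt <- features[tr_idx, , drop = FALSE]; Yt <- labels[tr_idx, , drop = FALSE]
  Xv <- features[val_idx, , drop = FALSE]; Yv <- labels[val_idx, , drop = FALSE]

  net <- init_mlp(ncol(features), ncol(labels), config$hidden_sizes)
  params <- flatten_net(net)
  st <- adam_init(params)
  t_adam <- 0L
  log_epoch <- numeric(0); log_loss <- numeric(0); log_val <- numeric(0)
  best <- list(val = Inf, params = params, rs = NULL, epoch = 0L)
  wait <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nrow(Xt))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      if (length(bi) < 2L) next  # batch-norm needs at least 2 rows
      net <- unflatten_net(net, params)
      res <- mlp_batch_grad(net, Xt[bi, , drop = FALSE],
                            Yt[bi, , drop = FALSE], config$dropout_rate)
      if (!is.finite(res$loss))
        stop("train_mlp: non-finite loss at epoch ", epoch,
             " (learning rate too high or degenerate inputs)")
      net <- res$net  # running BN statistics advanced
      t_adam <- t_adam + 1L
      upd <- adam_step(params, res$grads, st, t_adam, config$learning_rate)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + res$loss * length(bi)
    }
    ep_loss <- ep_loss / length(ord)
    net <- unflatten_net(net, params)
    val_loss <- if (use_es)
      bce_loss(sigmoid(mlp_forward_inference(net, Xv)), Yv) else NA_real_
    log_epoch <- c(log_epoch, epoch)
    log_loss <- c(log_loss, ep_loss)
    log_val <- c(log_val, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train BCE %.5f  monitor BCE %s", epoch,
                      ep_loss, ifelse(is.na(val_loss), "-",
                                      sprintf("%.5f", val_loss))))
    if (use_es) {
      if (val_loss < best$val - 1e-6) {
        best <- list(val = val_loss, params = params,
                     rs = lapply(net$layers, function(l) l[c("rm", "rv")]),
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  if (use_es && is.finite(best$val)) {
    params <- best$params
    net <- unflatten_net(net, params)
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$rm <- best$rs[[l]]$rm
      net$layers[[l]]$rv <- best$rs[[l]]$rv
    }
  } else {
    net <- unflatten_net(net, params)
  }
  structure(list(net = net, config = config, groups = colnames(labels),
                 input_dim = ncol(features),
                 thresholds = stats::setNames(rep(0.5, ncol(labels)),
                                              colnames(labels)),
                 training_log = data.frame(epoch = log_epoch,
                                           train_bce = log_loss,
                                           monitor_bce = log_val)),
            class = "fg_mlp")
}

#' @export
print.fg_mlp <- function(x, ...) {
  cat(sprintf("<fg_mlp> %d -> %s -> %d groups; %d epochs trained\n",
              x$input_dim,
              paste(x$config$hidden_sizes, collapse = "-"),
              length(x$groups), nrow(x$training_log)))
  invisible(x)
}

#' Per-group sigmoid scores for new spectra
#'
#' Inference-mode forward pass: dropout disabled, batch normalization using
#' the running statistics accumulated during training, so single-row and
#' batch prediction agree.
#'
#' @param model an \code{fg_mlp}.
#' @param features matrix (or single row vector) with the training feature
#'   dimension.
#' @return matrix of scores in [0, 1], one column per group.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "fg_mlp"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != model$input_dim)
    stop("predict_scores: feature dimension ", ncol(features),
         " does not match the model's expected ", model$input_dim)
  P <- sigmoid(mlp_forward_inference(model$net, features))
  colnames(P) <- model$groups
  P
}
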