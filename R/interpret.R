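#' Guided backpropagation importance profile
#'
#' Computes the gradient of the chosen group's pre-sigmoid output with
#' respect to the input spectrum, propagated with the guided rule: at every
#' rectifier the gradient is zeroed both where the unit was inactive in the
#' forward pass and where the incoming gradient is negative, so only
#' evidence that *increases* the group's activation flows back. At the input
#' the absolute value of the surviving gradient is taken: on transmittance
#' spectra the informative evidence is a *dip*, i.e. a negative input
#' gradient, and the magnitude is what localizes the band. In a
#' rectifier-free linear model there is no hidden unit for the rule to act
#' on, so it is applied at the output unit instead and the profile reduces
#' to the positive part of the group's weight row. Batch-norm layers are
#' treated as frozen affine maps using their inference statistics.
#'
#' The returned importance is non-negative and max-normalized to 1 for
#' cross-molecule comparability; the raw guided gradient is also returned.
#' An all-zero gradient (e.g. an untrained or saturated model) yields a
#' degenerate flat profile with \code{degenerate = TRUE}.
#'
#' @param model an \code{fg_mlp}.
#' @param features a single feature row (vector or 1-row matrix).
#' @param group group name or index.
#' @param bin_centers optional abscissa values for the feature bins
#'   (defaults to the feature index).
#' @param compound_id optional identifier carried into the profile.
#' @return object of class \code{importance_profile}: list with
#'   \code{group}, \code{bin_centers}, \code{importance} (max = 1 unless
#'   degenerate), \code{raw_gradient}, \code{degenerate},
#'   \code{compound_id}.
#' @export
guided_backprop <- function(model, features, group, bin_centers = NULL,
                            compound_id = NA_character_) {
  stopifnot(inherits(model, "fg_mlp"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (nrow(features) != 1L)
    stop("guided_backprop: expected a single feature row")
  if (ncol(features) != model$input_dim)
    stop("guided_backprop: feature dimension mismatch")
  g <- if (is.character(group)) match(group, model$groups) else as.integer(group)
  if (is.na(g) || g < 1L || g > length(model$groups))
    stop("guided_backprop: unknown group: ", group)

  fw <- mlp_forward_inference(model$net, as.matrix(features),
                              keep_intermediate = TRUE)
  L <- length(model$net$layers)
  # seed gradient: d(logit_g)/d(last hidden) = out weight column g
  grad <- matrix(model$net$out$W[, g], nrow = 1L)
  if (L == 0L) {
    # rectifier-free linear model: the guided rule acts at the output unit
    grad <- pmax(as.numeric(grad), 0)
  } else {
    for (l in rev(seq_len(L))) {
      act <- fw$pre[[l]]                     # post-BN pre-ReLU activations
      grad <- grad * (act > 0) * (grad > 0)  # guided rule at the rectifier
      ly <- model$net$layers[[l]]
      # back through the frozen batch-norm affine map, then the dense layer
      grad <- sweep(grad, 2, ly$gamma / sqrt(ly$rv + .bn_eps), "*")
      grad <- tcrossprod(grad, ly$W)
    }
    grad <- abs(as.numeric(grad))            # dips count by their magnitude
  }
  degenerate <- max(grad) <= 0
  importance <- if (degenerate) grad else grad / max(grad)
  structure(list(group = model$groups[g],
                 bin_centers = bin_centers %||% seq_along(importance),
                 importance = importance,
                 raw_gradient = grad,
                 degenerate = degenerate,
                 compound_id = compound_id),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("<importance_profile> group '%s'%s, %d bins%s\n", x$group,
              if (is.na(x$compound_id)) "" else paste0(" (", x$compound_id, ")"),
              length(x$importance),
              if (x$degenerate) " [degenerate: zero gradient]" else ""))
  invisible(x)
}

#' Write an importance profile as CSV
#' @param profile an \code{importance_profile}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(bin_center = profile$bin_centers,
                              importance = profile$importance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Select exemplar molecules for saliency analysis
#'
#' Among validation molecules that are predicted perfectly (predicted set
#' identical to the true set) and that contain the group of interest,
#' returns the top-k by the group's output activation — the molecules the
#' model is most confident about, and hence the cleanest subjects for
#' guided backpropagation.
#'
#' @param model an \code{fg_mlp} with optimized thresholds.
#' @param features validation feature matrix with compound ids as rownames.
#' @param labels validation 0/1 label matrix.
#' @param group group name or index.
#' @param k number of exemplars (default 1).
#' @return character vector of compound ids (row names, or indices as
#'   strings when unnamed), best first; may be shorter than \code{k}.
#' @export
select_exemplars <- function(model, features, labels, group, k = 1L) {
  stopifnot(inherits(model, "fg_mlp"))
  labels <- as.matrix(labels)
  g <- if (is.character(group)) match(group, model$groups) else as.integer(group)
  if (is.na(g)) stop("select_exemplars: unknown group: ", group)
  scores <- predict_scores(model, features)
  pred <- apply_thresholds(scores, model$thresholds)
  perfect <- rowSums(labels != pred) == 0L
  has_group <- labels[, g] == 1L
  cand <- which(perfect & has_group)
  if (length(cand) == 0L) return(character(0))
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  cand <- cand[order(scores[cand, g], decreasing = TRUE)]
  ids[utils::head(cand, k)]
}
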