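# Shared fixtures, all generated in code at test time.

# Linearly separable multi-label fixture: each group g is driven by its own
# block of features (mean shifted when the label is 1), so a small MLP can
# reach near-perfect validation F1.
make_separable <- function(n = 200L, p = 40L, n_groups = 2L, seed = 1L,
                           shift = 1.0, noise = 0.1) {
  withr::with_seed(seed, {
    labels <- matrix(rbinom(n * n_groups, 1L, 0.5), n, n_groups,
                     dimnames = list(NULL, paste0("g", seq_len(n_groups))))
    block <- floor(p / n_groups)
    X <- matrix(rnorm(n * p, sd = noise), n, p)
    for (g in seq_len(n_groups)) {
      cols <- ((g - 1L) * block + 1L):(g * block)
      X[, cols] <- X[, cols] + shift * labels[, g]
    }
    X <- (X - min(X)) / (max(X) - min(X))
    list(features = X, labels = labels)
  })
}

# Minimal raw FTIR spectrum sampled exactly at the centers of a small grid.
tiny_grid <- function() bin_grid(1000, 1400, 4)

ramp_spectrum <- function(grid = tiny_grid(), every = 1L, id = "ramp") {
  ctr <- bin_centers(grid)
  x <- ctr[seq(1L, length(ctr), by = every)]
  y <- seq(0, 1, length.out = length(ctr))[seq(1L, length(ctr), by = every)]
  raw_spectrum(id, "FTIR", x, y, "TRANSMITTANCE")
}

# Independent set-arithmetic oracle for the molecule-level metrics: operates
# on character sets, never on bit vectors, so it shares no code with the
# implementation.
oracle_mf1 <- function(true_names, pred_names) {
  tp <- length(intersect(true_names, pred_names))
  fp <- length(setdiff(pred_names, true_names))
  fn <- length(setdiff(true_names, pred_names))
  if (tp + fp + fn == 0) return(1)
  if (tp == 0) return(0)
  pr <- tp / (tp + fp); re <- tp / (tp + fn)
  2 * pr * re / (pr + re)
}
oracle_perfect <- function(true_names, pred_names)
  as.integer(setequal(true_names, pred_names))

# Threshold oracle: evaluate F1 at every candidate cutpoint (all distinct
# scores, their midpoints, and the extremes), return the best achievable F1.
brute_force_best_f1 <- function(y, s) {
  cand <- sort(unique(c(0, s, 1)))
  mids <- (cand[-1] + cand[-length(cand)]) / 2
  f1 <- function(t) {
    p <- as.integer(s >= t)
    tp <- sum(y & p); fp <- sum(!y & p); fn <- sum(y & !p)
    if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }
  max(vapply(c(cand, mids), f1, numeric(1)))
}

binary_f1 <- function(y, p) {
  tp <- sum(y == 1L & p == 1L); fp <- sum(y == 0L & p == 1L)
  fn <- sum(y == 1L & p == 0L)
  if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
}

# Random (but valid-by-construction) SMILES for property tests.
random_smiles <- function(n = 100L, seed = 7L) {
  alkyl <- c("C", "CC", "CCC", "CC(C)", "CCCC", "CC(C)C")
  mid <- c("", "O", "C(=O)", "C(=O)O", "C(=O)N", "N", "OC", "c1ccccc1", "C=C")
  term <- c("C", "CC", "Cl", "Br", "c1ccccc1", "C#N", "O", "N", "")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste0(sample(alkyl, 1), sample(mid, 1), sample(term, 1)),
      character(1))
  })
}
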