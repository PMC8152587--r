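# Hand-built models with known weights let the guided-backprop closed forms
# be checked exactly.

linear_model <- function(W, b = NULL, groups = paste0("g", seq_len(ncol(W)))) {
  structure(list(
    net = list(layers = list(), out = list(W = W, b = b %||% numeric(ncol(W)))),
    config = mlp_config(hidden_sizes = integer(0)),
    groups = groups, input_dim = nrow(W),
    thresholds = stats::setNames(rep(0.5, ncol(W)), groups),
    training_log = data.frame()), class = "fg_mlp")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a zero-weight model yields a flagged degenerate flat profile", {
  m <- linear_model(matrix(0, 5, 2))
  prof <- guided_backprop(m, rep(0.3, 5), "g1")
  expect_true(prof$degenerate)
  expect_true(all(prof$importance == 0))
})

test_that("guided gradient of a linear model is the positive weight part", {
  W <- matrix(c(0.5, -1, 2, 0, 1.5,
                -2, 3, -1, 0.5, 0), 5, 2)
  m <- linear_model(W)
  prof <- guided_backprop(m, runif(5), "g1")
  expected <- pmax(W[, 1], 0)
  expect_equal(prof$raw_gradient, expected)
  expect_equal(prof$importance, expected / max(expected))
  expect_equal(max(prof$importance), 1)
  expect_error(guided_backprop(m, runif(5), "nope"), "unknown group")
  expect_error(guided_backprop(m, matrix(runif(10), 2), "g1"), "single")
})

test_that("guided gradient equals the numeric gradient on an all-active path", {
  # all-positive weights + positive inputs: every ReLU is active and every
  # backward gradient positive, so the guided gradient is the true gradient
  fx <- make_separable(60L, 8L, 1L, seed = 14)
  m <- train_mlp(fx$features, fx$labels,
                 mlp_config(hidden_sizes = c(6L, 4L), epochs = 3L, seed = 5L))
  for (l in seq_along(m$net$layers)) {
    m$net$layers[[l]]$W <- abs(m$net$layers[[l]]$W)
    m$net$layers[[l]]$b <- abs(m$net$layers[[l]]$b)
    m$net$layers[[l]]$gamma <- abs(m$net$layers[[l]]$gamma) + 0.1
    m$net$layers[[l]]$beta <- abs(m$net$layers[[l]]$beta) + 1
    m$net$layers[[l]]$rm <- m$net$layers[[l]]$rm * 0
  }
  # small output weights keep the logit away from sigmoid saturation so the
  # numeric differentiation of qlogis(score) stays accurate
  m$net$out$W <- abs(m$net$out$W) * 0.05
  x <- withr::with_seed(77, runif(8, 0.4, 0.6))
  prof <- guided_backprop(m, x, 1)
  logit_of <- function(x) stats::qlogis(predict_scores(m, x)[1, 1])
  num <- vapply(1:8, function(j) {
    h <- 1e-5
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    (logit_of(xp) - logit_of(xm)) / (2 * h)
  }, numeric(1))
  expect_true(all(num > 0))
  expect_equal(prof$raw_gradient, num, tolerance = 1e-4)
})

test_that("profiles are reproducible and respect the importance contract", {
  fx <- make_separable(80L, 12L, 2L, seed = 15)
  m <- train_mlp(fx$features, fx$labels,
                 mlp_config(hidden_sizes = c(8L, 6L, 4L), epochs = 10L,
                            seed = 6L))
  p1 <- guided_backprop(m, fx$features[3, ], "g2")
  p2 <- guided_backprop(m, fx$features[3, ], "g2")
  expect_identical(p1$importance, p2$importance)
  expect_true(all(p1$importance >= 0))
  if (!p1$degenerate) expect_equal(max(p1$importance), 1)
})

test_that("exemplar selection keeps only perfect molecules, ranked by activation", {
  groups <- c("g1", "g2")
  withr::with_seed(16, {
    labels <- matrix(rbinom(20 * 2, 1, 0.5), 20, 2,
                     dimnames = list(sprintf("m%02d", 1:20), groups))
    # features carry the labels with a per-row confidence wobble
    conf <- runif(20, 0.05, 0.45)
  })
  features <- ifelse(labels == 1L, 0.5 + conf, 0.5 - conf)
  rownames(features) <- rownames(labels)
  m <- linear_model(diag(2) * 8, b = c(-4, -4), groups = groups)
  # model recovers the labels exactly -> every molecule is perfect
  expect_equal(unname(predict_labels(m, features)), unname(labels))
  sc <- predict_scores(m, features)
  cand <- rownames(labels)[labels[, 1] == 1L]
  brute <- cand[order(sc[cand, 1], decreasing = TRUE)]
  expect_equal(select_exemplars(m, features, labels, "g1", k = 1), brute[1])
  expect_equal(select_exemplars(m, features, labels, "g1", k = 3), brute[1:3])

  # break one molecule's prediction: it must drop out of the candidates
  spoiled <- labels
  spoiled[brute[1], 2] <- 1L - spoiled[brute[1], 2]
  expect_false(brute[1] %in%
                 select_exemplars(m, features, spoiled, "g1", k = 20))
})
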