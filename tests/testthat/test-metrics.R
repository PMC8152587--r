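test_that("molecular F1 reproduces the published mixture worked examples", {
  groups2 <- c("aromatic", "halide", "amide")
  mf1_m2 <- molecular_f1(label_from_set(groups2, groups2),
                         label_from_set(c("aromatic", "halide"), groups2))
  expect_equal(round(mf1_m2, 2), 0.80)

  groups3 <- c("aromatic", "halide", "nitro", "ether", "methyl", "amine")
  mf1_m3 <- molecular_f1(label_from_set(groups3, groups3),
                         label_from_set(c("aromatic", "halide", "amine"),
                                        groups3))
  expect_equal(round(mf1_m3, 2), 0.67)
})

test_that("molecular F1 follows the harmonic-mean formula and conventions", {
  g <- letters[1:7]
  # TP=2, FP=1, FN=2 -> PR=2/3, RE=1/2, MF1=4/7
  truth <- label_from_set(c("a", "b", "c", "d"), g)
  pred <- label_from_set(c("a", "b", "e"), g)
  expect_equal(molecular_f1(truth, pred), 4 / 7)
  expect_equal(molecular_f1(truth, truth), 1.0)
  empty <- label_from_set(character(0), g)
  expect_equal(molecular_f1(empty, empty), 1.0)
  expect_equal(molecular_f1(truth, empty), 0.0)
  expect_equal(molecular_f1(empty, pred), 0.0)
  expect_error(molecular_f1(truth, label_from_set("x", c("x", "y"))),
               "different")
})

test_that("MF1, perfection and group F1 match the set-arithmetic oracle on all 5-group pairs", {
  g <- paste0("fg", 1:5)
  subsets <- lapply(0:31, function(k) g[bitwAnd(k, 2^(0:4)) > 0])
  for (ts in subsets) {
    tv <- label_from_set(ts, g)
    for (ps in subsets) {
      pv <- label_from_set(ps, g)
      expect_identical(molecular_f1(tv, pv), oracle_mf1(ts, ps))
      expect_identical(as.integer(molecular_f1(tv, pv) == 1),
                       oracle_perfect(ts, ps))
    }
  }
  # matrix form agrees with the scalar form
  withr::with_seed(17, {
    truth <- matrix(rbinom(200 * 5, 1, 0.4), 200, 5, dimnames = list(NULL, g))
    pred <- matrix(rbinom(200 * 5, 1, 0.4), 200, 5, dimnames = list(NULL, g))
  })
  rows <- molecular_f1_rows(truth, pred)
  sc <- vapply(1:200, function(i)
    molecular_f1(label_vector(g, truth[i, ]), label_vector(g, pred[i, ])),
    numeric(1))
  expect_equal(rows, sc)
  expect_equal(molecular_perfection_rate(truth, pred), mean(rows == 1))
})

test_that("MF1 is symmetric under swapping false positives and negatives", {
  g <- letters[1:6]
  withr::with_seed(23, {
    for (i in 1:25) {
      tv <- rbinom(6, 1, 0.5); pv <- rbinom(6, 1, 0.5)
      expect_equal(molecular_f1(label_vector(g, tv), label_vector(g, pv)),
                   molecular_f1(label_vector(g, pv), label_vector(g, tv)))
    }
  })
})

test_that("group F1 matches a brute-force confusion-count oracle", {
  withr::with_seed(29, {
    for (rep in 1:50) {
      n <- sample(5:30, 1); ng <- sample(2:6, 1)
      truth <- matrix(rbinom(n * ng, 1, runif(1, 0.2, 0.8)), n, ng,
                      dimnames = list(NULL, paste0("g", 1:ng)))
      pred <- matrix(rbinom(n * ng, 1, runif(1, 0.2, 0.8)), n, ng,
                     dimnames = list(NULL, paste0("g", 1:ng)))
      got <- group_f1(truth, pred)
      for (g in 1:ng) {
        tp <- 0; fp <- 0; fn <- 0
        for (i in 1:n) {        # deliberate elementwise counting oracle
          if (truth[i, g] == 1 && pred[i, g] == 1) tp <- tp + 1
          if (truth[i, g] == 0 && pred[i, g] == 1) fp <- fp + 1
          if (truth[i, g] == 1 && pred[i, g] == 0) fn <- fn + 1
        }
        ef1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
        expect_equal(got$f1[g], ef1)
      }
    }
  })
})

test_that("group F1 edge conventions and closed forms hold", {
  truth <- matrix(c(1, 0, 1, 0, 1, 0), 6, 1, dimnames = list(NULL, "g"))
  expect_equal(group_f1(truth, truth)$f1, 1.0)
  fires <- matrix(1L, 6, 1, dimnames = list(NULL, "g"))
  gf <- group_f1(truth, fires)
  expect_equal(gf$precision, 0.5)  # prevalence of the group
  none <- matrix(0L, 6, 1, dimnames = list(NULL, "g"))
  gd <- group_f1(none, none)
  expect_true(gd$degenerate)
  expect_equal(gd$f1, 1.0)
  g0 <- group_f1(truth, none)
  expect_equal(g0$f1, 0)
})

test_that("overall MF1 dominates MPR and fold aggregation averages correctly", {
  withr::with_seed(31, {
    truth <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4,
                    dimnames = list(NULL, paste0("g", 1:4)))
    pred <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4,
                   dimnames = list(NULL, paste0("g", 1:4)))
  })
  rep1 <- metrics_report(truth, pred)
  expect_gte(rep1$overall_mf1, rep1$mpr)
  rep2 <- metrics_report(truth, truth)
  expect_equal(rep2$mpr, 1.0)
  agg <- aggregate_folds(list(rep1, rep2))
  expect_equal(agg$mpr_mean, mean(c(rep1$mpr, 1)))
  expect_equal(agg$macro_f1_sd, stats::sd(c(rep1$macro_f1, rep2$macro_f1)))
  expect_equal(nrow(agg$folds), 2L)
})

test_that("perfection-rate list form and errors behave", {
  g <- letters[1:3]
  a <- label_from_set("a", g); b <- label_from_set("b", g)
  expect_equal(molecular_perfection_rate(list(list(a, a), list(a, b),
                                              list(b, b), list(a, b))),
               0.5)
  expect_error(molecular_perfection_rate(list()), "non-empty")
})
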