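test_that("JCAMP round trip preserves points in both dialects", {
  s <- raw_spectrum("two-point", "FTIR", c(1000, 1004), c(0.2, 0.9),
                    "TRANSMITTANCE")
  p1 <- withr::local_tempfile(fileext = ".jdx")
  p2 <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(s, p1, dialect = "xydata")
  write_jcamp(s, p2, dialect = "peaktable")
  r1 <- read_jcamp(p1)
  r2 <- read_jcamp(p2)
  expect_length(r1$x, 2L)
  expect_equal(r1$x, s$x, tolerance = 1e-8)
  expect_equal(r1$y, s$y, tolerance = 1e-8)
  # the two encodings of the same points parse to the same spectrum
  expect_equal(r1$x, r2$x, tolerance = 1e-8)
  expect_equal(r1$y, r2$y, tolerance = 1e-8)
  expect_equal(r1$technique, r2$technique)

  ms <- raw_spectrum("frag", "MS", c(43, 58, 71.5), c(100, 50, 10),
                     "ABUNDANCE")
  pm <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(ms, pm)
  rm_ <- read_jcamp(pm)
  expect_equal(rm_$technique, "MS")
  expect_equal(rm_$y_unit, "ABUNDANCE")
  expect_equal(rm_$x, ms$x, tolerance = 1e-8)
})

test_that("JCAMP parse errors are explicit", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(character(0), p)
  expect_error(read_jcamp(p), "empty")

  # a compressed (SQZ-style) ordinate line must be rejected, not misparsed
  writeLines(c("##TITLE=x", "##DATA TYPE=INFRARED SPECTRUM",
               "##FIRSTX=1000", "##LASTX=1008", "##NPOINTS=3",
               "##XYDATA=(X++(Y..Y))", "1000 J05K21L3", "##END="), p)
  expect_error(read_jcamp(p), "unsupported compressed")

  writeLines(c("##TITLE=x", "##DATA TYPE=INFRARED SPECTRUM",
               "##XYDATA=(X++(Y..Y))", "1000 0.5 0.6", "##END="), p)
  expect_error(read_jcamp(p), "spacing")

  writeLines(c("##TITLE=x", "##DATA TYPE=MASS SPECTRUM",
               "##PEAK TABLE=(XY..XY)", "43,100 58", "##END="), p)
  expect_error(read_jcamp(p), "malformed")
})

test_that("FTIR standardization is identity on exactly-sampled spectra", {
  g <- tiny_grid()
  y <- seq(0, 1, length.out = g$n_bins)
  s <- raw_spectrum("id", "FTIR", bin_centers(g), y, "TRANSMITTANCE")
  std <- standardize_ftir(s, g)
  expect_equal(std$values, y, tolerance = 1e-12)
  expect_false(any(std$interpolated_mask))
  expect_length(std$values, g$n_bins)
})

test_that("spline fill reproduces a linear ramp at skipped bins", {
  g <- tiny_grid()
  s <- ramp_spectrum(g, every = 2L)
  std <- standardize_ftir(s, g)
  # sampling every 2nd bin covers bins 1, 3, ..., 99; min-max normalization
  # of the covered means rescales the line to (i-1)/98, and the last bin
  # lies beyond the recorded range, i.e. at the baseline 1.0
  truth <- pmin((seq_len(g$n_bins) - 1) / (g$n_bins - 2), 1)
  # collinear support points: the cubic spline must reproduce the line
  expect_equal(std$values, truth, tolerance = 1e-6)
  expect_true(any(std$interpolated_mask))
  expect_true(all(std$interpolated_mask[seq(2, g$n_bins - 2, 2)]))
})

test_that("degenerate and edge FTIR cases follow the documented conventions", {
  g <- tiny_grid()
  const <- raw_spectrum("c", "FTIR", bin_centers(g), rep(0.37, g$n_bins),
                        "TRANSMITTANCE")
  expect_true(all(standardize_ftir(const, g)$values == 1.0))

  # absorbance input is converted to transmittance before normalization:
  # the most absorbing point becomes the minimum of the output
  ctr <- bin_centers(g)
  a <- raw_spectrum("a", "FTIR", ctr, seq(0, 2, length.out = g$n_bins),
                    "ABSORBANCE")
  va <- standardize_ftir(a, g)$values
  expect_equal(which.min(va), g$n_bins)
  expect_equal(which.max(va), 1L)

  # bins outside the recorded range sit at the transmittance baseline 1.0
  part <- raw_spectrum("p", "FTIR", ctr[10:50],
                       0.2 + 0.5 * sin(seq(0, 3, length.out = 41)),
                       "TRANSMITTANCE")
  vp <- standardize_ftir(part, g)
  expect_true(all(vp$values[c(1:9, 51:g$n_bins)] == 1.0))
  expect_false(any(vp$interpolated_mask[c(1:9, 51:g$n_bins)]))

  expect_error(standardize_ftir(raw_spectrum("m", "MS", 1:5, 1:5,
                                             "ABUNDANCE"), g),
               "not FTIR")
})

test_that("FTIR standardization clips to [0,1] and is idempotent", {
  g <- tiny_grid()
  withr::with_seed(42, {
    for (i in 1:10) {
      n <- sample(50:200, 1)
      x <- sort(runif(n, g$low, g$high))
      y <- runif(n)
      s <- raw_spectrum(paste0("r", i), "FTIR", x, y, "TRANSMITTANCE")
      std <- standardize_ftir(s, g)
      expect_true(all(std$values >= 0 & std$values <= 1))
      expect_length(std$values, g$n_bins)
      again <- standardize_ftir(as_raw(std), g)
      expect_equal(again$values, std$values, tolerance = 1e-12)
    }
  })
})

test_that("MS standardization bins, floors and base-peak normalizes", {
  g <- default_ms_grid()
  s <- raw_spectrum("two", "MS", c(43, 58), c(100, 50), "ABUNDANCE")
  v <- standardize_ms(s, g)$values
  ctr <- bin_centers(g)
  expect_equal(v[floor(ctr) == 43], 1.0)
  expect_equal(v[floor(ctr) == 58], 0.5)
  expect_equal(sum(v > 0), 2L)

  one <- standardize_ms(raw_spectrum("one", "MS", 91, 20, "ABUNDANCE"), g)
  expect_equal(sum(one$values == 1.0), 1L)
  expect_false(any(one$interpolated_mask))

  # fractional m/z accumulate into the floor bin: (12+7)/19 against base 19
  fr <- raw_spectrum("fr", "MS", c(43.2, 43.4, 60.1), c(12, 7, 19),
                     "ABUNDANCE")
  vf <- standardize_ms(fr, g)$values
  expect_equal(vf[floor(ctr) == 43], 19 / 19)
  expect_equal(sum(vf > 0), 2L)

  expect_error(standardize_ms(raw_spectrum("z", "MS", c(10, 20), c(0, 0),
                                           "ABUNDANCE"), g),
               "base peak")
})

test_that("MS standardization preserves abundance rank order and drops out-of-grid peaks", {
  g <- default_ms_grid()
  withr::with_seed(7, {
    mz <- sample(1:640, 20)
    ab <- runif(20, 1, 100)
  })
  s <- raw_spectrum("rank", "MS", mz, ab, "ABUNDANCE")
  v <- standardize_ms(s, g)$values
  got <- v[mz]   # unit grid from m/z 1: bin of integer m/z m is element m
  expect_equal(order(got), order(ab))

  far <- raw_spectrum("far", "MS", c(100, 900), c(10, 99), "ABUNDANCE")
  expect_message(vfar <- standardize_ms(far, g), "dropped 1")
  expect_equal(sum(vfar$values > 0), 1L)
})

test_that("standardized spectra export to a bin-center-headed CSV", {
  g <- tiny_grid()
  specs <- list(
    standardize_ftir(ramp_spectrum(g, id = "a"), g),
    standardize_ftir(raw_spectrum("b", "FTIR", bin_centers(g),
                                  rep(0.5, g$n_bins), "TRANSMITTANCE"), g))
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(specs, p)
  df <- utils::read.csv(p, check.names = FALSE)
  expect_equal(nrow(df), 2L)
  expect_equal(df$compound_id, c("a", "b"))
  expect_equal(names(df)[2], sprintf("ftir_%g", bin_centers(g)[1]))
  expect_equal(as.numeric(df[1, -1]), specs[[1]]$values, tolerance = 1e-12)
  ms <- standardize_ms(raw_spectrum("m", "MS", 43, 10, "ABUNDANCE"))
  expect_error(write_spectra_csv(list(specs[[1]], ms), p), "different grids")
})
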