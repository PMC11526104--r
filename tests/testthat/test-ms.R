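# ms_processing: correction matrices, NNLS correction, MID tables

null_abundances <- function() {
  a <- default_isotope_abundances()
  lapply(a, function(x) 1)   # no heavy isotopes at all
}

test_that("correction matrix degenerates to identity without isotopes", {
  f <- fragment_def("X", "PYR.obs", 1:3, "C3")
  C <- correction_matrix(f, null_abundances(), n_extra = 0L)
  expect_equal(C, diag(4))
})

test_that("single derivatization carbon gives the binomial column", {
  a <- null_abundances()
  a$C <- c(1 - 0.0107, 0.0107)
  f <- fragment_def("X", "CO2.m", 1, "C2")   # 1 skeleton + 1 extra carbon
  C <- correction_matrix(f, a, n_extra = 2L)
  expect_equal(C[, 1], c(1 - 0.0107, 0.0107, 0, 0))
})

test_that("column 0 equals the theoretical natural MID (polynomial oracle)", {
  f <- fragment_def("ALA", "ALA.obs", 1:3, "C11H26NO2Si2")
  C <- correction_matrix(f)
  # independent oracle: polynomial expansion via stats::convolve (FFT),
  # over the non-skeleton atoms C8 H26 N O2 Si2
  ab <- default_isotope_abundances()
  poly <- 1
  for (el in list(c("C", 8), c("H", 26), c("N", 1), c("O", 2), c("Si", 2))) {
    d <- ab[[el[1]]]
    for (i in seq_len(as.integer(el[2])))
      poly <- stats::convolve(poly, rev(d), type = "open")
  }
  expect_equal(C[, 1], poly[1:nrow(C)], tolerance = 1e-12)
  expect_true(all(colSums(C) <= 1 + 1e-12))
})

test_that("correct_mid inverts the convolution exactly and under noise", {
  frags <- default_fragment_library()
  f <- frags$GLU_3tbdms
  C <- correction_matrix(f)
  set.seed(4)
  x <- skeleton_mid(f$n_skeleton)
  raw <- as.vector(C %*% x)
  out <- correct_mid(raw, f, sd = rep(0.003, length(raw)))
  expect_equal(out$mid, x, tolerance = 1e-10)
  expect_true(all(out$mid >= 0))
  # unlabeled sample: the raw natural MID corrects to a delta at M0
  out0 <- correct_mid(C[, 1], f)
  expect_equal(out0$mid, c(1, rep(0, f$n_skeleton)), tolerance = 1e-10)
  # Monte-Carlo: mean corrected MID unbiased within 2 standard errors
  nrep <- 200
  acc <- matrix(0, nrep, f$n_skeleton + 1)
  for (i in seq_len(nrep)) {
    noisy <- raw + stats::rnorm(length(raw), 0, 0.003)
    acc[i, ] <- correct_mid(pmax(noisy, 0), f)$mid
  }
  se <- apply(acc, 2, stats::sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(acc) - x) <= 2.5 * se + 1e-4))
})

test_that("round-trip property holds for every fragment in the library", {
  frags <- default_fragment_library()
  set.seed(9)
  for (f in frags) {
    C <- correction_matrix(f)
    for (i in 1:20) {
      x <- skeleton_mid(f$n_skeleton)
      got <- correct_mid(as.vector(C %*% x), f)$mid
      expect_lt(max(abs(got - x)), 1e-10)
    }
  }
})

test_that("mid tables validate and round-trip", {
  df <- data.frame(
    fragment_id = rep(c("ALA_2tbdms", "LAC_2tbdms"), each = 4),
    replicate = 1L, time_h = 24,
    mass_shift = rep(0:3, 2),
    fraction = rep(c(0.7, 0.2, 0.08, 0.02), 2),
    sd = 0.003)
  path <- tempfile(fileext = ".csv")
  write_mid_table(df, path)
  frags <- default_fragment_library()
  got <- read_mid_table(path, frags)
  expect_equal(nrow(got), 8)
  expect_equal(sort(unique(got$fragment_id)),
               c("ALA_2tbdms", "LAC_2tbdms"))

  bad <- df; bad$fraction[3] <- -0.01
  write_mid_table(bad, path)
  expect_error(read_mid_table(path), "negative mass fraction")

  dup <- rbind(df, df[1, ])
  write_mid_table(dup, path)
  expect_error(read_mid_table(path), "duplicate")

  expect_error(read_mid_table(textConnection("a,b\n1,2")), "missing column")
})

test_that("prepare_mids averages replicates with the SD floor", {
  frags <- default_fragment_library()
  f <- frags$LAC_2tbdms
  C <- correction_matrix(f)
  x <- c(0.3, 0.05, 0.05, 0.6)
  raw <- as.vector(C %*% x)
  rows <- do.call(rbind, lapply(1:3, function(r)
    data.frame(fragment_id = "LAC_2tbdms", replicate = r, time_h = 24,
               mass_shift = seq_along(raw) - 1L, fraction = raw, sd = 0.003)))
  got <- prepare_mids(rows, frags, time_h = 24)
  expect_length(got, 1)
  expect_equal(got[[1]]$mid, x, tolerance = 1e-8)
  expect_true(all(got[[1]]$sd >= 0.003))     # identical reps hit the floor
  blocks <- prepare_mids(rows, frags, time_h = 24, replicate_mode = "blocks")
  expect_length(blocks, 3)
})
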