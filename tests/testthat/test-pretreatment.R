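test_that("SNV centers and scales each spectrum to mean 0, sample SD 1", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "constant")
  set.seed(3)
  x <- rnorm(451, 0.5, 0.2)
  z <- snv(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
})

test_that("MSC matches the per-row least-squares oracle and fixes exact scatter", {
  set.seed(11)
  m <- sort(runif(20))
  a <- runif(5, -0.2, 0.2); b <- runif(5, 0.5, 2)
  X <- outer(a, rep(1, 20)) + outer(b, m)
  fit <- msc_fit(X)
  # rows that are exact affine images of the reference collapse onto it
  for (i in 1:5)
    expect_equal(unname(fit$corrected[i, ]), fit$reference, tolerance = 1e-9)
  # the reference spectrum itself passes through unchanged
  expect_equal(unname(msc_apply(fit$reference, fit$reference)),
               fit$reference)
  # random matrix: corrected rows equal (x - a_i)/b_i with (a_i, b_i) from lm
  Xr <- matrix(rnorm(5 * 20, 1, 0.3), 5)
  fr <- msc_fit(Xr)
  for (i in 1:5) {
    cf <- coef(lm(Xr[i, ] ~ fr$reference))
    expect_equal(unname(fr$corrected[i, ]),
                 unname((Xr[i, ] - cf[1]) / cf[2]), tolerance = 1e-10)
  }
})

test_that("detrend annihilates quadratics and leaves orthogonal residuals", {
  wl <- seq(1100, 2000, 2)
  x <- 3 + 0.01 * wl - 2e-6 * wl^2
  expect_lt(max(abs(detrend(x, wl))), 1e-9)
  set.seed(5)
  xr <- rnorm(length(wl))
  d <- detrend(xr, wl)
  for (basis in list(rep(1, length(wl)), wl, wl^2))
    expect_lt(abs(sum(d * basis)) / sqrt(sum(basis^2)) / sd(xr), 1e-8)
  # matches an explicit polynomial-fit-and-subtract oracle
  expect_equal(unname(d), unname(resid(lm(xr ~ wl + I(wl^2)))),
               tolerance = 1e-9)
})

test_that("gap-segment derivative follows the gap-difference definition", {
  wl <- seq_len(40) * 2 + 1098
  x <- seq_len(40)  # unit increments per channel
  # identity code
  id <- gap_segment_derivative(x, wl, 0, 0, 1, 1)
  expect_equal(id$X, x)
  expect_equal(id$wavelengths, wl)
  # first derivative, gap 4: x(i+2) - x(i-2) = 4 everywhere valid
  d1 <- gap_segment_derivative(x, wl, 1, 4, 1, 1)
  expect_true(all(d1$X == 4))
  expect_length(d1$X, 36)
  expect_equal(d1$wavelengths, wl[3:38])  # midpoints of symmetric gap
  # odd gap: forward ceiling, backward floor
  d3 <- gap_segment_derivative(x, wl, 1, 3, 1, 1)
  expect_true(all(d3$X == 3))
  expect_length(d3$X, 37)
  # derivative of a constant is zero
  dc <- gap_segment_derivative(rep(7, 40), wl, 2, 4, 3, 3)
  expect_true(all(abs(dc$X) < 1e-12))
  # window bookkeeping errors
  expect_error(gap_segment_derivative(x[1:3], wl[1:3], 1, 4, 1, 1), "length")
  expect_error(gap_segment_derivative(x, wl, 1, 0, 1, 1), "gap")
})

test_that("boxcar smoothing averages consecutive channels and trims edges", {
  wl <- seq(1100, 1118, 2)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  sm <- gap_segment_derivative(x, wl, 0, 0, 4, 1)
  expect_equal(sm$X, c(2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5))
  expect_equal(sm$wavelengths, (wl[1:7] + wl[4:10]) / 2)
  expect_equal(diff(sm$wavelengths), rep(2, 6))  # grid stays uniform
})

test_that("treatment strings parse exactly as printed in calibration tables", {
  t1 <- math_treatment("Standard MSC 1,4,4,1")
  expect_equal(t1$scatter, "msc")
  expect_equal(c(t1$d, t1$g, t1$s1, t1$s2), c(1, 4, 4, 1))
  expect_equal(math_treatment("SNV only 2,4,4,1")$scatter, "snv")
  expect_equal(math_treatment("None 0,0,1,1")$scatter, "none")
  expect_equal(math_treatment("Detrend only 2,10,10,1")$scatter, "detrend")
  expect_equal(math_treatment("SNV-DT 1,4,4,1")$scatter, "snv_detrend")
  expect_equal(math_treatment("snv only2,4,4,1")$scatter, "snv")  # Cr-style
  expect_error(math_treatment("Fourier 1,4,4,1"), "unknown")
  expect_error(math_treatment("SNV only 1,0,1,1"), "gap 0")
})

test_that("apply_treatment composes scatter then derivative and replays state", {
  ds <- default_dataset()
  X <- average_replicates(ds$spectra)$absorbance[1:12, ]
  wl <- ds$spectra$wavelengths
  # derivative-only: no scatter state involved
  tr <- apply_treatment("None 1,4,4,1", X, wl)
  direct <- gap_segment_derivative(X, wl, 1, 4, 4, 1)
  expect_equal(tr$X, rbind(direct$X))
  expect_equal(tr$wavelengths, direct$wavelengths)
  # SNV then second derivative
  tr2 <- apply_treatment("SNV only 2,4,4,1", X, wl)
  expect_equal(tr2$X, rbind(gap_segment_derivative(snv(X), wl, 2, 4, 4, 1)$X))
  # stored state reproduces training output bit for bit
  tr3 <- apply_treatment("Standard MSC 1,4,4,1", X, wl)
  replay <- apply_treatment("Standard MSC 1,4,4,1", X, wl, state = tr3$state)
  expect_identical(replay$X, tr3$X)
  # grid mismatch is refused at prediction time
  expect_error(apply_treatment("Standard MSC 1,4,4,1", X[, -1], wl[-1],
                               state = tr3$state), "grid")
})

test_that("pretreatments commute with row permutation (MSC state shared)", {
  ds <- default_dataset()
  X <- average_replicates(ds$spectra)$absorbance[1:10, ]
  wl <- ds$spectra$wavelengths
  perm <- c(4, 1, 9, 10, 2, 3, 7, 5, 8, 6)
  for (tr in c("SNV only 1,4,4,1", "Detrend only 2,4,4,1",
               "Standard MSC 0,0,1,1")) {
    a <- apply_treatment(tr, X, wl)
    b <- apply_treatment(tr, X[perm, ], wl)
    expect_equal(unname(b$X), unname(a$X[perm, ]), tolerance = 1e-12)
  }
})
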