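test_that("MPLS with unit scalings equals the Krylov-subspace PLS1 oracle", {
  set.seed(101)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 50), 30)
    y <- rnorm(30)
    f <- sample(2:6, 1)
    m <- fit_mpls(X, y, f, residual_scaling = FALSE)
    oracle <- pls1_krylov(X, y, f)
    cf <- mpls_coefficients(m)
    scale_ref <- max(abs(oracle$b))
    expect_lt(max(abs(cf$b - oracle$b)) / scale_ref, 1e-8)
    expect_lt(abs(cf$b0 - oracle$b0) / max(1, abs(oracle$b0)), 1e-6)
    expect_equal(unname(predict(m, X)),
                 drop(X %*% oracle$b) + oracle$b0, tolerance = 1e-8)
  }
})

test_that("factor recursion and collapsed linear form agree for MPLS", {
  set.seed(103)
  X <- matrix(rnorm(25 * 40), 25)
  y <- rnorm(25)
  m <- fit_mpls(X, y, 6)  # residual scaling on
  Xnew <- matrix(rnorm(10 * 40), 10)
  p_rec <- predict(m, Xnew, method = "recursion")
  p_lin <- predict(m, Xnew, method = "linear")
  expect_lt(max(abs(p_rec - p_lin)) / sd(y), 1e-8)
  # training replay reproduces fitted values
  expect_equal(unname(predict(m, X)), m$fitted, tolerance = 1e-10)
  # the training center predicts the training mean
  expect_equal(unname(predict(m, rbind(m$x_center))), m$y_center)
})

test_that("degenerate factor counts behave as documented", {
  set.seed(107)
  X <- matrix(rnorm(12 * 20), 12)
  y <- rnorm(12)
  m0 <- fit_mpls(X, y, 0)
  expect_true(all(predict(m0, X) == mean(y)))
  expect_error(fit_mpls(X, y, 12), "exceeds")
  expect_error(fit_mpls(X, rep(1, 12), 2), "zero variance")
  # noiseless single-band signal is fit perfectly with one factor
  band <- exp(-(seq(0, 1, length.out = 20) - 0.5)^2 / 0.02)
  a <- rnorm(12)
  m1 <- fit_mpls(outer(a, band), 2 + 3 * a, 1)
  expect_lt(rmse(m1$fitted - (2 + 3 * a)), 1e-8 * sd(2 + 3 * a))
})

test_that("RMSEC is non-increasing in the number of factors", {
  set.seed(109)
  X <- matrix(rnorm(30 * 45), 30)
  y <- rnorm(30)
  for (scaling in c(TRUE, FALSE)) {
    rmsec <- vapply(1:10, function(f)
      rmse(fit_mpls(X, y, f, residual_scaling = scaling)$fitted - y),
      numeric(1))
    expect_true(all(diff(rmsec) <= 1e-10))
  }
})

test_that("six-group cross-validation predicts every sample exactly once", {
  groups <- mplsnir:::cv_groups(71, 6, seed = 17)
  expect_length(groups, 71)
  expect_setequal(unique(groups), 1:6)
  expect_true(all(table(groups) %in% c(11, 12)))
  # every sample receives exactly one held-out prediction
  blk <- calibration_block("K")
  cv <- cross_validate(blk$X, blk$y, blk$wavelengths, "None 0,0,1,1",
                       seed = 17, max_factors = 8)
  expect_length(cv$predictions, length(blk$y))
  expect_false(anyNA(cv$predictions))
  expect_equal(cv$rmsecv[cv$n_factors + 1],
               sqrt(mean((cv$predictions - blk$y)^2)))
})

test_that("small-sample grouped CV equals the fold-by-fold brute force", {
  tb <- two_band_set(12, seed = 53)
  groups <- rep(1:6, each = 2)
  cv <- cross_validate(tb$X, tb$y, tb$wl, "SNV only 0,0,1,1",
                       groups = groups, max_factors = 3)
  # brute force: same folds, pretreat and fit by hand
  for (f in 1:3) {
    pred <- numeric(12)
    for (g in 1:6) {
      hold <- groups == g
      tr <- apply_treatment("SNV only 0,0,1,1", tb$X[!hold, ], tb$wl)
      te <- apply_treatment("SNV only 0,0,1,1", tb$X[hold, ], tb$wl,
                            state = tr$state)
      m <- fit_mpls(tr$X, tb$y[!hold], f)
      pred[hold] <- predict(m, te$X)
    }
    expect_equal(cv$rmsecv[f + 1], sqrt(mean((pred - tb$y)^2)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless three-band mixtures cross-validate essentially perfectly", {
  set.seed(61)
  wl <- seq(1100, 2000, 2)
  shapes <- sapply(c(1300, 1550, 1800), function(ctr)
    exp(-(wl - ctr)^2 / (2 * 25^2)))
  A <- matrix(runif(36 * 3), 36)
  X <- A %*% t(shapes) + 0.2
  y <- drop(A %*% c(3, -2, 1)) + 5
  cv <- cross_validate(X, y, wl, "None 0,0,1,1", seed = 3, max_factors = 5)
  expect_lte(cv$rmsecv[4], 0.01 * sd(y))
})

test_that("statistics are invariant to sample order given mapped folds", {
  blk <- calibration_block("P")
  n <- length(blk$y)
  groups <- mplsnir:::cv_groups(n, 6, seed = 23)
  set.seed(77)
  perm <- sample(n)
  cv1 <- cross_validate(blk$X, blk$y, blk$wavelengths, "SNV only 1,4,4,1",
                        groups = groups, max_factors = 8)
  cv2 <- cross_validate(blk$X[perm, ], blk$y[perm], blk$wavelengths,
                        "SNV only 1,4,4,1", groups = groups[perm],
                        max_factors = 8)
  expect_equal(cv2$rmsecv, cv1$rmsecv, tolerance = 1e-10)
  expect_equal(cv2$n_factors, cv1$n_factors)
  expect_equal(cv2$predictions, cv1$predictions[perm], tolerance = 1e-10)
})

test_that("calibration with elimination reports bookkeeping that adds up", {
  blk <- calibration_block("K")
  cal <- fit_with_elimination(blk$X, blk$y, blk$wavelengths,
                              "None 1,4,4,1", ids = blk$ids, seed = 19)
  expect_equal(cal$summary$N, cal$n_input - nrow(cal$outliers))
  expect_true(all(cal$outliers$reason %in% c("H", "T")))
  expect_false(any(cal$outliers$sample_id %in% cal$ids))
  # clean synthetic data loses only a few samples
  expect_lte(nrow(cal$outliers), 8)
  expect_equal(cal$summary$rpd, cal$summary$sd / cal$summary$rmsecv)
})

test_that("models serialize to JSON and reload to identical predictions", {
  blk <- calibration_block("Zn")
  cal <- fit_with_elimination(blk$X, blk$y, blk$wavelengths,
                              "SNV only 2,4,4,1", ids = blk$ids, seed = 29,
                              max_factors = 8)
  f <- withr::local_tempfile(fileext = ".json")
  mpls_to_json(cal, f)
  back <- mpls_from_json(f)
  expect_equal(predict_calibration(back, blk$X),
               predict_calibration(cal, blk$X), tolerance = 1e-12)
  expect_equal(back$treatment$label, cal$treatment$label)
})

test_that("coefficient extrema report the largest |beta| wavelengths", {
  m <- structure(list(x_center = rep(0, 451), y_center = 0,
                      coef = list(b = rep(0, 451), b0 = 0),
                      n_factors = 1,
                      wavelengths = seq(1100, 2000, 2)),
                 class = "mpls_model")
  m$coef$b[116] <- 5    # 1330 nm
  m$coef$b[229] <- -7   # 1556 nm
  ce <- coefficient_extrema(m, top_k = 2)
  expect_equal(ce$wavelength, c(1556, 1330))
  expect_equal(ce$beta, c(-7, 5))
})
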