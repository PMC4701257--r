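test_that("the default cohort reproduces the study layout", {
  ds <- default_dataset()
  expect_equal(length(ds$reference$sample_ids), 91)
  region <- ds$truth$region
  expect_equal(unname(table(region)[c("Chile", "Galicia", "Castilla-Leon")]),
               c(52, 16, 23), ignore_attr = TRUE)
  expect_length(ds$truth$calibration_ids, 71)
  expect_length(ds$truth$validation_ids, 20)
  expect_equal(nrow(ds$spectra$absorbance), 91 * 3)
  expect_equal(length(ds$spectra$wavelengths), 451)
})

test_that("sampled concentrations respect the configured regional ranges", {
  ds <- default_dataset()
  conc <- ds$reference$concentrations
  region <- ds$truth$region
  comp <- regional_composition()
  for (i in seq_len(nrow(comp))) {
    if (is.na(comp$lo[i])) next
    v <- conc[region == comp$region[i], comp$element[i]]
    v <- v[!is.na(v)]
    expect_true(all(v >= comp$lo[i] & v <= comp$hi[i]),
                label = paste(comp$element[i], comp$region[i], "in range"))
  }
  # Cu/Ni/Pb carry below-LOQ flags at the configured fraction
  expect_gt(sum(ds$reference$below_loq[, c("Cu", "Ni", "Pb")]), 0)
  expect_equal(sum(ds$reference$below_loq[, "K"]), 0)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 33)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1$reference$concentrations, d2$reference$concentrations)
  expect_identical(d1$spectra$absorbance, d2$spectra$absorbance)
  expect_identical(d1$truth$validation_ids, d2$truth$validation_ids)
  # written CSVs are byte-identical across runs
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  make_dataset(cfg, dir = t1)
  make_dataset(cfg, dir = t2)
  for (f in c("spectra.csv", "reference.csv"))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
  # a different seed changes the draw
  d3 <- make_dataset(synthetic_config(seed = 34))
  expect_false(identical(d1$reference$concentrations,
                         d3$reference$concentrations))
})

test_that("copula calibration lands moderate correlation targets on the raw scale", {
  big <- sample_concentrations(synthetic_config(
    n_samples = 3000, n_validation = 20, nd_fraction = 0, seed = 3))
  obs <- correlation_matrix(big)$r
  tgt <- default_correlations()
  nz <- which(upper.tri(tgt) & tgt != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i <- nz[k, 1]; j <- nz[k, 2]
    # all stated associations reproduce in sign
    expect_equal(sign(obs[i, j]), sign(tgt[i, j]),
                 label = paste(rownames(tgt)[i], colnames(tgt)[j], "sign"))
    if (abs(tgt[i, j]) <= 0.6)  # moderate pairs: close on the raw scale
      expect_lt(abs(obs[i, j] - tgt[i, j]), 0.15,
                label = paste(rownames(tgt)[i], colnames(tgt)[j]))
  }
  # the two strongest targets give the two strongest observed correlations
  diag(obs) <- 0
  top2 <- sort(obs[upper.tri(obs)], decreasing = TRUE)[1:2]
  expect_setequal(round(top2, 10),
                  round(c(obs["Ca", "Mg"], obs["Cr", "Ni"]), 10))
  expect_gt(obs["Ca", "Mg"], 0.75)
  expect_gt(obs["Cr", "Ni"], 0.75)
})

test_that("noise- and scatter-free spectra are exactly the linear mixture", {
  cfg <- synthetic_config(seed = 51, nd_fraction = 0)
  ref <- sample_concentrations(cfg)
  sp <- generate_spectra(ref, cfg, clean = TRUE)
  # doubling one element's concentration doubles its band contribution
  ref2 <- ref
  ref2$concentrations[, "K"] <- 2 * ref$concentrations[, "K"]
  sp2 <- generate_spectra(ref2, cfg, clean = TRUE)
  delta <- sp2$absorbance - sp$absorbance
  prof <- mplsnir:::band_profile(cfg$wavelengths, cfg$bands)[, "K"]
  expect_equal(unname(delta),
               unname(outer(ref$concentrations[, "K"], prof)),
               tolerance = 1e-12)
  # clean spectra lie exactly in the span of baseline, interferents and
  # band shapes: per-sample concentrations are recoverable by least squares
  profs <- mplsnir:::band_profile(cfg$wavelengths, cfg$bands)
  interf <- mplsnir:::interferent_profiles(cfg$wavelengths)
  base <- mplsnir:::synthetic_baseline(cfg$wavelengths)
  fitted <- lm.fit(cbind(base, interf, profs), t(sp$absorbance))
  est <- t(fitted$coefficients)
  expect_lt(max(abs(fitted$residuals)), 1e-8)
  for (el in c("K", "P", "Zn"))
    expect_equal(unname(est[, el]), unname(ref$concentrations[, el]),
                 tolerance = 1e-6)
})

test_that("scatter corrections remove the injected multiplicative/additive variance", {
  # replicate disagreement ratio: within-replicate variance over total,
  # for a draw whose replicate artifacts are mult/add scatter only
  cfg <- synthetic_config(seed = 61, scatter_tilt_sd = 0,
                          noise_sd = 1e-5)
  ds <- make_dataset(cfg)
  M <- ds$spectra$absorbance
  repof <- ds$spectra$replicate_of
  ratio <- function(M) {
    wv <- mean(unlist(tapply(seq_len(nrow(M)), repof, function(i) {
      C <- scale(M[i, , drop = FALSE], scale = FALSE); mean(C^2)
    })))
    wv / mean(scale(M, scale = FALSE)^2)
  }
  r_raw <- ratio(M)
  expect_gte(1 - ratio(snv(M)) / r_raw, 0.95)
  expect_gte(1 - ratio(msc_fit(M)$corrected) / r_raw, 0.95)
})

test_that("cross-validation error degrades monotonically with instrument noise", {
  rmsecv_at <- function(noise) {
    cfg <- synthetic_config(seed = 71, noise_sd = noise)
    ds <- make_dataset(cfg)
    sp <- average_replicates(ds$spectra)
    blk <- align_element(sp[ds$truth$calibration_ids], ds$reference, "K")
    cv <- cross_validate(blk$X, blk$y, blk$wavelengths, "SNV only 1,4,4,1",
                         seed = 7, max_factors = 10)
    cv$rmsecv[cv$n_factors + 1]
  }
  ladder <- vapply(c(0.002, 0.01, 0.05), rmsecv_at, numeric(1))
  expect_true(all(diff(ladder) > 0))
})
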