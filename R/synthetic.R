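#' Regional composition statistics emulated by the generator
#'
#' Per-region means and observed ranges (mg/kg) of the eleven elements in
#' propolis from the three source regions the generator emulates (Bio-Bio,
#' Chile; Galicia and Castilla-Leon, Spain).  A lower bound of `NA` marks
#' elements whose lowest values fall below the quantification limit of the
#' reference method.
#'
#' @return Data frame with columns `element`, `region`, `mean`, `lo`, `hi`.
#' @export
regional_composition <- function() {
  rows <- list(
    #         element  Chile: mean lo hi      Galicia            Castilla-Leon
    list("Al", 354.9, 156.0, 833.9,  105.2, 43.0, 193.7,  213.2, 78.6, 518.4),
    list("Ca", 910.4, 274.0, 5173.0, 563.2, 219.1, 1176.1, 847.3, 416.7, 2169.2),
    list("Fe", 536.6, 181.8, 1538.0, 245.8, 46.1, 656.7,  295.8, 104.5, 874.0),
    list("K",  550.0, 267.0, 1841.2, 1522.1, 359.0, 3182.1, 1569.4, 685.9, 4428.3),
    list("Mg", 261.8, 75.1, 1398.0,  206.4, 63.5, 427.0,  190.6, 88.2, 460.3),
    list("P",  228.8, 118.1, 402.0,  307.5, 152.3, 729.0, 198.5, 116.0, 327.7),
    list("Cr", 3.1, 1.4, 5.5,        2.7, 0.8, 7.5,       5.7, 2.3, 48.9),
    list("Cu", 1.6, NA, 6.2,         5.4, NA, 33.4,       2.8, NA, 7.2),
    list("Ni", 1.2, NA, 9.7,         1.4, 0.5, 4.0,       2.4, 0.6, 29.9),
    list("Pb", 2.6, NA, 8.0,         2.2, NA, 6.0,        15.5, NA, 74.0),
    list("Zn", 57.8, 5.5, 105.0,     89.8, 17.4, 460.7,   54.4, 11.1, 145.3))
  regions <- c("Chile", "Galicia", "Castilla-Leon")
  do.call(rbind, lapply(rows, function(r) data.frame(
    element = r[[1]], region = regions,
    mean = unlist(r[c(2, 5, 8)]), lo = unlist(r[c(3, 6, 9)]),
    hi = unlist(r[c(4, 7, 10)]), stringsAsFactors = FALSE)))
}

#' Default inter-element correlation targets
#'
#' The pairwise Pearson correlations the concentration sampler aims for:
#' the strong Ca-Mg and Cr-Ni associations, the Fe cluster (Al, Ca, Mg,
#' Zn), and the positive and negative K associations; unlisted pairs are 0.
#' The matrix is projected to the nearest positive-definite correlation
#' matrix before use.
#'
#' @return Symmetric 11 x 11 correlation matrix.
#' @export
default_correlations <- function() {
  el <- nir_elements
  R <- diag(length(el)); dimnames(R) <- list(el, el)
  set <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set("Ca", "Mg", 0.97); set("Cr", "Ni", 0.90)
  set("Fe", "Al", 0.57); set("Fe", "Ca", 0.36); set("Fe", "Mg", 0.35)
  set("Fe", "Zn", 0.31); set("Mg", "P", 0.31)
  set("K", "Pb", 0.33); set("K", "P", 0.28); set("K", "Cu", 0.26)
  set("K", "Al", -0.29); set("K", "Fe", -0.32)
  R
}

#' Default element absorption-band library
#'
#' Each element contributes two Gaussian bands, centered at the wavelengths
#' where NIR regression coefficients for these elements peak (reflecting the
#' association of the minerals with flavonoid and O-H chromophores).
#' Amplitudes are in absorbance units per mg/kg, scaled so that at the
#' default concentration spreads the spectral signal spans from strong
#' (K, P, Zn) to weak (Cr, Ni) relative to the default noise.
#'
#' @return Data frame with columns `element`, `center` (nm), `width` (nm,
#'   Gaussian SD), `amplitude` (absorbance per mg/kg).
#' @export
default_bands <- function() {
  b <- function(element, c1, c2, amp, w = 10)
    data.frame(element = element, center = c(c1, c2), width = w,
               amplitude = c(amp, -0.8 * amp), stringsAsFactors = FALSE)
  rbind(
    b("Al", 1330, 1556, 1.0e-4),
    b("Ca", 1500, 1542, 3.5e-5),
    b("Fe", 1228, 1112, 6.5e-5),
    b("K",  1481, 1224, 5.0e-5),
    b("Mg", 1520, 1532, 1.2e-4),
    b("P",  1554, 1968, 5.0e-4),
    b("Cr", 1366, 1590, 1.2e-3),
    b("Cu", 1244, 1356, 1.2e-3),
    b("Ni", 1520, 1558, 1.8e-3),
    b("Pb", 1820, 1968, 1.2e-3),
    b("Zn", 1816, 1976, 1.0e-3))
}

#' Configuration of the synthetic propolis dataset generator
#'
#' Collects every knob of the generator: cohort size and regional makeup,
#' the per-region concentration distributions (truncated log-normal, matched
#' by moment adjustment to the regional means and ranges), the inter-element
#' correlation targets (imposed through a Gaussian copula), the absorption
#' band library, scatter and noise magnitudes, and the replicate layout.
#'
#' @param n_samples total cohort size (default 91).
#' @param regions named integer vector of per-region counts (default
#'   Chile 52, Galicia 16, Castilla-Leon 23); scaled proportionally if
#'   `n_samples` differs from their sum.
#' @param composition per-region composition table
#'   ([regional_composition()]).
#' @param correlations target correlation matrix ([default_correlations()]).
#' @param bands band library ([default_bands()]).
#' @param wavelengths spectral grid in nm (default 1100--2000 by 2).
#' @param scatter_mult_logsd SD of the per-replicate log multiplicative
#'   scatter factor (default 0.05).
#' @param scatter_add_sd SD of the per-replicate additive offset (default
#'   0.02 absorbance).
#' @param scatter_tilt_sd SD of the per-replicate linear baseline tilt
#'   across the grid (default 0.02 absorbance).
#' @param noise_sd per-channel instrument noise SD (default 0.004
#'   absorbance).
#' @param n_replicates scans per sample (default 3).
#' @param nd_fraction fraction of Cu/Ni/Pb values reported below the
#'   quantification limit in regions where that occurs (default 0.05).
#' @param calibrate_correlations logical: adjust the Gaussian-copula
#'   correlation so that the raw-scale Pearson correlations of the skewed
#'   marginals match the targets (default `TRUE`); see
#'   [sample_concentrations()].
#' @param loq quantification limit in mg/kg (default 0.01).
#' @param n_validation held-out external-validation samples (default 20,
#'   leaving 71 for calibration at the default cohort size).
#' @param seed integer seed; every random draw of the generator flows from
#'   it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 91,
                             regions = c("Chile" = 52, "Galicia" = 16,
                                         "Castilla-Leon" = 23),
                             composition = regional_composition(),
                             correlations = default_correlations(),
                             bands = default_bands(),
                             wavelengths = seq(1100, 2000, by = 2),
                             scatter_mult_logsd = 0.05,
                             scatter_add_sd = 0.02,
                             scatter_tilt_sd = 0.02,
                             noise_sd = 0.004,
                             n_replicates = 3,
                             nd_fraction = 0.05,
                             calibrate_correlations = TRUE,
                             loq = 0.01,
                             n_validation = 20,
                             seed = 1L) {
  if (n_samples != sum(regions)) {
    prop <- regions / sum(regions)
    regions <- round(prop * n_samples)
    regions[1] <- n_samples - sum(regions[-1])
  }
  if (any(regions < 0) || sum(regions) != n_samples)
    stop("inconsistent regional counts")
  if (any(composition$lo > composition$hi, na.rm = TRUE))
    stop("composition range with min > max")
  if (n_validation >= n_samples)
    stop("validation split must leave calibration samples")
  structure(list(
    n_samples = n_samples, regions = regions, composition = composition,
    correlations = correlations, bands = bands, wavelengths = wavelengths,
    scatter_mult_logsd = scatter_mult_logsd, scatter_add_sd = scatter_add_sd,
    scatter_tilt_sd = scatter_tilt_sd, noise_sd = noise_sd,
    n_replicates = n_replicates, nd_fraction = nd_fraction,
    calibrate_correlations = calibrate_correlations, loq = loq,
    n_validation = n_validation, seed = seed), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config: ", x$n_samples, " samples (",
      paste(names(x$regions), x$regions, collapse = ", "), "), ",
      x$n_replicates, " replicates, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Truncated log-normal with sigma set by range moment-matching — the
# printed range is treated as the expected range of n draws, whose width in
# SD units is 2 * qnorm((n - 0.375) / (n + 0.25)) — and mu adjusted so the
# truncated mean matches the target regional mean.
lognormal_params <- function(m, lo, hi, loq = 0.01, n = 30) {
  if (is.na(lo)) lo <- loq
  m <- min(max(m, lo * 1.001), hi * 0.999)
  width <- 2 * stats::qnorm((n - 0.375) / (n + 0.25))
  sigma <- max((log(hi) - log(lo)) / width, 0.05)
  trunc_mean <- function(mu) {
    plo <- stats::plnorm(lo, mu, sigma); phi <- stats::plnorm(hi, mu, sigma)
    if (phi - plo < 1e-12) return(ifelse(mu > log(hi), hi, lo))
    # E[X | lo < X < hi] for lognormal
    a <- stats::pnorm((log(lo) - mu - sigma^2) / sigma)
    b <- stats::pnorm((log(hi) - mu - sigma^2) / sigma)
    exp(mu + sigma^2 / 2) * (b - a) / (phi - plo)
  }
  mu <- stats::uniroot(function(mu) trunc_mean(mu) - m,
                       interval = log(c(lo, hi)) + c(-6, 6) * sigma,
                       tol = 1e-10)$root
  list(mu = mu, sigma = sigma, lo = lo, hi = hi)
}

marginal_params_table <- function(cfg) {
  pars <- list()
  for (i in seq_len(nrow(cfg$composition))) {
    row <- cfg$composition[i, ]
    n_region <- cfg$regions[row$region]
    if (is.na(n_region)) n_region <- 30
    pars[[paste(row$element, row$region, sep = ":")]] <-
      c(lognormal_params(row$mean, row$lo, row$hi, cfg$loq, n = n_region),
        nd_eligible = is.na(row$lo))
  }
  pars
}

# Map copula uniforms to concentrations through the per-region truncated
# log-normal marginals.
apply_marginals <- function(U, region, pars, el) {
  conc <- matrix(NA_real_, nrow(U), length(el), dimnames = list(NULL, el))
  for (e in el) {
    for (rg in unique(region)) {
      p <- pars[[paste(e, rg, sep = ":")]]
      if (is.null(p)) stop("no composition entry for ", e, " in ", rg)
      idx <- which(region == rg)
      plo <- stats::plnorm(p$lo, p$mu, p$sigma)
      phi <- stats::plnorm(p$hi, p$mu, p$sigma)
      u <- plo + U[idx, e] * (phi - plo)
      conc[idx, e] <- pmin(pmax(stats::qlnorm(u, p$mu, p$sigma),
                                p$lo), p$hi)
    }
  }
  conc
}

# Adjust the Gaussian-copula correlation so the raw-scale Pearson
# correlations land near the targets despite the skewed marginals and the
# between-region mean structure (which attenuates some pairs and amplifies
# others).  Damped fixed-point iteration against a large seeded Monte-Carlo
# draw, always evaluated through the positive-definite projection; pairs
# whose target is unreachable saturate at the closest achievable value.
copula_calibrate <- function(cfg, n_mc = 20000, iters = 20, damping = 0.9) {
  target <- cfg$correlations
  el <- colnames(target)
  Rg <- target
  counts <- round(cfg$regions / sum(cfg$regions) * n_mc)
  region_mc <- rep(names(cfg$regions), times = pmax(counts, 1))
  pars <- marginal_params_table(cfg)
  adj <- upper.tri(target) & target != 0
  for (it in seq_len(iters)) {
    Rpd <- nearest_pd_correlation(Rg)
    U <- stats::pnorm(with_seed(20201L + it, {
      matrix(stats::rnorm(length(region_mc) * length(el)),
             length(region_mc)) %*% chol(Rpd)
    }))
    robs <- stats::cor(apply_marginals(U, region_mc, pars, el))
    # unreported pairs are unconstrained: keep whatever the projection
    # assigned them, and only steer the pairs with a stated target
    step <- damping * (target - robs)
    step[!adj & !t(adj)] <- 0
    Rg <- pmax(pmin(Rpd + step, 0.999), -0.999)
    diag(Rg) <- 1
  }
  nearest_pd_correlation(Rg)
}

#' Draw correlated element concentrations
#'
#' Gaussian-copula draw: correlated standard normals are mapped through
#' per-region truncated log-normal marginals whose parameters are
#' moment-matched to the configured regional means and ranges.  Because the
#' marginals are skewed, a Pearson correlation imposed in the Gaussian
#' layer attenuates on the concentration scale; with
#' `calibrate_correlations = TRUE` the copula correlation is first adjusted
#' by iterative proportional scaling against a large seeded Monte-Carlo
#' draw so the raw-scale correlations land on the targets (unreachable
#' targets saturate at the comonotone bound).  The working matrix is
#' projected to the nearest positive-definite correlation matrix before
#' sampling.  In regions where Cu, Ni or Pb fall below the quantification
#' limit, the lowest `nd_fraction` of draws per element is flagged
#' below-LOQ.
#'
#' @param cfg a [synthetic_config()].
#' @return A [reference_table()] with a `region` attribute and a
#'   `correlation_used` attribute (the Gaussian-layer matrix actually
#'   sampled from).
#' @export
sample_concentrations <- function(cfg) {
  el <- colnames(cfg$correlations)
  n <- cfg$n_samples
  Rpd <- if (isTRUE(cfg$calibrate_correlations)) copula_calibrate(cfg)
         else nearest_pd_correlation(cfg$correlations)
  region <- rep(names(cfg$regions), times = cfg$regions)
  Z <- with_seed(cfg$seed, {
    matrix(stats::rnorm(n * length(el)), n) %*% chol(Rpd)
  })
  pars <- marginal_params_table(cfg)
  conc <- apply_marginals(stats::pnorm(Z), region, pars, el)
  nd <- matrix(FALSE, n, length(el), dimnames = list(NULL, el))
  if (cfg$nd_fraction > 0) {
    for (e in el) {
      for (rg in names(cfg$regions)) {
        p <- pars[[paste(e, rg, sep = ":")]]
        idx <- which(region == rg)
        if (isTRUE(p$nd_eligible)) {
          k <- floor(cfg$nd_fraction * length(idx))
          if (k > 0)
            nd[idx[order(conc[idx, e])[seq_len(k)]], e] <- TRUE
        }
      }
    }
  }
  ids <- sprintf("S%03d", seq_len(n))
  out <- reference_table(ids, conc, below_loq = nd, loq = cfg$loq)
  attr(out, "region") <- stats::setNames(region, ids)
  attr(out, "correlation_used") <- Rpd
  out
}

nearest_pd_correlation <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(R)
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  attr(out, "projection_distance") <- sqrt(sum((out - R)^2))
  out
}

# Smooth absorbance baseline shared by all samples: gentle slope plus the
# broad water O-H overtone bands near 1400 and 1900 nm.
synthetic_baseline <- function(wl) {
  0.45 + 2.5e-4 * (wl - 1100) +
    0.10 * exp(-(wl - 1400)^2 / (2 * 45^2)) +
    0.16 * exp(-(wl - 1900)^2 / (2 * 55^2))
}

# Sample-level interferent shapes: a water O-H band level and a broad
# flavonoid absorption near 1530 nm, both varying between samples.
interferent_profiles <- function(wl) {
  cbind(water = 0.05 * exp(-(wl - 1400)^2 / (2 * 45^2)) +
                0.08 * exp(-(wl - 1900)^2 / (2 * 55^2)),
        flavonoid = 0.06 * exp(-(wl - 1530)^2 / (2 * 25^2)))
}

band_profile <- function(wl, bands) {
  # channels x elements matrix of summed Gaussian band shapes (per mg/kg)
  el <- unique(bands$element)
  out <- matrix(0, length(wl), length(el), dimnames = list(NULL, el))
  for (i in seq_len(nrow(bands)))
    out[, bands$element[i]] <- out[, bands$element[i]] +
      bands$amplitude[i] * exp(-(wl - bands$center[i])^2 /
                                 (2 * bands$width[i]^2))
  out
}

#' Generate NIR spectra from element concentrations
#'
#' Linear-mixture model: each sample's clean spectrum is the shared baseline
#' plus each element's concentration times its summed Gaussian band profile,
#' plus sample-level interferents (a water band level and a broad flavonoid
#' band near 1530 nm).  Each replicate scan then receives multiplicative
#' scatter, an additive offset, a linear tilt, and per-channel instrument
#' noise.  Below-LOQ concentrations contribute at half the quantification
#' limit.
#'
#' @param ref a [reference_table()] of concentrations (e.g. from
#'   [sample_concentrations()]).
#' @param cfg a [synthetic_config()].
#' @param clean logical: skip scatter, noise and replicates, returning one
#'   noise-free spectrum per sample (default `FALSE`).
#' @return A [spectra_set()]; with replicates unless `clean = TRUE`.
#' @export
generate_spectra <- function(ref, cfg, clean = FALSE) {
  wl <- cfg$wavelengths
  conc <- ref$concentrations
  conc[ref$below_loq] <- cfg$loq / 2
  profiles <- band_profile(wl, cfg$bands)
  miss <- setdiff(colnames(conc), colnames(profiles))
  if (length(miss)) stop("no bands configured for: ",
                         paste(miss, collapse = ", "))
  base <- synthetic_baseline(wl)
  interf <- interferent_profiles(wl)
  n <- nrow(conc)
  with_seed(cfg$seed + 1L, {
    water_lvl <- stats::rnorm(n, 1, 0.10)
    flav_lvl <- stats::rnorm(n, 1, 0.20)
    clean_mat <- matrix(base, n, length(wl), byrow = TRUE) +
      conc[, colnames(profiles), drop = FALSE] %*% t(profiles) +
      outer(water_lvl, interf[, "water"]) +
      outer(flav_lvl, interf[, "flavonoid"])
    if (clean) {
      spectra_set(wl, clean_mat, ref$sample_ids)
    } else {
      nrep <- cfg$n_replicates
      span <- diff(range(wl))
      rows <- vector("list", n * nrep)
      ids <- character(n * nrep); parent <- character(n * nrep)
      k <- 0
      for (i in seq_len(n)) {
        for (r in seq_len(nrep)) {
          k <- k + 1
          mfac <- exp(stats::rnorm(1, 0, cfg$scatter_mult_logsd))
          add <- stats::rnorm(1, 0, cfg$scatter_add_sd)
          tilt <- stats::rnorm(1, 0, cfg$scatter_tilt_sd)
          eps <- stats::rnorm(length(wl), 0, cfg$noise_sd)
          rows[[k]] <- mfac * clean_mat[i, ] + add +
            tilt * (wl - mean(wl)) / span + eps
          ids[k] <- paste0(ref$sample_ids[i], "/", r)
          parent[k] <- ref$sample_ids[i]
        }
      }
      spectra_set(wl, do.call(rbind, rows), ids, replicate_of = parent)
    }
  })
}

#' Generate a complete synthetic propolis dataset
#'
#' Draws the reference chemistry, generates replicate spectra, splits the
#' cohort into calibration and external-validation sets (seeded random
#' draw), and optionally writes the CSV pair plus a truth record (band
#' library, correlation targets and the projected matrix actually used,
#' scatter/noise levels, split membership) for recovery studies.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory; when given, writes
#'   `spectra.csv`, `reference.csv`, and `truth.json`.
#' @return A list with `spectra` (replicate-level [spectra_set()]),
#'   `reference` ([reference_table()]), and `truth` (list: `bands`,
#'   `correlation_target`, `correlation_used`, noise/scatter levels,
#'   `region`, `calibration_ids`, `validation_ids`, `seed`).
#' @export
make_dataset <- function(cfg = synthetic_config(), dir = NULL) {
  ref <- sample_concentrations(cfg)
  spectra <- generate_spectra(ref, cfg)
  val_ids <- with_seed(cfg$seed + 2L,
                       sort(sample(ref$sample_ids, cfg$n_validation)))
  truth <- list(
    bands = cfg$bands,
    correlation_target = cfg$correlations,
    correlation_used = attr(ref, "correlation_used"),
    scatter_mult_logsd = cfg$scatter_mult_logsd,
    scatter_add_sd = cfg$scatter_add_sd,
    scatter_tilt_sd = cfg$scatter_tilt_sd,
    noise_sd = cfg$noise_sd,
    region = attr(ref, "region"),
    calibration_ids = setdiff(ref$sample_ids, val_ids),
    validation_ids = val_ids,
    seed = cfg$seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectra(spectra, file.path(dir, "spectra.csv"))
    write_reference(ref, file.path(dir, "reference.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(spectra = spectra, reference = ref, truth = truth)
}
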