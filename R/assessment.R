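#' Root mean square error
#'
#' `sqrt(mean(e^2))` with the plain `n` denominator, the convention used for
#' RMSEC, RMSECV and RMSEP throughout.
#'
#' @param e error vector (predicted minus reference).
#' @return The RMSE.
#' @export
rmse <- function(e) {
  if (length(e) == 0) stop("empty error vector")
  sqrt(mean(e^2))
}

#' Coefficient of determination as squared Pearson correlation
#'
#' `R^2 = cor(y, y_hat)^2`.  Note this differs from `1 - SSE/SST` when the
#' predictions are biased or mis-scaled; the squared correlation is the
#' headline statistic of NIR calibration tables.
#'
#' @param y reference values (must have positive variance).
#' @param y_hat predicted values.
#' @return Squared Pearson correlation in `[0, 1]`; 0 (with a warning) when
#'   the predictions have zero variance.
#' @export
r_squared <- function(y, y_hat) {
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (stats::sd(y_hat) == 0) {
    warning("predictions have zero variance; R^2 set to 0")
    return(0)
  }
  stats::cor(y, y_hat)^2
}

#' Ratio of performance to deviation (RPD)
#'
#' The standard deviation of the reference values divided by the prediction
#' error (RMSECV for internal validation, bias-corrected RMSEP for external
#' validation).  An RPD above 2 marks a good calibration; below 1.5, a poor
#' one.
#'
#' @param sd_ref standard deviation of the reference values.
#' @param rmse_val RMSECV or RMSEP(C).
#' @param digits rounding for table display; `NULL` for the raw ratio.
#'   Defaults to 1 decimal, matching calibration-table convention.
#' @return The (optionally rounded) ratio.
#' @export
rpd <- function(sd_ref, rmse_val, digits = NULL) {
  if (rmse_val <= 0) stop("RPD undefined for a non-positive error")
  out <- sd_ref / rmse_val
  if (!is.null(digits)) round(out, digits) else out
}

#' Summarize a calibration (one table row)
#'
#' Collects the statistics conventionally reported per element: surviving N,
#' mean and SD of the reference values, the estimated applicability range
#' `Est.Min = max(0, mean - 3 SD)` / `Est.Max = mean + 3 SD`, RMSEC, R^2 (on
#' the calibration fit), RMSECV at the selected factor count, and
#' RPD = SD / RMSECV.
#'
#' @param y surviving reference values (mg/kg).
#' @param fitted calibration fitted values.
#' @param cv an `mpls_cv` object (or `NULL`; RMSECV/RPD then `NA`).
#' @param treatment optional [math_treatment()] echoed in the summary.
#' @param element optional element name.
#' @return An object of class `calibration_summary` (a one-row data frame
#'   with columns element, treatment, n_factors, N, mean, sd, est_min,
#'   est_max, rmsec, r2, rmsecv, rpd).
#' @export
calibration_summary <- function(y, fitted, cv = NULL, treatment = NULL,
                                element = NA_character_) {
  m <- mean(y); s <- stats::sd(y)
  out <- data.frame(
    element = element,
    treatment = if (!is.null(treatment)) treatment$label else NA_character_,
    n_factors = if (!is.null(cv)) cv$n_factors else NA_integer_,
    N = length(y),
    mean = m, sd = s,
    est_min = max(0, m - 3 * s), est_max = m + 3 * s,
    rmsec = rmse(fitted - y),
    r2 = r_squared(y, fitted),
    rmsecv = if (!is.null(cv)) cv$rmsecv[cv$n_factors + 1] else NA_real_,
    rpd = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(cv)) out$rpd <- rpd(out$sd, out$rmsecv)
  class(out) <- c("calibration_summary", "data.frame")
  out
}

#' @export
print.calibration_summary <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 2))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' External validation of a fitted calibration
#'
#' Applies a stored calibration (treatment state included) to an independent
#' validation set and reports the external statistics: with errors
#' `e = y_hat - y`, `bias = mean(e)`, `RMSEP = sqrt(mean(e^2))`, the
#' bias-corrected `RMSEP(C) = sqrt(sum((e - bias)^2) / (n - 1))` (the SEP),
#' and `RPD = sd(y) / RMSEP(C)`.  The applicability range `Est.Min/Est.Max`
#' uses the same mean +/- 3 SD rule as the calibration summary.
#'
#' @param cal an `mpls_calibration` (or a list with `model`, `treatment`,
#'   `pretreat_state`, e.g. from [mpls_from_json()]).
#' @param X_new raw validation spectra on the training grid (replicates
#'   should be averaged beforehand).
#' @param y_new reference concentrations of the validation samples.
#' @param element optional element name.
#' @return An object of class `external_validation` (one-row data frame:
#'   element, n, mean, sd, est_min, est_max, rmsep, bias, rmsep_c, rpd, r2).
#' @export
external_validate <- function(cal, X_new, y_new, element = NA_character_) {
  if (length(y_new) < 3) stop("external validation needs >= 3 samples")
  y_hat <- predict_calibration(cal, X_new)
  e <- y_hat - y_new
  n <- length(e)
  bias <- mean(e)
  m <- mean(y_new); s <- stats::sd(y_new)
  out <- data.frame(
    element = element, n = n, mean = m, sd = s,
    est_min = max(0, m - 3 * s), est_max = m + 3 * s,
    rmsep = rmse(e), bias = bias,
    rmsep_c = sqrt(sum((e - bias)^2) / (n - 1)),
    rpd = NA_real_, r2 = r_squared(y_new, y_hat),
    stringsAsFactors = FALSE)
  out$rpd <- if (out$rmsep_c > 0) out$sd / out$rmsep_c else Inf
  class(out) <- c("external_validation", "data.frame")
  out
}

#' Predict concentrations from raw spectra with a stored calibration
#'
#' Replays the stored pretreatment state (so e.g. the MSC reference is the
#' training one) and evaluates the MPLS model.
#'
#' @param cal an `mpls_calibration` or the list returned by
#'   [mpls_from_json()].
#' @param X_new raw spectra matrix on the training wavelength grid.
#' @return Numeric vector of predicted concentrations (mg/kg).
#' @export
predict_calibration <- function(cal, X_new) {
  tr <- apply_treatment(cal$treatment, rbind(X_new),
                        cal$pretreat_state$wavelengths_in,
                        state = cal$pretreat_state)
  predict(cal$model, tr$X)
}

#' Pairwise Pearson correlations between elements
#'
#' Pairwise-complete Pearson correlation matrix of the reference chemistry
#' (below-LOQ cells are missing) with two-sided p-values from the t
#' transform `t = r sqrt((n-2)/(1-r^2))`.  Cells with fewer than
#' `min_pairs` complete pairs are set to `NA`.
#'
#' @param r a [reference_table()] or a numeric samples x elements matrix.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return A list with matrices `r`, `p`, and `n` (pair counts).
#' @export
correlation_matrix <- function(r, min_pairs = 3) {
  M <- if (inherits(r, "reference_table")) r$concentrations else as.matrix(r)
  k <- ncol(M)
  cr <- stats::cor(M, use = "pairwise.complete.obs")
  np <- crossprod(!is.na(M))
  low <- np < min_pairs
  cr[low] <- NA
  pv <- matrix(NA_real_, k, k, dimnames = dimnames(cr))
  ok <- !is.na(cr) & np > 2
  tstat <- cr * sqrt((np - 2) / pmax(1 - cr^2, .Machine$double.eps))
  pv[ok] <- 2 * stats::pt(abs(tstat[ok]), np[ok] - 2, lower.tail = FALSE)
  diag(pv) <- NA
  list(r = cr, p = pv, n = np)
}
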