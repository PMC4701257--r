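#' Principal component model of a pretreated spectra matrix
#'
#' Fits PCA by singular value decomposition of the column-centered matrix
#' and keeps the smallest number of components whose cumulative explained
#' variance reaches `target_variance` (conventionally 99% of the spectral
#' variability).
#'
#' @param X pretreated spectra matrix (samples x channels), >= 2 rows.
#' @param target_variance cumulative explained-variance target in (0, 1].
#' @param max_components optional hard cap on the component count.
#' @return An object of class `nir_pca`: `center`, `loadings` (channels x k),
#'   `score_sd` (per-component score standard deviations), `explained`
#'   (fractions, all components), `k`.
#' @export
pca_fit <- function(X, target_variance = 0.99, max_components = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2
  tot <- sum(ev)
  if (tot == 0) stop("spectra matrix has rank 0 after centering")
  pos <- ev > tot * 1e-12
  ev <- ev[pos]
  frac <- ev / tot
  k <- which(cumsum(frac) >= target_variance)[1]
  if (is.na(k)) k <- length(frac)
  if (!is.null(max_components)) k <- min(k, max_components)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  structure(list(center = ctr,
                 loadings = sv$v[, seq_len(k), drop = FALSE],
                 score_sd = apply(scores, 2, stats::sd),
                 explained = frac, k = k, n = nrow(X)),
            class = "nir_pca")
}

#' @export
print.nir_pca <- function(x, ...) {
  cat("nir_pca: ", x$k, " components explaining ",
      round(100 * sum(x$explained[seq_len(x$k)]), 2), "% of variance (n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' @param object a `nir_pca` model.
#' @param newdata spectra matrix on the training grid.
#' @param ... unused.
#' @return Score matrix (samples x k).
#' @export
predict.nir_pca <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$center))
    stop("channel count does not match the PCA model")
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' Global H (standardized Mahalanobis distance in score space)
#'
#' `H_i = mean over components of (t_if / s_f)^2`: the squared Mahalanobis
#' distance of a spectrum from the population mean, computed in the
#' standardized principal-component score space and divided by the number of
#' components, so that the training-set mean of H is (n-1)/n, about 1.
#' Spectra with H above 3 are conventionally treated as members of a
#' different population.
#'
#' @param scores score matrix (samples x k).
#' @param score_sd per-component score standard deviations from the training
#'   set.
#' @return Numeric vector of H values.
#' @export
global_h <- function(scores, score_sd) {
  scores <- rbind(scores)
  if (ncol(scores) != length(score_sd))
    stop("score_sd length does not match the number of components")
  if (any(score_sd <= 0)) stop("zero score variance in component(s) ",
                               paste(which(score_sd <= 0), collapse = ", "))
  rowMeans(sweep(scores, 2, score_sd, "/")^2)
}

#' Eliminate spectral outliers by the global-H criterion
#'
#' Fits a PCA on the pretreated spectra, computes global H for every sample
#' and removes, in a single pass, all samples with H above the threshold.
#'
#' @param X pretreated spectra matrix with sample ids as row names.
#' @param threshold H cutoff (default 3).
#' @param target_variance PCA explained-variance target (default 0.99).
#' @param max_components cap on PCA components used for H.
#' @return A list with `keep` (logical), `H` (all samples), `report`
#'   (data frame of eliminated samples), and `pca`.
#' @export
eliminate_h <- function(X, threshold = 3, target_variance = 0.99,
                        max_components = NULL) {
  X <- as.matrix(X)
  pca <- pca_fit(X, target_variance, max_components)
  H <- global_h(predict(pca, X), pca$score_sd)
  keep <- H <= threshold
  if (sum(keep) < 2 * pca$k)
    stop("H elimination would leave ", sum(keep),
         " samples for a ", pca$k, "-component model")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  report <- data.frame(sample_id = ids[!keep], statistic = H[!keep],
                       reason = rep("H", sum(!keep)),
                       pass = rep(1L, sum(!keep)),
                       stringsAsFactors = FALSE)
  list(keep = keep, H = stats::setNames(H, ids), report = report, pca = pca)
}

#' Flag chemistry outliers by the T criterion
#'
#' Standardizes calibration residuals by their sample standard deviation and
#' flags samples with `|t| > threshold` (conventionally 2.5).  This performs
#' one pass; the caller refits the model on the survivors and may repeat.
#'
#' @param y reference values.
#' @param y_hat fitted values from the current calibration.
#' @param threshold cutoff on `|residual| / sd(residuals)` (default 2.5).
#' @return A list with `keep` (logical), `t` (standardized residuals), and
#'   `flagged` (indices).
#' @export
t_outliers <- function(y, y_hat, threshold = 2.5) {
  e <- y - y_hat
  s <- stats::sd(e)
  if (!is.finite(s) || s == 0) {
    warning("residual standard deviation is 0; no T elimination possible")
    return(list(keep = rep(TRUE, length(e)), t = rep(0, length(e)),
                flagged = integer(0)))
  }
  t <- e / s
  flagged <- which(abs(t) > threshold)
  list(keep = abs(t) <= threshold, t = t, flagged = flagged)
}
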