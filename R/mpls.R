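#' Fit a modified partial least squares (MPLS) regression
#'
#' Single-response PLS1 by NIPALS deflation with the "modified" step used in
#' NIR calibration software: after each latent factor is extracted, the
#' spectral residuals at every wavelength are divided by their standard
#' deviation before the next factor is computed.  With
#' `residual_scaling = FALSE` the fit reduces exactly to standard PLS1.
#'
#' Per factor f the algorithm computes, on the current (centered, possibly
#' rescaled) matrix `X`: weight `w = X'y / |X'y|`, scores `t = X w`, loading
#' `p = X't / t't`, y-loading `q = y't / t't`, deflates `X <- X - t p'`,
#' `y <- y - t q`, then (MPLS only) records the per-column residual standard
#' deviations `s_f` and divides the columns of `X` by them.  Prediction
#' replays the identical transform sequence, so the model is also
#' collapsible into the linear form `y = b0 + sum(b * x)`.
#'
#' @param X pretreated spectra matrix (samples x channels).
#' @param y reference concentrations (mg/kg).
#' @param n_factors number of latent factors (0 gives the mean model).
#' @param residual_scaling logical; standardize spectral residuals between
#'   factors (the MPLS step).  Default `TRUE`.
#' @param wavelengths optional channel wavelengths stored for reporting.
#' @return An object of class `mpls_model`: `x_center`, `y_center`,
#'   `weights`, `loadings`, `y_loadings`, `residual_sd` (channels x factors),
#'   `coef` (named `b` and `b0`), `n_factors`, `fitted`, `wavelengths`.
#' @export
fit_mpls <- function(X, y, n_factors, residual_scaling = TRUE,
                     wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_factors > min(n - 1, p))
    stop("n_factors = ", n_factors, " exceeds min(n - 1, channels) = ",
         min(n - 1, p))
  if (stats::sd(y) == 0) stop("y has zero variance")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xw <- sweep(X, 2, x_center)
  yr <- y - y_center

  W <- P <- S <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  Tm <- matrix(0, n, n_factors)
  for (f in seq_len(n_factors)) {
    w <- crossprod(Xw, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("degenerate weight vector at factor ", f,
                          " (no covariance left)")
    w <- w / nw
    t <- drop(Xw %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xw, t)) / tt
    qf <- sum(yr * t) / tt
    Xw <- Xw - tcrossprod(t, pv)
    yr <- yr - t * qf
    if (residual_scaling) {
      s <- sqrt(pmax(colSums(Xw^2) - nrow(Xw) * colMeans(Xw)^2, 0) /
                  (nrow(Xw) - 1))
      zero <- s == 0 | !is.finite(s)
      if (any(zero)) {
        if (f < n_factors)
          warning(sum(zero), " residual column(s) with zero SD at factor ",
                  f, "; scale set to 1")
        s[zero] <- 1
      }
      Xw <- sweep(Xw, 2, s, "/")
    } else {
      s <- rep(1, p)
    }
    W[, f] <- w; P[, f] <- pv; S[, f] <- s; q[f] <- qf; Tm[, f] <- t
  }
  fitted <- y_center + if (n_factors > 0) drop(Tm %*% q) else 0
  structure(list(x_center = x_center, y_center = y_center,
                 weights = W, loadings = P, y_loadings = q,
                 residual_sd = S, n_factors = n_factors,
                 residual_scaling = residual_scaling,
                 fitted = fitted, wavelengths = wavelengths,
                 coef = NULL), class = "mpls_model")
}

#' Collapsed linear coefficients of an MPLS model
#'
#' Folds the stored factor recursion into the equivalent linear form
#' `y = b0 + sum(b * x)` on the pretreated wavelength grid.  Computed on
#' first use and cached on the returned model by functions that need it.
#'
#' @param m an `mpls_model`.
#' @return A list with `b` (coefficient vector) and `b0` (intercept).
#' @export
mpls_coefficients <- function(m) {
  if (!is.null(m$coef)) return(m$coef)
  collapse_coefficients(m)
}

# Collapse the factor recursion into y = b0 + b.x.  The recursion maps
# x_f = D_f (I - p_f w_f') x_{f-1} with x_0 = x - center, and accumulates
# q_f w_f' x_{f-1}; propagating the composed linear map gives b directly.
collapse_coefficients <- function(m) {
  p <- length(m$x_center)
  b <- numeric(p)
  if (m$n_factors > 0) {
    M <- diag(p)
    for (f in seq_len(m$n_factors)) {
      w <- m$weights[, f]; pv <- m$loadings[, f]
      b <- b + m$y_loadings[f] * drop(crossprod(M, w))
      wM <- drop(crossprod(w, M))
      M <- (M - tcrossprod(pv, wM)) / m$residual_sd[, f]
    }
  }
  list(b = b, b0 = m$y_center - sum(b * m$x_center))
}

#' @export
print.mpls_model <- function(x, ...) {
  cat("mpls_model: ", x$n_factors, " factors, ",
      length(x$x_center), " channels",
      if (!x$residual_scaling) " (standard PLS1, no residual scaling)",
      "\n", sep = "")
  invisible(x)
}

#' Predict from an MPLS model
#'
#' @param object an `mpls_model`.
#' @param newdata pretreated spectra matrix on the training grid.
#' @param method `"recursion"` replays the stored factor transform;
#'   `"linear"` evaluates the collapsed form `b0 + sum(b * x)`.  The two
#'   agree to numerical precision.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mpls_model <- function(object, newdata,
                               method = c("recursion", "linear"), ...) {
  method <- match.arg(method)
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$x_center))
  if (method == "linear") {
    cf <- mpls_coefficients(object)
    return(drop(newdata %*% cf$b) + cf$b0)
  }
  pa <- predict_factorwise(object, newdata)
  pa[, ncol(pa)]
}

# Predictions at every factor count 0..n_factors in one replay (n x (F+1)).
predict_factorwise <- function(m, newdata) {
  Xw <- sweep(rbind(newdata), 2, m$x_center)
  out <- matrix(m$y_center, nrow(Xw), m$n_factors + 1)
  for (f in seq_len(m$n_factors)) {
    t <- drop(Xw %*% m$weights[, f])
    out[, f + 1] <- out[, f] + t * m$y_loadings[f]
    Xw <- sweep(Xw - tcrossprod(t, m$loadings[, f]), 2,
                m$residual_sd[, f], "/")
  }
  out
}

#' Grouped cross-validation of an MPLS calibration
#'
#' Splits the samples at random (seeded) into `n_groups` groups; each group
#' is predicted by a model trained on the others.  The pretreatment state
#' (e.g. the MSC reference spectrum) and the MPLS fit are recomputed inside
#' every fold, so no information leaks from the held-out group.  RMSECV is
#' pooled over all samples at each factor count and the factor count
#' minimizing it is selected.
#'
#' @param X raw (untreated) spectra matrix.
#' @param y reference concentrations.
#' @param wavelengths channel wavelengths in nm.
#' @param treatment a treatment string or [math_treatment()].
#' @param n_groups number of cross-validation groups (default 6).
#' @param max_factors largest factor count examined (default 16, further
#'   capped by fold size and channel count).
#' @param seed integer seed for the random partition, or `NULL` to use the
#'   current RNG state.
#' @param groups optional explicit group assignment (integer vector in
#'   `1..n_groups`), overriding the random partition.
#' @param selection `"min"` picks the global RMSECV minimum; `"onese"` picks
#'   the smallest factor count within one standard error of it.
#' @param residual_scaling passed to [fit_mpls()].
#' @return An object of class `mpls_cv`: `groups`, `rmsecv` (index f+1 is
#'   f factors), `n_factors` (selected), `predictions` (per-sample CV
#'   prediction at the selected factor count), `r2_cv`.
#' @export
cross_validate <- function(X, y, wavelengths, treatment, n_groups = 6,
                           max_factors = 16, seed = NULL, groups = NULL,
                           selection = c("min", "onese"),
                           residual_scaling = TRUE) {
  selection <- match.arg(selection)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_groups) stop("need at least as many samples as groups")
  if (is.null(groups)) {
    groups <- cv_groups(n, n_groups, seed)
  } else if (length(groups) != n) {
    stop("groups must assign every sample")
  }
  if (min(table(factor(groups, levels = seq_len(n_groups)))) < 2)
    stop("every cross-validation group needs at least 2 samples")
  fmax <- min(max_factors, ncol(X), n - max(table(groups)) - 1)
  if (fmax < 1) stop("too few samples per fold for even one factor")
  pred <- matrix(NA_real_, n, fmax + 1)
  for (g in seq_len(n_groups)) {
    hold <- groups == g
    tr <- apply_treatment(treatment, X[!hold, , drop = FALSE], wavelengths)
    te <- apply_treatment(treatment, X[hold, , drop = FALSE], wavelengths,
                          state = tr$state)
    fg <- min(fmax, sum(!hold) - 1, ncol(tr$X))
    m <- fit_mpls(tr$X, y[!hold], fg, residual_scaling = residual_scaling)
    pg <- predict_factorwise(m, te$X)
    pred[hold, seq_len(fg + 1)] <- pg
    if (fg < fmax)  # tiny fold: carry the deepest available prediction
      pred[hold, (fg + 2):(fmax + 1)] <- pg[, fg + 1]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  f_best <- select_factors(pred, y, groups, rmsecv, selection)
  cvp <- pred[, f_best + 1]
  structure(list(groups = groups, rmsecv = rmsecv, n_factors = f_best,
                 predictions = cvp, max_factors = fmax,
                 r2_cv = r_squared(y, cvp), selection = selection),
            class = "mpls_cv")
}

cv_groups <- function(n, n_groups, seed = NULL) {
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_groups, n_groups) +
    (seq_len(n_groups) <= n %% n_groups)
  g <- integer(n)
  g[perm] <- rep(seq_len(n_groups), times = sizes)
  g
}

# Run code under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

select_factors <- function(pred, y, groups, rmsecv, selection) {
  cand <- seq_along(rmsecv)[-1]          # at least one factor
  best <- cand[which.min(rmsecv[cand])]
  if (selection == "onese") {
    # SE of the CV error at the minimizer from the fold-wise spread
    mse_g <- tapply(seq_along(y), groups, function(i)
      mean((pred[i, best] - y[i])^2))
    se_rmse <- stats::sd(sqrt(mse_g)) / sqrt(length(mse_g))
    best <- cand[which(rmsecv[cand] <= rmsecv[best] + se_rmse)[1]]
  }
  best - 1L
}

#' @export
print.mpls_cv <- function(x, ...) {
  cat("mpls_cv: ", length(unique(x$groups)), " groups; selected ",
      x$n_factors, " factors; RMSECV = ",
      signif(x$rmsecv[x$n_factors + 1], 4), "; CV R^2 = ",
      signif(x$r2_cv, 3), "\n", sep = "")
  invisible(x)
}

#' Calibrate one element with spectral and chemical outlier elimination
#'
#' The full single-element loop: pretreat, eliminate spectral outliers by
#' global H (> `h_threshold`, single pass), select the factor count by
#' grouped cross-validation, fit the MPLS model, then eliminate chemistry
#' outliers by the T criterion (|standardized residual| > `t_threshold`),
#' refitting and re-cross-validating after each pass (at most
#' `max_t_passes`).  The pretreatment state is refit on the surviving
#' samples at every stage.
#'
#' @param X raw spectra matrix with sample ids as row names.
#' @param y reference concentrations.
#' @param wavelengths channel wavelengths in nm.
#' @param treatment a treatment string or [math_treatment()].
#' @param ids sample identifiers (default row names of `X`).
#' @param h_threshold global-H cutoff (default 3).
#' @param t_threshold T cutoff (default 2.5).
#' @param max_t_passes maximum chemistry-elimination passes (default 2).
#' @param n_groups,max_factors,seed,selection,residual_scaling passed to
#'   [cross_validate()].
#' @param target_variance PCA explained-variance target for H (default
#'   0.99).
#' @param h_components cap on the PCA score-space dimension used for the H
#'   statistic; defaults to `max_factors` (derivative-treated spectra can
#'   need far more components for 99% variance than a calibration ever
#'   uses, and H is meaningful in the modelled subspace).
#' @return An object of class `mpls_calibration`: `model`, `cv`,
#'   `treatment`, `outliers` (data frame: sample_id, statistic, reason
#'   `"H"`/`"T"`, pass), `ids` (survivors), `y`, `summary` (a
#'   [calibration_summary()]), `pretreat_state`.
#' @export
fit_with_elimination <- function(X, y, wavelengths, treatment,
                                 ids = rownames(X), h_threshold = 3,
                                 t_threshold = 2.5, max_t_passes = 2,
                                 n_groups = 6, max_factors = 16,
                                 seed = NULL, target_variance = 0.99,
                                 h_components = max_factors,
                                 selection = "min",
                                 residual_scaling = TRUE) {
  X <- as.matrix(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  rownames(X) <- ids
  tr0 <- apply_treatment(treatment, X, wavelengths)
  elim_h <- eliminate_h(tr0$X, threshold = h_threshold,
                        target_variance = target_variance,
                        max_components = min(h_components,
                                             floor((nrow(X) - 1) / 2)))
  outliers <- elim_h$report
  keep <- elim_h$keep
  Xk <- X[keep, , drop = FALSE]; yk <- y[keep]

  refit <- function(Xk, yk, pass_seed) {
    cv <- cross_validate(Xk, yk, wavelengths, treatment,
                         n_groups = n_groups, max_factors = max_factors,
                         seed = pass_seed, selection = selection,
                         residual_scaling = residual_scaling)
    tr <- apply_treatment(treatment, Xk, wavelengths)
    model <- fit_mpls(tr$X, yk, cv$n_factors,
                      residual_scaling = residual_scaling,
                      wavelengths = tr$wavelengths)
    list(cv = cv, model = model, state = tr$state)
  }
  fit <- refit(Xk, yk, seed)
  for (pass in seq_len(max_t_passes)) {
    flag <- t_outliers(yk, fit$model$fitted, t_threshold)
    if (length(flag$flagged) == 0) break
    outliers <- rbind(outliers, data.frame(
      sample_id = rownames(Xk)[flag$flagged],
      statistic = flag$t[flag$flagged],
      reason = rep("T", length(flag$flagged)), pass = pass,
      stringsAsFactors = FALSE))
    Xk <- Xk[flag$keep, , drop = FALSE]; yk <- yk[flag$keep]
    fit <- refit(Xk, yk, if (is.null(seed)) NULL else seed + pass)
  }
  if (nrow(Xk) < 3 * max(fit$model$n_factors, 1))
    stop("only ", nrow(Xk), " samples survive elimination for a ",
         fit$model$n_factors, "-factor model")
  summ <- calibration_summary(yk, fit$model$fitted, fit$cv,
                              treatment = math_treatment(treatment))
  structure(list(model = fit$model, cv = fit$cv,
                 treatment = math_treatment(treatment), outliers = outliers,
                 ids = rownames(Xk), y = yk, summary = summ,
                 pretreat_state = fit$state,
                 n_input = nrow(X), n_final = nrow(Xk)),
            class = "mpls_calibration")
}

#' @export
print.mpls_calibration <- function(x, ...) {
  cat("mpls_calibration: ", x$treatment$label, "; N = ", x$n_final,
      " of ", x$n_input, " (", nrow(x$outliers), " eliminated); ",
      x$model$n_factors, " factors\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Wavelengths of the largest regression coefficients
#'
#' Reports the `top_k` wavelengths at which the collapsed linear form of the
#' model has the largest absolute coefficients, with their signed values —
#' the channels where the correlation between concentration and absorbance
#' is strongest.
#'
#' @param m an `mpls_model` fitted with `wavelengths` recorded, or an
#'   `mpls_calibration`.
#' @param top_k number of extrema to report (default 2).
#' @return Data frame with columns `wavelength` and `beta`, ordered by
#'   decreasing `|beta|`.
#' @export
coefficient_extrema <- function(m, top_k = 2) {
  if (inherits(m, "mpls_calibration")) m <- m$model
  if (is.null(m$wavelengths))
    stop("model carries no wavelength grid")
  b <- mpls_coefficients(m)$b
  ord <- order(abs(b), decreasing = TRUE)[seq_len(min(top_k, length(b)))]
  data.frame(wavelength = m$wavelengths[ord], beta = b[ord])
}

#' Serialize an MPLS calibration to JSON
#'
#' Stores everything needed to reproduce predictions exactly: the treatment
#' and its fitted state, the wavelength grid, centers, per-factor vectors
#' and the collapsed coefficients.  [mpls_from_json()] restores the object.
#'
#' @param cal an `mpls_calibration` (or bare `mpls_model`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
mpls_to_json <- function(cal, path) {
  if (inherits(cal, "mpls_model")) cal <- list(model = cal)
  m <- cal$model
  m$coef <- mpls_coefficients(m)
  payload <- list(
    schema = "mplsnir/model/1",
    treatment = if (!is.null(cal$treatment)) cal$treatment$label,
    pretreat_state = cal$pretreat_state,
    model = list(
      x_center = m$x_center, y_center = m$y_center,
      weights = m$weights, loadings = m$loadings,
      y_loadings = m$y_loadings, residual_sd = m$residual_sd,
      n_factors = m$n_factors, residual_scaling = m$residual_scaling,
      coef = m$coef, wavelengths = m$wavelengths))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname mpls_to_json
#' @export
mpls_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- payload$model
  as_mat <- function(x, nr) {
    if (is.matrix(x)) return(unname(x))
    matrix(as.numeric(x), nrow = nr)  # single factor simplifies to vector
  }
  p <- length(m$x_center)
  model <- structure(list(
    x_center = as.numeric(m$x_center), y_center = m$y_center,
    weights = as_mat(m$weights, p), loadings = as_mat(m$loadings, p),
    y_loadings = as.numeric(m$y_loadings),
    residual_sd = as_mat(m$residual_sd, p),
    n_factors = m$n_factors, residual_scaling = m$residual_scaling,
    coef = list(b = as.numeric(m$coef$b), b0 = m$coef$b0),
    wavelengths = if (!is.null(m$wavelengths)) as.numeric(m$wavelengths)),
    class = "mpls_model")
  state <- payload$pretreat_state
  if (!is.null(state)) {
    state$wavelengths_in <- as.numeric(state$wavelengths_in)
    if (!is.null(state$msc_reference))
      state$msc_reference <- as.numeric(state$msc_reference)
  }
  list(model = model,
       treatment = if (!is.null(payload$treatment))
         math_treatment(payload$treatment),
       pretreat_state = state)
}
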