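#' Standard normal variate (SNV) transform
#'
#' Centers each spectrum to mean zero and scales it to unit standard
#' deviation (n-1 denominator), removing additive offsets and multiplicative
#' scatter on a per-spectrum basis.  No training state is involved.
#'
#' @param X numeric matrix (samples x channels) or a single spectrum.
#' @return Transformed matrix (or vector) of the same shape.
#' @export
snv <- function(X) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) < 2) stop("SNV needs at least 2 channels")
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0))
    stop("constant spectrum (zero variance); SNV undefined for row(s) ",
         paste(which(s == 0), collapse = ", "))
  out <- (X - m) / s
  if (vec) drop(out) else out
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed by ordinary least squares on a reference
#' spectrum, `x ~ a + b * m`, and corrected as `(x - a) / b`.  The reference
#' is the mean of the training set and must be reused unchanged when
#' correcting prediction spectra.
#'
#' `msc_fit()` computes the reference and corrects the training matrix;
#' `msc_apply()` corrects new spectra against a stored reference.
#'
#' @param X numeric matrix (samples x channels); at least 2 training rows.
#' @return For `msc_fit()`, a list with `corrected` and `reference`; for
#'   `msc_apply()`, the corrected matrix (or spectrum).
#' @export
msc_fit <- function(X) {
  X <- rbind(X)
  if (nrow(X) < 2) stop("MSC needs at least 2 training spectra")
  ref <- colMeans(X)
  list(corrected = msc_apply(ref, X), reference = ref)
}

#' @rdname msc_fit
#' @param reference the stored reference (mean training) spectrum.
#' @export
msc_apply <- function(reference, X) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) != length(reference))
    stop("spectrum length does not match the MSC reference")
  mc <- reference - mean(reference)
  ss <- sum(mc^2)
  b <- as.vector(X %*% mc) / ss
  a <- rowMeans(X) - b * mean(reference)
  if (any(b == 0)) stop("MSC slope of 0 for row(s) ",
                        paste(which(b == 0), collapse = ", "))
  out <- (X - a) / b
  if (vec) drop(out) else out
}

#' Detrend a spectrum by polynomial baseline removal
#'
#' Subtracts the least-squares polynomial in wavelength (default quadratic)
#' from each spectrum, leaving residuals orthogonal to the polynomial basis.
#' Per-spectrum, stateless.
#'
#' @param X numeric matrix (samples x channels) or a single spectrum.
#' @param wavelengths channel wavelengths in nm.
#' @param degree polynomial degree (default 2).
#' @return Detrended matrix (or vector) of the same shape.
#' @export
detrend <- function(X, wavelengths, degree = 2) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) != length(wavelengths))
    stop("wavelengths do not match spectrum length")
  if (ncol(X) < degree + 1) stop("too few channels for degree ", degree)
  B <- stats::poly(wavelengths, degree = degree)  # orthogonal, centered
  B <- cbind(1, B)
  # projection onto the polynomial space; B has orthonormal poly columns
  coef <- t(qr.coef(qr(B), t(X)))
  out <- X - coef %*% t(B)
  if (vec) drop(out) else out
}

#' Gap-segment derivative with boxcar smoothing
#'
#' The classic NIR "math treatment" chain: boxcar smoothing over `s1`
#' consecutive channels, then the gap difference
#' `d[x](i) = x(i + ceiling(g/2)) - x(i - floor(g/2))` applied `d` times,
#' then boxcar smoothing over `s2` channels.  Edge channels without full
#' support are trimmed, never padded, and the retained wavelength subgrid is
#' returned: each smoothing or differencing step re-centers the grid on the
#' window midpoints, so the output grid remains uniform with the input step.
#'
#' @param X numeric matrix (samples x channels) or a single spectrum.
#' @param wavelengths channel wavelengths in nm.
#' @param d derivative order (0 = none).
#' @param g gap width in channels (ignored when `d = 0`; must be >= 1
#'   otherwise).
#' @param s1,s2 first and second smoothing segment lengths in channels
#'   (1 = no smoothing).
#' @return A list with `X` (trimmed transformed matrix) and `wavelengths`.
#' @export
gap_segment_derivative <- function(X, wavelengths, d, g, s1 = 1, s2 = 1) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) != length(wavelengths))
    stop("wavelengths do not match spectrum length")
  if (d < 0 || s1 < 1 || s2 < 1 || g < 0)
    stop("invalid treatment code: need d >= 0, g >= 0, s1,s2 >= 1")
  if (d > 0 && g < 1)
    stop("derivative of order ", d, " needs a gap of at least 1 channel")

  sm <- function(M, wl, s) {       # boxcar mean over s consecutive channels
    if (s == 1) return(list(M = M, wl = wl))
    if (ncol(M) < s) stop("smoothing segment exceeds spectrum length")
    cs <- cbind(0, t(apply(M, 1, cumsum)))
    j <- seq_len(ncol(M) - s + 1)
    list(M = (cs[, j + s, drop = FALSE] - cs[, j, drop = FALSE]) / s,
         wl = (wl[j] + wl[j + s - 1]) / 2)
  }
  out <- sm(X, wavelengths, s1)
  if (d > 0) {
    fwd <- ceiling(g / 2); back <- floor(g / 2)
    for (k in seq_len(d)) {
      n <- ncol(out$M)
      if (n <= g) stop("gap derivative exceeds spectrum length")
      i <- (back + 1):(n - fwd)
      out <- list(M = out$M[, i + fwd, drop = FALSE] -
                      out$M[, i - back, drop = FALSE],
                  wl = (out$wl[i + fwd] + out$wl[i - back]) / 2)
    }
  }
  out <- sm(out$M, out$wl, s2)
  list(X = if (vec) drop(out$M) else out$M, wavelengths = out$wl)
}

#' Parse a math-treatment string
#'
#' Accepts the strings conventionally printed with NIR calibrations, e.g.
#' `"Standard MSC 1,4,4,1"`, `"SNV only 2,4,4,1"`, `"Detrend only
#' 2,10,10,1"`, `"SNV-DT 1,4,4,1"`, `"None 0,0,1,1"`.  The scatter keyword is
#' case-insensitive; the four-number code reads (derivative order, gap,
#' first smoothing segment, second smoothing segment), all in channels.
#'
#' @param spec a treatment string, or an already-parsed `math_treatment`.
#' @return An object of class `math_treatment` with fields `scatter`
#'   (one of `"none"`, `"msc"`, `"snv"`, `"detrend"`, `"snv_detrend"`),
#'   `d`, `g`, `s1`, `s2`.
#' @export
math_treatment <- function(spec) {
  if (inherits(spec, "math_treatment")) return(spec)
  txt <- trimws(spec)
  m <- regmatches(txt, regexec("^(.*?)\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*,\\s*([0-9]+)$", txt))[[1]]
  if (length(m) == 0) stop("cannot parse treatment string: '", spec, "'")
  key <- tolower(gsub("[^a-z]+", " ", tolower(m[2])))
  key <- trimws(gsub("\\s+", " ", key))
  scatter <- switch(key,
    "none" = "none",
    "standard msc" = , "msc" = "msc",
    "snv only" = , "snv" = "snv",
    "detrend only" = , "detrend" = , "dt" = "detrend",
    "snv dt" = , "snv detrend" = "snv_detrend",
    stop("unknown scatter correction: '", m[2], "'"))
  code <- as.integer(m[3:6])
  out <- structure(list(scatter = scatter, d = code[1], g = code[2],
                        s1 = code[3], s2 = code[4], label = txt),
                   class = "math_treatment")
  if (out$d > 0 && out$g < 1)
    stop("derivative order ", out$d, " with gap 0 in '", spec, "'")
  if (out$s1 < 1 || out$s2 < 1)
    stop("smoothing segments must be >= 1 in '", spec, "'")
  out
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("math_treatment:", x$label, "\n")
  invisible(x)
}

#' @export
format.math_treatment <- function(x, ...) x$label

#' Apply a math treatment to a spectra matrix
#'
#' Applies the scatter correction first, then the gap-segment derivative
#' chain.  On training data (`state = NULL`) any stateful component (the MSC
#' reference spectrum) is fitted and returned; passing the returned `state`
#' back in reproduces the training transform exactly on new spectra.
#'
#' @param treatment a treatment string or [math_treatment()].
#' @param X numeric matrix (samples x channels).
#' @param wavelengths channel wavelengths in nm.
#' @param state `NULL` to fit on training data, or the `state` of a previous
#'   call to reuse at prediction time.
#' @param detrend_degree polynomial degree for the detrend step (default 2).
#' @return A list with `X` (transformed, possibly trimmed), `wavelengths`
#'   (retained subgrid), `state`, and `treatment`.
#' @export
apply_treatment <- function(treatment, X, wavelengths, state = NULL,
                            detrend_degree = 2) {
  t <- math_treatment(treatment)
  X <- rbind(X)
  if (!is.null(state)) {
    if (!identical(state$wavelengths_in, wavelengths))
      stop("prediction spectra are not on the training wavelength grid")
    detrend_degree <- state$detrend_degree
  }
  new_state <- list(wavelengths_in = wavelengths,
                    detrend_degree = detrend_degree, msc_reference = NULL)
  if (t$scatter %in% c("msc")) {
    if (is.null(state)) {
      fit <- msc_fit(X)
      X <- fit$corrected
      new_state$msc_reference <- fit$reference
    } else {
      if (is.null(state$msc_reference))
        stop("stored state has no MSC reference")
      X <- msc_apply(state$msc_reference, X)
      new_state$msc_reference <- state$msc_reference
    }
  } else if (t$scatter == "snv") {
    X <- snv(X)
  } else if (t$scatter == "detrend") {
    X <- detrend(X, wavelengths, degree = detrend_degree)
  } else if (t$scatter == "snv_detrend") {
    X <- detrend(snv(X), wavelengths, degree = detrend_degree)
  }
  out <- gap_segment_derivative(X, wavelengths, t$d, t$g, t$s1, t$s2)
  list(X = rbind(out$X), wavelengths = out$wavelengths, state = new_state,
       treatment = t)
}
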