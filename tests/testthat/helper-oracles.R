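# Independent PLS1 oracle: the PLS1 solution with f factors is the least
# squares fit restricted to the Krylov subspace span{X'y, (X'X)X'y, ...}.
# Entirely different route from the NIPALS deflation it checks.
pls1_krylov <- function(X, y, n_factors) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  v <- crossprod(Xc, yc)
  S <- crossprod(Xc)
  K <- matrix(0, ncol(X), n_factors)
  for (f in seq_len(n_factors)) {
    K[, f] <- v
    v <- S %*% v
  }
  Q <- qr.Q(qr(K))
  b <- Q %*% solve(crossprod(Q, S %*% Q), crossprod(Q, crossprod(Xc, yc)))
  list(b = drop(b), b0 = mean(y) - sum(b * colMeans(X)))
}

# Two-band Gaussian-mixture spectra with well-behaved (Gaussian) sample
# variation; used where heavy tails would get in the way of exact
# outlier-count assertions.
two_band_set <- function(n, wl = seq(1100, 2000, 2), noise = 1e-3,
                         seed = 1) {
  set.seed(seed)
  band1 <- exp(-(wl - 1400)^2 / (2 * 30^2))
  band2 <- exp(-(wl - 1700)^2 / (2 * 30^2))
  a <- rnorm(n, 1, 0.2)
  b <- rnorm(n, 0.5, 0.1)
  X <- outer(a, band1) + outer(b, band2) + 0.3 +
    matrix(rnorm(n * length(wl), 0, noise), n)
  rownames(X) <- sprintf("G%03d", seq_len(n))
  list(X = X, wl = wl, a = a, b = b,
       y = 100 + 40 * a + rnorm(n, 0, 0.5))
}
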