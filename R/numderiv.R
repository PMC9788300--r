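# Central finite differences on the link scale. Step 1e-4 link units is
# small relative to the curvature of these likelihoods yet large enough to
# stay clear of optimizer noise at reltol ~1e-9.

fd_gradient <- function(f, x, h = 1e-4) {
  p <- length(x)
  g <- numeric(p)
  for (i in seq_len(p)) {
    e <- numeric(p)
    e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < p) {
      for (j in seq((i + 1L), p)) {
        ej <- numeric(p); ej[j] <- h
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) -
             f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

# Symmetric positive-definite inverse via Cholesky; NULL if not PD.
pd_inverse <- function(H) {
  H <- (H + t(H)) / 2
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  chol2inv(ch)
}
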