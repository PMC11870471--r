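# Small internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# log I0 and I1/I0, stable for large arguments (besselI underflows its
# scaled value past ~2e5; switch to the large-argument expansion well
# before that, where it is already accurate to ~1e-8)
.log_bessel_i0 <- function(x) {
  big <- x > 50
  out <- numeric(length(x))
  if (any(!big)) {
    xb <- x[!big]
    out[!big] <- log(besselI(xb, 0, expon.scaled = TRUE)) + xb
  }
  if (any(big)) {
    xb <- x[big]
    out[big] <- xb - 0.5 * log(2 * pi * xb) +
      log1p(1 / (8 * xb) + 9 / (128 * xb^2))
  }
  out
}

.bessel_ratio_i1_i0 <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  big <- x > 50
  mid <- !small & !big
  out[small] <- x[small] / 2
  if (any(mid)) {
    xm <- x[mid]
    out[mid] <- besselI(xm, 1, expon.scaled = TRUE) /
      besselI(xm, 0, expon.scaled = TRUE)
  }
  if (any(big)) {
    xb <- x[big]
    out[big] <- 1 - 1 / (2 * xb) - 1 / (8 * xb^2) - 1 / (8 * xb^3)
  }
  out
}

.log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch via the symmetric
# tridiagonal Jacobi matrix).
.gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}
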