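# Shared fixtures: tiny datasets built in code.

single_voxel_dataset <- function(signal, protocol) {
  dwi_dataset(array(signal, c(1L, 1L, 1L, length(signal))), protocol)
}

random_spd_d6 <- function(max_diag = 1.5) {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  lam <- sort(runif(3, 0.1, max_diag), decreasing = TRUE)
  cortmicro:::mat_to_d6(R %*% diag(lam) %*% t(R))
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# A denser direction set for tests that need a fully identifiable kurtosis
# design (the 12-direction study scheme does not span all 15 components).
dense_protocol <- function(n_dirs = 30, bvals = c(0, seq(0.5, 4.5, 0.5))) {
  set.seed(99)
  d <- matrix(rnorm(3 * n_dirs), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  diffusion_protocol(bvals, d)
}

# Equal-area Fibonacci sphere grid: an oracle quadrature independent of the
# package's internal product-rule grid.
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Isotropic two-site mixture: mean D and excess kurtosis of a bi-exponential
# with equal fractions -- K = 3 Var(D) / mean(D)^2.
mixture_dk <- function(f = 0.5, d1 = 0.5, d2 = 1.5) {
  md <- f * d1 + (1 - f) * d2
  k <- 3 * (f * d1^2 + (1 - f) * d2^2 - md^2) / md^2
  list(md = md, k = k,
       d6 = c(md, md, md, 0, 0, 0),
       w15 = cortmicro:::w15_isotropic(k))
}
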