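#' Gauss--Legendre nodes and weights on [-1, 1]
#'
#' Golub--Welsch eigenvalue construction of the n-point Gauss--Legendre rule,
#' exact for polynomials up to degree 2n - 1.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, both length `n`.
#' @keywords internal
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

#' Quadrature grid on the unit sphere
#'
#' Product rule: Gauss--Legendre in cos(theta) crossed with a uniform
#' (trapezoidal, exact for trigonometric polynomials) grid in phi. Integrates
#' spherical harmonics exactly up to high band and converges spectrally for
#' smooth integrands such as directional kurtosis.
#'
#' @param n_theta Gauss--Legendre order in the polar direction.
#' @param n_phi number of equispaced azimuthal nodes.
#' @return list with `points` (n x 3 unit vectors) and `weights` summing to 1
#'   (so weighted sums are spherical means).
#' @keywords internal
sphere_grid <- function(n_theta = 24, n_phi = 48) {
  gl <- gauss_legendre(n_theta)
  ct <- gl$nodes
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  pts <- cbind(
    x = as.vector(outer(st, cos(phi))),
    y = as.vector(outer(st, sin(phi))),
    z = rep(ct, times = n_phi)
  )
  w <- rep(gl$weights / (2 * n_phi), times = n_phi)
  list(points = pts, weights = w)
}

#' Legendre polynomials P_0..P_lmax evaluated at t
#'
#' @param t numeric vector in [-1, 1].
#' @param lmax maximum degree.
#' @return matrix length(t) x (lmax + 1); column l + 1 holds P_l(t).
#' @keywords internal
legendre_poly <- function(t, lmax) {
  out <- matrix(0, length(t), lmax + 1L)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- t
  if (lmax >= 2) {
    for (l in 2:lmax) {
      out[, l + 1] <- ((2 * l - 1) * t * out[, l] - (l - 1) * out[, l - 1]) / l
    }
  }
  out
}

# Associated Legendre P_l^m(x) (with Condon-Shortley phase) for fixed m,
# all l in m..lmax. Returns matrix length(x) x (lmax - m + 1).
assoc_legendre <- function(x, m, lmax) {
  s <- sqrt(pmax(0, 1 - x^2))
  n_l <- lmax - m + 1L
  out <- matrix(0, length(x), n_l)
  pmm <- rep(1, length(x))
  if (m > 0) {
    dfact <- prod(seq(1, 2 * m - 1, by = 2))
    pmm <- (-1)^m * dfact * s^m
  }
  out[, 1] <- pmm
  if (n_l >= 2) {
    out[, 2] <- x * (2 * m + 1) * pmm
    if (n_l >= 3) {
      for (l in (m + 2):lmax) {
        out[, l - m + 1] <- ((2 * l - 1) * x * out[, l - m] -
                               (l + m - 1) * out[, l - m - 1]) / (l - m)
      }
    }
  }
  out
}

#' Real even spherical-harmonic basis
#'
#' Orthonormal real spherical harmonics for even bands l = 0, 2, ..., lmax,
#' ordered (l, m) with m = -l..l within each band. With this normalisation a
#' function f = sum c_lm Y_lm has spherical integral c_00 * sqrt(4 pi).
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum (even) band.
#' @return n x n_coef matrix; `attr(, "bands")` gives each column's l.
#' @keywords internal
real_sh <- function(dirs, lmax = 4) {
  dirs <- matrix(dirs, ncol = 3)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ells <- seq(0, lmax, by = 2)
  ncoef <- sum(2 * ells + 1)
  out <- matrix(0, nrow(dirs), ncoef)
  bands <- integer(ncoef)
  col <- 1L
  for (l in ells) {
    for (m in (-l):l) {
      am <- abs(m)
      P <- assoc_legendre(ct, am, l)[, l - am + 1]
      N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      out[, col] <- if (m > 0) {
        sqrt(2) * N * P * cos(m * phi)
      } else if (m < 0) {
        sqrt(2) * N * P * sin(am * phi)
      } else {
        N * P
      }
      bands[col] <- l
      col <- col + 1L
    }
  }
  attr(out, "bands") <- bands
  out
}
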