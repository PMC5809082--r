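# Cached sphere quadrature for mean-kurtosis averaging (spherical product
# rule, exact for high-band harmonics; see sphere_grid()).
.mk_grid_env <- new.env(parent = emptyenv())

mk_grid <- function() {
  if (is.null(.mk_grid_env$grid)) {
    g <- sphere_grid(24, 48)
    g$Nd <- d_design(g$points)
    g$Nw <- w_design(g$points)
    .mk_grid_env$grid <- g
  }
  .mk_grid_env$grid
}

# DKI design matrix for log-signal: columns (lnS0 | D (6) | V (15)) where
# V = MD^2 * W is the raw quartic coefficient tensor.
dki_design <- function(frames) {
  g <- as.matrix(frames[, c("gx", "gy", "gz")])
  cbind(1, -frames$b * d_design(g), (frames$b^2 / 6) * w_design(g))
}

# sqrt-multiplicity column scaling on the V block so that the pseudoinverse
# minimum-norm solution minimises the Frobenius norm of the kurtosis tensor
# (the direction set may not span all 15 components; 12 directions cannot).
dki_col_scale <- function() c(1, rep(1, 6), 1 / sqrt(.w_tab$mult))

#' Fit the diffusion kurtosis tensor (conventional NLLS)
#'
#' Voxel-wise non-linear least-squares fit of
#' `ln S(b, n) = ln S0 - b D_app(n) + (b^2 / 6) MD^2 What(n)`
#' on the shells with b <= `b_max` (default 4.5 ms/um^2). Initialisation is
#' the weighted log-linear solution (minimum-Frobenius-norm pseudoinverse,
#' which keeps the fit well-defined when the direction set does not span all
#' 15 kurtosis components); refinement is Levenberg--Marquardt on the
#' magnitude signal with an analytic Jacobian. No positivity or kurtosis-range
#' constraints are imposed (optional clamping via `k_clamp`).
#'
#' @param dataset a [dwi_dataset()].
#' @param mask logical 3-D array of voxels to fit.
#' @param b_max largest b-value used, ms/um^2 (default 4.5).
#' @param max_iter Levenberg--Marquardt iteration cap; non-converged voxels
#'   keep the log-linear estimate and are flagged.
#' @param k_clamp optional length-2 numeric; when given, directional kurtosis
#'   summaries are clamped to this range at metric time.
#' @return an object of class `dki_fit` with per-voxel `d6` (um^2/ms), `v15`
#'   (raw quartic tensor, MD^2-scaled kurtosis), `w15` (dimensionless kurtosis
#'   tensor), `s0`, `rss`, `converged`, and the tensor eigensystem.
#' @export
fit_dki <- function(dataset, mask = NULL, b_max = 4.5, max_iter = 100L,
                    k_clamp = NULL) {
  pr <- prep_signal(dataset, mask, b_max)
  fr <- pr$frames
  b_nz <- unique(fr$b[fr$b > 0])
  dirs <- unique(round(as.matrix(fr[fr$b > 0, c("gx", "gy", "gz")]), 10))
  if (length(b_nz) < 3L) stop("insufficient shells: DKI needs >= 3 distinct non-zero b-values <= b_max")
  if (nrow(dirs) < 9L) stop("insufficient directions: DKI needs >= 9")
  if (nrow(fr) < 22L) stop("fewer than 22 usable measurements")
  X <- dki_design(fr)
  cs <- dki_col_scale()
  Xs <- sweep(X, 2, cs, `*`)
  # Row-space projector in the scaled coordinates: when the direction set
  # does not span all kurtosis components (12 directions cannot), the NLLS
  # solution is defined only up to the design's null space; all estimates
  # are reported as the minimum-Frobenius-norm representative, which leaves
  # predicted signals unchanged.
  sv <- svd(Xs)
  Vr <- sv$v[, sv$d > 1e-10 * sv$d[1], drop = FALSE]
  Y <- t(log(pr$signal))
  # log-linear init with one WLLS pass
  theta <- sweep(pinv_solve(Xs, Y), 1, cs, `*`)
  pred <- exp(X %*% theta)
  nvox <- ncol(Y)
  conv <- logical(nvox)
  for (v in seq_len(nvox)) {
    th <- cs * pinv_solve(Xs, Y[, v], w = pred[, v]^2)
    y <- pr$signal[v, ]
    res_fn <- function(p) exp(drop(X %*% (cs * p))) - y
    jac_fn <- function(p) {
      s <- exp(drop(X %*% (cs * p)))
      (s * X) * rep(cs, each = length(s))
    }
    fit <- minpack.lm::nls.lm(
      par = th / cs, fn = res_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    )
    if (fit$info %in% 1:4) {
      theta[, v] <- cs * drop(Vr %*% crossprod(Vr, fit$par))
      conv[v] <- TRUE
    } # else: keep log-linear estimate, flagged
  }
  d6 <- t(theta[2:7, , drop = FALSE])
  v15 <- t(theta[8:22, , drop = FALSE])
  md <- rowMeans(d6[, 1:3, drop = FALSE])
  w15 <- v15 / md^2
  resid <- exp(X %*% theta) - t(pr$signal)
  eigs <- lapply(seq_len(nvox), function(v) tensor_eigen(d6[v, ]))
  structure(list(
    d6 = d6, v15 = v15, w15 = w15,
    s0 = exp(theta[1, ]),
    rss = colSums(resid^2),
    converged = conv,
    eigvals = do.call(rbind, lapply(eigs, `[[`, "values")),
    eigvecs = lapply(eigs, `[[`, "vectors"),
    voxels = pr$voxels, mask = pr$mask, dims = pr$dims,
    voxel_size_mm = pr$voxel_size_mm, b_max = b_max, k_clamp = k_clamp
  ), class = "dki_fit")
}

#' @exportS3Method base::print
print.dki_fit <- function(x, ...) {
  cat("Diffusion kurtosis fit:", nrow(x$d6), "voxels (b <=", x$b_max,
      "ms/um^2),", sum(!x$converged), "non-converged\n")
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) {
  out <- data.frame(voxel = object$voxels, s0 = object$s0, object$d6,
                    object$w15, rss = object$rss,
                    converged = object$converged)
  names(out) <- c("voxel", "s0", paste0("d_", d6_names),
                  paste0("w_", .w_tab$names), "rss", "converged")
  out
}

#' @export
predict.dki_fit <- function(object, protocol = NULL, ...) {
  if (is.null(protocol)) stop("supply the protocol to predict signals for")
  X <- dki_design(protocol$frames)
  exp(X %*% rbind(log(object$s0), t(object$d6), t(object$v15)))
}

#' Construct a single-voxel kurtosis fit from known tensors
#'
#' Convenience constructor (e.g. for analytically known ground truth): takes
#' the diffusion tensor and the dimensionless kurtosis tensor directly.
#'
#' @param d either a 3 x 3 symmetric matrix or a packed 6-vector, um^2/ms.
#' @param w15 packed 15-component kurtosis tensor (dimensionless,
#'   MD^2-normalised convention).
#' @param s0 signal scale.
#' @return a `dki_fit` with one voxel.
#' @export
dki_voxel <- function(d, w15, s0 = 1) {
  d6 <- if (is.matrix(d)) mat_to_d6(d) else as.numeric(d)
  md <- mean(d6[1:3])
  e <- tensor_eigen(d6)
  structure(list(
    d6 = matrix(d6, 1), v15 = matrix(w15 * md^2, 1), w15 = matrix(w15, 1),
    s0 = s0, rss = 0, converged = TRUE,
    eigvals = matrix(e$values, 1), eigvecs = list(e$vectors),
    voxels = 1L, mask = array(TRUE, c(1L, 1L, 1L)), dims = c(1L, 1L, 1L),
    voxel_size_mm = c(0.25, 0.25, 0.25), b_max = Inf, k_clamp = NULL
  ), class = "dki_fit")
}

#' Apparent (directional) kurtosis
#'
#' `K_app(n) = MD^2 What(n) / D_app(n)^2` for a fitted voxel.
#'
#' @param fit a `dki_fit`.
#' @param n unit direction vector.
#' @param voxel voxel row index within the fit (default 1).
#' @return dimensionless apparent kurtosis; `NaN` with a warning when
#'   `D_app(n) <= 0`.
#' @export
directional_kurtosis <- function(fit, n, voxel = 1L) {
  n <- as.numeric(n)
  if (abs(sum(n^2) - 1) > 1e-6) stop("direction must have unit norm")
  d6 <- fit$d6[voxel, ]
  md <- mean(d6[1:3])
  d_app <- drop(d_design(n) %*% d6)
  if (d_app <= 0) {
    warning("non-positive apparent diffusivity; K_app undefined")
    return(NaN)
  }
  w_app <- drop(w_design(n) %*% fit$w15[voxel, ])
  md^2 * w_app / d_app^2
}

# Per-voxel kurtosis summary used by kurtosis_metrics().
kurtosis_metrics_voxel <- function(d6, w15, n_phi = 64L) {
  md <- mean(d6[1:3])
  g <- mk_grid()
  d_app <- drop(g$Nd %*% d6)
  w_app <- drop(g$Nw %*% w15)
  mk <- sum(g$weights * md^2 * w_app / d_app^2)
  e <- tensor_eigen(d6)
  e1 <- e$vectors[, 1]
  ak <- md^2 * drop(w_design(e1) %*% w15) / drop(d_design(e1) %*% d6)^2
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  perp <- cbind(cos(phi)) %*% rbind(e$vectors[, 2]) +
    cbind(sin(phi)) %*% rbind(e$vectors[, 3])
  rk <- mean(md^2 * drop(w_design(perp) %*% w15) /
               drop(d_design(perp) %*% d6)^2)
  wp <- rotate_w15(w15, t(e$vectors))       # eigenframe components
  names(wp) <- .w_tab$names
  mkt <- (wp["1111"] + wp["2222"] + wp["3333"] +
            2 * (wp["1122"] + wp["1133"] + wp["2233"])) / 5
  w_l <- wp["1111"]
  w_t <- (3 / 8) * (wp["2222"] + wp["3333"] + 2 * wp["2233"])
  c(MK = mk, AK = ak, RK = rk, MKT = unname(mkt), W_L = unname(w_l),
    W_T = unname(w_t))
}

#' Kurtosis metrics (MK, AK, RK, MKT, W_L, W_T)
#'
#' Directional summaries: MK is the spherical mean of the apparent kurtosis
#' `K_app(n)` by quadrature; AK is `K_app` along the principal diffusion
#' eigenvector; RK is the azimuthal mean of `K_app` over the perpendicular
#' plane. Tensor summaries are contractions of W in the diffusion eigenframe:
#' `MKT = (1/5) [W'1111 + W'2222 + W'3333 + 2 (W'1122 + W'1133 + W'2233)]`
#' (equal to the spherical surface average of What), `W_L = W'1111`, and
#' `W_T = (3/8) [W'2222 + W'3333 + 2 W'2233]`. Near-degenerate eigenvalues are
#' resolved by a deterministic tie-break (largest |z| component).
#'
#' @param fit a `dki_fit`.
#' @return for a single-voxel fit, a named vector of the six metrics;
#'   otherwise a named list of [parameter_map()]s.
#' @export
kurtosis_metrics <- function(fit) {
  vals <- t(vapply(seq_len(nrow(fit$d6)), function(v) {
    kurtosis_metrics_voxel(fit$d6[v, ], fit$w15[v, ])
  }, numeric(6)))
  if (!is.null(fit$k_clamp)) {
    vals[, c("MK", "AK", "RK")] <- pmin(pmax(vals[, c("MK", "AK", "RK")],
                                             fit$k_clamp[1]), fit$k_clamp[2])
  }
  if (nrow(vals) == 1L) return(vals[1, ])
  lapply(stats::setNames(nm = colnames(vals)),
         function(m) fit_map(fit, vals[, m], m))
}
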