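# Shared voxel-wise signal preparation: selects frames with b <= b_max,
# averages all b = 0 frames into one effective measurement, and returns the
# masked voxel x frame signal matrix. Voxels containing a non-positive signal
# in any used frame are dropped from the mask (log-domain fitting is
# undefined there) and reported.
prep_signal <- function(dataset, mask = NULL, b_max = Inf) {
  dims <- dim(dataset$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  keep <- subset_frames(dataset$protocol, b_max)
  fr <- dataset$protocol$frames[keep, , drop = FALSE]
  sig <- aperm(dataset$signal, c(4, 1, 2, 3))
  dim(sig) <- c(dim(dataset$signal)[4], prod(dims))
  sig <- sig[keep, , drop = FALSE]
  vox <- which(as.vector(mask))
  sig <- t(sig[, vox, drop = FALSE])          # voxel x frame
  b0 <- fr$b == 0
  if (!any(b0)) stop("protocol has no b = 0 frame")
  s0_obs <- rowMeans(sig[, b0, drop = FALSE])
  sig <- cbind(s0_obs, sig[, !b0, drop = FALSE])
  fr <- rbind(data.frame(b = 0, gx = 0, gy = 0, gz = 0),
              fr[!b0, , drop = FALSE])
  bad <- which(apply(sig, 1, function(s) any(s <= 0)))
  if (length(bad)) {
    message(length(bad), " voxel(s) with non-positive signal excluded from fit")
    mask[vox[bad]] <- FALSE
    vox <- vox[-bad]
    sig <- sig[-bad, , drop = FALSE]
  }
  list(signal = sig, frames = fr, voxels = vox, mask = mask, dims = dims,
       voxel_size_mm = dataset$voxel_size_mm)
}

# Min-norm (Frobenius-weighted) least squares via SVD pseudoinverse.
pinv_solve <- function(X, Y, w = NULL, tol = 1e-10) {
  if (!is.null(w)) {
    X <- X * sqrt(w)
    Y <- Y * sqrt(w)
  }
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% Y) / sv$d[keep])
}

#' Fit the diffusion tensor (weighted log-linear least squares)
#'
#' Voxel-wise diffusion tensor estimation on the shells at or below `b_max`.
#' All b = 0 frames are averaged first. The estimator is linear least squares
#' on the log-signal followed by one reweighting pass with weights equal to
#' the squared predicted signal (WLLS), the standard deterministic
#' approximation to the Gaussian maximum-likelihood tensor fit.
#'
#' @param dataset a [dwi_dataset()].
#' @param mask logical 3-D array of voxels to fit (default: all).
#' @param b_max largest b-value used, ms/um^2. Default 1.0 for a pure
#'   Gaussian-regime fit; pipelines that also fit the kurtosis tensor take MD
#'   and FA from that joint fit instead (see [fit_dki()]).
#' @return an object of class `dti_fit`: per-voxel tensors (packed
#'   xx, yy, zz, xy, xz, yz in um^2/ms), `s0`, residual sums of squares,
#'   eigensystem, and a `neg_eig` diagnostic flag. Negative eigenvalues are
#'   permitted but flagged.
#' @export
fit_dti <- function(dataset, mask = NULL, b_max = 1.0) {
  pr <- prep_signal(dataset, mask, b_max)
  fr <- pr$frames
  if (length(unique(fr$b)) < 2L || nrow(fr) < 7L) {
    stop("insufficient shells: DTI needs >= 7 measurements over >= 2 distinct b-values <= b_max")
  }
  X <- cbind(1, -fr$b * d_design(as.matrix(fr[, c("gx", "gy", "gz")])))
  Y <- t(log(pr$signal))                       # frame x voxel
  beta <- pinv_solve(X, Y)
  # one WLLS refinement per voxel (weights = squared predicted signal)
  pred <- exp(X %*% beta)
  nvox <- ncol(Y)
  for (v in seq_len(nvox)) {
    beta[, v] <- pinv_solve(X, Y[, v], w = pred[, v]^2)
  }
  resid <- Y - X %*% beta
  d6 <- t(beta[-1, , drop = FALSE])
  eigs <- lapply(seq_len(nvox), function(v) tensor_eigen(d6[v, ]))
  structure(list(
    d6 = d6,
    s0 = exp(beta[1, ]),
    rss = colSums(resid^2),
    eigvals = do.call(rbind, lapply(eigs, `[[`, "values")),
    eigvecs = lapply(eigs, `[[`, "vectors"),
    neg_eig = vapply(eigs, function(e) any(e$values < 0), logical(1)),
    voxels = pr$voxels, mask = pr$mask, dims = pr$dims,
    voxel_size_mm = pr$voxel_size_mm, b_max = b_max
  ), class = "dti_fit")
}

#' @exportS3Method base::print
print.dti_fit <- function(x, ...) {
  cat("Diffusion tensor fit:", nrow(x$d6), "voxels (b <=", x$b_max, "ms/um^2)\n")
  cat("  voxels with negative eigenvalues:", sum(x$neg_eig), "\n")
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) {
  out <- data.frame(voxel = object$voxels, s0 = object$s0, object$d6,
                    object$eigvals, rss = object$rss)
  names(out) <- c("voxel", "s0", paste0("d_", d6_names),
                  paste0("lambda", 1:3), "rss")
  out
}

# MD and FA from sorted eigenvalues; FA clamped to [0, 1] and defined as 0
# for near-zero tensors (MD < 1e-6 um^2/ms).
md_from_eigvals <- function(lam) mean(lam)

fa_from_eigvals <- function(lam) {
  md <- mean(lam)
  if (abs(md) < 1e-6) return(0)
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  min(1, max(0, sqrt(1.5 * sum((lam - md)^2) / ss)))
}

#' Diffusion tensor metrics (MD, FA)
#'
#' MD = (lambda1 + lambda2 + lambda3) / 3; FA = sqrt(3/2 * sum((lambda_i -
#' MD)^2) / sum(lambda_i^2)), clamped to [0, 1], with FA := 0 when
#' MD < 1e-6 um^2/ms. Axial/radial diffusivities are computed internally
#' (available from the eigenvalues) but not emitted as maps.
#'
#' @param fit a `dti_fit` (or a `dki_fit`, whose tensor is used unchanged).
#' @return named list of [parameter_map()]s `MD` and `FA`.
#' @export
dti_metrics <- function(fit) {
  md <- apply(fit$eigvals, 1, md_from_eigvals)
  fa <- apply(fit$eigvals, 1, fa_from_eigvals)
  list(MD = fit_map(fit, md, "MD"), FA = fit_map(fit, fa, "FA"))
}

# Wrap a per-fitted-voxel vector into a parameter_map on the fit's grid.
fit_map <- function(fit, values, name) {
  arr <- array(NA_real_, fit$dims)
  arr[fit$voxels] <- values
  parameter_map(name, arr, mask = fit$mask, voxel_size_mm = fit$voxel_size_mm)
}

#' @export
predict.dti_fit <- function(object, protocol = NULL, ...) {
  if (is.null(protocol)) stop("supply the protocol to predict signals for")
  fr <- protocol$frames
  X <- cbind(1, -fr$b * d_design(as.matrix(fr[, c("gx", "gy", "gz")])))
  exp(X %*% rbind(log(object$s0), t(object$d6)))
}
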