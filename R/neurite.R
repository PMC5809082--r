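# Stick-kernel Legendre band coefficients. The intra-neurite (stick)
# response exp(-u t^2), u = b * D_L, t = cos(angle between gradient and
# neurite), expanded as sum_l k_l(u) P_l(t); coefficients by 64-point
# Gauss--Legendre quadrature. kd gives dk/du (for the analytic Jacobian).
.stick_env <- new.env(parent = emptyenv())

stick_quad <- function() {
  if (is.null(.stick_env$q)) {
    gl <- gauss_legendre(64)
    .stick_env$q <- list(t = gl$nodes, w = gl$weights,
                         P = legendre_poly(gl$nodes, 4))
  }
  .stick_env$q
}

stick_kernel_bands <- function(u, ells = c(0, 2, 4), deriv = FALSE) {
  q <- stick_quad()
  E <- exp(-outer(q$t^2, u))                     # node x u
  if (deriv) E <- E * (-q$t^2)
  out <- matrix(0, length(u), length(ells))
  for (j in seq_along(ells)) {
    l <- ells[j]
    out[, j] <- drop(crossprod(E, q$w * q$P[, l + 1])) * (2 * l + 1) / 2
  }
  out
}

#' Two-compartment neurite model parameters
#'
#' The model splits the diffusion signal into a stick compartment (axons and
#' dendrites, longitudinal diffusivity `d_long`, zero transverse diffusivity)
#' whose orientations follow an even spherical-harmonic distribution, and an
#' isotropic Gaussian extra-neurite compartment with scalar diffusivity
#' `d_eff`. `neu` is the stick compartment's T2-weighted signal fraction (the
#' "neurite density"), not a volume fraction.
#'
#' @param neu neurite signal fraction in [0, 1].
#' @param d_long longitudinal intra-neurite diffusivity D_L, um^2/ms, in
#'   [0, 3] (ex-vivo bound).
#' @param d_eff extra-neurite isotropic diffusivity, um^2/ms, in [0, 3].
#' @param odf_coeffs real even spherical-harmonic ODF coefficients (bands
#'   0, 2, ..., `sh_order`); the l = 0 coefficient is fixed at 1/sqrt(4 pi)
#'   so the ODF integrates to one. `NULL` gives the isotropic ODF.
#' @param s0 non-diffusion-weighted signal scale.
#' @param sh_order maximum (even) spherical-harmonic band, default 4.
#' @return an object of class `neurite_params`.
#' @export
neurite_params <- function(neu, d_long, d_eff, odf_coeffs = NULL, s0 = 1,
                           sh_order = 4) {
  if (neu < 0 || neu > 1) stop("neu must lie in [0, 1]")
  if (d_long < 0 || d_long > 3 || d_eff < 0 || d_eff > 3) {
    stop("diffusivities must lie in [0, 3] um^2/ms")
  }
  ncoef <- sum(2 * seq(0, sh_order, by = 2) + 1)
  if (is.null(odf_coeffs)) {
    odf_coeffs <- c(1 / sqrt(4 * pi), rep(0, ncoef - 1))
  }
  if (length(odf_coeffs) != ncoef) {
    stop("odf_coeffs must have ", ncoef, " entries for sh_order ", sh_order)
  }
  if (abs(odf_coeffs[1] * sqrt(4 * pi) - 1) > 1e-6) {
    stop("ODF not normalised: the l = 0 coefficient must be 1/sqrt(4 pi)")
  }
  structure(list(neu = neu, d_long = d_long, d_eff = d_eff,
                 odf_coeffs = as.numeric(odf_coeffs), s0 = s0,
                 sh_order = sh_order),
            class = "neurite_params")
}

#' @exportS3Method base::print
print.neurite_params <- function(x, ...) {
  cat(sprintf("Neurite model: neu = %.3f, D_L = %.3f, D_eff = %.3f um^2/ms (SH order %d)\n",
              x$neu, x$d_long, x$d_eff, x$sh_order))
  invisible(x)
}

# Axially symmetric ODF coefficients from a Watson-like concentration kappa,
# oriented along `axis`: band-limited projection of exp(kappa (n.axis)^2).
watson_odf_coeffs <- function(kappa, axis = c(0, 0, 1), sh_order = 4) {
  q <- stick_quad()
  f <- exp(kappa * q$t^2)
  norm <- sum(q$w * f) * 2 * pi
  ells <- seq(0, sh_order, by = 2)
  # zonal coefficients along +z: c_l = 2 pi int f(t) Ybar_l0(t) dt / norm
  cz <- vapply(ells, function(l) {
    N <- sqrt((2 * l + 1) / (4 * pi))
    2 * pi * sum(q$w * f * N * q$P[, l + 1]) / norm
  }, numeric(1))
  axis <- axis / sqrt(sum(axis^2))
  # rotate the zonal ODF to `axis` via the addition theorem:
  # f(n) = sum_l cz_l sqrt((2l+1)/(4pi)) P_l(n . axis); project onto the basis
  grid <- sphere_grid(24, 48)
  t_ax <- drop(grid$points %*% axis)
  P <- legendre_poly(t_ax, sh_order)
  fvals <- rep(0, nrow(grid$points))
  for (j in seq_along(ells)) {
    l <- ells[j]
    fvals <- fvals + cz[j] * sqrt((2 * l + 1) / (4 * pi)) * P[, l + 1]
  }
  Y <- real_sh(grid$points, sh_order)
  drop(crossprod(Y, grid$weights * fvals)) * 4 * pi
}

#' Forward signal of the two-compartment neurite model
#'
#' `S(b, g) = s0 [ neu * int f(n) exp(-b D_L (g.n)^2) dn +
#' (1 - neu) exp(-b D_eff) ]`, the orientation integral evaluated by
#' expanding the stick kernel in Legendre bands (64-point Gauss--Legendre)
#' and contracting with the ODF's spherical-harmonic coefficients.
#'
#' @param params a [neurite_params()].
#' @param protocol a [diffusion_protocol()].
#' @return numeric vector of predicted signals, one per protocol frame.
#' @export
neurite_forward <- function(params, protocol) {
  fr <- protocol$frames
  if (any(fr$b < 0)) stop("negative b-value")
  Y <- real_sh(as.matrix(fr[, c("gx", "gy", "gz")]), params$sh_order)
  bands <- attr(Y, "bands")
  ells <- seq(0, params$sh_order, by = 2)
  K <- stick_kernel_bands(fr$b * params$d_long, ells)
  fac <- K[, match(bands, ells)] * rep(4 * pi / (2 * bands + 1), each = nrow(fr))
  intra <- drop((Y * fac) %*% params$odf_coeffs)
  intra[fr$b == 0] <- 1   # exact no-weighting limit
  params$s0 * (params$neu * intra + (1 - params$neu) * exp(-fr$b * params$d_eff))
}

# --- fitting ---------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Fitting options for [fit_neurite()]
#'
#' @param sh_order even spherical-harmonic order of the fitted ODF (4 by
#'   default; 2 is exposed for reduced direction sets).
#' @param grid_neu,grid_d_long,grid_d_eff multi-start initial values; the
#'   full 3 x 3 x 3 grid is scored and starts are refined by
#'   Levenberg--Marquardt in order of initial residual.
#' @param refine_top number of grid starts refined (default: all 27).
#'   Refinement stops early once a start reaches the noise floor (an
#'   essentially perfect fit cannot be improved by further restarts), so
#'   noiseless fits remain cheap at the full default. Reduced values trade
#'   robustness to local minima for speed in large simulation studies.
#' @param max_iter LM iteration cap per start.
#' @return list of options.
#' @export
neurite_fit_options <- function(sh_order = 4,
                                grid_neu = c(0.2, 0.5, 0.8),
                                grid_d_long = c(0.5, 1.0, 1.5),
                                grid_d_eff = c(0.3, 0.7, 1.1),
                                refine_top = 27L, max_iter = 80L) {
  list(sh_order = sh_order, grid_neu = grid_neu, grid_d_long = grid_d_long,
       grid_d_eff = grid_d_eff, refine_top = refine_top, max_iter = max_iter)
}

# Model evaluation machinery shared by residual and Jacobian; precomputed per
# protocol: SH design of the frame directions and band bookkeeping.
neurite_eval_ctx <- function(frames, sh_order) {
  Y <- real_sh(as.matrix(frames[, c("gx", "gy", "gz")]), sh_order)
  bands <- attr(Y, "bands")
  ells <- seq(0, sh_order, by = 2)
  ub <- unique(frames$b)
  list(Y = Y, bands = bands, ells = ells, band_col = match(bands, ells),
       band_fac = 4 * pi / (2 * bands + 1), b = frames$b,
       ub = ub, shell_of = match(frames$b, ub),
       is_b0 = frames$b == 0, ncoef = ncol(Y))
}

neurite_unpack <- function(p, ctx) {
  list(s0 = exp(p[1]), neu = sigmoid(p[2]),
       d_long = 3 * sigmoid(p[3]), d_eff = 3 * sigmoid(p[4]),
       f = c(1 / sqrt(4 * pi), p[-(1:4)]))
}

neurite_model_parts <- function(p, ctx, deriv = FALSE) {
  th <- neurite_unpack(p, ctx)
  K <- stick_kernel_bands(ctx$ub * th$d_long, ctx$ells)[ctx$shell_of, ,
                                                        drop = FALSE]
  M <- ctx$Y * K[, ctx$band_col] * rep(ctx$band_fac, each = length(ctx$b))
  intra <- drop(M %*% th$f)
  intra[ctx$is_b0] <- 1
  E <- exp(-ctx$b * th$d_eff)
  S <- th$s0 * (th$neu * intra + (1 - th$neu) * E)
  out <- list(theta = th, S = S, intra = intra, E = E, M = M)
  if (deriv) {
    Kd <- stick_kernel_bands(ctx$ub * th$d_long, ctx$ells,
                             deriv = TRUE)[ctx$shell_of, , drop = FALSE]
    Md <- ctx$Y * Kd[, ctx$band_col] * rep(ctx$band_fac, each = length(ctx$b))
    dintra_du <- drop(Md %*% th$f)          # d intra / d(D_L) per unit b
    dintra_du[ctx$is_b0] <- 0
    out$dintra_dDL <- ctx$b * dintra_du
  }
  out
}

neurite_jacobian <- function(p, ctx) {
  m <- neurite_model_parts(p, ctx, deriv = TRUE)
  th <- m$theta
  J <- matrix(0, length(ctx$b), length(p))
  J[, 1] <- m$S                                           # d/d log s0
  J[, 2] <- th$s0 * (m$intra - m$E) * th$neu * (1 - th$neu)
  J[, 3] <- th$s0 * th$neu * m$dintra_dDL * th$d_long * (1 - th$d_long / 3)
  J[, 4] <- -th$s0 * (1 - th$neu) * ctx$b * m$E * th$d_eff * (1 - th$d_eff / 3)
  if (ctx$ncoef > 1) {
    Mfree <- m$M[, -1, drop = FALSE]
    Mfree[ctx$is_b0, ] <- 0
    J[, -(1:4)] <- th$s0 * th$neu * Mfree
  }
  J
}

#' Fit the two-compartment neurite model voxel-wise
#'
#' Levenberg--Marquardt minimisation of squared residuals on the magnitude
#' signal, with bound enforcement by sigmoid reparametrisation (neu in
#' [0, 1]; diffusivities in [0, 3] um^2/ms) and multi-start initialisation
#' over a 3 x 3 x 3 grid of (neu, D_L, D_eff); the grid is scored on initial
#' RSS and the best `refine_top` starts are refined. Intended for the full
#' multi-shell protocol (all shells, b up to 8 ms/um^2).
#'
#' @param dataset a [dwi_dataset()].
#' @param mask logical 3-D array of voxels to fit.
#' @param options a [neurite_fit_options()] list.
#' @return an object of class `neurite_fit` with per-voxel estimates
#'   (`neu`, `d_long`, `d_eff`, `s0`, ODF coefficients), `rss`, convergence
#'   and identifiability flags (`identifiable` is FALSE when the fitted neu
#'   is outside [0.02, 0.98] or the Jacobian is rank-deficient at the
#'   optimum), the number of restarts refined, and the fraction of ODF mass
#'   below zero as a diagnostic.
#' @export
fit_neurite <- function(dataset, mask = NULL, options = neurite_fit_options()) {
  pr <- prep_signal(dataset, mask, Inf)
  fr <- pr$frames
  if (nrow(fr) < 40L) stop("neurite model needs >= 40 measurements")
  ctx <- neurite_eval_ctx(fr, options$sh_order)
  starts <- as.matrix(expand.grid(neu = options$grid_neu,
                                  d_long = options$grid_d_long,
                                  d_eff = options$grid_d_eff))
  nvox <- nrow(pr$signal)
  npar <- 4L + ctx$ncoef - 1L
  est <- matrix(NA_real_, nvox, npar)
  rss <- rep(NA_real_, nvox)
  conv <- logical(nvox)
  ident <- logical(nvox)
  n_used <- integer(nvox)
  odf_neg <- rep(NA_real_, nvox)
  grid <- sphere_grid(12, 24)
  Ygrid <- real_sh(grid$points, options$sh_order)
  for (v in seq_len(nvox)) {
    y <- pr$signal[v, ]
    s0_init <- y[ctx$is_b0][1]
    p0s <- lapply(seq_len(nrow(starts)), function(i) {
      c(log(s0_init), logit(starts[i, 1]), logit(starts[i, 2] / 3),
        logit(starts[i, 3] / 3), rep(0, ctx$ncoef - 1L))
    })
    init_rss <- vapply(p0s, function(p) {
      sum((neurite_model_parts(p, ctx)$S - y)^2)
    }, numeric(1))
    ord <- order(init_rss)[seq_len(min(options$refine_top, length(p0s)))]
    best <- NULL
    for (i in ord) {
      fit <- try(minpack.lm::nls.lm(
        par = p0s[[i]],
        fn = function(p) neurite_model_parts(p, ctx)$S - y,
        jac = function(p) neurite_jacobian(p, ctx),
        control = minpack.lm::nls.lm.control(maxiter = options$max_iter)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (best$deviance < 1e-12 * sum(y^2)) break   # perfect fit reached
    }
    if (is.null(best)) next                  # all restarts failed: unfit
    th <- neurite_unpack(best$par, ctx)
    est[v, ] <- c(th$s0, th$neu, th$d_long, th$d_eff, th$f[-1])
    rss[v] <- best$deviance
    conv[v] <- best$info %in% 1:4
    n_used[v] <- length(ord)
    # Scalar identifiability: the reported parameters (s0, neu, D_L, D_eff)
    # are identifiable iff no null direction of the Jacobian at the optimum
    # has a component on them (high-band ODF coefficients may legitimately
    # be underdetermined on reduced direction sets).
    J <- neurite_jacobian(best$par, ctx)
    sj <- svd(J)
    null_dirs <- sj$v[, sj$d < 1e-8 * sj$d[1], drop = FALSE]
    scalars_ok <- !ncol(null_dirs) || max(abs(null_dirs[1:4, ])) < 1e-6
    ident[v] <- scalars_ok && th$neu >= 0.02 && th$neu <= 0.98
    fo <- drop(Ygrid %*% th$f)
    odf_neg[v] <- sum(grid$weights * pmax(-fo, 0)) /
      sum(grid$weights * abs(fo))
  }
  ok <- !is.na(rss)
  mask_out <- pr$mask
  mask_out[pr$voxels[!ok]] <- FALSE
  colnames(est) <- c("s0", "neu", "d_long", "d_eff",
                     paste0("f", seq_len(ctx$ncoef - 1L)))
  structure(list(
    estimates = est[ok, , drop = FALSE], rss = rss[ok],
    converged = conv[ok], identifiable = ident[ok],
    n_restarts_used = n_used[ok], odf_neg_frac = odf_neg[ok],
    voxels = pr$voxels[ok], mask = mask_out, dims = pr$dims,
    voxel_size_mm = pr$voxel_size_mm, sh_order = options$sh_order
  ), class = "neurite_fit")
}

#' @exportS3Method base::print
print.neurite_fit <- function(x, ...) {
  cat("Neurite model fit:", nrow(x$estimates), "voxels,",
      sum(!x$identifiable), "flagged non-identifiable\n")
  invisible(x)
}

#' @export
coef.neurite_fit <- function(object, ...) {
  data.frame(voxel = object$voxels, object$estimates, rss = object$rss,
             identifiable = object$identifiable)
}

#' @export
predict.neurite_fit <- function(object, protocol = NULL, ...) {
  if (is.null(protocol)) stop("supply the protocol to predict signals for")
  ctx <- neurite_eval_ctx(protocol$frames, object$sh_order)
  t(apply(object$estimates, 1, function(e) {
    p <- c(log(e[1]), logit(min(max(e[2], 1e-9), 1 - 1e-9)),
           logit(min(max(e[3] / 3, 1e-9), 1 - 1e-9)),
           logit(min(max(e[4] / 3, 1e-9), 1 - 1e-9)), e[-(1:4)])
    neurite_model_parts(p, ctx)$S
  }))
}

#' Parameter maps from a neurite fit
#'
#' @param fit a `neurite_fit`.
#' @return named list of [parameter_map()]s `Neu`, `D_L`, `D_eff`.
#' @export
neurite_maps <- function(fit) {
  list(Neu = fit_map(fit, fit$estimates[, "neu"], "Neu"),
       D_L = fit_map(fit, fit$estimates[, "d_long"], "D_L"),
       D_eff = fit_map(fit, fit$estimates[, "d_eff"], "D_eff"))
}

#' Per-voxel diagnostics table of a neurite fit
#'
#' @param fit a `neurite_fit`.
#' @param path optional CSV path to write the table to.
#' @return data.frame of voxel index, estimates, RSS, convergence,
#'   identifiability, restarts used and negative-ODF-mass fraction.
#' @export
neurite_diagnostics <- function(fit, path = NULL) {
  out <- data.frame(voxel = fit$voxels, fit$estimates, rss = fit$rss,
                    converged = fit$converged, identifiable = fit$identifiable,
                    n_restarts_used = fit$n_restarts_used,
                    odf_neg_frac = fit$odf_neg_frac)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
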