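test_that("forward model reproduces its closed-form limits", {
  p <- default_protocol()
  b <- p$frames$b
  # b = 0: no diffusion weighting
  np <- neurite_params(0.37, 1.1, 0.7, s0 = 42)
  expect_equal(neurite_forward(np, p)[b == 0], 42)
  # neu = 0: pure mono-exponential extra-neurite decay
  s <- neurite_forward(neurite_params(0, 1, 0.6, s0 = 1), p)
  expect_equal(s[abs(b - 2) < 1e-9][1], exp(-1.2), tolerance = 1e-12)
  # neu = 1, isotropic ODF: powder-averaged stick
  s1 <- neurite_forward(neurite_params(1, 1.2, 0.6, s0 = 1), p)
  # erf(x) = 2 pnorm(x sqrt(2)) - 1
  closed <- ifelse(b == 0, 1,
                   sqrt(pi / (4 * b * 1.2)) * (2 * pnorm(sqrt(2 * b * 1.2)) - 1))
  expect_lt(max(abs(s1 - closed)), 1e-10)
})

test_that("forward model is rotation-equivariant and monotone in b", {
  p <- default_protocol()
  odf <- cortmicro:::watson_odf_coeffs(4, c(1, 0.3, 0.2))
  np <- neurite_params(0.5, 1.3, 0.6, odf_coeffs = odf)
  set.seed(31)
  R <- random_rotation()
  # rotate ODF and gradients together: signals unchanged.
  # f_rot(n) = f(R' n); its coefficients come from re-projecting f on a grid.
  grid <- cortmicro:::sphere_grid(24, 48)
  Y <- cortmicro:::real_sh(grid$points, 4)
  fvals_rot <- drop(cortmicro:::real_sh(grid$points %*% R, 4) %*% odf)
  f_rot <- drop(crossprod(Y, grid$weights * fvals_rot)) * 4 * pi
  np_rot <- neurite_params(0.5, 1.3, 0.6, odf_coeffs = f_rot)
  p_rot <- diffusion_protocol(p$bvalues, p$directions %*% R)
  expect_lt(max(abs(neurite_forward(np, p_rot) - neurite_forward(np_rot, p))),
            1e-9)
  # strict monotone decay in b along any fixed direction
  bgrid <- seq(0.1, 8, by = 0.1)
  for (g in list(c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    pr <- diffusion_protocol(c(0, bgrid),
                             matrix(g, 1), n_b0 = 1)
    s <- neurite_forward(np, pr)[-1]
    expect_true(all(diff(s) < 0))
  }
})

test_that("the ODF must be normalised and b must be non-negative", {
  expect_error(neurite_params(0.5, 1, 0.6, odf_coeffs = c(1, rep(0, 14))),
               "normalised")
  expect_error(neurite_params(1.2, 1, 0.6), "neu")
  expect_error(neurite_params(0.5, 4, 0.6), "diffusivities")
})

test_that("noiseless voxel fits recover the three scalar parameters", {
  p <- default_protocol()
  odf <- cortmicro:::watson_odf_coeffs(3, c(0.4, 0.2, 1))
  tr <- neurite_params(0.4, 1.2, 0.6, odf_coeffs = odf, s0 = 100)
  fit <- fit_neurite(single_voxel_dataset(simulate_voxel(tr, p), p))
  e <- fit$estimates[1, ]
  expect_equal(unname(e["neu"]), 0.4, tolerance = 1e-2 * 0.4)
  expect_equal(unname(e["d_long"]), 1.2, tolerance = 1e-2 * 1.2)
  expect_equal(unname(e["d_eff"]), 0.6, tolerance = 1e-2 * 0.6)
  expect_true(fit$identifiable)
  maps <- neurite_maps(fit)
  expect_equal(maps$Neu$values[1, 1, 1], unname(e["neu"]))
  expect_equal(maps$D_eff$units, "um^2/ms")
})

test_that("an absent stick compartment is flagged non-identifiable", {
  p <- default_protocol()
  tr <- neurite_params(0, 1.2, 0.6)
  fit <- fit_neurite(single_voxel_dataset(simulate_voxel(tr, p), p))
  expect_false(fit$identifiable)
  expect_lt(fit$estimates[1, "neu"], 0.02)
})

test_that("fit(forward(theta)) round-trips over a small admissible design", {
  p <- default_protocol()
  set.seed(33)
  thetas <- cbind(neu = runif(6, 0.15, 0.85),
                  d_long = runif(6, 0.5, 1.8),
                  d_eff = runif(6, 0.3, 1.2),
                  kappa = runif(6, 1, 6))
  for (i in seq_len(nrow(thetas))) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    odf <- cortmicro:::watson_odf_coeffs(thetas[i, "kappa"], ax)
    tr <- neurite_params(thetas[i, "neu"], thetas[i, "d_long"],
                         thetas[i, "d_eff"], odf_coeffs = odf)
    fit <- fit_neurite(single_voxel_dataset(simulate_voxel(tr, p), p))
    e <- fit$estimates[1, c("neu", "d_long", "d_eff")]
    expect_lt(max(abs(e - thetas[i, 1:3]) / thetas[i, 1:3]), 0.02)
  }
})

test_that("diagnostics table includes restarts and ODF negativity", {
  tmp <- withr::local_tempdir()
  p <- default_protocol()
  tr <- neurite_params(0.5, 1.0, 0.6)
  fit <- fit_neurite(single_voxel_dataset(simulate_voxel(tr, p), p))
  d <- neurite_diagnostics(fit, file.path(tmp, "diag.csv"))
  expect_true(all(c("n_restarts_used", "odf_neg_frac", "rss") %in% names(d)))
  expect_true(file.exists(file.path(tmp, "diag.csv")))
})
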