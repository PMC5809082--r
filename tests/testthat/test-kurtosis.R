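test_that("Gaussian signals yield zero kurtosis tensor and metrics", {
  p <- default_protocol()
  set.seed(21)
  d6 <- random_spd_d6()
  fit <- fit_dki(single_voxel_dataset(simulate_voxel(list(d6 = d6), p), p))
  expect_lt(max(abs(fit$w15)), 1e-8)
  expect_lt(max(abs(kurtosis_metrics(fit))), 1e-8)
  expect_lt(max(abs(fit$d6 - d6)), 1e-8)
})

test_that("a known (D, W) pair is recovered exactly on a spanning direction set", {
  p30 <- dense_protocol(30)
  set.seed(22)
  for (i in 1:5) {
    d6 <- random_spd_d6()
    w15 <- rnorm(15, 0, 0.25)
    sig <- simulate_voxel(list(d6 = d6, w15 = w15), p30)
    fit <- fit_dki(single_voxel_dataset(sig, p30))
    expect_lt(max(abs(fit$d6 - d6)), 1e-6)
    expect_lt(max(abs(fit$w15 - w15)), 1e-6)
  }
})

test_that("on the 12-direction scheme D and the apparent kurtosis per axis are recovered", {
  # 12 directions cannot span all 15 kurtosis components; the recoverable
  # quantities are D (fully) and W's contraction along each measured axis.
  p <- default_protocol()
  set.seed(23)
  d6 <- random_spd_d6()
  w15 <- rnorm(15, 0, 0.25)
  sig <- simulate_voxel(list(d6 = d6, w15 = w15), p)
  fit <- fit_dki(single_voxel_dataset(sig, p))
  expect_lt(max(abs(fit$d6 - d6)), 1e-6)
  Nw <- cortmicro:::w_design(p$directions)
  expect_lt(max(abs(Nw %*% fit$w15[1, ] - Nw %*% w15)), 1e-6)
  expect_lt(max(abs(predict(fit, p) - sig)), 1e-8)
})

test_that("directional kurtosis matches the defining ratio", {
  mix <- mixture_dk()
  fit <- dki_voxel(mix$d6, mix$w15)
  expect_equal(directional_kurtosis(fit, c(1, 0, 0)), 0.75, tolerance = 1e-12)
  expect_equal(directional_kurtosis(fit, c(1, 1, 1) / sqrt(3)), 0.75,
               tolerance = 1e-12)
  # Gaussian: zero in any direction
  g <- dki_voxel(c(1, 0.5, 0.3, 0, 0, 0), rep(0, 15))
  expect_equal(directional_kurtosis(g, c(0, 1, 0)), 0)
  # single W_1111 component along e1: K = MD^2 W_1111 / lambda1^2
  w <- rep(0, 15); w[1] <- 0.6
  d6 <- c(1.2, 0.8, 0.4, 0, 0, 0)
  f1 <- dki_voxel(d6, w)
  md <- mean(d6[1:3])
  expect_equal(directional_kurtosis(f1, c(1, 0, 0)), md^2 * 0.6 / 1.2^2,
               tolerance = 1e-12)
  expect_warning(
    expect_true(is.nan(directional_kurtosis(dki_voxel(c(0, 0, 0, 0, 0, 0) -
                                                        c(1e-3, 1e-3, 1e-3, 0, 0, 0), w), c(1, 0, 0)))),
    "non-positive")
})

test_that("closed-form tensor metrics match brute-force quadrature oracles", {
  set.seed(24)
  for (i in 1:8) {
    d6 <- random_spd_d6()
    w15 <- rnorm(15, 0, 0.3)
    met <- cortmicro:::kurtosis_metrics_voxel(d6, w15)
    # MKT = surface average of What(n) over a dense equal-area grid
    pts <- fibonacci_sphere(10000)
    expect_equal(unname(met["MKT"]),
                 mean(cortmicro:::w_design(pts) %*% w15), tolerance = 1e-3)
    # W_T = azimuthal average of What over the plane perpendicular to e1
    e <- cortmicro:::tensor_eigen(d6)
    phi <- seq(0, 2 * pi, length.out = 5001)[-1]
    perp <- cbind(cos(phi)) %*% rbind(e$vectors[, 2]) +
      cbind(sin(phi)) %*% rbind(e$vectors[, 3])
    expect_equal(unname(met["W_T"]),
                 mean(cortmicro:::w_design(perp) %*% w15), tolerance = 1e-6)
    # AK equals K_app along e1
    expect_equal(unname(met["AK"]),
                 directional_kurtosis(dki_voxel(d6, w15), e$vectors[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("tensor metrics are invariant under joint rotation of (D, W)", {
  set.seed(25)
  d6 <- random_spd_d6()
  w15 <- rnorm(15, 0, 0.3)
  m0 <- cortmicro:::kurtosis_metrics_voxel(d6, w15)
  for (i in 1:3) {
    R <- random_rotation()
    m1 <- cortmicro:::kurtosis_metrics_voxel(cortmicro:::rotate_d6(d6, R),
                                             cortmicro:::rotate_w15(w15, R))
    expect_lt(max(abs(m1[c("MKT", "W_L", "W_T")] -
                        m0[c("MKT", "W_L", "W_T")])), 1e-8)
  }
})

test_that("MK equals MKT exactly for isotropic D", {
  set.seed(26)
  w15 <- rnorm(15, 0, 0.3)
  m <- cortmicro:::kurtosis_metrics_voxel(c(0.8, 0.8, 0.8, 0, 0, 0), w15)
  expect_equal(unname(m["MK"]), unname(m["MKT"]), tolerance = 1e-10)
})

test_that("the fit is deterministic and validates its preconditions", {
  p <- default_protocol()
  set.seed(27)
  sig <- simulate_voxel(list(d6 = random_spd_d6(),
                             w15 = cortmicro:::w15_isotropic(0.5)), p,
                        snr_b0 = 30, seed = 4)
  f1 <- fit_dki(single_voxel_dataset(sig, p))
  f2 <- fit_dki(single_voxel_dataset(sig, p))
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_dki(single_voxel_dataset(sig, p), b_max = 0.6),
               "insufficient shells")
  p6 <- diffusion_protocol(c(0, seq(0.5, 4.5, 0.5)), diag(3))
  expect_error(
    fit_dki(single_voxel_dataset(rep(1, nrow(p6$frames)), p6)),
    "directions")
})

test_that("truncated-model fit of a heavy-tailed mixture underestimates its kurtosis", {
  # Fitting the quadratic cumulant model to bi-exponential decay over the
  # full 0-4.5 range is biased low by the mixture's higher cumulants: the
  # closed-form K = 0.75 is an upper reference, not the NLLS outcome.
  p <- default_protocol()
  b <- p$frames$b
  sig <- 0.5 * exp(-b * 0.5) + 0.5 * exp(-b * 1.5)
  fit <- fit_dki(single_voxel_dataset(sig, p))
  mk <- kurtosis_metrics(fit)["MK"]
  expect_true(mk > 0.2 && mk < 0.75)
})
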