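white_img <- function(h = 40, w = 40) {
  micrograph(array(1, c(h, w, 3)), um_per_px = 0.5)
}

test_that("preprocessing maps a pure-white image to zero stain", {
  expect_warning(enh <- preprocess_micrograph(white_img()), "constant")
  expect_true(all(enh == 0))
})

test_that("dark structures on white map to the top intensity decile", {
  px <- array(0.95, c(50, 50, 3))
  px[10:20, 10:20, ] <- 0.2
  enh <- preprocess_micrograph(micrograph(px, 0.5))
  expect_true(all(enh[10:20, 10:20] >= quantile(enh, 0.9)))
  expect_true(mean(enh[30:50, 30:50]) < 0.1)
})

test_that("batch processing with shared parameters is deterministic", {
  set.seed(51)
  imgs <- lapply(1:2, function(i) {
    px <- array(runif(50 * 50 * 3, 0.7, 1), c(50, 50, 3))
    px[5:15, 5:15, ] <- px[5:15, 5:15, ] * 0.3
    micrograph(px, 0.5)
  })
  pars <- histo_batch_params(imgs)
  a1 <- preprocess_micrograph(imgs[[1]], pars)
  a2 <- preprocess_micrograph(imgs[[1]], pars)
  expect_identical(a1, a2)
  # separate processing with the same fixed global parameters matches batch
  b1 <- preprocess_micrograph(imgs[[2]], pars)
  b2 <- preprocess_micrograph(imgs[[2]], pars)
  expect_identical(b1, b2)
})

test_that("thresholding follows the relative-range rule", {
  expect_true(all(!binarize_stain(matrix(0, 10, 10))))
  # constructed image with exactly 12% of pixels above the 30% level
  img <- matrix(0, 10, 10)
  img[1:12] <- 1
  img[13:100] <- 0.1
  expect_equal(mean(binarize_stain(img, 0.30)), 0.12)
  # threshold 0 keeps every pixel at or above the minimum
  expect_true(all(binarize_stain(img, 0)))
  expect_error(binarize_stain(img, 1), "threshold_frac")
  expect_error(binarize_stain(img, -0.1), "threshold_frac")
})

test_that("cell bodies are removed by shape; thin processes are retained", {
  um <- 0.5
  mask <- matrix(FALSE, 200, 200)
  # filled disc, diameter 15 um = 30 px
  disc <- cortmicro:::disc_pixels(200, 200, 150, 40, 15)
  mask[disc] <- TRUE
  # three thin non-crossing polylines
  mask[80:82, 5:195] <- TRUE        # horizontal
  mask[5:70, 150:152] <- TRUE       # vertical
  mask[cbind(10:60, 10:60)] <- TRUE # diagonal staircase
  mask[cbind(10:60, 11:61)] <- TRUE
  out <- remove_cell_bodies(mask, cell_body_criteria(), um_per_px = um)
  expect_equal(out$body_components, 1L)
  expect_true(all(mask[disc] == out$body_mask[disc]))
  expect_true(all(out$process_mask[80:82, 5:195]))   # polyline kept
  # oracle: component count by labelling
  expect_equal(max(cortmicro:::label_components_8(mask)), 4L)
  # diagonal staircase is one 8-connected component but many 4-connected ones
  diag_only <- matrix(FALSE, 30, 30)
  diag_only[cbind(1:20, 1:20)] <- TRUE
  expect_equal(max(cortmicro:::label_components_8(diag_only)), 1L)
  # only elongated components: nothing removed
  thin <- matrix(FALSE, 60, 60); thin[10:12, 5:55] <- TRUE
  out2 <- remove_cell_bodies(thin, cell_body_criteria(), um)
  expect_equal(out2$body_components, 0L)
  expect_identical(out2$process_mask, thin)
  # disc larger than the diameter bound stays in the process mask
  big <- matrix(FALSE, 200, 200)
  big[cortmicro:::disc_pixels(200, 200, 100, 100, 60)] <- TRUE  # 60 um diam
  out3 <- remove_cell_bodies(big, cell_body_criteria(), um)
  expect_equal(out3$body_components, 0L)
  expect_identical(out3$process_mask, big)
  # empty input
  out4 <- remove_cell_bodies(matrix(FALSE, 5, 5), cell_body_criteria(), um)
  expect_equal(sum(out4$process_mask) + sum(out4$body_mask), 0L)
})

test_that("hole-filled somata are measured as single round bodies", {
  mask <- matrix(FALSE, 80, 80)
  mask[cortmicro:::disc_pixels(80, 80, 40, 40, 14)] <- TRUE
  mask[cortmicro:::disc_pixels(80, 80, 40, 40, 5)] <- FALSE  # nuclear hole
  out <- remove_cell_bodies(mask, cell_body_criteria(), um_per_px = 0.5)
  expect_equal(out$body_components, 1L)
  expect_equal(sum(out$process_mask), 0L)
})

test_that("density percentage is a plain pixel fraction", {
  m <- matrix(FALSE, 100, 100); m[seq_len(500)] <- TRUE
  expect_equal(density_percent(m)$density_pct, 5.0)
  expect_equal(density_percent(matrix(FALSE, 10, 10))$density_pct, 0)
})

test_that("pixel classes are conserved through the chain", {
  sm <- synth_micrograph(micrograph_spec(size_px = c(256L, 256L),
                                         n_cell_bodies = 4L, seed = 3))
  enh <- preprocess_micrograph(sm$image)
  bin <- binarize_stain(enh)
  out <- remove_cell_bodies(bin, cell_body_criteria(), sm$image$um_per_px)
  overlap <- sum(bin & out$body_mask)
  expect_identical(sum(out$process_mask) + overlap, sum(bin))
})

test_that("recovered density is stable under 2x downsampling", {
  sm <- synth_micrograph(micrograph_spec(seed = 9))
  d1 <- stain_density(sm$image)$density_pct
  ds <- sm$image$pixels[seq(1, 512, 2), seq(1, 512, 2), ]
  d2 <- stain_density(micrograph(ds, sm$image$um_per_px * 2))$density_pct
  expect_lt(abs(d1 - d2), 1)
})

test_that("thickness is the calibrated endpoint distance", {
  l1 <- data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 400)
  expect_warning(t1 <- cortical_thickness(l1, um_per_px = 5), "protocol")
  expect_equal(t1$thickness_um, 2000)
  l2 <- data.frame(x1 = 0, y1 = 0, x2 = 300, y2 = 400)
  expect_warning(t2 <- cortical_thickness(l2, um_per_px = 1), "protocol")
  expect_equal(t2$thickness_um, 500)
  lz <- rbind(l1, data.frame(x1 = 1, y1 = 1, x2 = 1, y2 = 1))
  expect_warning(tz <- cortical_thickness(lz, 5), "zero-length")
  expect_equal(nrow(tz), 1L)
})
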