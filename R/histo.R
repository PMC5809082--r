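#' Calibrated stained micrograph
#'
#' @param pixels h x w x 3 RGB array in [0, 1].
#' @param um_per_px pixel calibration, micrometres per pixel (> 0).
#' @param stain stain label, `"NF-H"` (axonal) or `"MAP2"` (dendritic).
#' @param roi,animal_id,group,section_index metadata carried to the cohort
#'   table.
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(pixels, um_per_px, stain = c("NF-H", "MAP2"),
                       roi = NA_character_, animal_id = NA_character_,
                       group = NA_character_, section_index = NA_integer_) {
  stain <- match.arg(stain)
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] < 3L || !prod(dim(pixels))) {
    stop("pixels must be a non-empty RGB array")
  }
  if (um_per_px <= 0) stop("um_per_px must be positive")
  structure(list(pixels = pixels[, , 1:3], um_per_px = um_per_px,
                 stain = stain, roi = roi, animal_id = animal_id,
                 group = group, section_index = section_index),
            class = "micrograph")
}

#' @exportS3Method base::print
print.micrograph <- function(x, ...) {
  cat("Micrograph", x$stain, ":", paste(dim(x$pixels)[1:2], collapse = " x "),
      "px @", x$um_per_px, "um/px\n")
  invisible(x)
}

#' Read a micrograph from TIFF or PNG
#' @param path image path (.tif/.tiff/.png).
#' @inheritParams micrograph
#' @return a `micrograph`.
#' @export
read_micrograph <- function(path, um_per_px, stain = "NF-H", ...) {
  px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  micrograph(px, um_per_px, stain, ...)
}

#' Write a micrograph to TIFF or PNG
#' @param img a `micrograph`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_micrograph <- function(img, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img$pixels, path)
  } else {
    png::writePNG(img$pixels, path)
  }
  invisible(path)
}

#' Shared enhancement parameters for a batch of micrographs
#'
#' Computes the luminosity scaling and contrast-stretch parameters once from
#' pooled pixels so that every image in a batch is processed with identical
#' settings.
#'
#' @param imgs list of [micrograph()]s.
#' @return list with `bg` (background luminance) and `stretch` (1st/99th
#'   percentile of the pooled stain intensity).
#' @export
histo_batch_params <- function(imgs) {
  lum <- unlist(lapply(imgs, function(i) as.vector(micro_luminance(i$pixels))))
  bg <- bg_luminance(lum)
  norm_lum <- lum / bg
  norm_lum[norm_lum > 1] <- 1
  stain <- clamp01(1 - norm_lum)
  list(bg = bg, stretch = stats::quantile(stain, c(0.01, 0.99), names = FALSE))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

micro_luminance <- function(px) (px[, , 1] + px[, , 2] + px[, , 3]) / 3

# 99th-percentile luminance among the least-stained (brightest) decile.
bg_luminance <- function(lum) {
  top <- lum[lum >= stats::quantile(lum, 0.9)]
  stats::quantile(top, 0.99, names = FALSE)
}

#' Preprocess a stained micrograph into a stain-intensity image
#'
#' Luminosity scaling (each image divided by its background luminance, the
#' 99th percentile of the least-stained decile of pixels), inversion to a
#' stain intensity (1 - normalised luminance, so darker DAB product maps
#' higher), and percentile contrast stretch (1st to 99th percentile mapped to
#' [0, 1]). Pass `params` from [histo_batch_params()] to apply identical
#' settings across a batch.
#'
#' @param img a [micrograph()].
#' @param params optional shared parameters; computed per image when NULL.
#' @return matrix of stain intensity in [0, 1].
#' @export
preprocess_micrograph <- function(img, params = NULL) {
  lum <- micro_luminance(img$pixels)
  if (max(lum) - min(lum) < 1e-12) {
    warning("constant image: contrast enhancement skipped")
    return(matrix(0, nrow(lum), ncol(lum)))
  }
  bg <- if (is.null(params)) bg_luminance(lum) else params$bg
  norm_lum <- lum / bg
  norm_lum[norm_lum > 1] <- 1
  stain <- clamp01(1 - norm_lum)
  st <- if (is.null(params)) {
    stats::quantile(stain, c(0.01, 0.99), names = FALSE)
  } else {
    params$stretch
  }
  if (st[2] - st[1] < 1e-12) {
    warning("degenerate stain range: contrast enhancement skipped")
    return(stain)
  }
  clamp01((stain - st[1]) / (st[2] - st[1]))
}

#' Threshold a stain-intensity image
#'
#' A pixel is foreground iff its intensity is at least
#' `min + threshold_frac * (max - min)` of the per-image post-enhancement
#' range (the "30% relative to the signal level" rule).
#'
#' @param enhanced stain-intensity matrix in [0, 1].
#' @param threshold_frac relative threshold in [0, 1); default 0.30.
#' @return logical matrix.
#' @export
binarize_stain <- function(enhanced, threshold_frac = 0.30) {
  if (threshold_frac < 0 || threshold_frac >= 1) {
    stop("threshold_frac must lie in [0, 1)")
  }
  rng <- range(enhanced)
  if (rng[2] - rng[1] == 0) {        # no signal: nothing is foreground
    return(matrix(FALSE, nrow(enhanced), ncol(enhanced)))
  }
  enhanced >= rng[1] + threshold_frac * (rng[2] - rng[1])
}

#' Cell-body shape criteria
#'
#' Connected components classified as neuronal cell bodies must have best-fit
#' ellipse eccentricity at most `max_eccentricity`, equivalent diameter (the
#' diameter of the circle with the component's area) within the given bounds,
#' and at least `min_area_px` pixels. Defaults reflect typical neuronal soma
#' sizes; all four are configuration-exposed.
#'
#' @param max_eccentricity maximum eccentricity in [0, 1] (default 0.85).
#' @param min_equiv_diameter_um,max_equiv_diameter_um equivalent-diameter
#'   bounds in micrometres (defaults 6 and 25).
#' @param min_area_px minimum component area in pixels (default 20).
#' @return list of criteria.
#' @export
cell_body_criteria <- function(max_eccentricity = 0.85,
                               min_equiv_diameter_um = 6,
                               max_equiv_diameter_um = 25,
                               min_area_px = 20) {
  if (max_eccentricity < 0 || max_eccentricity > 1) {
    stop("max_eccentricity must lie in [0, 1]")
  }
  if (min_equiv_diameter_um > max_equiv_diameter_um) {
    stop("diameter bounds out of order")
  }
  list(max_eccentricity = max_eccentricity,
       min_equiv_diameter_um = min_equiv_diameter_um,
       max_equiv_diameter_um = max_equiv_diameter_um,
       min_area_px = min_area_px)
}

# 8-connected component labelling: 4-connected labelling (EBImage::bwlabel)
# followed by union-find merging of diagonally adjacent labels.
label_components_8 <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow(mask))
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Remove stained cell bodies from a binary stain mask
#'
#' 8-connected components are hole-filled (DAB somata contain unstained,
#' counterstained nuclei) and measured; components satisfying the
#' [cell_body_criteria()] are classified as cell bodies and subtracted.
#'
#' @param binary logical matrix from [binarize_stain()].
#' @param criteria a [cell_body_criteria()] list.
#' @param um_per_px pixel calibration.
#' @return list with `process_mask` (binary minus body pixels), `body_mask`
#'   (filled footprints of detected bodies) and `body_components` (count).
#' @export
remove_cell_bodies <- function(binary, criteria = cell_body_criteria(),
                               um_per_px = 1) {
  binary <- matrix(as.logical(binary), nrow(binary))
  if (!any(binary)) {
    empty <- matrix(FALSE, nrow(binary), ncol(binary))
    return(list(process_mask = empty, body_mask = empty, body_components = 0L))
  }
  lab <- label_components_8(binary)
  filled <- EBImage::fillHull(lab)
  n <- max(lab)
  areas <- tabulate(filled[filled > 0], n)
  eqd_um <- 2 * sqrt(areas / pi) * um_per_px
  mom <- EBImage::computeFeatures.moment(filled)
  ecc <- mom[, "m.eccentricity"]
  is_body <- ecc <= criteria$max_eccentricity &
    eqd_um >= criteria$min_equiv_diameter_um &
    eqd_um <= criteria$max_equiv_diameter_um &
    areas >= criteria$min_area_px
  body_ids <- which(is_body)
  body_mask <- matrix(filled %in% body_ids, nrow(binary))
  list(process_mask = binary & !body_mask,
       body_mask = body_mask,
       body_components = length(body_ids))
}

#' Stain-positive area fraction
#'
#' @param process_mask logical matrix of process (axonal/dendritic) pixels.
#' @param body_mask optional logical matrix of removed cell-body pixels (for
#'   bookkeeping).
#' @return an object of class `density_result`: `density_pct` = 100 x
#'   foreground / total pixels, with pixel counts.
#' @export
density_percent <- function(process_mask, body_mask = NULL) {
  total <- length(process_mask)
  fg <- sum(process_mask)
  structure(list(
    density_pct = 100 * fg / total,
    foreground_px = fg,
    body_px = if (is.null(body_mask)) 0L else sum(body_mask),
    total_px = total,
    body_components = attr(body_mask, "components") %||% NA_integer_
  ), class = "density_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.density_result <- function(x, ...) {
  cat(sprintf("Stain density: %.2f%% (%d / %d px; %d body px removed)\n",
              x$density_pct, x$foreground_px, x$total_px, x$body_px))
  invisible(x)
}

#' Full stain-density chain for one micrograph
#'
#' preprocess -> threshold -> cell-body removal -> area fraction.
#'
#' @param img a [micrograph()].
#' @param criteria [cell_body_criteria()] profile for the stain.
#' @param threshold_frac relative threshold (default 0.30).
#' @param params optional shared batch parameters.
#' @return a `density_result` with the body count attached.
#' @export
stain_density <- function(img, criteria = cell_body_criteria(),
                          threshold_frac = 0.30, params = NULL) {
  enh <- preprocess_micrograph(img, params)
  bin <- binarize_stain(enh, threshold_frac)
  rm <- remove_cell_bodies(bin, criteria, img$um_per_px)
  out <- density_percent(rm$process_mask, rm$body_mask)
  out$body_components <- rm$body_components
  out
}

#' Cortical thickness from line annotations
#'
#' Straight-line measurements (Euclidean endpoint distance scaled by the
#' pixel calibration), grouped per ROI and montage. The acquisition protocol
#' of at least 3 montages x 5 lines per ROI is enforced as a validation
#' warning, not an error. Zero-length lines are skipped with a warning.
#'
#' @param lines data.frame with columns `x1`, `y1`, `x2`, `y2` (pixel
#'   coordinates) and optionally `roi` and `montage`.
#' @param um_per_px pixel calibration.
#' @return data.frame of the input annotations plus `thickness_um`.
#' @export
cortical_thickness <- function(lines, um_per_px) {
  lines <- as.data.frame(lines)
  if (nrow(lines) < 1L) stop("need at least one line annotation")
  if (!"roi" %in% names(lines)) lines$roi <- "ROI"
  if (!"montage" %in% names(lines)) lines$montage <- 1L
  len_px <- sqrt((lines$x2 - lines$x1)^2 + (lines$y2 - lines$y1)^2)
  zero <- len_px == 0
  if (any(zero)) {
    warning(sum(zero), " zero-length line(s) skipped")
    lines <- lines[!zero, , drop = FALSE]
    len_px <- len_px[!zero]
  }
  lines$thickness_um <- len_px * um_per_px
  per_roi <- split(lines, lines$roi)
  for (roi in names(per_roi)) {
    d <- per_roi[[roi]]
    n_mont <- length(unique(d$montage))
    per_mont <- table(d$montage)
    if (n_mont < 3L || any(per_mont != 5L)) {
      warning("ROI ", roi, ": protocol expects >= 3 montages x 5 lines (",
              n_mont, " montage(s), ",
              paste(per_mont, collapse = "/"), " lines)")
    }
  }
  lines
}

#' Read line annotations from CSV
#'
#' Columns: `image`, `roi`, `montage`, `x1`, `y1`, `x2`, `y2`.
#' @param path CSV path.
#' @return data.frame of annotations.
#' @export
read_line_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
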