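#' Diffusion-weighted image dataset
#'
#' A 4-D signal array (x, y, z, measurement) tied to its acquisition protocol
#' and voxel geometry.
#'
#' @param signal 4-D numeric array, arbitrary scanner units, finite and >= 0.
#' @param protocol a [diffusion_protocol()] whose frame count matches the 4th
#'   dimension.
#' @param voxel_size_mm length-3 voxel size (default 0.25 mm isotropic, the
#'   study's resolution).
#' @param affine 4 x 4 voxel-to-world (RAS) map; defaults to a scaled identity.
#' @return an object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, protocol, voxel_size_mm = c(0.25, 0.25, 0.25),
                        affine = NULL) {
  if (length(dim(signal)) == 1L) dim(signal) <- c(1L, 1L, 1L, length(signal))
  if (length(dim(signal)) != 4L) stop("signal must be a 4-D array")
  n_meas <- dim(signal)[4]
  if (n_meas != nrow(protocol$frames)) {
    stop("measurement-count mismatch: image has ", n_meas,
         " frames but b-table has ", nrow(protocol$frames), " rows")
  }
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    ii <- arrayInd(bad[1], dim(signal))
    stop("non-finite signal at voxel (", paste(ii[1:3] - 1L, collapse = ", "),
         "), frame ", ii[4] - 1L)
  }
  if (any(signal < 0)) stop("negative signal values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(list(signal = signal, protocol = protocol,
                 voxel_size_mm = voxel_size_mm, affine = affine),
            class = "dwi_dataset")
}

#' @exportS3Method base::print
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI dataset:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "measurements\n")
  print(x$protocol)
  invisible(x)
}

#' Read a diffusion dataset from NIfTI + b-table
#'
#' @param image_path 4-D NIfTI volume (.nii or .nii.gz).
#' @param btable_path FSL `.bval` (with `.bvec` sibling) or TSV b-table; see
#'   [read_btable()] for unit handling.
#' @return a `dwi_dataset`.
#' @export
read_dwi <- function(image_path, btable_path) {
  img <- RNifti::readNifti(image_path)
  protocol <- read_btable(btable_path)
  arr <- array(as.numeric(img), dim = dim(img))
  vox <- RNifti::pixdim(img)[1:3]
  dwi_dataset(arr, protocol, voxel_size_mm = vox,
              affine = structure(RNifti::xform(img), dimnames = NULL))
}

#' Write a diffusion dataset to NIfTI + b-table
#'
#' @param dataset a `dwi_dataset`.
#' @param image_path output NIfTI path.
#' @param btable_stem output b-table stem (FSL dialect).
#' @return invisibly, `image_path`.
#' @export
write_dwi <- function(dataset, image_path, btable_stem) {
  img <- RNifti::asNifti(dataset$signal)
  RNifti::pixdim(img) <- c(dataset$voxel_size_mm, 1)
  RNifti::writeNifti(img, image_path, datatype = "double")
  write_btable(dataset$protocol, btable_stem)
  invisible(image_path)
}

supported_metrics <- c("Neu", "D_L", "D_eff", "MD", "FA",
                       "MK", "AK", "RK", "MKT", "W_L", "W_T")

metric_units <- function(name) {
  if (name %in% c("MD", "D_L", "D_eff")) "um^2/ms" else "dimensionless"
}

#' Named voxel-wise parameter map
#'
#' @param name metric identifier (e.g. `"FA"`, `"D_eff"`); names outside the
#'   reported metric set are allowed (diagnostics) with a warning at write
#'   time.
#' @param values 3-D array; finite inside `mask`, `NA` outside.
#' @param mask logical 3-D array of fitted voxels (defaults to finite values).
#' @param units unit string; inferred from the name when missing.
#' @param voxel_size_mm length-3 voxel size.
#' @return an object of class `parameter_map`.
#' @export
parameter_map <- function(name, values, mask = NULL, units = NULL,
                          voxel_size_mm = c(0.25, 0.25, 0.25)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (is.null(mask)) mask <- is.finite(values)
  if (!all(dim(mask) == dim(values))) stop("mask/values dimension mismatch")
  if (any(!is.finite(values[mask]))) stop("non-finite values inside mask")
  values[!mask] <- NA_real_
  if (is.null(units)) units <- metric_units(name)
  structure(list(name = name, values = values, mask = mask, units = units,
                 voxel_size_mm = voxel_size_mm),
            class = "parameter_map")
}

#' @exportS3Method base::print
print.parameter_map <- function(x, ...) {
  cat("Parameter map", x$name, "[", x$units, "]:",
      paste(dim(x$values), collapse = " x "), "voxels,",
      sum(x$mask), "fitted\n")
  if (any(x$mask)) {
    cat("  range:", format(range(x$values[x$mask])), "\n")
  }
  invisible(x)
}

#' Write a parameter map to NIfTI
#'
#' The metric name and units are recorded in the header description; values
#' outside the mask are NaN. Round-trips bit-exact through [read_map()]
#' (double-precision storage).
#'
#' @param map a `parameter_map`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_map <- function(map, path) {
  if (!map$name %in% supported_metrics) {
    warning("metric '", map$name, "' is not in the reported metric list; ",
            "writing as a diagnostic map")
  }
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size_mm
  img$descrip <- paste0(map$name, ";", map$units)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a parameter map written by [write_map()]
#'
#' @param path NIfTI path.
#' @return a `parameter_map`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  desc <- strsplit(RNifti::niftiHeader(img)$descrip, ";")[[1]]
  vals <- array(as.numeric(img), dim = dim(img))
  parameter_map(name = desc[1], values = vals,
                units = if (length(desc) > 1) desc[2] else NULL,
                voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' ROI label mask
#'
#' Integer label volume aligned to a dataset, with named labels and the slice
#' window (half-open `[lo, hi)` on the slice axis, 1-based lower index) that
#' emulates the anatomical section selection.
#'
#' @param labels integer 3-D array; 0 is background.
#' @param label_names named integer vector mapping ROI name -> label.
#' @param slice_range integer length-2, half-open `[lo, hi)` window on the
#'   slice axis; defaults to the full extent.
#' @param slice_axis axis (1-3) indexed by `slice_range`; default 3.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(labels, label_names, slice_range = NULL, slice_axis = 3L) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  missing_lab <- setdiff(unname(label_names), present)
  if (length(missing_lab)) {
    stop("labels absent from array: ", paste(missing_lab, collapse = ", "))
  }
  if (is.null(slice_range)) slice_range <- c(1L, dim(labels)[slice_axis] + 1L)
  structure(list(labels = labels, label_names = label_names,
                 slice_range = as.integer(slice_range),
                 slice_axis = as.integer(slice_axis)),
            class = "roi_mask")
}

#' Write / read an ROI mask as NIfTI
#'
#' @param mask a `roi_mask`.
#' @param path NIfTI path; label names go to a JSON sidecar.
#' @return invisibly, `path`.
#' @export
write_roi_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(mask$labels), path, datatype = "int16")
  jsonlite::write_json(list(label_names = as.list(mask$label_names),
                            slice_range = mask$slice_range,
                            slice_axis = mask$slice_axis),
                       sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  roi_mask(array(as.integer(img), dim = dim(img)),
           label_names = unlist(meta$label_names),
           slice_range = meta$slice_range, slice_axis = meta$slice_axis)
}
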