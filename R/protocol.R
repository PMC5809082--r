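#' Diffusion acquisition protocol
#'
#' Bundles the shell b-values, the fixed gradient direction set and the pulse
#' timing of a multi-shell acquisition. Internally every b-value is carried in
#' ms/um^2; `read_btable()` converts from s/mm^2 automatically. The
#' measurement ("frame") table lists one row per acquired volume in
#' acquisition order: all b = 0 frames use a zero gradient vector.
#'
#' @param bvalues shell b-values in ms/um^2 (must contain 0).
#' @param directions n x 3 matrix of gradient directions; renormalised to unit
#'   length. Shared by all non-zero shells.
#' @param n_b0 number of b = 0 frames acquired.
#' @param delta_big,delta_small diffusion time Delta and gradient duration
#'   delta, ms.
#' @param te_ms,tr_ms optional echo/repetition time metadata, ms.
#' @param frames optional per-frame table (columns `b`, `gx`, `gy`, `gz`) when
#'   the acquisition order differs from the canonical shell-major expansion.
#' @return an object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvalues, directions, n_b0 = 1L,
                               delta_big = 15, delta_small = 5,
                               te_ms = NA_real_, tr_ms = NA_real_,
                               frames = NULL) {
  bvalues <- sort(unique(as.numeric(bvalues)))
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (!any(bvalues == 0)) stop("protocol must contain a b = 0 shell")
  directions <- matrix(as.numeric(directions), ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm <= 0)) stop("zero-length gradient direction")
  directions <- directions / nrm
  if (is.null(frames)) {
    b_nz <- bvalues[bvalues > 0]
    frames <- data.frame(
      b = c(rep(0, n_b0), rep(b_nz, each = nrow(directions))),
      gx = c(rep(0, n_b0), rep(directions[, 1], times = length(b_nz))),
      gy = c(rep(0, n_b0), rep(directions[, 2], times = length(b_nz))),
      gz = c(rep(0, n_b0), rep(directions[, 3], times = length(b_nz)))
    )
  } else {
    frames <- as.data.frame(frames)[, c("b", "gx", "gy", "gz")]
  }
  structure(list(
    bvalues = bvalues, directions = directions,
    n_b0 = sum(frames$b == 0), frames = frames,
    delta_big = delta_big, delta_small = delta_small,
    te_ms = te_ms, tr_ms = tr_ms
  ), class = "diffusion_protocol")
}

#' @exportS3Method base::print
print.diffusion_protocol <- function(x, ...) {
  cat("Diffusion protocol:", length(x$bvalues), "shells x",
      nrow(x$directions), "directions (", nrow(x$frames), "frames )\n")
  cat("  b [ms/um^2]:", paste(format(x$bvalues), collapse = ", "), "\n")
  cat("  Delta/delta:", x$delta_big, "/", x$delta_small, "ms\n")
  invisible(x)
}

#' The 12-direction icosahedral gradient scheme
#'
#' Vertices of a regular icosahedron (six antipodal axes), the classic fixed
#' 12-direction preclinical scheme.
#'
#' @return 12 x 3 matrix of unit vectors.
#' @export
icosahedral_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c(1,  phi, 0), c(-1,  phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0,  1), c(phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1)
  )
  v / sqrt(rowSums(v^2))
}

#' The study's ex-vivo multi-shell protocol
#'
#' 14 b-values (0, 0.5, 1, ..., 4.5, 5, 6, 7, 8 ms/um^2) with 12 fixed
#' icosahedral directions, Delta/delta = 15/5 ms.
#'
#' @param n_b0 number of b = 0 frames (acquisition repetitions are not
#'   standardised; defaults to 1).
#' @return a `diffusion_protocol`.
#' @export
default_protocol <- function(n_b0 = 1L) {
  diffusion_protocol(
    bvalues = c(0, seq(0.5, 4.5, by = 0.5), 5, 6, 7, 8),
    directions = icosahedral_directions(),
    n_b0 = n_b0, delta_big = 15, delta_small = 5,
    te_ms = 26, tr_ms = 6500
  )
}

#' Read a diffusion b-table
#'
#' Accepts either the FSL dialect (a `.bval` file of white-space separated
#' b-values plus a `.bvec` file with three rows gx/gy/gz) or a single TSV with
#' columns `b`, `gx`, `gy`, `gz`. B-values are interpreted as ms/um^2 when
#' `max(b) < 100`, otherwise as s/mm^2 and divided by 1000. Pulse timing is
#' taken from a JSON sidecar (`<stem>.json`, keys `delta_big`, `delta_small`,
#' `te_ms`, `tr_ms`) when present.
#'
#' @param path path to the `.bval` file (its `.bvec` sibling is inferred) or
#'   to a TSV b-table.
#' @return a `diffusion_protocol` with per-frame ordering as listed.
#' @export
read_btable <- function(path) {
  if (grepl("\\.bval$", path)) {
    b <- scan(path, quiet = TRUE)
    bvec_path <- sub("\\.bval$", ".bvec", path)
    if (!file.exists(bvec_path)) stop("missing bvec file: ", bvec_path)
    g <- as.matrix(read.table(bvec_path))
    if (nrow(g) != 3L) stop("bvec file must have 3 rows")
    if (ncol(g) != length(b)) {
      stop("b-table mismatch: ", length(b), " b-values vs ", ncol(g), " directions")
    }
    tab <- data.frame(b = b, gx = g[1, ], gy = g[2, ], gz = g[3, ])
    sidecar <- sub("\\.bval$", ".json", path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    if (!all(c("b", "gx", "gy", "gz") %in% names(tab))) {
      stop("TSV b-table needs columns b, gx, gy, gz")
    }
    sidecar <- sub("\\.[^.]+$", ".json", path)
  }
  if (max(tab$b) >= 100) tab$b <- tab$b / 1000  # s/mm^2 -> ms/um^2
  nz <- tab$b > 0
  nrm <- sqrt(tab$gx^2 + tab$gy^2 + tab$gz^2)
  if (any(nz & nrm == 0)) stop("zero gradient vector on a b > 0 frame")
  tab$gx[nz] <- tab$gx[nz] / nrm[nz]
  tab$gy[nz] <- tab$gy[nz] / nrm[nz]
  tab$gz[nz] <- tab$gz[nz] / nrm[nz]
  tab$gx[!nz] <- 0; tab$gy[!nz] <- 0; tab$gz[!nz] <- 0
  timing <- list(delta_big = 15, delta_small = 5, te_ms = NA_real_, tr_ms = NA_real_)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in names(timing)) if (!is.null(meta[[k]])) timing[[k]] <- meta[[k]]
  }
  dirs <- unique(round(as.matrix(tab[nz, c("gx", "gy", "gz")]), 10))
  diffusion_protocol(
    bvalues = unique(tab$b), directions = dirs,
    delta_big = timing$delta_big, delta_small = timing$delta_small,
    te_ms = timing$te_ms, tr_ms = timing$tr_ms,
    frames = tab
  )
}

#' Write a protocol's b-table
#'
#' @param protocol a `diffusion_protocol`.
#' @param stem output path stem; writes `<stem>.bval`, `<stem>.bvec` and a
#'   JSON timing sidecar, or `<stem>.tsv` when `format = "tsv"`.
#' @param format `"fsl"` or `"tsv"`.
#' @return invisibly, the paths written.
#' @export
write_btable <- function(protocol, stem, format = c("fsl", "tsv")) {
  format <- match.arg(format)
  fr <- protocol$frames
  if (format == "fsl") {
    paths <- paste0(stem, c(".bval", ".bvec", ".json"))
    fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
    writeLines(fmt(fr$b), paths[1])
    writeLines(c(fmt(fr$gx), fmt(fr$gy), fmt(fr$gz)), paths[2])
  } else {
    paths <- paste0(stem, c(".tsv", ".json"))
    fr_out <- as.data.frame(lapply(fr, sprintf, fmt = "%.17g"))
    names(fr_out) <- names(fr)
    utils::write.table(fr_out, paths[1], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  jsonlite::write_json(list(delta_big = protocol$delta_big,
                            delta_small = protocol$delta_small,
                            te_ms = protocol$te_ms, tr_ms = protocol$tr_ms),
                       paths[length(paths)], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Shell index of every frame (0 for b = 0), by matching b to protocol shells.
frame_shells <- function(protocol) {
  match(protocol$frames$b, protocol$bvalues)
}

# Frames with b <= b_max (always keeps b = 0 frames).
subset_frames <- function(protocol, b_max) {
  which(protocol$frames$b <= b_max + 1e-9)
}
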