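# Run expr with a temporarily seeded RNG, restoring the caller's RNG state
# (generators are pure functions of spec + seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Simulate one multi-shell diffusion voxel
#'
#' Noiseless signal from the forward model of the given ground truth (either
#' [neurite_params()] or a diffusion/kurtosis tensor pair), optionally
#' corrupted with Rician noise: the magnitude of the signal plus a complex
#' Gaussian with per-channel SD `s0 / snr_b0`.
#'
#' @param truth a `neurite_params` object, or a list with elements `d6`
#'   (packed diffusion tensor, um^2/ms), optionally `w15` (dimensionless
#'   kurtosis tensor) and `s0`.
#' @param protocol a [diffusion_protocol()].
#' @param snr_b0 signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed integer seed (RNG state is restored afterwards).
#' @return numeric signal vector, one value per protocol frame.
#' @export
simulate_voxel <- function(truth, protocol, snr_b0 = Inf, seed = NULL) {
  if (!is.infinite(snr_b0) && snr_b0 <= 0) stop("snr_b0 must be positive")
  if (inherits(truth, "neurite_params")) {
    s <- neurite_forward(truth, protocol)
    s0 <- truth$s0
  } else {
    s0 <- truth$s0 %||% 1
    fr <- protocol$frames
    X <- dki_design(fr)
    w15 <- truth$w15 %||% rep(0, 15)
    md <- mean(truth$d6[1:3])
    s <- exp(drop(X %*% c(log(s0), truth$d6, w15 * md^2)))
  }
  if (is.infinite(snr_b0)) return(s)
  sigma <- s0 / snr_b0
  with_seed(seed, {
    e1 <- stats::rnorm(length(s), 0, sigma)
    e2 <- stats::rnorm(length(s), 0, sigma)
    sqrt((s + e1)^2 + e2^2)
  })
}

#' Cohort effect specification
#'
#' Defines the hierarchical structure of a simulated cohort: group sizes
#' (defaults 7 control / 6 anhedonic / 8 resilient, the post-exclusion
#' sizes), per-(metric, roi, group) means and variance components, and the
#' stress-group variance inflation that emulates heterogeneous stress
#' response (applied to both the between- and within-animal SDs of the
#' stress groups).
#'
#' @param effects data.frame with columns `metric`, `roi`, `group`, `mean`,
#'   `between_sd`, `within_sd`; see [default_cohort_effects()].
#' @param groups named integer vector of animals per group.
#' @param stress_groups groups whose SDs are inflated.
#' @param variance_inflation multiplier on stress-group SDs (default 1.5).
#' @param n_replicates replicates (slices/sections) per animal (default 4,
#'   the number of 250-um slices spanning the 1-mm anatomical window).
#' @param seed integer seed.
#' @param mode `"table"` draws metric values directly; `"maps"` simulates
#'   voxel-wise diffusion signals so the full fitting chain can run (d-MRI
#'   metrics only).
#' @param snr_b0 Rician SNR for map mode (default 50).
#' @param n_voxels_per_slice voxels per ROI cross-section in map mode
#'   (default 4; a cost-scaled stand-in for the tens of voxels of a real
#'   cortical cross-section).
#' @param sh_order spherical-harmonic order of the map-mode voxel ODF
#'   (default 2: a smooth axially symmetric Watson-type dispersion).
#' @param odf_kappa Watson concentration of the map-mode ODF (default 3).
#' @return an object of class `cohort_effect_spec`.
#' @export
cohort_effect_spec <- function(effects = default_cohort_effects(),
                               groups = c(control = 7L, anhedonic = 6L,
                                          resilient = 8L),
                               stress_groups = c("anhedonic", "resilient"),
                               variance_inflation = 1.5,
                               n_replicates = 4L, seed = 1L,
                               mode = c("table", "maps"),
                               snr_b0 = 50, n_voxels_per_slice = 4L,
                               sh_order = 2L, odf_kappa = 3) {
  mode <- match.arg(mode)
  if (any(groups < 2L)) stop("need >= 2 animals per group")
  if (any(effects$between_sd < 0) || any(effects$within_sd < 0)) {
    stop("SDs must be non-negative")
  }
  missing_g <- setdiff(names(groups), unique(effects$group))
  if (length(missing_g)) stop("effects missing groups: ",
                              paste(missing_g, collapse = ", "))
  structure(list(effects = effects, groups = groups,
                 stress_groups = stress_groups,
                 variance_inflation = variance_inflation,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 mode = mode, snr_b0 = snr_b0,
                 n_voxels_per_slice = as.integer(n_voxels_per_slice),
                 sh_order = as.integer(sh_order), odf_kappa = odf_kappa),
            class = "cohort_effect_spec")
}

#' Default cohort effect template
#'
#' Encodes the qualitative group-difference structure under study: lower
#' extracellular diffusivity (D_eff) in auditory cortex of both stress
#' groups, higher FA and axonal density and lower cortical thickness in
#' motor cortex, no planted effect elsewhere. Magnitudes are configurable
#' defaults, not measured values.
#'
#' @param rois ROI names.
#' @return data.frame usable as the `effects` field of
#'   [cohort_effect_spec()].
#' @export
default_cohort_effects <- function(rois = c("MC", "SC", "AC", "VC")) {
  groups <- c("control", "anhedonic", "resilient")
  base <- expand.grid(metric = c("D_eff", "FA", "axonal_density_pct",
                                 "cortical_thickness_um"),
                      roi = rois, group = groups,
                      stringsAsFactors = FALSE)
  base$mean <- c(D_eff = 0.60, FA = 0.25, axonal_density_pct = 8,
                 cortical_thickness_um = 1800)[base$metric]
  base$between_sd <- c(D_eff = 0.03, FA = 0.02, axonal_density_pct = 0.8,
                       cortical_thickness_um = 60)[base$metric]
  base$within_sd <- c(D_eff = 0.03, FA = 0.02, axonal_density_pct = 0.8,
                      cortical_thickness_um = 60)[base$metric]
  stress <- base$group %in% c("anhedonic", "resilient")
  base$mean[base$metric == "D_eff" & base$roi == "AC" & stress] <- 0.48
  base$mean[base$metric == "FA" & base$roi == "MC" &
              base$group == "resilient"] <- 0.30
  base$mean[base$metric == "axonal_density_pct" & base$roi == "MC" &
              base$group == "resilient"] <- 10
  base$mean[base$metric == "cortical_thickness_um" & base$roi == "MC" &
              stress] <- 1650
  base
}

cohort_animal_ids <- function(groups) {
  unlist(lapply(names(groups), function(g) {
    sprintf("%s%02d", substr(g, 1, 1), seq_len(groups[[g]]))
  }))
}

#' Simulate a cohort with known ground truth
#'
#' Hierarchical draws: animal effect ~ Normal(0, between_sd), replicate value
#' = group mean + animal effect + Normal(0, within_sd), with both SDs
#' multiplied by `variance_inflation` in the stress groups. In `"maps"` mode
#' each replicate's D_eff value parametrises the two-compartment forward
#' model and voxel signals are generated with Rician noise, so the full
#' fit -> aggregate -> mixed-model chain can run on the output.
#'
#' @param spec a [cohort_effect_spec()].
#' @return class `cohort_sim`. In table mode: `table` (a [cohort_table()])
#'   and `truth` (replicate-level truth in the same tidy schema). In map
#'   mode: additionally `datasets` (one [dwi_dataset()] per animal), `mask`
#'   (a [roi_mask()]) and `meta` (animal/group table); the protocol is the
#'   study's 14-shell scheme.
#' @export
simulate_cohort <- function(spec) {
  with_seed(spec$seed, {
    meta <- data.frame(animal_id = cohort_animal_ids(spec$groups),
                       group = rep(names(spec$groups), spec$groups))
    truth <- NULL
    for (i in seq_len(nrow(spec$effects))) {
      ef <- spec$effects[i, ]
      infl <- if (ef$group %in% spec$stress_groups) spec$variance_inflation else 1
      animals <- meta$animal_id[meta$group == ef$group]
      a_eff <- stats::rnorm(length(animals), 0, ef$between_sd * infl)
      for (j in seq_along(animals)) {
        vals <- ef$mean + a_eff[j] +
          stats::rnorm(spec$n_replicates, 0, ef$within_sd * infl)
        truth <- rbind(truth, data.frame(
          animal_id = animals[j], group = ef$group, roi = ef$roi,
          replicate = seq_len(spec$n_replicates), metric = ef$metric,
          value = vals))
      }
    }
    if (spec$mode == "table") {
      return(structure(list(table = cohort_table(truth,
                                                 groups = names(spec$groups)),
                            truth = truth, meta = meta, spec = spec),
                       class = "cohort_sim"))
    }
    # map mode: voxel-wise simulation driven by the D_eff truth values
    dmri <- truth[truth$metric %in% c("Neu", "D_L", "D_eff"), , drop = FALSE]
    if (!nrow(dmri)) stop("map mode needs a d-MRI metric (Neu, D_L or D_eff) in the effect table")
    protocol <- default_protocol()
    rois <- unique(dmri$roi)
    nv <- spec$n_voxels_per_slice
    ns <- spec$n_replicates
    labels <- array(0L, c(nv, length(rois), ns))
    for (r in seq_along(rois)) labels[, r, ] <- r
    mask <- roi_mask(labels, stats::setNames(seq_along(rois), rois))
    odf <- watson_odf_coeffs(spec$odf_kappa, c(0, 0, 1), spec$sh_order)
    datasets <- list()
    for (aid in meta$animal_id) {
      sig <- array(0, c(nv, length(rois), ns, nrow(protocol$frames)))
      for (r in seq_along(rois)) {
        tr <- dmri[dmri$animal_id == aid & dmri$roi == rois[r], ]
        for (s in seq_len(ns)) {
          val <- tr$value[tr$replicate == s]
          pars <- list(neu = 0.5, d_long = 1.0, d_eff = 0.6)
          pars[[c(Neu = "neu", D_L = "d_long", D_eff = "d_eff")[tr$metric[1]]]] <-
            min(max(val, 0.01), 2.99)
          np <- neurite_params(pars$neu, pars$d_long, pars$d_eff,
                               odf_coeffs = odf, s0 = 1,
                               sh_order = spec$sh_order)
          for (v in seq_len(nv)) {
            sig[v, r, s, ] <- simulate_voxel(np, protocol, spec$snr_b0)
          }
        }
      }
      datasets[[aid]] <- dwi_dataset(sig, protocol)
    }
    structure(list(datasets = datasets, mask = mask, meta = meta,
                   truth = dmri, protocol = protocol, spec = spec),
              class = "cohort_sim")
  })
}

#' @exportS3Method base::print
print.cohort_sim <- function(x, ...) {
  cat("Simulated cohort (", x$spec$mode, " mode): ",
      nrow(x$meta), " animals\n", sep = "")
  invisible(x)
}

#' Micrograph generator specification
#'
#' @param size_px image size (rows, cols).
#' @param um_per_px calibration.
#' @param process_area_fraction target stained process (axon/dendrite) area
#'   fraction, in [0, 0.5].
#' @param n_cell_bodies number of quasi-circular somata.
#' @param body_diameter_um soma diameter range.
#' @param process_width_um process width range.
#' @param background_noise_sd Gaussian noise SD on the white background.
#' @param stain stain label carried to the micrograph.
#' @param seed integer seed.
#' @return an object of class `micrograph_spec`.
#' @export
micrograph_spec <- function(size_px = c(512L, 512L), um_per_px = 0.5,
                            process_area_fraction = 0.08, n_cell_bodies = 10L,
                            body_diameter_um = c(12, 18),
                            process_width_um = c(0.8, 1.6),
                            background_noise_sd = 0.02,
                            stain = "NF-H", seed = 1L) {
  if (process_area_fraction < 0 || process_area_fraction > 0.5) {
    stop("process_area_fraction must lie in [0, 0.5]")
  }
  structure(list(size_px = as.integer(size_px), um_per_px = um_per_px,
                 process_area_fraction = process_area_fraction,
                 n_cell_bodies = as.integer(n_cell_bodies),
                 body_diameter_um = body_diameter_um,
                 process_width_um = process_width_um,
                 background_noise_sd = background_noise_sd,
                 stain = stain, seed = seed),
            class = "micrograph_spec")
}

disc_pixels <- function(h, w, cx, cy, r) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(h, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(w, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(NULL)
  gx <- x0:x1; gy <- y0:y1
  d2 <- outer((gx - cx)^2, (gy - cy)^2, `+`)
  cbind(rep(gx, length(gy))[d2 <= r^2],
        rep(gy, each = length(gx))[d2 <= r^2])
}

#' Generate a synthetic stained micrograph with known ground truth
#'
#' White background with dark quasi-circular somata and dark random-walk
#' polylines of given width (processes). Processes avoid a margin around
#' somata so the rendered classes stay disjoint; the truth table records the
#' exact rendered pixel fraction of each class.
#'
#' @param spec a [micrograph_spec()].
#' @return list with `image` (a [micrograph()]) and `truth` (exact process /
#'   body pixel fractions and the soma inventory).
#' @export
synth_micrograph <- function(spec) {
  with_seed(spec$seed, {
    h <- spec$size_px[1]; w <- spec$size_px[2]
    total <- h * w
    body <- matrix(FALSE, h, w)
    keepout <- matrix(FALSE, h, w)
    margin_px <- 4
    bodies <- NULL
    tries <- 0
    while (is.null(bodies) || nrow(bodies) < spec$n_cell_bodies) {
      tries <- tries + 1
      if (tries > 2000) stop("cannot place the requested cell bodies in this image size")
      d_um <- stats::runif(1, spec$body_diameter_um[1], spec$body_diameter_um[2])
      r <- d_um / spec$um_per_px / 2
      cx <- stats::runif(1, r + margin_px, h - r - margin_px)
      cy <- stats::runif(1, r + margin_px, w - r - margin_px)
      if (!is.null(bodies) &&
          any((bodies[, 1] - cx)^2 + (bodies[, 2] - cy)^2 <
                (bodies[, 3] + r + 2 * margin_px)^2)) next
      bodies <- rbind(bodies, c(cx, cy, r))
      body[disc_pixels(h, w, cx, cy, r)] <- TRUE
      keepout[disc_pixels(h, w, cx, cy, r + margin_px)] <- TRUE
    }
    proc <- matrix(FALSE, h, w)
    target_px <- spec$process_area_fraction * total
    if (target_px > 0) {
      max_walks <- 5000
      walk <- 0
      while (sum(proc) < target_px) {
        walk <- walk + 1
        if (walk > max_walks) stop("requested process fraction unreachable in this image size")
        wd <- stats::runif(1, spec$process_width_um[1], spec$process_width_um[2])
        rw <- wd / spec$um_per_px / 2
        x <- stats::runif(1, 1, h); y <- stats::runif(1, 1, w)
        ang <- stats::runif(1, 0, 2 * pi)
        n_steps <- stats::rpois(1, 150) + 50
        for (step in seq_len(n_steps)) {
          ang <- ang + stats::rnorm(1, 0, 0.15)
          x <- x + cos(ang); y <- y + sin(ang)
          if (x < 2 || x > h - 1 || y < 2 || y > w - 1) break
          if (keepout[round(x), round(y)]) break
          proc[disc_pixels(h, w, x, y, max(rw, 0.6))] <- TRUE
        }
      }
    }
    proc <- proc & !body   # body paint wins any residual ties
    img <- matrix(1, h, w) +
      matrix(stats::rnorm(total, 0, spec$background_noise_sd), h, w)
    rgb <- array(0, c(h, w, 3))
    tint <- c(0.40, 0.28, 0.20)       # DAB-brown structures
    for (ch in 1:3) {
      plane <- img
      plane[proc] <- tint[ch] + stats::rnorm(sum(proc), 0, 0.02)
      plane[body] <- tint[ch] * 0.8 + stats::rnorm(sum(body), 0, 0.02)
      rgb[, , ch] <- pmin(1, pmax(0, plane))
    }
    truth <- data.frame(
      process_fraction = sum(proc) / total,
      body_fraction = sum(body) / total,
      n_bodies = nrow(bodies))
    list(image = micrograph(rgb, spec$um_per_px, spec$stain),
         truth = truth,
         body_inventory = data.frame(cx = bodies[, 1], cy = bodies[, 2],
                                     radius_px = bodies[, 3]),
         process_mask = proc, body_mask = body)
  })
}

#' Generate a synthetic cortex montage with line annotations
#'
#' A tissue band whose pial and white-matter boundaries are separated by the
#' requested thickness, with optional smooth sinusoidal undulation. Five
#' annotation lines per ROI are drawn from the pial boundary along its local
#' normal to the deep boundary.
#'
#' @param thickness_um named vector of true cortical thickness per ROI, um.
#' @param um_per_px calibration (default 5 um/px, a 4x montage scale).
#' @param seed integer seed (randomises undulation phase).
#' @param undulation_frac undulation amplitude as a fraction of thickness
#'   (default 0 = flat).
#' @param n_lines annotation lines per ROI (default 5).
#' @param roi_width_px horizontal extent per ROI.
#' @param height_px image height; sized automatically to fit the band when
#'   NULL. An explicit height too small for the requested thickness is an
#'   error.
#' @return list with `image` (grayscale matrix), `lines` (annotation table
#'   with pixel-coordinate endpoints) and `truth` (per-ROI thickness).
#' @export
synth_cortex_montage <- function(thickness_um, um_per_px = 5, seed = 1L,
                                 undulation_frac = 0, n_lines = 5L,
                                 roi_width_px = 400L, height_px = NULL) {
  if (any(thickness_um <= 0)) stop("thickness must be positive")
  if (is.null(names(thickness_um))) {
    names(thickness_um) <- paste0("ROI", seq_along(thickness_um))
  }
  with_seed(seed, {
    t_px <- thickness_um / um_per_px
    h <- height_px %||% (ceiling(max(t_px) * 1.6) + 40L)
    w <- roi_width_px * length(thickness_um)
    if (max(t_px) * (1 + undulation_frac) > h - 20) {
      stop("thickness exceeds image extent")
    }
    img <- matrix(1, h, w)
    lines <- NULL
    for (k in seq_along(thickness_um)) {
      x0 <- (k - 1L) * roi_width_px
      Tpx <- t_px[k]
      A <- undulation_frac * Tpx
      lambda <- max(roi_width_px, 4 * Tpx)
      phase <- stats::runif(1, 0, 2 * pi)
      y_off <- 10 + A
      xg <- seq_len(roi_width_px)
      y_top <- y_off + A * sin(2 * pi * xg / lambda + phase)
      for (xi in xg) {
        ys <- max(1, round(y_top[xi]))
        ye <- min(h, round(y_top[xi] + Tpx))
        img[ys:ye, x0 + xi] <- 0.6
      }
      xs <- round(seq(roi_width_px * 0.15, roi_width_px * 0.85,
                      length.out = n_lines))
      for (xi in xs) {
        yt <- y_off + A * sin(2 * pi * xi / lambda + phase)
        slope <- A * (2 * pi / lambda) * cos(2 * pi * xi / lambda + phase)
        nrm <- c(-slope, 1) / sqrt(1 + slope^2)   # (dx, dy), pointing down
        g <- function(t) {
          xe <- xi + t * nrm[1]
          (yt + t * nrm[2]) -
            (y_off + A * sin(2 * pi * xe / lambda + phase) + Tpx)
        }
        tt <- stats::uniroot(g, c(Tpx * 0.5, Tpx * 1.5))$root
        lines <- rbind(lines, data.frame(
          image = "montage", roi = names(thickness_um)[k], montage = 1L,
          x1 = x0 + xi, y1 = yt, x2 = x0 + xi + tt * nrm[1],
          y2 = yt + tt * nrm[2]))
      }
    }
    list(image = img, lines = lines,
         truth = data.frame(roi = names(thickness_um),
                            thickness_um = as.numeric(thickness_um)))
  })
}

#' Run the simulate -> fit -> aggregate -> test chain once
#'
#' Executes the full recovery chain on one seeded map-mode cohort: voxel-wise
#' neurite-model fitting of every animal's dataset, slice-wise ROI
#' aggregation, the mixed-model group test with gatekept BH-corrected
#' post-hoc contrasts, and descriptive per-group confidence intervals.
#'
#' @param spec a map-mode [cohort_effect_spec()].
#' @param metric,roi cell to test (default `"D_eff"` in `"AC"`).
#' @param options fitting options; defaults match the generator's ODF order.
#' @param alpha significance level.
#' @return list with the fitted `lmm_result` (post-hoc attached), the
#'   [group_summary()] table, and the cohort table.
#' @export
run_cohort_chain <- function(spec, metric = "D_eff", roi = "AC",
                             options = neurite_fit_options(
                               sh_order = spec$sh_order, refine_top = 3L),
                             alpha = 0.05) {
  sim <- simulate_cohort(spec)
  if (spec$mode != "maps") stop("run_cohort_chain needs a map-mode spec")
  maps <- lapply(sim$datasets, function(ds) {
    neurite_maps(fit_neurite(ds, options = options))
  })
  tab <- aggregate_roi(maps, sim$mask, sim$meta)
  res <- lmm_group_test(tab, metric, roi, alpha = alpha)
  res <- posthoc_pairwise(res)
  list(result = res, groups = group_summary(tab, metric, roi), table = tab,
       truth = sim$truth)
}
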