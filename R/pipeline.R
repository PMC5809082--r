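#' Pipeline configuration
#'
#' Builds (or reads from YAML/JSON) the configuration driving
#' [run_pipeline()]. Every default that fills a gap left open by the
#' acquisition/analysis description is echoed into the run report for
#' auditability.
#'
#' @param path YAML or JSON config file; overrides the other arguments.
#' @param simulate list of arguments to [cohort_effect_spec()] (or `TRUE`
#'   for defaults) to drive the run from generated data; `NULL` to read
#'   inputs from `paths`.
#' @param paths list of input paths: `dwi` (named per-animal NIfTI),
#'   `btable`, `roi_mask`, `cohort_meta` (CSV: animal_id, group), optional
#'   `micrograph_manifest` (CSV: path, um_per_px, stain, roi, animal_id,
#'   group, section_index), optional `line_annotations` (CSV).
#' @param fit list: `models` (subset of "dti", "dki", "neurite"),
#'   `b_max_dki` (default 4.5 ms/um^2), `sh_order` (default 4), `dti_from`
#'   ("dki" default: MD/FA from the joint kurtosis fit; or "dti"),
#'   `refine_top` multi-start refinements.
#' @param stats list: `alpha` (default 0.05), `metrics`, `rois` to test
#'   (default: everything present).
#' @param histology list: per-stain threshold and [cell_body_criteria()]
#'   overrides.
#' @param outdir output directory.
#' @param seed integer seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, simulate = NULL, paths = list(),
                            fit = list(), stats = list(), histology = list(),
                            outdir = "cortmicro-out", seed = 1L) {
  if (!is.null(path)) {
    raw <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    return(do.call(pipeline_config, c(raw, list(path = NULL))))
  }
  fit <- utils::modifyList(list(models = c("neurite"), b_max_dki = 4.5,
                                sh_order = 4, dti_from = "dki",
                                refine_top = 5L), fit)
  stats <- utils::modifyList(list(alpha = 0.05, metrics = NULL, rois = NULL),
                             stats)
  histology <- utils::modifyList(list(threshold_frac = 0.30,
                                      criteria = cell_body_criteria()),
                                 histology)
  if (stats$alpha <= 0 || stats$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (isTRUE(simulate)) simulate <- list()
  cfg <- structure(list(simulate = simulate, paths = paths, fit = fit,
                        stats = stats, histology = histology,
                        outdir = outdir, seed = seed),
                   class = "pipeline_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    need <- c("dwi", "btable", "roi_mask", "cohort_meta")
    for (k in need) {
      if (is.null(cfg$paths[[k]])) stop("config missing required path: ", k)
    }
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  bad <- setdiff(cfg$fit$models, c("dti", "dki", "neurite"))
  if (length(bad)) stop("unknown fit models: ", paste(bad, collapse = ", "))
  cfg
}

pipe_log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = state$logfile, append = TRUE)
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: load or simulate inputs -> voxel-wise model fitting (DTI / DKI /
#' neurite model as configured) -> ROI aggregation into a tidy cohort table
#' -> histology quantification (when micrographs / line annotations are
#' provided) -> mixed-model group tests with gatekept BH-corrected post-hoc
#' contrasts -> report (results CSV, JSON summary, per-ROI forest figures,
#' log). A stage failure aborts with the stage name; partial outputs are
#' preserved in `outdir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cohort table, the per-(metric, roi)
#'   `lmm_result`s, and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logfile = file.path(config$outdir, "pipeline.log"))
  cat("", file = state$logfile)
  pipe_log(state, "run_pipeline seed=", config$seed)
  stage <- function(name, expr) {
    pipe_log(state, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      spec <- do.call(cohort_effect_spec,
                      utils::modifyList(list(mode = "maps", seed = config$seed),
                                        config$simulate))
      sim <- simulate_cohort(spec)
      list(datasets = sim$datasets, mask = sim$mask, meta = sim$meta,
           histo_table = NULL)
    } else {
      meta <- utils::read.csv(config$paths$cohort_meta,
                              stringsAsFactors = FALSE)
      datasets <- lapply(config$paths$dwi, read_dwi,
                         btable_path = config$paths$btable)
      list(datasets = datasets, mask = read_roi_mask(config$paths$roi_mask),
           meta = meta, histo_table = NULL)
    }
  })

  maps <- stage("fit", {
    out <- list()
    for (aid in names(inputs$datasets)) {
      ds <- inputs$datasets[[aid]]
      m <- list()
      if ("neurite" %in% config$fit$models) {
        nf <- fit_neurite(ds, options = neurite_fit_options(
          sh_order = config$fit$sh_order,
          refine_top = config$fit$refine_top))
        m <- c(m, neurite_maps(nf))
      }
      if ("dki" %in% config$fit$models) {
        kf <- fit_dki(ds, b_max = config$fit$b_max_dki)
        m <- c(m, kurtosis_metrics(kf))
        if (config$fit$dti_from == "dki") m <- c(m, dti_metrics(kf))
      }
      if ("dti" %in% config$fit$models &&
          !("dki" %in% config$fit$models && config$fit$dti_from == "dki")) {
        df <- fit_dti(ds, b_max = min(4.5, config$fit$b_max_dki))
        m <- c(m, dti_metrics(df))
      }
      out[[aid]] <- m
    }
    out
  })

  table <- stage("aggregate", {
    aggregate_roi(maps, inputs$mask, inputs$meta)
  })

  table <- stage("histology", {
    recs <- NULL
    if (!is.null(config$paths$micrograph_manifest)) {
      man <- utils::read.csv(config$paths$micrograph_manifest,
                             stringsAsFactors = FALSE)
      for (i in seq_len(nrow(man))) {
        img <- read_micrograph(man$path[i], man$um_per_px[i], man$stain[i])
        dens <- stain_density(img, config$histology$criteria,
                              config$histology$threshold_frac)
        metric <- if (man$stain[i] == "NF-H") "axonal_density_pct" else "dendritic_density_pct"
        recs <- rbind(recs, data.frame(
          animal_id = man$animal_id[i], group = man$group[i],
          roi = man$roi[i], replicate = man$section_index[i],
          metric = metric, value = dens$density_pct))
      }
    }
    if (!is.null(config$paths$line_annotations)) {
      ann <- read_line_annotations(config$paths$line_annotations)
      th <- cortical_thickness(ann, um_per_px = ann$um_per_px[1])
      agg <- stats::aggregate(thickness_um ~ roi + montage + animal_id + group,
                              data = th, FUN = mean)
      recs <- rbind(recs, data.frame(
        animal_id = agg$animal_id, group = agg$group, roi = agg$roi,
        replicate = agg$montage, metric = "cortical_thickness_um",
        value = agg$thickness_um))
    }
    if (is.null(recs)) table else {
      cohort_table(rbind(as.data.frame(table), recs),
                   groups = unique(c(levels(table$group), recs$group)))
    }
  })

  results <- stage("stats", {
    metrics <- config$stats$metrics %||% unique(table$metric)
    rois <- config$stats$rois %||% unique(table$roi)
    out <- list()
    for (m in metrics) for (r in rois) {
      if (!nrow(table[table$metric == m & table$roi == r, ])) next
      res <- lmm_group_test(table, m, r, alpha = config$stats$alpha)
      res <- posthoc_pairwise(res)
      out[[paste(m, r, sep = ".")]] <- res
    }
    out
  })

  paths <- stage("report", {
    write_report(table, results, config)
  })

  pipe_log(state, "done")
  invisible(list(table = table, results = results, paths = paths,
                 config = config))
}

# Results CSV, JSON summary (parameters echoed for audit), per-metric forest
# figures.
write_report <- function(table, results, config) {
  outdir <- config$outdir
  res_df <- do.call(rbind, lapply(results, function(r) {
    base <- data.frame(metric = r$metric, roi = r$roi, f_stat = r$f_stat,
                       df_num = r$df_num, df_den = r$df_den,
                       p_value = r$p_value, degraded = r$degraded)
    pw <- r$pairwise
    if (is.null(pw)) {               # gatekeeping: no post-hoc entries
      pw <- data.frame(contrast = NA_character_, estimate = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       p_raw = NA_real_, p_fdr = NA_real_)
    }
    pw$metric <- r$metric; pw$roi <- r$roi
    merge(base, pw, by = c("metric", "roi"))
  }))
  res_path <- file.path(outdir, "results.csv")
  utils::write.csv(res_df, res_path, row.names = FALSE)
  write_cohort_table(table, file.path(outdir, "cohort_table.csv"))
  summary <- list(
    seed = config$seed,
    alpha = config$stats$alpha,
    fit = config$fit,
    histology = list(threshold_frac = config$histology$threshold_frac,
                     criteria = config$histology$criteria),
    n_records = nrow(table),
    tests = lapply(results, function(r) {
      list(metric = r$metric, roi = r$roi, p_value = r$p_value,
           significant = r$p_value <= config$stats$alpha)
    })
  )
  json_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  fig_paths <- c()
  for (m in unique(vapply(results, `[[`, "", "metric"))) {
    fp <- file.path(outdir, paste0("forest_", m, ".png"))
    grDevices::png(fp, width = 900, height = 500)
    forest_plot(results[vapply(results, `[[`, "", "metric") == m])
    grDevices::dev.off()
    fig_paths <- c(fig_paths, fp)
  }
  c(results = res_path, summary = json_path, figures = fig_paths)
}

#' Forest plot of estimated group means with 95% CIs per ROI
#'
#' Mirrors the study's figure layout: one panel row per metric, groups
#' side by side within each ROI.
#'
#' @param results list of `lmm_result`s (same metric, different ROIs).
#' @param ... passed to [graphics::plot()].
#' @export
forest_plot <- function(results, ...) {
  results <- Filter(function(r) !is.null(r$group_means), results)
  if (!length(results)) {
    graphics::plot.new()
    graphics::title("no group means available")
    return(invisible(NULL))
  }
  gm <- do.call(rbind, lapply(results, function(r) {
    cbind(roi = r$roi, r$group_means)
  }))
  ng <- length(unique(gm$group))
  x <- as.numeric(factor(gm$roi)) +
    (as.numeric(factor(gm$group)) - (ng + 1) / 2) * 0.2
  graphics::plot(x, gm$estimate,
                 ylim = range(gm$ci_low, gm$ci_high),
                 xaxt = "n", xlab = "ROI",
                 ylab = results[[1]]$metric,
                 pch = as.numeric(factor(gm$group)), ...)
  graphics::axis(1, at = seq_along(unique(gm$roi)),
                 labels = levels(factor(gm$roi)))
  graphics::arrows(x, gm$ci_low, x, gm$ci_high, angle = 90, code = 3,
                   length = 0.03)
  graphics::legend("topright", legend = levels(factor(gm$group)),
                   pch = seq_len(ng), bty = "n")
  invisible(NULL)
}

#' @export
plot.lmm_result <- function(x, ...) {
  forest_plot(list(x), ...)
}
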