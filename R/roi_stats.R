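#' Long-format cohort table
#'
#' One record per (animal, ROI, replicate, metric): the unit entering the
#' mixed model. Replicates are slice-wise ROI means for d-MRI metrics and
#' sections/montages for histology metrics.
#'
#' @param records data.frame with columns `animal_id`, `group`, `roi`,
#'   `replicate`, `metric`, `value`.
#' @param groups declared group levels.
#' @return a `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(records,
                         groups = c("control", "anhedonic", "resilient")) {
  need <- c("animal_id", "group", "roi", "replicate", "metric", "value")
  if (!all(need %in% names(records))) {
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  }
  records <- as.data.frame(records)[, need]
  if (!all(records$group %in% groups)) {
    stop("group values outside the declared set: ",
         paste(setdiff(unique(records$group), groups), collapse = ", "))
  }
  if (any(!is.finite(records$value))) stop("non-finite values in cohort table")
  key <- paste(records$animal_id, records$roi, records$replicate,
               records$metric, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (animal, roi, replicate, metric) records")
  }
  records$group <- factor(records$group, levels = groups)
  structure(records, class = c("cohort_table", "data.frame"))
}

#' @exportS3Method base::print
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "records;",
      length(unique(x$animal_id)), "animals;",
      "metrics:", paste(unique(x$metric), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a cohort table as tidy CSV
#' @param table a `cohort_table`.
#' @param path CSV path.
#' @return invisibly `path` (write) or a `cohort_table` (read).
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df, groups = unique(df$group))
}

#' Aggregate parameter maps over ROIs into a cohort table
#'
#' Per animal x ROI x metric, one record per slice inside the mask's slice
#' window, holding the mean of valid (fitted, finite) voxels of that slice's
#' ROI cross-section. Empty cross-sections are skipped with a warning.
#'
#' @param maps for a single animal, a named list of [parameter_map()]s; for a
#'   cohort, a list of such lists keyed by animal id.
#' @param mask a [roi_mask()] aligned to the maps.
#' @param cohort_meta data.frame with columns `animal_id`, `group` (one row
#'   for a single-animal call).
#' @return a [cohort_table()].
#' @export
aggregate_roi <- function(maps, mask, cohort_meta) {
  if (length(maps) && inherits(maps[[1]], "parameter_map")) {
    maps <- stats::setNames(list(maps), cohort_meta$animal_id[1])
  }
  recs <- list()
  slices <- seq(mask$slice_range[1], mask$slice_range[2] - 1L)
  slice_idx <- slice.index(mask$labels, mask$slice_axis)
  for (aid in names(maps)) {
    grp <- cohort_meta$group[match(aid, cohort_meta$animal_id)]
    for (m in maps[[aid]]) {
      if (!all(dim(m$values) == dim(mask$labels))) {
        stop("map '", m$name, "' not aligned to the ROI mask grid")
      }
      for (roi in names(mask$label_names)) {
        lab <- mask$label_names[[roi]]
        for (s in slices) {
          sel <- mask$labels == lab & slice_idx == s & m$mask &
            is.finite(m$values)
          n_valid <- sum(sel)
          if (n_valid == 0L) {
            warning("empty ROI cross-section: ", aid, " ", roi, " slice ", s,
                    " metric ", m$name, " (skipped)")
            next
          }
          recs[[length(recs) + 1L]] <- data.frame(
            animal_id = aid, group = as.character(grp), roi = roi,
            replicate = s, metric = m$name, value = mean(m$values[sel]),
            n_voxels = n_valid)
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  ct <- cohort_table(out[, 1:6], groups = unique(cohort_meta$group))
  attr(ct, "n_voxels") <- out$n_voxels
  ct
}

#' Mixed-model group test for one metric in one ROI
#'
#' REML fit of `value ~ group + (1 | animal)` with an overall group F-test
#' using Satterthwaite denominator degrees of freedom, and estimated group
#' means with 95% confidence intervals. When the random-effect variance is
#' singular (zero between-animal variance) or each animal contributes a
#' single observation, the model degrades gracefully to a fixed-effects
#' one-way ANOVA and is flagged `degraded`.
#'
#' @param table a [cohort_table()].
#' @param metric metric name to test.
#' @param roi ROI name to test.
#' @param alpha significance level for the overall test (default 0.05).
#' @param means compute estimated group means with CIs (default TRUE; can be
#'   switched off in large simulation loops).
#' @return an object of class `lmm_result`.
#' @export
lmm_group_test <- function(table, metric, roi, alpha = 0.05, means = TRUE) {
  d <- table[table$metric == metric & table$roi == roi, , drop = FALSE]
  d <- droplevels(as.data.frame(d))
  if (length(unique(d$group)) < 2L) stop("need >= 2 groups")
  if (any(tapply(d$animal_id, d$group, function(a) length(unique(a))) < 2)) {
    stop("need >= 2 animals per group")
  }
  d$animal_id <- factor(d$animal_id)
  one_obs <- max(table(d$animal_id)) == 1L
  degraded <- FALSE
  model <- NULL
  if (!one_obs) {
    model <- suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ group + (1 | animal_id), data = d, REML = TRUE)))
    if (lme4::isSingular(model, tol = 1e-4)) {
      degraded <- TRUE
      model <- NULL
    }
  } else {
    degraded <- TRUE
  }
  if (is.null(model)) {
    model <- stats::lm(value ~ group, data = d)
    an <- stats::anova(model)
    f_stat <- an["group", "F value"]
    df_num <- an["group", "Df"]
    df_den <- an["Residuals", "Df"]
    p_value <- an["group", "Pr(>F)"]
  } else {
    an <- stats::anova(model)   # lmerTest: Satterthwaite F by default
    f_stat <- an["group", "F value"]
    df_num <- an["group", "NumDF"]
    df_den <- an["group", "DenDF"]
    p_value <- an["group", "Pr(>F)"]
  }
  group_means <- NULL
  if (means) {
    em <- emmeans::emmeans(model, "group", lmer.df = "satterthwaite",
                           level = 0.95)
    group_means <- as.data.frame(em)
    names(group_means)[names(group_means) == "emmean"] <- "estimate"
    names(group_means)[names(group_means) == "lower.CL"] <- "ci_low"
    names(group_means)[names(group_means) == "upper.CL"] <- "ci_high"
  }
  structure(list(metric = metric, roi = roi,
                 f_stat = f_stat, df_num = df_num, df_den = df_den,
                 p_value = p_value, alpha = alpha,
                 group_means = group_means, pairwise = NULL,
                 degraded = degraded, model = model, data = d),
            class = "lmm_result")
}

#' @exportS3Method base::print
print.lmm_result <- function(x, ...) {
  cat(sprintf("%s in %s: F(%.3g, %.3g) = %.3f, p = %.4g%s\n",
              x$metric, x$roi, x$df_num, x$df_den, x$f_stat, x$p_value,
              if (x$degraded) " [fixed-effects fallback]" else ""))
  if (!is.null(x$group_means)) {
    print(x$group_means[, c("group", "estimate", "ci_low", "ci_high")],
          row.names = FALSE)
  }
  if (!is.null(x$pairwise)) {
    cat("Pairwise contrasts (BH-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.lmm_result <- function(object, ...) {
  print(object)
}

#' Post-hoc pairwise contrasts with BH correction
#'
#' Run only when the overall F-test is significant at `alpha` (gatekeeping);
#' otherwise the result is returned unchanged with a note. Pairwise t-tests
#' on the fixed-effect group contrasts use Satterthwaite degrees of freedom;
#' p-values are Benjamini--Hochberg adjusted across the contrast family
#' within this (metric, roi).
#'
#' @param result an `lmm_result`.
#' @param alpha gate level (defaults to the level stored in `result`).
#' @return the updated `lmm_result` with a `pairwise` data.frame of
#'   (contrast, estimate, ci_low, ci_high, p_raw, p_fdr).
#' @export
posthoc_pairwise <- function(result, alpha = result$alpha) {
  if (result$p_value > alpha) {
    result$note <- "overall test not significant; post-hoc skipped"
    return(result)
  }
  em <- emmeans::emmeans(result$model, "group", lmer.df = "satterthwaite")
  prs <- emmeans::contrast(em, method = "pairwise", adjust = "none")
  tab <- as.data.frame(prs)
  ci <- as.data.frame(stats::confint(prs, level = 0.95))
  result$pairwise <- data.frame(
    contrast = tab$contrast,
    estimate = tab$estimate,
    ci_low = ci$lower.CL,
    ci_high = ci$upper.CL,
    p_raw = tab$p.value,
    p_fdr = stats::p.adjust(tab$p.value, method = "BH")
  )
  result
}

#' Descriptive per-group summary with group-specific confidence intervals
#'
#' Per-animal means are computed first (the animal is the experimental
#' unit); each group then gets its own mean and a 95% t-interval using that
#' group's own spread. Unlike the homoscedastic mixed model -- whose pooled
#' group-mean CIs differ between groups only through group size -- these
#' intervals reflect group-specific variance heterogeneity, which is what a
#' per-group error-bar figure displays.
#'
#' @param table a [cohort_table()].
#' @param metric,roi cell to summarise.
#' @param level confidence level (default 0.95).
#' @return data.frame of group, n animals, mean, sd of animal means, ci_low,
#'   ci_high, ci_width.
#' @export
group_summary <- function(table, metric, roi, level = 0.95) {
  d <- as.data.frame(table[table$metric == metric & table$roi == roi, ])
  am <- stats::aggregate(value ~ animal_id + group, data = d, FUN = mean)
  out <- do.call(rbind, lapply(split(am, am$group, drop = TRUE), function(g) {
    n <- nrow(g)
    m <- mean(g$value)
    s <- stats::sd(g$value)
    half <- stats::qt(1 - (1 - level) / 2, n - 1) * s / sqrt(n)
    data.frame(group = g$group[1], n = n, mean = m, sd = s,
               ci_low = m - half, ci_high = m + half, ci_width = 2 * half)
  }))
  rownames(out) <- NULL
  out
}
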