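test_that("cohort tables validate their schema", {
  rec <- data.frame(animal_id = "a1", group = "control", roi = "AC",
                    replicate = 1, metric = "D_eff", value = 0.5)
  expect_s3_class(cohort_table(rec), "cohort_table")
  expect_error(cohort_table(rbind(rec, rec)), "duplicate")
  bad <- rec; bad$group <- "sham"
  expect_error(cohort_table(bad), "declared set")
  nf <- rec; nf$value <- NA
  expect_error(cohort_table(nf), "non-finite")
})

test_that("ROI aggregation takes slice-wise means of valid voxels", {
  lab <- array(0L, c(3, 3, 2)); lab[1:2, 1:2, ] <- 1L
  mask <- roi_mask(lab, c(AC = 1L))
  meta <- data.frame(animal_id = "a1", group = "control")
  # constant map
  tab <- aggregate_roi(list(AC = parameter_map("D_eff", array(0.7, c(3, 3, 2)))),
                       mask, meta)
  expect_true(all(tab$value == 0.7))
  expect_equal(nrow(tab), 2L)  # one record per slice
  # explicit arithmetic mean
  vals <- array(NA_real_, c(3, 3, 2))
  vals[1:2, 1:2, 1] <- c(1, 2, 3, 4)
  vals[1:2, 1:2, 2] <- 10
  tab2 <- aggregate_roi(list(m = parameter_map("MD", vals)), mask, meta)
  expect_equal(tab2$value[tab2$replicate == 1], 2.5)
  # NaN (unfit) voxels excluded from the mean; hand-computed on a 3x3 slice
  vals3 <- array(NA_real_, c(3, 3, 1))
  vals3[, , 1] <- matrix(c(1, NA, 3, NA, 5, NA, 7, NA, 9), 3, 3)
  lab3 <- array(1L, c(3, 3, 1))
  tab3 <- aggregate_roi(list(m = parameter_map("FA", vals3)),
                        roi_mask(lab3, c(AC = 1L)), meta)
  expect_equal(tab3$value, mean(c(1, 3, 5, 7, 9)))
  expect_equal(attr(tab3, "n_voxels"), 5L)
  # empty cross-section skipped with warning
  vals4 <- array(NA_real_, c(3, 3, 2)); vals4[1, 1, 1] <- 1
  expect_warning(
    t4 <- aggregate_roi(list(m = parameter_map("FA", vals4)), mask, meta),
    "empty ROI cross-section")
  expect_equal(nrow(t4), 1L)
  # misaligned grids are a hard error
  expect_error(aggregate_roi(list(m = parameter_map("FA", array(1, c(2, 2, 2)))),
                             mask, meta), "not aligned")
})

test_that("clearly separated groups give a vanishing p-value", {
  set.seed(41)
  d <- data.frame(animal_id = sprintf("a%02d", 1:12),
                  group = rep(c("control", "anhedonic", "resilient"), each = 4),
                  roi = "AC", replicate = 1, metric = "m")
  d$value <- c(0, 0, 5)[match(d$group, c("control", "anhedonic", "resilient"))] +
    rnorm(nrow(d), 0, 1e-6)
  r <- lmm_group_test(cohort_table(d), "m", "AC")
  expect_lt(r$p_value, 1e-10)
  expect_true(r$degraded)   # one observation per animal
})

test_that("balanced-design F and CIs agree with the animal-mean ANOVA closed form", {
  spec <- cohort_effect_spec(groups = c(control = 6L, anhedonic = 6L,
                                        resilient = 6L),
                             variance_inflation = 1, seed = 7)
  sim <- simulate_cohort(spec)
  r <- lmm_group_test(sim$table, "D_eff", "AC")
  d <- as.data.frame(sim$table)
  d <- d[d$metric == "D_eff" & d$roi == "AC", ]
  am <- aggregate(value ~ animal_id + group, data = d, FUN = mean)
  a <- anova(lm(value ~ group, data = am))
  expect_equal(r$f_stat, a["group", "F value"], tolerance = 1e-6)
  expect_equal(r$df_den, a["Residuals", "Df"], tolerance = 1e-6)
  expect_equal(r$p_value, a["group", "Pr(>F)"], tolerance = 1e-6)
  # group-mean CI = t-interval on animal means with the pooled MS
  mse <- a["Residuals", "Mean Sq"]
  half <- qt(0.975, a["Residuals", "Df"]) * sqrt(mse / 6)
  gm <- r$group_means[r$group_means$group == "control", ]
  expect_equal(gm$ci_high - gm$ci_low, 2 * half, tolerance = 1e-6)
  expect_equal(gm$estimate, mean(am$value[am$group == "control"]),
               tolerance = 1e-9)
})

test_that("degenerate designs degrade to fixed-effects ANOVA with a flag", {
  # one observation per animal
  spec <- cohort_effect_spec(n_replicates = 1, seed = 8)
  r1 <- lmm_group_test(simulate_cohort(spec)$table, "D_eff", "AC")
  expect_true(r1$degraded)
  expect_true(is.finite(r1$p_value))
  # zero between-animal variance: singular random effect.  Values are
  # centred per animal so the animal-mean variance is exactly zero and the
  # REML estimate sits on the boundary.
  set.seed(9)
  d2 <- expand.grid(animal_id = sprintf("b%02d", 1:9), replicate = 1:4)
  d2$group <- rep(c("control", "anhedonic", "resilient"), each = 3)[
    match(d2$animal_id, sprintf("b%02d", 1:9))]
  d2$roi <- "AC"; d2$metric <- "m"
  d2$value <- rnorm(nrow(d2))
  d2$value <- d2$value - ave(d2$value, d2$animal_id) +
    c(0, 0.2, 0.4)[match(d2$group, c("control", "anhedonic", "resilient"))]
  r2 <- lmm_group_test(cohort_table(d2), "m", "AC")
  expect_true(r2$degraded)
  expect_true(is.finite(r2$p_value))
  # preconditions
  tab <- simulate_cohort(cohort_effect_spec(seed = 1))$table
  expect_error(lmm_group_test(tab[tab$group == "control", ], "D_eff", "AC"),
               ">= 2 groups")
})

test_that("BH adjustment reproduces the step-up closed form and gatekeeping holds", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(p.adjust(c(0.001, 0.9, 0.95), "BH"), c(0.003, 0.95, 0.95))
  # significant overall test: pairwise present, monotone, bounded
  spec <- cohort_effect_spec(seed = 12)
  r <- posthoc_pairwise(lmm_group_test(simulate_cohort(spec)$table,
                                       "D_eff", "AC"))
  expect_false(is.null(r$pairwise))
  pw <- r$pairwise
  expect_true(all(pw$p_fdr >= pw$p_raw - 1e-12))
  expect_true(all(pw$p_fdr <= 1))
  expect_equal(order(pw$p_fdr), order(pw$p_raw))
  expect_equal(pw$p_fdr, p.adjust(pw$p_raw, "BH"))
  expect_true(all(pw$ci_low <= pw$estimate & pw$estimate <= pw$ci_high))
  # non-significant overall test: unchanged, with a note
  r0 <- posthoc_pairwise(lmm_group_test(simulate_cohort(spec)$table,
                                        "D_eff", "VC"))
  expect_null(r0$pairwise)
  expect_match(r0$note, "skipped")
})

test_that("power under the planted AC effect is monotone in cohort size", {
  eff <- data.frame(metric = "D_eff", roi = "AC",
                    group = c("control", "anhedonic", "resilient"),
                    mean = c(0.60, 0.54, 0.54),   # moderate effect
                    between_sd = 0.05, within_sd = 0.05)
  pow <- function(groups, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_cohort(cohort_effect_spec(eff, groups = groups, seed = s))
      lmm_group_test(sim$table, "D_eff", "AC", means = FALSE)$p_value < 0.05
    }, logical(1)))
  }
  seeds <- 300 + 1:60
  p_big <- pow(c(control = 8L, anhedonic = 7L, resilient = 8L), seeds)
  p_small <- pow(c(control = 3L, anhedonic = 3L, resilient = 3L), seeds)
  expect_gt(p_big, p_small)
})
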