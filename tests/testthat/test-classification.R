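test_that("classification follows the four-class plane rules", {
  expect_equal(classify(0.03, 0.01, 0.01, 0.2), "BMIonly+")
  expect_equal(classify(0.03, 0.01, 0.05, 0.03), "BMI+WHR+")  # supra-expected
  expect_equal(classify(0.03, 0.01, -0.02, 0.03), "BMI+WHR-")
  expect_equal(classify(0.01, 0.3, -0.02, 0.001), "WHRonly-")
  expect_equal(classify(0.01, 0.5, 0.01, 0.5), "unclassified")
  # vectorized, exactly one label each
  set.seed(4)
  lab <- classify(rnorm(500), runif(500), rnorm(500), runif(500))
  expect_true(all(lab %in% c("BMI+WHR+", "BMIonly+", "WHRonly-", "BMI+WHR-",
                             "unclassified")))
  expect_length(lab, 500)
  # degenerate zero beta carries no direction
  expect_equal(classify(0, 0.01, 0.05, 0.01), "WHRonly-")
})

test_that("classification is invariant to effect-allele relabeling", {
  set.seed(5)
  b_bmi <- rnorm(200, 0, 0.05); b_whr <- rnorm(200, 0, 0.05)
  p_bmi <- runif(200); p_whr <- runif(200)
  expect_equal(classify(-b_bmi, p_bmi, -b_whr, p_whr),
               classify(b_bmi, p_bmi, b_whr, p_whr))
})

test_that("allele alignment makes classes hip-increasing by convention", {
  wide <- data.table(
    variant_id = paste0("rs", 1:4),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta_BMI = c(-0.05, 0.04, 0.001, -0.03),
    se_BMI = 0.005, p_BMI = c(1e-5, 1e-5, 0.8, 1e-5),
    beta_WHR = c(-0.04, 0.001, -0.03, 0.03),
    se_WHR = 0.005, p_WHR = c(1e-5, 0.8, 1e-5, 1e-5))
  out <- classify_variants(wide, alpha = 0.05, r = 0.5)
  expect_equal(out$class_label,
               c("BMI+WHR+", "BMIonly+", "WHRonly-", "BMI+WHR-"))
  # BMI-led classes align to the BMI-increasing allele
  expect_true(all(out[class_label != "WHRonly-", beta_BMI] > 0))
  # WHRonly- aligns to the WHR-decreasing allele
  expect_true(all(out[class_label == "WHRonly-", beta_WHR] < 0))
  # a flip negates betas, swaps alleles, complements eaf
  expect_equal(out$align_sign, c(-1, 1, 1, -1))
  expect_equal(out$effect_allele, c("G", "A", "A", "G"))
  expect_equal(out$eaf, c(0.7, 0.3, 0.3, 0.7))
  # already-aligned WHRonly- rows are untouched
  expect_equal(out[3, beta_WHR], -0.03)
})

test_that("stricter thresholds move borderline variants between classes", {
  wide <- data.table(variant_id = c("move", "stay"),
                     beta_BMI = c(0.02, 0.05), se_BMI = 0.005,
                     p_BMI = c(0.01, 1e-20),
                     beta_WHR = c(-0.04, -0.05), se_WHR = 0.005,
                     p_WHR = c(1e-5, 1e-20))
  res <- reclassify_sensitivity(wide, alpha = 0.05, alpha_strict = 3e-4)
  tr <- res$transitions
  expect_equal(tr[variant_id == "move", class_old], "BMI+WHR-")
  expect_equal(tr[variant_id == "move", class_new], "WHRonly-")
  expect_equal(tr[variant_id == "stay", class_new], "BMI+WHR-")
  expect_equal(res$n_retained, 1L)
  expect_equal(res$n_changed, 1L)
  # nothing moves when all p-values are far below the strict threshold
  allstrong <- data.table(variant_id = "x", beta_BMI = 0.05, se_BMI = 0.005,
                          p_BMI = 1e-30, beta_WHR = 0.05, se_WHR = 0.005,
                          p_WHR = 1e-30)
  expect_equal(reclassify_sensitivity(allstrong, 0.05, 3e-4)$n_changed, 0L)
})

test_that("planted classes are retained under the strict threshold at large n", {
  spec <- architecture_spec(effect_mode = "calibrated", z_bmi = 20,
                            z_whr = 20, n_individuals = 3e5, seed = 23)
  ss <- sumstats_direct(spec)
  w <- sumstats_wide(ss, traits = c("BMI", "WHR"))
  res <- reclassify_sensitivity(w, alpha = 0.05, alpha_strict = 0.05 / 159)
  truth <- attr(ss, "truth")
  map <- c(concordant = "BMI+WHR+", bmi_only = "BMIonly+",
           whr_only = "WHRonly-", discordant = "BMI+WHR-")
  tr <- merge(res$transitions, truth[, .(variant_id, true_class)],
              by = "variant_id")
  # every variant whose nominal label matches its planted class keeps it:
  # all non-null z-scores are ~20 (concordant WHR ~ r*20), far beyond 3e-4
  consistent <- tr[class_old == map[true_class]]
  expect_equal(consistent[, mean(class_new == class_old)], 1)
  # the only moves come from nominal false positives on a null trait
  # (probability ~0.05 per single-trait variant), so retention stays high
  expect_gte(res$n_retained / nrow(w), 0.95)
})

test_that("the sex-difference z-test matches the normal-tail oracle", {
  eq <- sexdiff_test(0.05, 0.01, 0.05, 0.01)
  expect_equal(eq$z_diff, 0); expect_equal(eq$p_sexdiff, 1)
  r <- sexdiff_test(0.05, 0.01, 0, 0.01, rho = 0)
  expect_equal(r$z_diff, 3.535534, tolerance = 1e-6)
  expect_equal(r$p_sexdiff, 0.000406952, tolerance = 1e-6)
  # correlated estimates shrink the difference SE
  rc <- sexdiff_test(0.05, 0.01, 0, 0.01, rho = 0.5)
  expect_gt(rc$z_diff, r$z_diff)
  expect_error(sexdiff_test(NA, 0.01, 0, 0.01), "non-finite")
})

test_that("planted women-specific effects are detected at the corrected level", {
  # women-specific WHR effects; men null. 53-variant lookup, 0.05/53.
  spec <- architecture_spec(
    n_variants_per_class = c(concordant = 0, bmi_only = 0, whr_only = 53,
                             discordant = 0),
    effect_size_whr = 0.06, sex_scale_whr = c(women = 2, men = 0),
    n_individuals = 30000, seed = 29)
  ss <- cohort_to_sumstats(simulate_cohort(spec), traits = "WHR",
                          strata = c("women", "men"))
  ww <- sumstats_wide(ss, traits = "WHR", stratum = "women")
  wm <- sumstats_wide(ss, traits = "WHR", stratum = "men")
  sd <- sexdiff_test(ww$beta_WHR, ww$se_WHR, wm$beta_WHR, wm$se_WHR)
  # per-variant non-centrality ~ -0.12 * sqrt(2 f (1-f) 15000) / sqrt(2);
  # power at 0.05/53 is high but not 1 -- require a clear majority flagged
  expect_gt(mean(sd$p_sexdiff < 0.05 / 53), 0.8)
  expect_lt(median(sd$z_diff), 0)   # women-specific WHR decrease
})
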