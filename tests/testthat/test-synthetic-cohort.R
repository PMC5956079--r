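small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_variants_per_class = c(concordant = 5, bmi_only = 5,
                                            whr_only = 5, discordant = 5),
                   n_individuals = 4000, seed = 101)
  do.call(architecture_spec, utils::modifyList(defaults, args))
}

test_that("direct-path standard errors follow 1/sqrt(2 f (1-f) N)", {
  spec <- small_spec(maf_range = c(0.5, 0.5), n_individuals = 10000,
                     effect_size_bmi = 0, effect_size_whr = 0)
  ss <- sumstats_direct(spec)
  expect_equal(unique(ss$se), 1 / sqrt(5000), tolerance = 1e-12)
  expect_equal(1 / sqrt(5000), 0.01414214, tolerance = 1e-6)
})

test_that("null genetics reproduce the target phenotype correlation", {
  spec <- small_spec(effect_size_bmi = 0, effect_size_whr = 0,
                     r_target = 0.5, r_women = 0.5, r_men = 0.5,
                     n_individuals = 40000, seed = 7)
  co <- simulate_cohort(spec)
  r_hat <- cor(co$phenotypes$bmi, co$phenotypes$whr)
  expect_equal(r_hat, 0.5, tolerance = 3 / sqrt(40000) / (1 - 0.5^2)^-1)
  expect_lt(abs(r_hat - 0.5), 0.02)
})

test_that("an unreachable correlation target is a parameter error", {
  # bmi_only variants contribute no genetic covariance, so a strongly
  # negative phenotype correlation needs an infeasible noise correlation
  spec <- small_spec(n_variants_per_class = c(concordant = 0, bmi_only = 200,
                                              whr_only = 0, discordant = 0),
                     effect_size_bmi = 0.08, r_target = -0.97,
                     r_women = -0.97, r_men = -0.97)
  expect_error(simulate_cohort(spec), "parameter error")
})

test_that("null direct-path estimates are calibrated and error-correlated", {
  spec <- architecture_spec(
    n_variants_per_class = c(concordant = 0, bmi_only = 0, whr_only = 20000,
                             discordant = 0),
    effect_size_whr = 0, effect_size_bmi = 0, r_target = 0.44,
    n_individuals = 50000, seed = 5)
  ss <- sumstats_direct(spec)
  bmi <- ss[trait == "BMI"]; whr <- ss[trait == "WHR"]
  expect_lt(abs(mean(bmi$p < 0.05) - 0.05), 0.006)
  expect_equal(cor(bmi$beta, whr$beta), 0.44, tolerance = 0.02)
})

test_that("association z matches the closed-form non-centrality", {
  # per-allele effect 0.05, maf 0.3, N = 50,000 -> E[z] ~ 7.25
  spec <- architecture_spec(
    n_variants_per_class = c(concordant = 0, bmi_only = 400, whr_only = 0,
                             discordant = 0),
    effect_size_bmi = 0.05, maf_range = c(0.3, 0.3),
    n_individuals = 50000, seed = 9)
  ss <- sumstats_direct(spec)
  z <- ss[trait == "BMI", beta / se]
  expect_equal(0.05 * sqrt(2 * 0.3 * 0.7 * 50000), 7.245688,
               tolerance = 1e-6)
  expect_equal(mean(z), 7.2457, tolerance = 3 / sqrt(400) + 0.01)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- small_spec(seed = 33)
  expect_equal(sumstats_direct(spec), sumstats_direct(spec),
               ignore_attr = TRUE)
  c1 <- simulate_cohort(spec); c2 <- simulate_cohort(spec)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
  s1 <- cohort_to_sumstats(c1, traits = "BMI", strata = "combined")
  s2 <- cohort_to_sumstats(c2, traits = "BMI", strata = "combined")
  expect_identical(s1, s2)
})

test_that("cohort-derived summary statistics recover the planted effects", {
  spec <- small_spec(n_variants_per_class = c(concordant = 40, bmi_only = 40,
                                              whr_only = 40, discordant = 40),
                     n_individuals = 30000, effect_size_bmi = 0.04,
                     effect_size_whr = 0.04, seed = 21)
  co <- simulate_cohort(spec)
  ss <- cohort_to_sumstats(co, strata = "combined")
  w <- sumstats_wide(ss, traits = c("BMI", "WHR", "WHRadjBMI"))
  tr <- co$truth
  # mean beta over variants of a class is within 3 Monte-Carlo SEs of truth
  for (cl in unique(tr$true_class)) {
    idx <- which(tr$true_class == cl)
    mc_se <- sqrt(mean(w$se_BMI[idx]^2) / length(idx))
    expect_lt(abs(mean(w$beta_BMI[idx] - tr$true_beta_bmi[idx])), 3 * mc_se)
    mc_se_w <- sqrt(mean(w$se_WHR[idx]^2) / length(idx))
    expect_lt(abs(mean(w$beta_WHR[idx] - tr$true_beta_whr[idx])), 3 * mc_se_w)
  }
  # adjusted, unadjusted and covariate effects obey the linear relation
  r <- cor(co$phenotypes$bmi, co$phenotypes$whr)
  gap <- abs(w$beta_WHRadjBMI - (w$beta_WHR - r * w$beta_BMI))
  expect_true(all(gap < 2 * w$se_WHRadjBMI))
})

test_that("null disease gives calibrated association and monomorphics are flagged", {
  spec <- small_spec(n_variants_per_class = c(concordant = 0, bmi_only = 200,
                                              whr_only = 0, discordant = 0),
                     causal_disease_beta = 0, effect_size_bmi = 0,
                     n_individuals = 3000, seed = 13)
  co <- simulate_cohort(spec)
  ss <- cohort_to_sumstats(co, traits = "disease", strata = "combined")
  z <- ss[trait == "disease", beta / se]
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(200))
  expect_equal(stats::var(z), 1, tolerance = 0.25)

  co$genotypes[, 1] <- 0L
  ss <- suppressMessages(
    cohort_to_sumstats(co, traits = "BMI", strata = "combined"))
  expect_true(is.na(ss$beta[1]))
  expect_true(all(!is.na(ss$beta[-1])))
})

test_that("direct and cohort generation paths agree in distribution", {
  # matched null specs; two-sample KS on association z-scores
  base <- list(n_variants_per_class = c(concordant = 0, bmi_only = 10000,
                                        whr_only = 0, discordant = 0),
               effect_size_bmi = 0, effect_size_whr = 0,
               n_individuals = 12000)
  direct <- sumstats_direct(do.call(architecture_spec,
                                    c(base, list(seed = 61))))
  co <- simulate_cohort(do.call(architecture_spec, c(base, list(seed = 62))))
  cs <- cohort_to_sumstats(co, traits = "BMI", strata = "combined")
  ks <- suppressWarnings(stats::ks.test(direct[trait == "BMI", beta / se],
                                        cs[, beta / se]))
  expect_gt(ks$p.value, 0.001)
})
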