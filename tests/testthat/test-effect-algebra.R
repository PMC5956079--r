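test_that("adjusted/unadjusted conversion follows the linear relation", {
  # r = 0 leaves the unadjusted effect untouched
  expect_equal(adjusted_from_unadjusted(0.04, 0.01, 0.02, 0.01, 0)$beta, 0.04)
  # direct substitutions
  expect_equal(adjusted_from_unadjusted(0.04, 0.01, 0.02, 0.01, 0.5)$beta,
               0.03)
  expect_equal(unadjusted_from_adjusted(-0.01, 0.01, 0.02, 0.01, 0.5)$beta, 0)
  # SE propagation and p recomputation
  out <- adjusted_from_unadjusted(0.04, 0.003, 0.02, 0.004, 0.5)
  expect_equal(out$se, sqrt(0.003^2 + 0.25 * 0.004^2))
  expect_equal(out$p, 2 * pnorm(-out$beta / out$se))
})

test_that("the conversion round trip is exact at fixed r", {
  set.seed(1)
  b_whr <- rnorm(50, 0, 0.05); se_whr <- runif(50, 0.002, 0.01)
  b_bmi <- rnorm(50, 0, 0.05); se_bmi <- runif(50, 0.002, 0.01)
  for (r in c(-0.6, 0, 0.44, 0.5)) {
    adj <- adjusted_from_unadjusted(b_whr, se_whr, b_bmi, se_bmi, r)
    # the adjusted-scale SE is not the forward input SE; invert the algebra
    back <- unadjusted_from_adjusted(adj$beta, adj$se, b_bmi, se_bmi, r)
    expect_equal(back$beta, b_whr, tolerance = 1e-14)
  }
})

test_that("conversion contracts are enforced", {
  expect_error(adjusted_from_unadjusted(0.1, 0.01, 0.1, 0.01, 1), "\\|r\\|")
  expect_error(adjusted_from_unadjusted(0.1, -0.01, 0.1, 0.01, 0.4),
               "positive")
  expect_error(adjusted_from_unadjusted(0.1, 0.01, 0.1, 0.01, 0.4,
                                        stratum_a = "women",
                                        stratum_b = "men"), "stratum")
})

test_that("propagated SE grows with |r| and the covariate SE", {
  se <- sapply(c(0, 0.2, 0.44, 0.6, -0.7),
               function(r) adjusted_from_unadjusted(0.1, 0.01, 0.1,
                                                    0.02, r)$se)
  expect_true(all(diff(se[1:4]) > 0))
  expect_gt(se[5], se[4])     # depends on |r|, not its sign
  se_b <- sapply(c(0.005, 0.01, 0.02),
                 function(s) unadjusted_from_adjusted(0.1, 0.01, 0.1,
                                                      s, 0.5)$se)
  expect_true(all(diff(se_b) > 0))
})

test_that("beta_from_z inverts the z/standardized-effect relation", {
  expect_equal(beta_from_z(0, 1e4, 0.3)$beta, 0)
  out <- beta_from_z(5, 1e4, 0.5)
  expect_equal(out$beta, 0.07071068, tolerance = 1e-7)
  expect_equal(out$beta / out$se, 5, tolerance = 1e-12)
  expect_error(beta_from_z(1, 1e4, 0), "domain")
  expect_error(beta_from_z(1, 0, 0.3), "positive")
})

test_that("IVW meta-analysis combines estimates by inverse variance", {
  one <- ivw_meta(0.04, 0.01, n = 1000)
  expect_equal(one$beta, 0.04); expect_equal(one$se, 0.01)
  expect_equal(one$n, 1000)
  two <- ivw_meta(c(0.04, 0.04), c(0.01, 0.01), n = c(1000, 2000))
  expect_equal(two$beta, 0.04)
  expect_equal(two$se, 0.01 / sqrt(2))
  expect_equal(two$n, 3000)
  expect_error(ivw_meta(numeric(0), numeric(0)), "empty")
  # permutation invariance and associativity over grouping
  set.seed(2)
  b <- rnorm(6); s <- runif(6, 0.5, 2)
  full <- ivw_meta(b, s)
  perm <- ivw_meta(b[c(3, 1, 6, 2, 5, 4)], s[c(3, 1, 6, 2, 5, 4)])
  expect_equal(perm$beta, full$beta); expect_equal(perm$se, full$se)
  g1 <- ivw_meta(b[1:3], s[1:3]); g2 <- ivw_meta(b[4:6], s[4:6])
  nested <- ivw_meta(c(g1$beta, g2$beta), c(g1$se, g2$se))
  expect_equal(nested$beta, full$beta, tolerance = 1e-12)
  expect_equal(nested$se, full$se, tolerance = 1e-12)
})

test_that("meta of sex strata matches the combined-stratum estimate", {
  spec <- architecture_spec(n_variants_per_class = c(concordant = 30,
                                                     bmi_only = 30,
                                                     whr_only = 30,
                                                     discordant = 30),
                            n_individuals = 20000, seed = 17)
  ss <- cohort_to_sumstats(simulate_cohort(spec), traits = "BMI")
  w <- sumstats_wide(ss, traits = "BMI", stratum = "combined")
  ww <- sumstats_wide(ss, traits = "BMI", stratum = "women")
  wm <- sumstats_wide(ss, traits = "BMI", stratum = "men")
  meta <- mapply(function(b1, s1, b2, s2)
    ivw_meta(c(b1, b2), c(s1, s2))$beta,
    ww$beta_BMI, ww$se_BMI, wm$beta_BMI, wm$se_BMI)
  se_meta <- sqrt(1 / (1 / ww$se_BMI^2 + 1 / wm$se_BMI^2))
  expect_true(all(abs(meta - w$beta_BMI) < 2 * se_meta))
})

test_that("compare_effects reports rank agreement", {
  x <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(compare_effects(x, x)$rank_correlation, 1)
  expect_equal(compare_effects(x, rev(x))$rank_correlation, -1)
  expect_equal(compare_effects(x, x, c(1, 1, 1, 1),
                               c(2, 2, 2, 2))$mean_se_ratio, 0.5)
  expect_error(compare_effects(x, x[1:3]), "matched")
})

test_that("converted null effects have uniform p-values", {
  spec <- architecture_spec(
    n_variants_per_class = c(concordant = 0, bmi_only = 10000, whr_only = 0,
                             discordant = 0),
    effect_size_bmi = 0, effect_size_whr = 0, n_individuals = 50000,
    seed = 19)
  ss <- sumstats_direct(spec)
  w <- sumstats_wide(ss, traits = c("BMI", "WHRadjBMI"))
  conv <- unadjusted_from_adjusted(w$beta_WHRadjBMI, w$se_WHRadjBMI,
                                   w$beta_BMI, w$se_BMI, 0.44)
  ks <- suppressWarnings(stats::ks.test(conv$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})
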