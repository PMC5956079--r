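#' Classify variants by their co-association with BMI and WHR
#'
#' Assigns each variant a class from its position on the b_WHR vs b_BMI
#' effect plane, calling an effect non-null when it is nominally significant
#' at `alpha`:
#' \describe{
#'   \item{`BMI+WHR+`}{both effects significant, same direction (including
#'     WHR effects larger than expected from the BMI effect).}
#'   \item{`BMIonly+`}{only the BMI effect significant.}
#'   \item{`WHRonly-`}{only the WHR effect significant.}
#'   \item{`BMI+WHR-`}{both significant, opposite directions.}
#'   \item{`unclassified`}{neither effect significant.}
#' }
#' A degenerate exactly-zero beta with a significant p-value carries no
#' direction and is treated as non-significant for that trait.
#' Classification is invariant to relabeling the effect allele (flipping
#' the allele negates both betas and preserves the class).
#'
#' @param b_bmi,p_bmi BMI effect and p-value (vectorized).
#' @param b_whr,p_whr WHR effect and p-value.
#' @param alpha Nominal significance threshold (default 0.05).
#' @return Character vector of class labels.
#' @export
classify <- function(b_bmi, p_bmi, b_whr, p_whr, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig_bmi <- is.finite(p_bmi) & p_bmi < alpha & is.finite(b_bmi) & b_bmi != 0
  sig_whr <- is.finite(p_whr) & p_whr < alpha & is.finite(b_whr) & b_whr != 0
  same_dir <- sign(b_bmi) == sign(b_whr)
  out <- rep("unclassified", length(b_bmi))
  out[sig_bmi & !sig_whr] <- "BMIonly+"
  out[!sig_bmi & sig_whr] <- "WHRonly-"
  out[sig_bmi & sig_whr & same_dir] <- "BMI+WHR+"
  out[sig_bmi & sig_whr & !same_dir] <- "BMI+WHR-"
  out
}

#' Classify a merged variant table and align alleles by class
#'
#' Takes a wide per-variant table with BMI and WHR effect columns
#' (`beta_BMI, se_BMI, p_BMI, beta_WHR, se_WHR, p_WHR`), classifies every
#' variant via [classify()], and applies the class-specific allele alignment
#' of [align_alleles_by_class()].  A `supra_expected` indicator is emitted
#' as metadata: the observed WHR effect exceeds the expected `r * b_BMI` in
#' the BMI direction by more than 1.96 propagated SEs.
#'
#' @param wide Wide per-variant `data.table` (see above; extra columns pass
#'   through, and any further `beta_*` columns are sign-aligned too).
#' @param alpha Nominal threshold.
#' @param r Phenotype correlation for the supra-expected indicator.
#' @return The table with `class_label`, `align_sign`, `aligned_allele`,
#'   `supra_expected` columns added and beta columns aligned.
#' @export
classify_variants <- function(wide, alpha = 0.05, r = 0.44) {
  out <- data.table::copy(data.table::as.data.table(wide))
  out[, class_label := classify(beta_BMI, p_BMI, beta_WHR, p_WHR, alpha)]
  excess <- out$beta_WHR - r * out$beta_BMI
  se_excess <- sqrt(out$se_WHR^2 + r^2 * out$se_BMI^2)
  out[, supra_expected := class_label == "BMI+WHR+" &
        sign(beta_WHR) == sign(beta_BMI) &
        abs(beta_WHR) > abs(r * beta_BMI) &
        abs(excess) / se_excess > qnorm(0.975)]
  align_alleles_by_class(out)
}

#' Align effect alleles by class convention
#'
#' Re-signs each variant's effects so that the reported allele is the
#' BMI-increasing allele for classes with a BMI effect (`BMI+WHR+`,
#' `BMIonly+`, `BMI+WHR-`) and the WHR-decreasing allele for `WHRonly-`
#' (consistent with `BMI+WHR-`, so all four classes are aligned for
#' hip-increasing alleles).  Every `beta_*` column is negated together,
#' effect/other alleles are swapped and `eaf_*` columns complemented for
#' flipped variants, and the flip is recorded in `align_sign` so that
#' later-merged lookup effects can be aligned consistently.
#'
#' @param classified A table with `class_label` plus `beta_*` (and
#'   optionally `eaf_*`, `effect_allele`, `other_allele`) columns.
#' @return The aligned table with `align_sign` and `aligned_allele` columns.
#' @export
align_alleles_by_class <- function(classified) {
  out <- data.table::copy(data.table::as.data.table(classified))
  flip <- rep(FALSE, nrow(out))
  bmi_led <- out$class_label %in% c("BMI+WHR+", "BMIonly+", "BMI+WHR-")
  flip[bmi_led] <- out$beta_BMI[bmi_led] < 0
  wo <- out$class_label == "WHRonly-"
  flip[wo] <- out$beta_WHR[wo] > 0
  sgn <- ifelse(flip, -1, 1)
  if ("align_sign" %in% names(out)) sgn <- sgn * out$align_sign
  for (cl in grep("^beta_", names(out), value = TRUE))
    data.table::set(out, j = cl, value = out[[cl]] * sgn)
  for (cl in grep("^eaf", names(out), value = TRUE))
    data.table::set(out, j = cl,
                    value = ifelse(sgn < 0, 1 - out[[cl]], out[[cl]]))
  if (all(c("effect_allele", "other_allele") %in% names(out))) {
    ea <- out$effect_allele
    out[sgn < 0, effect_allele := other_allele]
    out[sgn < 0, other_allele := ea[sgn < 0]]
  }
  out[, align_sign := sgn]
  out[, aligned_allele := if ("effect_allele" %in% names(out))
    effect_allele else NA_character_]
  out[]
}

#' Re-classify at a stricter threshold and tabulate transitions
#'
#' Sensitivity analysis of the nominal classification: classes are
#' re-derived at `alpha_strict` (e.g. the Bonferroni level 0.05 / number of
#' signals) and each variant's old-to-new transition is reported.
#'
#' @param wide Wide per-variant table as for [classify_variants()].
#' @param alpha Default nominal threshold.
#' @param alpha_strict Stricter threshold, `< alpha`.
#' @return List with `transitions` (per-variant old/new labels) and
#'   `summary` (counts by old/new pair, plus retained/changed totals as
#'   attributes on the list: `n_retained`, `n_changed`).
#' @export
reclassify_sensitivity <- function(wide, alpha = 0.05, alpha_strict) {
  stopifnot(alpha_strict < alpha)
  old <- classify(wide$beta_BMI, wide$p_BMI, wide$beta_WHR, wide$p_WHR, alpha)
  new <- classify(wide$beta_BMI, wide$p_BMI, wide$beta_WHR, wide$p_WHR,
                  alpha_strict)
  transitions <- data.table::data.table(
    variant_id = if ("variant_id" %in% names(wide)) wide$variant_id
                 else seq_along(old),
    class_old = old, class_new = new)
  summary <- transitions[, .N, by = .(class_old, class_new)]
  list(transitions = transitions, summary = summary,
       n_retained = sum(old == new), n_changed = sum(old != new))
}

#' Test for a sex difference in genetic effect
#'
#' Compares women- and men-specific estimates of the same variant and trait:
#' `z = (b_w - b_m) / sqrt(se_w^2 + se_m^2 - 2 rho se_w se_m)` with `rho`
#' the between-sex estimate correlation (0 for non-overlapping samples,
#' configurable for consortia that used a correlation-adjusted difference
#' test), and a two-sided normal p-value.
#'
#' @param beta_women,se_women Women-specific estimate (vectorized).
#' @param beta_men,se_men Men-specific estimate.
#' @param rho Between-sex estimate correlation (default 0).
#' @return `data.table` with `z_diff, p_sexdiff`.
#' @export
sexdiff_test <- function(beta_women, se_women, beta_men, se_men, rho = 0) {
  if (any(!is.finite(c(beta_women, se_women, beta_men, se_men, rho))))
    stop("contract error: non-finite inputs to the sex-difference test")
  stopifnot(all(se_women > 0), all(se_men > 0), abs(rho) < 1)
  se_d <- sqrt(se_women^2 + se_men^2 - 2 * rho * se_women * se_men)
  z <- (beta_women - beta_men) / se_d
  data.table::data.table(z_diff = z, p_sexdiff = p_from_z(z))
}
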