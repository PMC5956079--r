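#' Inverse-variance-weighted Mendelian randomization
#'
#' First-order IVW estimator of the causal effect of the exposure on the
#' outcome from per-variant summary statistics:
#' `slope = sum(bx * by / sey^2) / sum(bx^2 / sey^2)`,
#' `se = 1 / sqrt(sum(bx^2 / sey^2))`, p from the two-sided normal tail.
#' This equals the zero-intercept weighted least-squares regression of the
#' outcome effects on the exposure effects with weights `1/sey^2` — the
#' meta-regression line through the per-class effect scatter, interpretable
#' as the association of a genetic risk score of exposure-increasing alleles
#' with the outcome.  `WHRonly-` variants have no effective instrument
#' strength for BMI and are refused.
#'
#' @param b_exposure Exposure (BMI) effects of the instruments.
#' @param b_outcome Outcome effects, same variants and allele alignment.
#' @param se_outcome Outcome standard errors.
#' @param class_label Optional class of the instrument set; `"WHRonly-"` is
#'   refused with an explanatory error.
#' @return One-row `data.table`: `slope, se_slope, p_grs, n_instruments,
#'   q_statistic` (Cochran's Q heterogeneity diagnostic).
#' @export
ivw_mr <- function(b_exposure, b_outcome, se_outcome, class_label = NULL) {
  if (!is.null(class_label) && any(class_label == "WHRonly-"))
    stop("WHRonly- variants are no effective instruments for BMI (no ",
         "exposure effect by construction); MR for this class is refused")
  keep <- is.finite(b_exposure) & is.finite(b_outcome) & is.finite(se_outcome)
  bx <- b_exposure[keep]; by <- b_outcome[keep]; sey <- se_outcome[keep]
  if (length(bx) < 1L) stop("contract error: no usable instruments")
  stopifnot(all(sey > 0))
  w <- 1 / sey^2
  denom <- sum(bx^2 * w)
  slope <- sum(bx * by * w) / denom
  se_slope <- 1 / sqrt(denom)
  q <- sum(w * (by - slope * bx)^2)
  data.table::data.table(slope = slope, se_slope = se_slope,
                         p_grs = p_from_z(slope / se_slope),
                         n_instruments = length(bx), q_statistic = q)
}

#' Class-restricted MR across outcomes
#'
#' Runs [ivw_mr()] for every eligible class x outcome pair, restricting the
#' instruments to the class's variants; `WHRonly-` is excluded.  Results are
#' flagged at the Bonferroni level `0.05 / n_tests` (default: eligible
#' classes x outcomes).
#'
#' @param classified Aligned classified variants with `variant_id`,
#'   `class_label`, `align_sign`, and aligned exposure effects in
#'   `beta_BMI`.
#' @param outcomes Long-format outcome effects: `variant_id, trait, beta,
#'   se` on the harmonized (pre-alignment) allele.
#' @param n_tests Bonferroni denominator; default eligible classes x
#'   outcome traits.
#' @param exclude Classes excluded as instrument sets.
#' @return `data.table` with one row per class x outcome.
#' @export
run_class_mr <- function(classified, outcomes, n_tests = NULL,
                         exclude = c("WHRonly-", "unclassified")) {
  classes <- setdiff(intersect(CLASS_LEVELS,
                               unique(classified$class_label)), exclude)
  traits <- sort(unique(outcomes$trait))
  if (is.null(n_tests)) n_tests <- length(classes) * length(traits)
  oc <- merge(outcomes,
              classified[, .(variant_id, class_label, align_sign, beta_BMI)],
              by = "variant_id")
  res <- lapply(classes, function(cl) {
    data.table::rbindlist(lapply(traits, function(tr) {
      sub <- oc[class_label == cl & trait == tr]
      r <- ivw_mr(sub$beta_BMI, sub$beta * sub$align_sign, sub$se)
      cbind(data.table::data.table(class_label = cl, outcome = tr), r)
    }))
  })
  out <- data.table::rbindlist(res)
  out[, significant_flag := p_grs < 0.05 / n_tests]
  data.table::setattr(out, "n_tests", n_tests)
  out[]
}

#' Joint allele-score relative risk of a class
#'
#' Exponentiated sum of the aligned per-allele log-odds over the class's
#' variants with an available outcome estimate: the relative risk of
#' carrying one aligned risk allele at every variant of the class, relative
#' to none.  The summary assumes log-additive, independent per-allele
#' effects; it is additive over disjoint variant subsets on the log scale.
#'
#' @param log_or Aligned per-allele log-odds ratios of the class's variants
#'   (NA entries, i.e. missing lookups, are dropped).
#' @return List with `joint_log_or`, `joint_rr`, `n_variants`.
#' @export
joint_risk <- function(log_or) {
  keep <- is.finite(log_or)
  if (!any(keep)) stop("contract error: no available outcome effects")
  s <- sum(log_or[keep])
  list(joint_log_or = s, joint_rr = exp(s), n_variants = sum(keep))
}
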