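#' Convert an unadjusted WHR effect to the BMI-adjusted scale
#'
#' The genetic effect on the covariate-adjusted trait relates to the
#' unadjusted effects through the phenotype correlation `r`:
#' `b_adj = b_WHR - r * b_BMI`.  The standard error is propagated as
#' `se_adj^2 = se_WHR^2 + r^2 * se_BMI^2`, treating the two estimates'
#' sampling errors as independent (the covariance between the adjusted-trait
#' and covariate estimates is approximately zero by construction of the
#' adjustment); the p-value is recomputed from the two-sided normal tail of
#' `beta/se` and any input p-value is discarded.
#'
#' All arguments are vectorized over variants.
#'
#' @param beta_whr,se_whr Unadjusted-trait effect and SE.
#' @param beta_bmi,se_bmi Covariate-trait effect and SE.
#' @param r Phenotype correlation, `|r| < 1`; use the stratum-matched value
#'   when converting sex-specific effects.
#' @param stratum_a,stratum_b Optional stratum labels; a mismatch is a
#'   contract error.
#' @return `data.table` with columns `beta, se, p`.
#' @export
adjusted_from_unadjusted <- function(beta_whr, se_whr, beta_bmi, se_bmi, r,
                                     stratum_a = NULL, stratum_b = NULL) {
  check_conversion_args(se_whr, se_bmi, r, stratum_a, stratum_b)
  beta <- beta_whr - r * beta_bmi
  se <- sqrt(se_whr^2 + r^2 * se_bmi^2)
  data.table::data.table(beta = beta, se = se, p = p_from_z(beta / se))
}

#' Recover the unadjusted WHR effect from adjusted and BMI effects
#'
#' Inverse of [adjusted_from_unadjusted()]: `b_WHR = b_adj + r * b_BMI`,
#' with `se^2 = se_adj^2 + r^2 * se_BMI^2` and the p-value recomputed.
#' The round trip through both conversions restores the input effect
#' exactly at fixed `r`.
#'
#' @inheritParams adjusted_from_unadjusted
#' @param beta_adj,se_adj Adjusted-trait effect and SE.
#' @return `data.table` with columns `beta, se, p`.
#' @export
unadjusted_from_adjusted <- function(beta_adj, se_adj, beta_bmi, se_bmi, r,
                                     stratum_a = NULL, stratum_b = NULL) {
  check_conversion_args(se_adj, se_bmi, r, stratum_a, stratum_b)
  beta <- beta_adj + r * beta_bmi
  se <- sqrt(se_adj^2 + r^2 * se_bmi^2)
  data.table::data.table(beta = beta, se = se, p = p_from_z(beta / se))
}

check_conversion_args <- function(se_a, se_b, r, stratum_a, stratum_b) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("correlation r must be finite with |r| < 1")
  if (any(!is.finite(se_a)) || any(se_a <= 0) ||
      any(!is.finite(se_b)) || any(se_b <= 0))
    stop("standard errors must be finite and positive")
  if (!is.null(stratum_a) && !is.null(stratum_b) &&
      any(stratum_a != stratum_b))
    stop("contract error: stratum mismatch between the two estimates")
  invisible(TRUE)
}

#' Effect size from a reported z-score
#'
#' For a standardized outcome, `beta = z / sqrt(N * 2 * eaf * (1 - eaf))`,
#' with companion `se = 1 / sqrt(N * 2 * eaf * (1 - eaf))`, so that
#' `beta / se` reproduces `z` exactly.  Used for lookup consortia that
#' publish z-scores instead of betas.
#'
#' @param z z-score(s).
#' @param n Meta-analysis sample size(s), > 0.
#' @param eaf Effect-allele frequency(ies), strictly in (0, 1).
#' @return `data.table` with columns `beta, se`.
#' @export
beta_from_z <- function(z, n, eaf) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be positive")
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("domain error: eaf must lie strictly inside (0, 1)")
  denom <- sqrt(n * 2 * eaf * (1 - eaf))
  data.table::data.table(beta = z / denom, se = 1 / denom)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines estimates of the same quantity with weights `1/se^2`:
#' `beta = sum(b_i/se_i^2) / sum(1/se_i^2)`, `se = 1/sqrt(sum(1/se_i^2))`,
#' sample sizes summed, p-value from the two-sided normal tail.  Used to
#' meta-analyze sex-specific estimates into a sex-combined one.
#'
#' @param beta,se Vectors of estimates and standard errors (>= 1 element).
#' @param n Optional sample sizes (summed; NA if missing).
#' @return One-row `data.table` with `beta, se, p, n`.
#' @export
ivw_meta <- function(beta, se, n = NULL) {
  if (length(beta) < 1L) stop("contract error: empty estimate list")
  stopifnot(length(se) == length(beta), all(is.finite(se)), all(se > 0),
            all(is.finite(beta)))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  data.table::data.table(beta = b, se = s, p = p_from_z(b / s),
                         n = if (is.null(n)) NA_real_ else sum(n))
}

#' Compare computed with directly estimated effects
#'
#' Summarizes the agreement between a set of computed effects (e.g. WHR
#' effects reconstructed from WHRadjBMI and BMI) and matched direct
#' estimates: Spearman rank correlation of the betas and the mean ratio of
#' computed to observed standard errors.
#'
#' @param beta_computed,beta_observed Matched effect vectors.
#' @param se_computed,se_observed Optional matched SE vectors.
#' @return List with `n_variants`, `rank_correlation`, `mean_se_ratio`.
#' @export
compare_effects <- function(beta_computed, beta_observed,
                            se_computed = NULL, se_observed = NULL) {
  if (length(beta_computed) != length(beta_observed))
    stop("contract error: effect vectors must be matched in length")
  list(n_variants = length(beta_computed),
       rank_correlation = cor(beta_computed, beta_observed,
                              method = "spearman"),
       mean_se_ratio = if (is.null(se_computed) || is.null(se_observed))
         NA_real_ else mean(se_computed / se_observed))
}

#' Reconstruct WHR summary statistics from WHRadjBMI and BMI tables
#'
#' Table-level driver for [unadjusted_from_adjusted()]: merges the adjusted
#' and covariate tables by variant and stratum and applies the conversion
#' with the stratum-matched correlation from `r_spec`.  Used by the pipeline
#' when no WHR scan is available.
#'
#' @param adj_table,bmi_table Long-format summary statistics for the
#'   adjusted trait and for BMI (matching strata).
#' @param r_spec A [correlation_spec()].
#' @return Summary-statistics `data.table` with `trait = "WHR"`.
#' @export
convert_whr_from_adjusted <- function(adj_table, bmi_table, r_spec) {
  m <- merge(adj_table, bmi_table, by = c("variant_id", "stratum"),
             suffixes = c("_adj", "_bmi"))
  if (nrow(m) == 0L) stop("no overlapping (variant, stratum) records")
  m[, r := vapply(stratum, function(s) stratum_r(r_spec, s), 0)]
  conv <- unadjusted_from_adjusted(m$beta_adj, m$se_adj, m$beta_bmi,
                                   m$se_bmi, m$r)
  data.table::data.table(variant_id = m$variant_id, chrom = m$chrom_adj,
                         pos = m$pos_adj,
                         effect_allele = m$effect_allele_adj,
                         other_allele = m$other_allele_adj,
                         eaf = m$eaf_adj, beta = conv$beta, se = conv$se,
                         p = conv$p, n = pmin(m$n_adj, m$n_bmi),
                         trait = "WHR", stratum = m$stratum)
}
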