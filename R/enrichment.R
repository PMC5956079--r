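#' Count nominally significant directional lookup effects
#'
#' For a set of class-aligned variants and one lookup trait, counts the
#' variants with an available lookup estimate (`n_tested`) and among them
#' those with a nominally significant trait-increasing or trait-decreasing
#' effect on the aligned allele.  Variants without a lookup estimate reduce
#' `n_tested`; they are not counted as non-significant.
#'
#' @param beta Aligned lookup effects (NA when the lookup is missing).
#' @param p Lookup p-values.
#' @param alpha Nominal threshold (default 0.05).
#' @return List with `n_tested`, `n_increasing`, `n_decreasing`.
#' @export
count_directional <- function(beta, p, alpha = 0.05) {
  avail <- is.finite(beta) & is.finite(p)
  sig <- avail & p < alpha
  list(n_tested = sum(avail),
       n_increasing = sum(sig & beta > 0),
       n_decreasing = sum(sig & beta < 0))
}

#' Upper-tail binomial enrichment probability
#'
#' `P(X >= n_significant)` for `X ~ Binomial(n_tested, p_null)`, evaluated
#' in log space so that extreme tails (down past 1e-300 on the log10 scale)
#' remain finite and accurate.
#'
#' @param n_tested Number of variants tested.
#' @param n_significant Number with a directionally significant effect.
#' @param p_null Null per-variant probability of a significant directional
#'   effect; the nominal two-sided rate split by direction, `alpha/2`
#'   (default 0.025).
#' @param log10p Return log10 of the tail probability instead.
#' @return Tail probability (or its log10), vectorized.
#' @export
binomial_enrichment <- function(n_tested, n_significant, p_null = 0.025,
                                log10p = FALSE) {
  stopifnot(all(n_significant >= 0), all(n_significant <= n_tested),
            all(p_null > 0), all(p_null < 1))
  lp <- pbinom(n_significant - 1, n_tested, p_null, lower.tail = FALSE,
               log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Class-specific directional enrichment across lookup traits
#'
#' Runs the directional binomial test for every class x lookup trait x
#' direction: under the null, each aligned variant has probability
#' `alpha / 2` of a nominally significant effect in a given direction, so an
#' excess of significant trait-increasing (or -decreasing) effects within a
#' class marks a class-specific association pattern.  Results are flagged at
#' the Bonferroni level `0.05 / n_tests` (default: classes x traits x 2
#' directions).
#'
#' @param classified Aligned classified variants ([classify_variants()]
#'   output) with `variant_id`, `class_label`, `align_sign`.
#' @param lookups Long-format lookup effects: `variant_id, trait, beta, p`
#'   on the harmonized (pre-alignment) allele.
#' @param alpha Nominal threshold for a directional effect (default 0.05).
#' @param n_tests Bonferroni denominator; default `classes * traits * 2`.
#' @param classes Classes to test (default the four named classes).
#' @return `data.table`: one row per class x trait x direction with
#'   `n_tested, n_significant, p_binomial, log10_p, significant_flag`.
#' @export
run_enrichment <- function(classified, lookups, alpha = 0.05, n_tests = NULL,
                           classes = setdiff(CLASS_LEVELS, "unclassified")) {
  lk <- merge(lookups,
              classified[, .(variant_id, class_label, align_sign)],
              by = "variant_id")
  lk <- lk[class_label %in% classes]
  lk[, beta_aligned := beta * align_sign]
  traits <- sort(unique(lookups$trait))
  if (is.null(n_tests)) n_tests <- length(classes) * length(traits) * 2
  grid <- data.table::CJ(class_label = classes, trait = traits)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- lk[class_label == grid$class_label[i] & trait == grid$trait[i]]
    cnt <- count_directional(sub$beta_aligned, sub$p, alpha)
    data.table::data.table(
      class_label = grid$class_label[i], trait = grid$trait[i],
      direction = c("increasing", "decreasing"),
      n_tested = cnt$n_tested,
      n_significant = c(cnt$n_increasing, cnt$n_decreasing))
  })
  out <- data.table::rbindlist(res)
  out[, p_binomial := binomial_enrichment(n_tested, n_significant,
                                          p_null = alpha / 2)]
  out[, log10_p := binomial_enrichment(n_tested, n_significant,
                                       p_null = alpha / 2, log10p = TRUE)]
  out[, significant_flag := p_binomial < 0.05 / n_tests]
  data.table::setattr(out, "n_tests", n_tests)
  out[]
}
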