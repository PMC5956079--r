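#' Rank-based inverse-normal transform
#'
#' Blom-type transform used to standardize phenotypes before association:
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties averaged.  The resulting trait has
#' mean 0 and variance ~1, so genetic effects are in SD units per allele.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @export
inverse_normal <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

#' Architecture specification for the synthetic generator
#'
#' Defines a planted four-class effect architecture on the BMI/WHR plane:
#' \describe{
#'   \item{concordant}{BMI and WHR effects in the same direction, placed on
#'     the null line `b_WHR = r * b_BMI` (fat distribution changes exactly as
#'     expected given the BMI change, i.e. a null WHRadjBMI effect).}
#'   \item{bmi_only}{a BMI effect with a zero WHR effect.}
#'   \item{whr_only}{a WHR-decreasing effect with a zero BMI effect.}
#'   \item{discordant}{a BMI-increasing together with a WHR-decreasing
#'     effect.}
#' }
#' Effects are either constant per allele (`effect_mode = "per_allele"`,
#' `effect_size_*` in SD units) or calibrated to a constant association
#' z-score across minor-allele frequencies (`effect_mode = "calibrated"`,
#' `z_bmi`/`z_whr` non-centralities at `n_individuals`), the latter being the
#' usual equal-variance-explained convention for power-controlled simulation.
#'
#' @param n_variants_per_class Named counts for classes
#'   `concordant, bmi_only, whr_only, discordant`.
#' @param maf_range Minor-allele-frequency sampling interval within (0, 0.5].
#' @param effect_size_bmi,effect_size_whr Per-allele effects (SD units) in
#'   `per_allele` mode.
#' @param effect_mode `"per_allele"` or `"calibrated"`.
#' @param z_bmi,z_whr Target association z-scores in `calibrated` mode.
#' @param r_target Overall BMI-WHR phenotype correlation.
#' @param r_women,r_men Sex-specific phenotype correlations.
#' @param sex_scale_whr Length-2 named multiplier `c(women=, men=)` applied
#'   to true WHR effects per sex (sexual dimorphism; default none).
#' @param n_individuals Cohort size (also the GWAS N of the direct path).
#' @param causal_disease_beta Log-odds of disease per SD of BMI.
#' @param causal_disease_beta_whr Log-odds of disease per SD of WHR
#'   (default 0; a positive value makes WHR-decreasing alleles protective).
#' @param disease_intercept Logistic intercept (default -2, prevalence ~0.12).
#' @param n_satellites Number of LD satellite variants per planted variant in
#'   the direct path (equicorrelated block; 0 disables).
#' @param satellite_r2 Squared LD correlation of satellites with their lead.
#' @param seed Integer seed; all generation is reproducible given the spec.
#' @return A list of class `"architecture_spec"`.
#' @export
architecture_spec <- function(n_variants_per_class = c(concordant = 82,
                                                       bmi_only = 25,
                                                       whr_only = 28,
                                                       discordant = 24),
                              maf_range = c(0.1, 0.5),
                              effect_size_bmi = 0.05,
                              effect_size_whr = 0.05,
                              effect_mode = c("per_allele", "calibrated"),
                              z_bmi = 7.8, z_whr = 9,
                              r_target = 0.44,
                              r_women = 0.46, r_men = 0.60,
                              sex_scale_whr = c(women = 1, men = 1),
                              n_individuals = 50000,
                              causal_disease_beta = 0.5,
                              causal_disease_beta_whr = 0,
                              disease_intercept = -2,
                              n_satellites = 0, satellite_r2 = 0.8,
                              seed = 1) {
  effect_mode <- match.arg(effect_mode)
  stopifnot(length(n_variants_per_class) == 4, all(n_variants_per_class >= 0),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            abs(r_target) < 1, abs(r_women) < 1, abs(r_men) < 1,
            n_individuals > 0)
  names(n_variants_per_class) <- c("concordant", "bmi_only", "whr_only",
                                   "discordant")
  structure(list(n_variants_per_class = n_variants_per_class,
                 maf_range = maf_range,
                 effect_size_bmi = effect_size_bmi,
                 effect_size_whr = effect_size_whr,
                 effect_mode = effect_mode, z_bmi = z_bmi, z_whr = z_whr,
                 r_target = r_target, r_women = r_women, r_men = r_men,
                 sex_scale_whr = sex_scale_whr,
                 n_individuals = n_individuals,
                 causal_disease_beta = causal_disease_beta,
                 causal_disease_beta_whr = causal_disease_beta_whr,
                 disease_intercept = disease_intercept,
                 n_satellites = n_satellites, satellite_r2 = satellite_r2,
                 seed = seed),
            class = "architecture_spec")
}

# True per-variant effects and a genome map for a spec (m variants spread
# over the autosomes, 10 Mb apart, so planted loci are well separated).
plant_truth <- function(spec) {
  cls <- rep(names(spec$n_variants_per_class), spec$n_variants_per_class)
  m <- length(cls)
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  s <- sqrt(2 * maf * (1 - maf) * spec$n_individuals)  # z per unit beta
  if (spec$effect_mode == "per_allele") {
    eb <- rep(spec$effect_size_bmi, m)
    ew <- rep(spec$effect_size_whr, m)
  } else {
    eb <- spec$z_bmi / s
    ew <- spec$z_whr / s
  }
  b_bmi <- ifelse(cls == "whr_only", 0, eb)
  b_whr <- numeric(m)
  b_whr[cls == "concordant"] <- spec$r_target * b_bmi[cls == "concordant"]
  b_whr[cls == "whr_only"]   <- -ew[cls == "whr_only"]
  b_whr[cls == "discordant"] <- -ew[cls == "discordant"]
  chrom <- as.character(rep_len(1:22, m))
  pos <- 10e6 * ceiling(seq_len(m) / 22)  # 10 Mb spacing within chromosome
  data.table::data.table(
    variant_id = sprintf("rs%05d", seq_len(m)),
    chrom = chrom, pos = as.numeric(pos),
    effect_allele = "A", other_allele = "G",
    maf = maf, true_class = cls, true_beta_bmi = b_bmi, true_beta_whr = b_whr)
}

#' Simulate an individual-level cohort
#'
#' Draws genotypes as binomial(2, MAF), builds standardized BMI-like and
#' WHR-like phenotypes as genetic score plus correlated noise tuned so the
#' within-sex phenotype correlation equals the spec's target, assigns sex
#' 1:1, and draws a binary disease from a logistic model whose log-odds are
#' `disease_intercept + causal_disease_beta * BMI`.  Sexual dimorphism is
#' introduced by scaling true WHR effects per sex via `sex_scale_whr`.
#'
#' @param spec An [architecture_spec()].
#' @return A list of class `"synthetic_cohort"` with elements `genotypes`
#'   (n x m integer matrix), `phenotypes` (data.table: sex, bmi, whr,
#'   disease), `truth` (per-variant map and true effects), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (spec$n_individuals <= sum(spec$n_variants_per_class))
    stop("parameter error: individual-level simulation needs more ",
         "individuals than variants")
  set.seed(spec$seed)
  truth <- plant_truth(spec)
  n <- spec$n_individuals
  m <- nrow(truth)
  G <- matrix(rbinom(n * m, 2L, rep(truth$maf, each = n)), nrow = n)
  colnames(G) <- truth$variant_id
  sex <- rep_len(c("women", "men"), n)
  r_sex <- c(women = spec$r_women, men = spec$r_men)
  bmi <- numeric(n); whr <- numeric(n)
  for (s in c("women", "men")) {
    idx <- which(sex == s)
    bw <- truth$true_beta_whr * spec$sex_scale_whr[[s]]
    g_b <- as.vector(G[idx, , drop = FALSE] %*% truth$true_beta_bmi)
    g_w <- as.vector(G[idx, , drop = FALSE] %*% bw)
    v <- 2 * truth$maf * (1 - truth$maf)
    var_gb <- sum(v * truth$true_beta_bmi^2)
    var_gw <- sum(v * bw^2)
    cov_g <- sum(v * truth$true_beta_bmi * bw)
    if (var_gb >= 1 || var_gw >= 1)
      stop("parameter error: genetic variance exceeds the unit phenotype ",
           "variance; reduce effect sizes or variant count")
    rho_e <- (r_sex[[s]] - cov_g) / sqrt((1 - var_gb) * (1 - var_gw))
    if (!is.finite(rho_e) || abs(rho_e) >= 1)
      stop("parameter error: requested phenotype correlation unreachable ",
           "given the planted genetic covariance (needed noise correlation ",
           sprintf("%.3f)", rho_e))
    z1 <- rnorm(length(idx)); z2 <- rnorm(length(idx))
    bmi[idx] <- g_b + sqrt(1 - var_gb) * z1
    whr[idx] <- g_w + sqrt(1 - var_gw) * (rho_e * z1 + sqrt(1 - rho_e^2) * z2)
  }
  lin <- spec$disease_intercept + spec$causal_disease_beta * bmi +
    (spec$causal_disease_beta_whr %||% 0) * whr
  disease <- rbinom(n, 1L, 1 / (1 + exp(-lin)))
  structure(list(genotypes = G,
                 phenotypes = data.table::data.table(sex = sex, bmi = bmi,
                                                     whr = whr,
                                                     disease = disease),
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

# Vectorized per-variant simple linear regression of y on allele count.
# Returns beta, se, p (two-sided normal), eaf, n.  Monomorphic variants get
# NA estimates.
assoc_linear <- function(G, y) {
  n <- length(y)
  gm <- colMeans(G)
  Sxx <- colSums(G^2) - n * gm^2
  Sxy <- as.vector(crossprod(G, y)) - n * gm * mean(y)
  Syy <- sum((y - mean(y))^2)
  mono <- Sxx <= 0
  beta <- ifelse(mono, NA_real_, Sxy / Sxx)
  rss <- Syy - ifelse(mono, 0, beta * Sxy)
  se <- ifelse(mono, NA_real_, sqrt(pmax(rss, 0) / (n - 2) / Sxx))
  data.table::data.table(beta = beta, se = se,
                         p = ifelse(mono, NA_real_, p_from_z(beta / se)),
                         eaf = gm / 2, n = n)
}

# Per-variant univariate logistic regression (disease outcomes); log-odds
# per allele with Wald SE.
assoc_logistic <- function(G, y) {
  n <- length(y)
  fit1 <- function(g) {
    if (stats::var(g) <= 0) return(c(NA_real_, NA_real_))
    f <- suppressWarnings(
      stats::glm.fit(cbind(1, g), y, family = stats::binomial()))
    eta <- f$linear.predictors
    w <- exp(eta) / (1 + exp(eta))^2
    X <- cbind(1, g)
    V <- solve(crossprod(X * sqrt(w)))
    c(f$coefficients[2L], sqrt(V[2L, 2L]))
  }
  est <- vapply(seq_len(ncol(G)), function(j) fit1(G[, j]), numeric(2))
  data.table::data.table(beta = est[1L, ], se = est[2L, ],
                         p = p_from_z(est[1L, ] / est[2L, ]),
                         eaf = colMeans(G) / 2, n = n)
}

#' Derive GWAS summary statistics from a synthetic cohort
#'
#' Emulates the consortium convention: within each sex, phenotypes are
#' inverse-normal transformed (for WHRadjBMI, WHR is first residualized on
#' BMI within sex, then the residuals are transformed), the `combined`
#' stratum pools the per-sex transformed values (equivalent to a sex-adjusted
#' analysis), and each variant is tested by simple linear regression of the
#' transformed trait on allele count.  The binary `disease` trait is tested
#' by univariate logistic regression, returning log-odds per allele.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param traits Subset of `c("BMI", "WHR", "WHRadjBMI", "disease")`.
#' @param strata Subset of `c("combined", "women", "men")`.
#' @return Long-format summary-statistics `data.table` (one record per
#'   variant x trait x stratum) in the canonical dialect.
#' @export
cohort_to_sumstats <- function(cohort,
                               traits = c("BMI", "WHR", "WHRadjBMI"),
                               strata = c("combined", "women", "men")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ph <- cohort$phenotypes
  G <- cohort$genotypes
  n_all <- nrow(ph)
  # per-sex transformed traits, pooled for the combined stratum
  tr <- list(BMI = numeric(n_all), WHR = numeric(n_all),
             WHRadjBMI = numeric(n_all))
  for (s in c("women", "men")) {
    idx <- which(ph$sex == s)
    tr$BMI[idx] <- inverse_normal(ph$bmi[idx])
    tr$WHR[idx] <- inverse_normal(ph$whr[idx])
    res <- stats::residuals(stats::lm(ph$whr[idx] ~ ph$bmi[idx]))
    tr$WHRadjBMI[idx] <- inverse_normal(res)
  }
  out <- list()
  for (st in strata) {
    idx <- if (st == "combined") seq_len(n_all) else which(ph$sex == st)
    Gs <- G[idx, , drop = FALSE]
    for (t in traits) {
      a <- if (t == "disease") assoc_logistic(Gs, ph$disease[idx])
           else assoc_linear(Gs, tr[[t]][idx])
      n_mono <- sum(is.na(a$beta))
      if (n_mono > 0)
        msg("cohort_to_sumstats: %d monomorphic variant(s) in %s/%s",
            n_mono, t, st)
      out[[paste(t, st)]] <- data.table::data.table(
        variant_id = cohort$truth$variant_id,
        chrom = cohort$truth$chrom, pos = cohort$truth$pos,
        effect_allele = cohort$truth$effect_allele,
        other_allele = cohort$truth$other_allele,
        eaf = a$eaf, beta = a$beta, se = a$se, p = a$p, n = a$n,
        trait = t, stratum = st)
    }
  }
  data.table::rbindlist(out)
}

#' Draw summary statistics directly from the sampling model
#'
#' Fast generation path: per-variant effect estimates are drawn as
#' `beta_hat ~ N(true beta, se^2)` with `se = 1/sqrt(2 maf (1-maf) N)`, the
#' BMI and WHR estimation errors of a variant drawn jointly with correlation
#' `r_target` (the within-cohort error correlation of two traits measured on
#' the same samples).  WHRadjBMI statistics follow by the linear relation on
#' the re-standardized residual scale,
#' `b_adj = (b_WHR - r b_BMI)/sqrt(1 - r^2)` with `se_adj = se`, matching the
#' moments of the cohort path.  Optional LD satellites place `n_satellites`
#' extra variants 50-250 kb around each planted variant with squared
#' correlation `satellite_r2` to it (attenuated effects, correlated errors),
#' and the implied LD pair table is attached as attribute `"ld_pairs"`.
#'
#' @param spec An [architecture_spec()].
#' @return Long-format summary-statistics `data.table` for traits
#'   BMI/WHR/WHRadjBMI (stratum `combined`), with the truth table attached as
#'   attribute `"truth"` (satellites carry `true_class = "satellite"`).
#' @export
sumstats_direct <- function(spec) {
  set.seed(spec$seed)
  truth <- plant_truth(spec)
  r <- spec$r_target
  if (spec$n_satellites > 0) {
    rho <- sqrt(spec$satellite_r2)
    sats <- truth[rep(seq_len(.N), each = spec$n_satellites)]
    k <- seq_len(nrow(sats))
    off <- sample(c(-1, 1), nrow(sats), replace = TRUE) *
      round(runif(nrow(sats), 5e4, 2.5e5))
    sats[, `:=`(variant_id = paste0(variant_id, "_sat",
                                    rep(seq_len(spec$n_satellites),
                                        times = nrow(truth))),
                pos = pos + off,
                true_beta_bmi = rho * true_beta_bmi,
                true_beta_whr = rho * true_beta_whr,
                lead_id = rep(truth$variant_id,
                              each = spec$n_satellites),
                true_class = "satellite")]
    truth[, lead_id := variant_id]
    truth <- data.table::rbindlist(list(truth, sats), use.names = TRUE)
  } else truth[, lead_id := variant_id]
  m <- nrow(truth)
  se <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * spec$n_individuals)
  # bivariate errors with correlation r, shared across a variant's traits;
  # satellites reuse their lead's error component with LD correlation rho
  e_b <- rnorm(m); e_w <- r * e_b + sqrt(1 - r^2) * rnorm(m)
  if (spec$n_satellites > 0) {
    rho <- sqrt(spec$satellite_r2)
    lead_idx <- match(truth$lead_id, truth$variant_id)
    is_sat <- truth$true_class == "satellite"
    e_b[is_sat] <- rho * e_b[lead_idx[is_sat]] +
      sqrt(1 - rho^2) * rnorm(sum(is_sat))
    e_w[is_sat] <- r * e_b[is_sat] + sqrt(1 - r^2) * rnorm(sum(is_sat))
  }
  b_bmi_hat <- truth$true_beta_bmi + se * e_b
  b_whr_hat <- truth$true_beta_whr + se * e_w
  b_adj_hat <- (b_whr_hat - r * b_bmi_hat) / sqrt(1 - r^2)
  mk <- function(beta, trait) data.table::data.table(
    variant_id = truth$variant_id, chrom = truth$chrom, pos = truth$pos,
    effect_allele = truth$effect_allele, other_allele = truth$other_allele,
    eaf = truth$maf, beta = beta, se = se, p = p_from_z(beta / se),
    n = spec$n_individuals, trait = trait, stratum = "combined")
  out <- data.table::rbindlist(list(mk(b_bmi_hat, "BMI"),
                                    mk(b_whr_hat, "WHR"),
                                    mk(b_adj_hat, "WHRadjBMI")))
  if (spec$n_satellites > 0) {
    lp <- truth[true_class == "satellite",
                .(id1 = lead_id, id2 = variant_id, r2 = spec$satellite_r2)]
    data.table::setattr(out, "ld_pairs", lp)
  }
  data.table::setattr(out, "truth", truth)
  out
}
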