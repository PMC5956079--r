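#' Pivot long summary statistics to a wide per-variant table
#'
#' One row per variant with `beta_<trait>, se_<trait>, p_<trait>` columns
#' for the requested traits in a given stratum; variant metadata (alleles,
#' position, eaf) is taken from the first trait.
#'
#' @param sumstats Long-format summary statistics.
#' @param traits Traits to spread into columns.
#' @param stratum Stratum to keep.
#' @return Wide `data.table`.
#' @export
sumstats_wide <- function(sumstats, traits = c("BMI", "WHR"),
                          stratum = "combined") {
  st <- stratum
  base <- sumstats[trait == traits[1L] & stratum == st,
                   .(variant_id, chrom, pos, effect_allele, other_allele,
                     eaf)]
  for (t in traits) {
    sub <- sumstats[trait == t & stratum == st,
                    .(variant_id, beta, se, p, n)]
    data.table::setnames(sub, c("beta", "se", "p", "n"),
                         paste0(c("beta_", "se_", "p_", "n_"), t))
    base <- merge(base, sub, by = "variant_id", all.x = TRUE, sort = FALSE)
  }
  base
}

#' Assemble a pipeline configuration
#'
#' All thresholds default to the analysis' reference values: genome-wide
#' significance 5e-8, nominal 0.05, clump window 500 kb to either side with
#' r2 threshold 0.1, minimum contributing N 10000.
#'
#' @param sumstats Long-format summary statistics for the scans, or NULL to
#'   simulate from `arch_spec`.
#' @param arch_spec [architecture_spec()] used when `sumstats` is NULL.
#' @param lookups,outcomes Optional long-format lookup/outcome effect tables
#'   for the enrichment and MR stages.
#' @param r_spec [correlation_spec()].
#' @param ld [ld_source()] or NULL.
#' @param gws_threshold,nominal_alpha,window_bp,r2_max,min_n Stage
#'   parameters (defaults above).
#' @param strict_alpha Stricter re-classification threshold; default
#'   `0.05 / n_signals`, resolved after clumping.
#' @param out_dir Directory for stage artifacts (NULL: nothing written).
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sumstats = NULL, arch_spec = NULL,
                            lookups = NULL, outcomes = NULL,
                            r_spec = correlation_spec(),
                            ld = NULL, gws_threshold = 5e-8,
                            nominal_alpha = 0.05, window_bp = 5e5,
                            r2_max = 0.1, min_n = 10000,
                            strict_alpha = NULL, out_dir = NULL, seed = 1) {
  stopifnot(gws_threshold > 0, gws_threshold < 1,
            nominal_alpha > 0, nominal_alpha < 1, window_bp > 0)
  if (is.null(sumstats) && is.null(arch_spec))
    stop("config error: either sumstats or arch_spec must be given")
  structure(list(sumstats = sumstats, arch_spec = arch_spec,
                 lookups = lookups, outcomes = outcomes, r_spec = r_spec,
                 ld = ld, gws_threshold = gws_threshold,
                 nominal_alpha = nominal_alpha, window_bp = window_bp,
                 r2_max = r2_max, min_n = min_n, strict_alpha = strict_alpha,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full joint-view analysis
#'
#' Executes QC, genome-wide selection, clumping, effect conversion (when the
#' WHR scan is absent it is reconstructed from WHRadjBMI and BMI),
#' classification of the lead variants with class-specific allele alignment,
#' and — when lookup/outcome tables are supplied — directional enrichment and
#' class-restricted MR.  Every stage's result is collected in the returned
#' manifest; with `out_dir` set, stage tables are also written as TSV.
#'
#' @param config A [pipeline_config()].
#' @return A manifest list: per-stage counts, per-class counts, signals,
#'   classified leads, and the optional enrichment/MR tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ss <- config$sumstats
  if (is.null(ss)) {
    spec <- config$arch_spec
    spec$seed <- config$seed
    ss <- sumstats_direct(spec)
  }
  if (!data.table::is.data.table(ss))
    ss <- data.table::rbindlist(ss, use.names = TRUE, fill = TRUE)
  ss <- apply_qc(ss, min_n = config$min_n)
  qc_counts <- attr(ss, "qc_counts")

  whr_computed <- FALSE
  scans <- intersect(c("BMI", "WHR", "WHRadjBMI"), unique(ss$trait))
  if (!"WHR" %in% scans && all(c("BMI", "WHRadjBMI") %in% scans)) {
    whr <- convert_whr_from_adjusted(ss[trait == "WHRadjBMI"],
                                     ss[trait == "BMI"], config$r_spec)
    ss <- data.table::rbindlist(list(ss, whr), use.names = TRUE, fill = TRUE)
    scans <- c(scans, "WHR")
    whr_computed <- TRUE
    msg("run_pipeline: WHR scan absent; computed from WHRadjBMI and BMI")
  }

  gws <- select_gws(ss[stratum == "combined"], config$gws_threshold)
  signals <- clump(gws, ld = config$ld, window_bp = config$window_bp,
                   r2_max = config$r2_max)
  strict_alpha <- config$strict_alpha %||% (0.05 / nrow(signals))

  wide <- sumstats_wide(ss, traits = c("BMI", "WHR"))
  leads <- merge(signals[, .(variant_id = lead, lead_trait, traits_text)],
                 wide, by = "variant_id", sort = FALSE)
  classified <- classify_variants(leads, alpha = config$nominal_alpha,
                                  r = stratum_r(config$r_spec, "combined"))
  sensitivity <- reclassify_sensitivity(leads, alpha = config$nominal_alpha,
                                        alpha_strict = strict_alpha)
  enrichment <- if (!is.null(config$lookups))
    run_enrichment(classified, config$lookups,
                   alpha = config$nominal_alpha) else NULL
  mr <- if (!is.null(config$outcomes))
    run_class_mr(classified, config$outcomes) else NULL

  class_counts <- table(factor(classified$class_label,
                               levels = CLASS_LEVELS))
  manifest <- list(
    seed = config$seed,
    params = list(gws_threshold = config$gws_threshold,
                  nominal_alpha = config$nominal_alpha,
                  strict_alpha = strict_alpha,
                  window_bp = config$window_bp, r2_max = config$r2_max,
                  min_n = config$min_n),
    counts = list(records_in = nrow(ss), qc = as.list(qc_counts),
                  gws_records = nrow(gws),
                  gws_variants = length(unique(gws$variant_id)),
                  n_signals = nrow(signals),
                  signals_by_scan = sapply(
                    scans, function(s) sum(vapply(
                      signals$traits_of_region,
                      function(tr) s %in% tr, TRUE)))),
    class_counts = as.list(class_counts),
    whr_computed = whr_computed,
    signals = signals, classified = classified,
    sensitivity = sensitivity, enrichment = enrichment, mr = mr)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x))
      data.table::fwrite(x, file.path(config$out_dir, f), sep = "\t")
    w(signals[, !c("member_variants", "traits_of_region")], "signals.tsv")
    w(classified, "classified.tsv")
    w(sensitivity$transitions, "class_transitions.tsv")
    w(enrichment, "enrichment.tsv")
    w(mr, "mr.tsv")
  }
  manifest
}
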