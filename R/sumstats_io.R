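#' Default GIANT-dialect column map
#'
#' Maps the canonical record fields onto the header names used by the public
#' GIANT 2015 summary-statistics releases.  Each element lists the header
#' spellings that are accepted for that field, in order of preference; lookup
#' consortia with other dialects can supply their own map to
#' [read_sumstats()].
#'
#' @return Named list of candidate header names per canonical field.
#' @export
giant_column_map <- function() {
  list(
    variant_id    = c("MarkerName", "SNP", "rsid", "variant_id"),
    chrom         = c("Chr", "CHR", "chromosome", "chrom"),
    pos           = c("Pos", "POS", "position", "pos"),
    effect_allele = c("Allele1", "A1", "effect_allele", "EA"),
    other_allele  = c("Allele2", "A2", "other_allele", "OA", "NEA"),
    eaf           = c("FreqAllele1HapMapCEU", "Freq1.Hapmap", "EAF", "eaf", "freq"),
    beta          = c("b", "beta", "Effect", "BETA"),
    se            = c("se", "SE", "StdErr"),
    p             = c("p", "P", "pvalue", "P-value", "Pvalue"),
    n             = c("N", "n", "SampleSize")
  )
}

norm_allele <- function(a) toupper(trimws(as.character(a)))

#' Read a GIANT-style summary-statistics table
#'
#' Reads a tab-separated (optionally gzipped) association table, maps its
#' header through `col_map`, coerces types, and drops records that violate
#' the record invariants, with a logged count per filter:
#' alleles must be distinct members of A/C/G/T, `eaf` strictly in (0, 1),
#' `se > 0`, `n > 0`, `p` in (0, 1].  A missing p-value is imputed from the
#' two-sided normal tail of `beta/se`; a reported p-value that disagrees with
#' `beta/se` by more than `p_rel_tol` (relative, on the -log10 scale, with an
#' absolute floor of 0.1 for near-1 p-values where the relative scale
#' degenerates) is treated as an invariant violation.  Chromosome and
#' position are optional in the dialect (the GIANT BMI release omits them);
#' records are then assigned `chrom = NA`.
#'
#' @param path Path to a tab-separated file, plain or `.gz`.
#' @param trait Trait label attached to every record (e.g. `"BMI"`).
#' @param stratum One of `"combined"`, `"women"`, `"men"`.
#' @param col_map Column map as from [giant_column_map()].
#' @param p_rel_tol Relative tolerance of the p vs beta/se consistency check.
#' @return A `data.table` with canonical columns `variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, n, trait, stratum`.
#'   Filter counts are attached as attribute `"filter_counts"`.
#' @export
read_sumstats <- function(path, trait, stratum = "combined",
                          col_map = giant_column_map(), p_rel_tol = 0.10) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- if (grepl("\\.gz$", path)) {
    data.table::as.data.table(
      read.table(gzfile(path), header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE, check.names = FALSE))
  } else {
    data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "n")
  cols <- lapply(names(col_map), function(field) {
    hit <- intersect(col_map[[field]], names(raw))
    if (length(hit) == 0L) {
      if (field %in% mandatory)
        stop("format error: no column found for mandatory field '", field,
             "' in ", path)
      rep(NA, nrow(raw))
    } else raw[[hit[1L]]]
  })
  names(cols) <- names(col_map)
  out <- data.table::as.data.table(cols)
  out[, `:=`(variant_id   = as.character(variant_id),
             chrom        = as.character(chrom),
             pos          = suppressWarnings(as.numeric(pos)),
             effect_allele = norm_allele(effect_allele),
             other_allele  = norm_allele(other_allele),
             eaf = as.numeric(eaf), beta = as.numeric(beta),
             se = as.numeric(se), p = as.numeric(p), n = as.numeric(n))]
  out[, `:=`(trait = trait, stratum = stratum)]

  counts <- c()
  drop_step <- function(dt, keep, label) {
    counts[[label]] <<- sum(!keep)
    dt[keep]
  }
  out <- drop_step(out, !is.na(out$variant_id) & nzchar(out$variant_id),
                   "missing_id")
  out <- drop_step(out, out$effect_allele %in% c("A", "C", "G", "T") &
                        out$other_allele %in% c("A", "C", "G", "T") &
                        out$effect_allele != out$other_allele, "bad_alleles")
  out <- drop_step(out, is.finite(out$eaf) & out$eaf > 0 & out$eaf < 1,
                   "bad_eaf")
  out <- drop_step(out, is.finite(out$beta) & is.finite(out$se) & out$se > 0,
                   "bad_beta_se")
  out <- drop_step(out, is.finite(out$n) & out$n > 0, "bad_n")
  out <- drop_step(out, is.na(out$pos) | out$pos >= 0, "bad_pos")

  # impute p where absent, then check reported p against beta/se
  imputed <- !is.finite(out$p)
  out[imputed, p := p_from_z(beta / se)]
  counts[["p_imputed"]] <- sum(imputed)
  out <- drop_step(out, out$p > 0 & out$p <= 1, "bad_p")
  lp_obs  <- -log10(out$p)
  lp_calc <- -log10(p_from_z(out$beta / out$se))
  ok <- abs(lp_obs - lp_calc) <= pmax(p_rel_tol * lp_calc, 0.1)
  out <- drop_step(out, ok, "p_inconsistent")

  if (nrow(out) == 0L)
    stop("empty-input error: no records left after validation of ", path)
  dropped <- sum(unlist(counts)) - counts[["p_imputed"]]
  if (dropped > 0)
    msg("%s (%s/%s): dropped %d invalid record(s)", trait, stratum,
        basename(path), dropped)
  data.table::setattr(out, "filter_counts", unlist(counts))
  out[]
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-separated dialect (gzipped when the path ends in
#' `.gz`).  [read_sumstats()] on the result reproduces the records.
#'
#' @param table A summary-statistics `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize effect alleles across traits and strata
#'
#' Expresses every record of every table on a single per-variant reference
#' effect allele (taken from the first table in which the variant occurs).
#' Records whose alleles are swapped relative to the reference get their beta
#' negated and eaf complemented; records on the opposite strand are
#' complemented; strand-ambiguous variants (A/T or C/G pairs) are retained
#' as-is but flagged in the `ambiguous` column, since strand flips are not
#' identifiable for them.  Records whose allele pair cannot be reconciled by
#' swap and/or complement are dropped with a logged count.
#'
#' @param tables A list of summary-statistics `data.table`s (or a single
#'   long-format table covering several traits/strata).
#' @return One long-format `data.table` with an added logical `ambiguous`
#'   column; the number of irreconcilable records dropped is attached as
#'   attribute `"n_dropped"`.
#' @export
harmonize_alleles <- function(tables) {
  if (data.table::is.data.table(tables)) tables <- list(tables)
  long <- data.table::rbindlist(tables, use.names = TRUE, fill = TRUE)
  if (!"ambiguous" %in% names(long)) long[, ambiguous := NA]
  ref <- long[, .(ref_ea = effect_allele[1L], ref_oa = other_allele[1L]),
              by = variant_id]
  long <- merge(long, ref, by = "variant_id", sort = FALSE)
  ea <- long$effect_allele; oa <- long$other_allele
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  same    <- ea == long$ref_ea & oa == long$ref_oa
  swapped <- ea == long$ref_oa & oa == long$ref_ea
  strand  <- cea == long$ref_ea & coa == long$ref_oa
  strand_swapped <- cea == long$ref_oa & coa == long$ref_ea
  palin <- is_palindromic(long$ref_ea, long$ref_oa)
  # palindromic pairs: swap and strand-flip coincide; keep orientation as
  # read (treat as 'same' when alleles match in either order) and flag
  keep <- same | swapped | strand | strand_swapped
  flip <- !palin & ((swapped & !same) | (strand_swapped & !strand))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    msg("harmonize_alleles: dropped %d irreconcilable record(s)", n_dropped)
  out <- long[keep]
  flip <- flip[keep]
  out[flip, `:=`(beta = -beta, eaf = 1 - eaf)]
  out[, `:=`(effect_allele = ref_ea, other_allele = ref_oa)]
  out[, ambiguous := is_palindromic(effect_allele, other_allele)]
  out[, c("ref_ea", "ref_oa") := NULL]
  data.table::setattr(out, "n_dropped", n_dropped)
  out[]
}

#' Sample-size and sex-chromosome QC filter
#'
#' Retains records with `n >= min_n` and, when `drop_sex_chroms` is set,
#' drops records mapped to sex or mitochondrial chromosomes (records with an
#' unknown chromosome are retained, matching summary-statistics releases that
#' omit positions).
#'
#' @param table Summary-statistics `data.table`.
#' @param min_n Minimum contributing sample size (default 10000).
#' @param drop_sex_chroms Drop non-autosomal records (default TRUE).
#' @return Filtered table with attribute `"qc_counts"`.
#' @export
apply_qc <- function(table, min_n = 10000, drop_sex_chroms = TRUE) {
  stopifnot(min_n >= 0)
  keep_n <- table$n >= min_n
  keep_chr <- if (drop_sex_chroms) {
    is.na(table$chrom) | !(toupper(table$chrom) %in% SEX_CHROMS)
  } else rep(TRUE, nrow(table))
  out <- table[keep_n & keep_chr]
  cnt <- c(low_n = sum(!keep_n), sex_chrom = sum(keep_n & !keep_chr))
  if (sum(cnt) > 0)
    msg("apply_qc: removed %d low-n and %d sex-chromosome record(s)",
        cnt[["low_n"]], cnt[["sex_chrom"]])
  data.table::setattr(out, "qc_counts", cnt)
  out[]
}

#' Phenotype-correlation specification
#'
#' Container for the BMI-WHR phenotype correlation used by the effect
#' conversion, overall and by sex.  Defaults are the UK Biobank interim
#' release estimates (overall 0.44; women 0.46; men 0.60).
#'
#' @param r_combined Overall correlation.
#' @param r_women,r_men Sex-specific correlations.
#' @return A named list of class `"correlation_spec"`.
#' @export
correlation_spec <- function(r_combined = 0.44, r_women = 0.46, r_men = 0.60) {
  r <- c(combined = r_combined, women = r_women, men = r_men)
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("correlations must be finite and strictly inside (-1, 1)")
  structure(as.list(r), class = "correlation_spec")
}

#' Look up the correlation for a stratum
#' @param spec A [correlation_spec()].
#' @param stratum `"combined"`, `"women"` or `"men"`.
#' @return The correlation coefficient.
#' @export
stratum_r <- function(spec, stratum) {
  if (!stratum %in% names(spec)) stop("unknown stratum: ", stratum)
  spec[[stratum]]
}
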