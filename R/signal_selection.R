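#' Linkage-disequilibrium source for clumping
#'
#' Wraps a symmetric pair table of squared correlations.  Pairs absent from
#' the table are assumed to have `default_r2` (0 when no LD information is
#' supplied, which reduces [clump()] to distance-only clumping).
#'
#' @param pairs `data.table`/data.frame with columns `id1, id2, r2`, or NULL.
#' @param default_r2 r-squared assumed for missing pairs.
#' @return A list of class `"ld_source"`.
#' @export
ld_source <- function(pairs = NULL, default_r2 = 0) {
  stopifnot(default_r2 >= 0, default_r2 <= 1)
  if (is.null(pairs)) {
    pairs <- data.table::data.table(id1 = character(), id2 = character(),
                                    r2 = numeric())
  } else {
    pairs <- data.table::as.data.table(pairs)[, .(id1 = as.character(id1),
                                                  id2 = as.character(id2),
                                                  r2 = as.numeric(r2))]
    stopifnot(all(pairs$r2 >= 0 & pairs$r2 <= 1))
  }
  # symmetrize for O(1) keyed lookup in either order
  sym <- data.table::rbindlist(list(pairs,
                                    pairs[, .(id1 = id2, id2 = id1, r2)]))
  sym <- unique(sym, by = c("id1", "id2"))
  data.table::setkey(sym, id1, id2)
  structure(list(pairs = sym, default_r2 = default_r2), class = "ld_source")
}

#' Read an LD pair table from a 3-column TSV
#' @param path TSV with columns `id1, id2, r2`.
#' @param default_r2 Passed to [ld_source()].
#' @return An `"ld_source"`.
#' @export
read_ld_pairs <- function(path, default_r2 = 0) {
  ld_source(data.table::fread(path, sep = "\t"), default_r2 = default_r2)
}

ld_r2 <- function(ld, a, b) {
  q <- data.table::data.table(id1 = rep_len(a, length(b)), id2 = b)
  hit <- ld$pairs[q, r2, on = c("id1", "id2")]
  ifelse(is.na(hit), ld$default_r2, hit)
}

#' Select genome-wide significant variants per scan
#'
#' Applies the strict threshold `p < threshold` within each scan and returns
#' the union over scans with scan provenance, one row per (variant, scan).
#'
#' @param tables Long-format summary statistics covering the scans (the
#'   `trait` column identifies the scan); a list of tables is also accepted.
#' @param threshold Significance threshold (default the conventional 5e-8).
#' @return `data.table` with the significant records (variant, scan = trait,
#'   and their association statistics).
#' @export
select_gws <- function(tables, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  if (!data.table::is.data.table(tables))
    tables <- data.table::rbindlist(tables, use.names = TRUE, fill = TRUE)
  tables[p < threshold]
}

chrom_order <- function(ch) {
  suppressWarnings(x <- as.numeric(ch))
  ifelse(is.na(x), 1e3, x)
}

#' Clump significant variants into independent signals
#'
#' Greedy lead-driven clumping: repeatedly take the unassigned candidate
#' with the smallest association p-value across scans as a new lead, and
#' absorb every unassigned candidate on the same chromosome that lies within
#' `window_bp` to either side of it *or* has squared LD correlation above
#' `r2_max` with it.  Two signals are therefore independent only if they are
#' both farther apart than the window and in low LD.  Ties on the minimal
#' p-value are broken by chromosome, then position, then variant ID.
#'
#' @param candidates Output of [select_gws()] (rows: variant x scan, with
#'   `chrom`, `pos`, `p`).
#' @param ld An [ld_source()] or NULL (distance-only clumping, logged).
#' @param window_bp Absorption window to either side of the lead, in bp.
#' @param r2_max LD threshold above which a candidate is absorbed.
#' @return `data.table` of signals: `lead, lead_trait, chrom, pos,
#'   region_start, region_end, n_members, traits_of_region, member_variants`
#'   (the last two as list columns plus a comma-separated text mirror).
#' @export
clump <- function(candidates, ld = NULL, window_bp = 5e5, r2_max = 0.1) {
  stopifnot(window_bp > 0, r2_max >= 0, r2_max <= 1)
  if (is.null(ld)) {
    msg("clump: no LD source supplied; distance-only clumping (default r2 = 0)")
    ld <- ld_source(NULL, default_r2 = 0)
  }
  # per-variant minimum p across scans, with its scan of origin
  cand <- candidates[order(p), .(p = p[1L], lead_trait = trait[1L],
                                 chrom = chrom[1L], pos = pos[1L]),
                     by = variant_id]
  scans <- candidates[, .(scans = list(unique(trait))), by = variant_id]
  cand <- merge(cand, scans, by = "variant_id", sort = FALSE)
  data.table::setorder(cand, p)
  cand <- cand[order(p, chrom_order(chrom), pos, variant_id)]
  assigned <- rep(FALSE, nrow(cand))
  signals <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1L]
    same_chr <- !assigned & cand$chrom == cand$chrom[i]
    near <- same_chr & abs(cand$pos - cand$pos[i]) <= window_bp
    linked <- rep(FALSE, nrow(cand))
    open <- which(same_chr & !near)
    if (length(open))
      linked[open] <- ld_r2(ld, cand$variant_id[i],
                            cand$variant_id[open]) > r2_max
    members <- which(near | linked)
    members <- union(i, members)
    assigned[members] <- TRUE
    mem <- cand[members]
    signals[[length(signals) + 1L]] <- data.table::data.table(
      lead = cand$variant_id[i], lead_trait = cand$lead_trait[i],
      chrom = cand$chrom[i], pos = cand$pos[i], p = cand$p[i],
      region_start = min(mem$pos), region_end = max(mem$pos),
      n_members = nrow(mem),
      member_variants = list(mem$variant_id),
      traits_of_region = list(sort(unique(unlist(mem$scans)))))
  }
  out <- data.table::rbindlist(signals)
  out[, traits_text := vapply(traits_of_region, paste, "", collapse = ",")]
  out[]
}

#' Scans contributing genome-wide significance to a signal
#'
#' The traits of a region are the union of scans in which any member of the
#' signal reaches genome-wide significance.
#'
#' @param signal One row of a [clump()] result (or a list with
#'   `member_variants`).
#' @param gws A [select_gws()] result.
#' @return Character vector of scan labels.
#' @export
traits_of_region <- function(signal, gws) {
  members <- unlist(signal$member_variants)
  sort(unique(gws[variant_id %in% members, trait]))
}
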