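#!/usr/bin/env Rscript
# QC the three scans, select genome-wide significant variants (P < 5e-8),
# take their union across scans and clump into independent signals
# (< 500 kb to either side, or r2 > 0.1, ties the candidate to the lead).

suppressMessages({library(adipoplane); library(data.table)})

scans <- rbindlist(lapply(c("BMI", "WHR", "WHRadjBMI"), function(t)
  read_sumstats(sprintf("results/scan_%s.tsv", t), trait = t)))
scans <- apply_qc(scans, min_n = 10000, drop_sex_chroms = TRUE)

gws <- select_gws(scans, threshold = 5e-8)
cat(sprintf("genome-wide significant records: %d (%d distinct variants)\n",
            nrow(gws), uniqueN(gws$variant_id)))
print(gws[, .N, by = trait])

ld <- read_ld_pairs("results/ld_pairs.tsv")
signals <- clump(gws, ld = ld, window_bp = 5e5, r2_max = 0.1)
cat(sprintf("clumped into %d independent signals\n", nrow(signals)))
by_scan <- sapply(c("BMI", "WHR", "WHRadjBMI"), function(s)
  sum(vapply(signals$traits_of_region, function(tr) s %in% tr, TRUE)))
cat("signals with genome-wide support by scan (union definition):\n")
print(by_scan)

fwrite(signals[, !c("member_variants", "traits_of_region")],
       "results/signals.tsv", sep = "\t")

# sanity against the planted truth: one signal per planted locus
truth <- fread("results/scan_truth.tsv")
lead_region <- truth[match(signals$lead, variant_id), lead_id]
cat(sprintf("distinct planted loci among leads: %d (duplicated: %d)\n",
            uniqueN(lead_region), sum(duplicated(lead_region))))
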