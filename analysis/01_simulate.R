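#!/usr/bin/env Rscript
# Generate the synthetic inputs for the analysis workflow:
#  - three-scan summary statistics (BMI, WHR, WHRadjBMI) from the direct
#    sampling path at a discovery-regime architecture, with LD satellites so
#    that clumping has work to do, plus the planted truth and LD pair table;
#  - an individual-level cohort (50,000 individuals, 200 variants, disease
#    causally downstream of BMI and WHR) whose derived summary statistics
#    feed the conversion, enrichment and MR steps.

suppressMessages({library(adipoplane); library(data.table)})
dir.create("results", showWarnings = FALSE)
SEED <- 20260930

message("-- direct-path scans (discovery regime, 159 planted loci) --")
scan_spec <- architecture_spec(effect_mode = "calibrated", z_bmi = 7.8,
                               z_whr = 9, n_individuals = 322135,
                               n_satellites = 3, satellite_r2 = 0.8,
                               seed = SEED)
scans <- sumstats_direct(scan_spec)
truth <- attr(scans, "truth")
for (t in c("BMI", "WHR", "WHRadjBMI"))
  write_sumstats(scans[trait == t], sprintf("results/scan_%s.tsv", t))
fwrite(truth, "results/scan_truth.tsv", sep = "\t")
fwrite(attr(scans, "ld_pairs"), "results/ld_pairs.tsv", sep = "\t")
cat(sprintf("wrote %d variants x 3 scans (%d planted loci + satellites)\n",
            nrow(truth), sum(truth$true_class != "satellite")))

message("-- individual-level cohort (conversion / enrichment / MR world) --")
cohort_spec <- architecture_spec(
  n_variants_per_class = c(concordant = 80, bmi_only = 40, whr_only = 40,
                           discordant = 40),
  n_individuals = 50000, r_target = 0.44, r_women = 0.46, r_men = 0.60,
  causal_disease_beta = 0.5, causal_disease_beta_whr = 1, seed = SEED + 1)
cohort <- simulate_cohort(cohort_spec)
ss <- cohort_to_sumstats(cohort,
                         traits = c("BMI", "WHR", "WHRadjBMI", "disease"))
write_sumstats(ss, "results/cohort_sumstats.tsv")
fwrite(cohort$truth, "results/cohort_truth.tsv", sep = "\t")
r_hat <- cor(cohort$phenotypes$bmi, cohort$phenotypes$whr)
cat(sprintf("cohort: n = %d, %d variants, observed corr(BMI, WHR) = %.3f\n",
            nrow(cohort$phenotypes), nrow(cohort$truth), r_hat))
cat(sprintf("disease prevalence: %.3f\n", mean(cohort$phenotypes$disease)))
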