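#!/usr/bin/env Rscript
# Class-specific directional binomial enrichment on the cohort world:
# classify the cohort's variants from their BMI/WHR statistics, align
# alleles by class, then test each class for an excess of nominally
# significant trait-increasing/-decreasing effects on the lookup traits
# (here: WHR, BMI themselves plus the simulated disease log-odds).

suppressMessages({library(adipoplane); library(data.table)})

ss <- fread("results/cohort_sumstats.tsv")
w <- sumstats_wide(ss, traits = c("BMI", "WHR"))
classified <- classify_variants(w, alpha = 0.05, r = 0.44)
cat("cohort-world class counts:\n")
print(classified[, .N, by = class_label])

lookups <- ss[stratum == "combined" & trait %in% c("BMI", "WHR", "disease"),
              .(variant_id, trait, beta, se, p)]
enr <- run_enrichment(classified, lookups, alpha = 0.05)
cat(sprintf("ran %d binomial tests (Bonferroni level %.2e)\n",
            nrow(enr), 0.05 / attr(enr, "n_tests")))
cat("flagged enrichments:\n")
print(enr[significant_flag == TRUE,
          .(class_label, trait, direction, n_tested, n_significant,
            p_binomial = signif(p_binomial, 2))])
fwrite(enr, "results/enrichment.tsv", sep = "\t")
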