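library(data.table)

# Write a small GIANT-dialect summary-statistics TSV and return its path.
write_fixture_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  fwrite(rows, path, sep = "\t")
  path
}

# A minimal well-formed GIANT-style table (WHR 2015 header dialect).
giant_fixture_rows <- function() {
  data.table(
    MarkerName = c("rs1", "rs2", "rs3"),
    Chr = c("1", "2", "16"),
    Pos = c(1000L, 2000L, 53800954L),
    Allele1 = c("A", "C", "T"),
    Allele2 = c("G", "T", "C"),
    FreqAllele1HapMapCEU = c(0.25, 0.5, 0.41),
    b = c(0.02, -0.015, 0.08),
    se = c(0.004, 0.005, 0.003),
    p = 2 * pnorm(-abs(c(0.02 / 0.004, -0.015 / 0.005, 0.08 / 0.003))),
    N = c(150000, 220000, 320000))
}

# Canonical in-memory summary-stat records for harmonization tests.
make_records <- function(variant_id, effect_allele, other_allele, beta,
                         eaf = 0.3, trait = "BMI", stratum = "combined",
                         chrom = "1", pos = seq_along(variant_id) * 1000L,
                         se = 0.01, n = 1e5) {
  data.table(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = n,
             trait = trait, stratum = stratum)
}

# Candidate table for clumping tests (variant x scan rows).
make_candidates <- function(id, chrom, pos, p, trait = "BMI") {
  data.table(variant_id = id, chrom = as.character(chrom),
             pos = as.numeric(pos), p = p, trait = trait,
             beta = 0.05, se = 0.01, eaf = 0.3, n = 1e5,
             effect_allele = "A", other_allele = "G", stratum = "combined")
}
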