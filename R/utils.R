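#' @importFrom stats pnorm qnorm pbinom dbinom rbinom rnorm runif rlogis
#'   setNames complete.cases cor ks.test
#' @importFrom utils read.table head
#' @import data.table
NULL

#' Two-sided normal-tail p-value from a z statistic
#'
#' Large-sample p-value used throughout: GWAS meta-analysis effects are
#' treated as normally distributed, so `p = 2 * pnorm(-|z|)`.
#'
#' @param z Numeric vector of z statistics (`beta / se`).
#' @return p-values in (0, 1].
#' @export
p_from_z <- function(z) 2 * pnorm(-abs(z))

# Autosome labels accepted for summary-statistic records.
AUTOSOMES <- as.character(1:22)

# Sex/mito chromosome labels recognised for the QC filter.
SEX_CHROMS <- c("X", "Y", "XY", "MT", "23", "24", "25", "26")

CLASS_LEVELS <- c("BMI+WHR+", "BMIonly+", "WHRonly-", "BMI+WHR-", "unclassified")

msg <- function(...) message("[adipoplane] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
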