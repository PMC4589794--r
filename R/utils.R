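#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats pbinom p.adjust cor median rnorm runif rbeta qbeta pnorm
#'   rbinom rpois wilcox.test lm predict sd var complete.cases coef quantile
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics plot abline
NULL

# The 12 genomic-element categories a CpG site can belong to.  The first
# eight (CGI- and gene-related) are the ones modelled by default; repeat
# classes and "others" are trainable but excluded from default reporting.
MESIC_ELEMENTS <- c("CGI", "shore", "shelf", "UTR5", "promoter", "exon",
                    "intron", "UTR3", "SINE", "LINE", "LTR", "others")
MESIC_GENE_ELEMENTS <- MESIC_ELEMENTS[1:8]

clamp01 <- function(x) pmin(1, pmax(0, x))

# Deterministic fan-out of a master seed into per-component seeds,
# kept well below .Machine$integer.max.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(k)) %% 2147483647L)
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(a, b) if (is.null(a)) b else a
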