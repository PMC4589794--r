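#' Call differentially methylated regions between two samples
#'
#' Sliding windows (default 1 kb, step 500 bp) with at least `min_cpg` CpG
#' sites are screened by the inter-sample Pearson correlation of per-CpG
#' levels: windows with PCC below `pcc_max` (or undefined PCC) become
#' candidates.  Each candidate is tested by an unpaired Wilcoxon rank-sum
#' test on the two samples' per-CpG values; p-values are Benjamini-Hochberg
#' adjusted across candidates and windows with q below `fdr` are reported,
#' overlapping significant windows merged.
#'
#' @param pred_a,pred_b Per-site methylation levels for the two samples,
#'   aligned with `sites`.
#' @param sites Shared CpG sites (GRanges with seqlengths).
#' @param window,step Window size and step in bp (defaults 1000, 500).
#' @param min_cpg Minimum CpGs per window (default 5).
#' @param pcc_max Candidate-screen correlation ceiling (default 0.25).
#' @param fdr BH threshold (default 0.05).
#' @return GRanges of merged DMRs with `n_cpg`, `mean_delta`, `p_value`,
#'   `q_value` (of the most significant constituent window); empty, with a
#'   warning, when no window holds `min_cpg` sites.
#' @export
call_dmrs <- function(pred_a, pred_b, sites, window = 1000, step = 500,
                      min_cpg = 5, pcc_max = 0.25, fdr = 0.05) {
  stopifnot(length(pred_a) == length(sites),
            length(pred_b) == length(sites))
  sl <- GenomeInfoDb::seqlengths(sites)
  wins <- do.call(c, lapply(names(sl), function(ch) {
    starts <- seq(1, max(1, sl[[ch]] - 1), by = step)
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts,
      pmin(starts + window - 1, sl[[ch]])))
  }))
  hits <- GenomicRanges::findOverlaps(sites, wins, ignore.strand = TRUE)
  bywin <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  bywin <- bywin[lengths(bywin) >= min_cpg]
  if (!length(bywin)) {
    warning("no window holds the minimum number of CpG sites")
    return(GenomicRanges::GRanges())
  }
  stats_list <- lapply(bywin, function(i) {
    a <- pred_a[i]; b <- pred_b[i]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < min_cpg) return(NULL)
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
         else stats::cor(a, b)
    if (!is.na(r) && r >= pcc_max) return(NULL)  # screened out
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    # identical groups: rank-sum test returns NaN; no difference to report
    if (is.nan(p)) p <- 1
    c(n = length(a), delta = mean(a - b), p = p)
  })
  keep <- !vapply(stats_list, is.null, logical(1))
  if (!any(keep)) return(GenomicRanges::GRanges())
  st <- do.call(rbind, stats_list[keep])
  cand <- wins[as.integer(names(bywin))[keep]]
  q <- stats::p.adjust(st[, "p"], method = "BH")
  sig <- q < fdr
  if (!any(sig)) return(GenomicRanges::GRanges())
  sig_w <- cand[sig]
  merged <- GenomicRanges::reduce(sig_w)
  ov <- GenomicRanges::findOverlaps(sig_w, merged)
  mi <- S4Vectors::subjectHits(ov)
  S4Vectors::mcols(merged)$n_cpg <- as.integer(
    tapply(st[sig, "n"], mi, max))
  S4Vectors::mcols(merged)$mean_delta <- as.numeric(
    tapply(st[sig, "delta"], mi, mean))
  S4Vectors::mcols(merged)$p_value <- as.numeric(
    tapply(st[sig, "p"], mi, min))
  S4Vectors::mcols(merged)$q_value <- as.numeric(
    tapply(q[sig], mi, min))
  merged
}
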