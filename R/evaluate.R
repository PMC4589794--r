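#' Concordance between predicted and reference methylation
#'
#' Fraction of sites whose absolute difference is below `threshold`
#' (default 0.25).
#'
#' @param pred,truth Equal-length numeric vectors in `[0, 1]`; `NA` pairs
#'   are dropped.
#' @param threshold Agreement threshold (default 0.25).
#' @return Scalar fraction in `[0, 1]`.
#' @export
concordance <- function(pred, truth, threshold = 0.25) {
  stopifnot(length(pred) == length(truth))
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok)) stop("no complete pairs")
  mean(abs(pred[ok] - truth[ok]) < threshold)
}

#' Pearson correlation between predicted and reference methylation
#'
#' Standard Pearson r; returns `NA` with a warning when either side has zero
#' variance or fewer than 3 complete pairs.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Scalar correlation, or `NA`.
#' @export
pcc <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  x <- pred[ok]; y <- truth[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Pearson correlation undefined (zero variance or n < 3)")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Prediction error stratified by local CpG density
#'
#' For each site, the CpG density of its flanking region (`flank` bp each
#' side) is the count of CpG sites within it; sites are binned on that count
#' (integer bins, small bins merged upward until each holds at least
#' `min_bin` sites) and median absolute error, concordance and n are
#' reported per bin.  A density-independent method shows flat per-bin
#' medians.
#'
#' @param pred,truth Per-site vectors aligned with `sites`.
#' @param sites CpG sites (GRanges).
#' @param flank Flank size in bp (default 500).
#' @param min_bin Minimum sites per reported bin (default 100).
#' @return data.frame: density_min, density_max, n, median_abs_diff,
#'   concordance.
#' @export
density_stratified_error <- function(pred, truth, sites, flank = 500,
                                     min_bin = 100) {
  ok <- !is.na(pred) & !is.na(truth)
  dens <- GenomicRanges::countOverlaps(
    suppressWarnings(IRanges::trim(sites + flank)), sites,
    ignore.strand = TRUE)
  d <- dens[ok]; p <- pred[ok]; t <- truth[ok]
  lev <- sort(unique(d))
  # merge consecutive integer density values until each bin is big enough
  bins <- list(); cur <- integer(0)
  for (v in lev) {
    cur <- c(cur, v)
    if (sum(d %in% cur) >= min_bin) { bins[[length(bins) + 1]] <- cur
                                      cur <- integer(0) }
  }
  if (length(cur)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    else bins[[1]] <- cur
  }
  do.call(rbind, lapply(bins, function(b) {
    i <- d %in% b
    data.frame(density_min = min(b), density_max = max(b), n = sum(i),
               median_abs_diff = stats::median(abs(p[i] - t[i])),
               concordance = concordance(p[i], t[i]))
  }))
}

#' No-read site discrimination test
#'
#' Among CpG sites with zero MeDIP coverage over their feature region, tests
#' whether predictions at unmethylated sites (reference level <=
#' `low`) are lower than at methylated sites (reference >= `high`), via a
#' one-sided Wilcoxon rank-sum test.  A model driven only by read counts
#' cannot separate the two groups; genomic features allow it to.
#'
#' @param pred,truth Per-site vectors (no-read sites only, or supply
#'   `no_read` to subset).
#' @param no_read Optional logical vector marking zero-coverage sites.
#' @param low,high Reference-level cutoffs defining the groups (defaults
#'   0.1, 0.9).
#' @return list(p_value, statistic, n_methylated, n_unmethylated), or a
#'   skipped marker when either group is empty.
#' @export
noread_discrimination <- function(pred, truth, no_read = NULL,
                                  low = 0.1, high = 0.9) {
  if (!is.null(no_read)) { pred <- pred[no_read]; truth <- truth[no_read] }
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  un <- pred[truth <= low]
  me <- pred[truth >= high]
  if (!length(un) || !length(me))
    return(list(skipped = TRUE, n_methylated = length(me),
                n_unmethylated = length(un)))
  wt <- stats::wilcox.test(un, me, alternative = "less", exact = FALSE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_methylated = length(me), n_unmethylated = length(un))
}

#' Mean methylation per annotated element instance
#'
#' Unweighted mean of a per-site quantity (predictions or reference levels)
#' over the CpG sites inside each individual annotation interval (each CpG
#' island, each promoter, ...).  Instances containing no site are dropped.
#'
#' @param values Per-site numeric vector aligned with `sites`.
#' @param sites CpG sites (GRanges).
#' @param instances GRanges of element instances (one row per interval).
#' @return data.frame: chrom, start, end, n_cpg, mean_value.
#' @export
regional_aggregate <- function(values, sites, instances) {
  hits <- GenomicRanges::findOverlaps(sites, instances, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ok <- !is.na(values[q])
  q <- q[ok]; s <- s[ok]
  if (!length(q))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0),
                      mean_value = numeric(0)))
  mv <- tapply(values[q], s, mean)
  nn <- tapply(q, s, length)
  keep <- as.integer(names(mv))
  data.frame(chrom = as.character(GenomicRanges::seqnames(instances[keep])),
             start = GenomicRanges::start(instances[keep]),
             end = GenomicRanges::end(instances[keep]),
             n_cpg = as.integer(nn), mean_value = as.numeric(mv),
             row.names = NULL)
}
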