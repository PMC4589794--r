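#' Feature region around a CpG site
#'
#' The 2m-bp window around the site's C: m-1 bp upstream and m bp downstream,
#' so the C sits at index m (1-based) of the region.  At the default m = 200
#' the region is the 400 bp window centred on the CpG.
#'
#' @param pos 1-based position(s) of the C.
#' @param m Half-size in bp (default 200).
#' @return data.frame with 1-based inclusive `start`, `end` (length 2m;
#'   regions may extend beyond the contig - callers zero-pad).
#' @export
feature_region <- function(pos, m = 200) {
  stopifnot(m >= 1)
  data.frame(start = pos - (m - 1), end = pos + m)
}

# Distance-decay weight functions for the coupling factor.  All map
# d in [0, m] to [0, 1], non-increasing, w(0) = 1.
cf_weight_fn <- function(weight = c("linear", "exponential", "tricube")) {
  if (is.function(weight)) return(weight)
  weight <- match.arg(weight)
  switch(weight,
         linear = function(d, m) pmax(0, 1 - d / m),
         exponential = function(d, m) exp(-3 * d / m),
         tricube = function(d, m) pmax(0, (1 - (d / m)^3))^3)
}

#' Per-base signal features for one CpG site
#'
#' `x_i` equals the RPM value at base i of the feature region when that base
#' is the C of a CpG dinucleotide, and 0 otherwise (including padding beyond
#' contig ends).
#'
#' @param pos 1-based position of the site's C.
#' @param track A `medip_track`.
#' @param cpg_pos Sorted 1-based positions of all CpG Cs on the chromosome.
#' @param chrom Chromosome name.
#' @param m Half-size (default 200).
#' @return Numeric vector of length 2m.
#' @export
signal_features <- function(pos, track, cpg_pos, chrom, m = 200) {
  reg <- feature_region(pos, m)
  x <- numeric(2 * m)
  inreg <- cpg_pos[cpg_pos >= reg$start & cpg_pos <= reg$end]
  if (length(inreg))
    x[inreg - reg$start + 1] <- track_values(track, chrom, inreg)
  x
}

#' Coupling factor of a CpG site
#'
#' Distance-weighted count of CpG Cs in the feature region:
#' `cf = sum_i w(|d_i|) * c_i`, where `c_i` is 1 at CpG Cs and `d_i` the
#' distance in bp from base i to the site.  The default weight is linear
#' decay `w(d) = 1 - d/m`, reaching 0 at the region edge; exponential and
#' tricube alternatives (or any function of `(d, m)` into `[0, 1]`) are
#' accepted.  The site's own CpG contributes w(0) = 1.
#'
#' @inheritParams signal_features
#' @param weight Weight function name or function(d, m).
#' @param signal Optional RPM values aligned with `cpg_pos`; when given, each
#'   CpG's contribution is additionally multiplied by its signal
#'   (sensitivity-analysis variant).
#' @return Scalar coupling factor.
#' @export
coupling_factor <- function(pos, cpg_pos, m = 200, weight = "linear",
                            signal = NULL) {
  wf <- cf_weight_fn(weight)
  reg <- feature_region(pos, m)
  keep <- cpg_pos >= reg$start & cpg_pos <= reg$end
  d <- abs(cpg_pos[keep] - pos)
  w <- wf(d, m)
  if (any(w < 0 | w > 1)) stop("weight function returned values outside [0,1]")
  if (!is.null(signal)) w <- w * signal[keep]
  sum(w)
}

#' Genome-derived features of a feature region
#'
#' GC fraction (N bases and off-contig padding count in the denominator,
#' matching bedtools `nuc` semantics), CpG density (count of CG dinucleotides
#' fully inside the region, divided by region length; the raw count is also
#' returned), and mean per-base conservation (missing scores and padding
#' contribute 0).
#'
#' @param pos 1-based position of the site's C.
#' @param genome DNAStringSet.
#' @param chrom Chromosome name.
#' @param cons Optional RleList of per-base conservation scores in `[0, 1]`.
#' @param m Half-size (default 200).
#' @return list(gc, cpg_density, cpg_count, cons).
#' @export
genome_features <- function(pos, genome, chrom, cons = NULL, m = 200) {
  reg <- feature_region(pos, m)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (reg$end < 1 || reg$start > len) stop("feature region fully off contig")
  s <- max(1, reg$start); e <- min(len, reg$end)
  seq <- Biostrings::subseq(genome[[chrom]], s, e)
  gc <- sum(Biostrings::letterFrequency(seq, c("G", "C"))) / (2 * m)
  n_cpg <- Biostrings::countPattern("CG", seq)
  cons_mean <- 0
  if (!is.null(cons) && chrom %in% names(cons)) {
    r <- cons[[chrom]]
    ce <- min(length(r), e)
    if (ce >= s) cons_mean <- sum(as.numeric(r[s:ce])) / (2 * m)
  }
  list(gc = gc, cpg_density = n_cpg / (2 * m), cpg_count = n_cpg,
       cons = cons_mean)
}

#' Assemble the full per-CpG feature table
#'
#' One row per site, `2m + 4` columns (404 at defaults): per-base signal
#' features `x0001..x0400`, coupling factor `cf`, GC fraction `gc`, CpG
#' density `cpg_density`, and mean conservation `cons`.  Column order is
#' fixed; output is deterministic given its inputs.
#'
#' @param sites CpG sites (GRanges, e.g. from [enumerate_cpg_sites()]).
#' @param track A `medip_track` (or `NULL` for a zero signal).
#' @param genome DNAStringSet.
#' @param cons Optional conservation RleList.
#' @param m Half-size (default 200).
#' @param weight Coupling-factor weight (see [coupling_factor()]).
#' @param signal_weighted_cf Use the signal-weighted coupling-factor variant.
#' @return Numeric matrix, rownames `chrom:pos`, with attribute `m`.
#' @export
mesic_features <- function(sites, track, genome, cons = NULL, m = 200,
                           weight = "linear", signal_weighted_cf = FALSE) {
  keys <- site_key(as.character(GenomicRanges::seqnames(sites)),
                   GenomicRanges::start(sites))
  if (anyDuplicated(keys)) stop("duplicate site keys")
  wf <- cf_weight_fn(weight)
  n <- length(sites)
  X <- matrix(0, n, 2 * m)
  cf <- numeric(n); gc <- numeric(n); dens <- numeric(n); cons_v <- numeric(n)
  chroms <- as.character(GenomicRanges::seqnames(sites))
  pos_all <- GenomicRanges::start(sites)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    pos <- pos_all[idx]
    len <- Biostrings::width(genome)[match(ch, names(genome))]
    cpg_pos <- IRanges::start(Biostrings::matchPattern("CG", genome[[ch]]))
    rpm <- if (is.null(track)) numeric(length(cpg_pos))
           else track_values(track, ch, cpg_pos)
    reg_start <- pos - (m - 1)
    # site x CpG co-occurrence within regions, vectorised via interval overlap
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(reg_start, pos + m),
      IRanges::IRanges(cpg_pos, width = 1))
    i <- S4Vectors::queryHits(ov); k <- S4Vectors::subjectHits(ov)
    X[cbind(idx[i], cpg_pos[k] - reg_start[i] + 1)] <- rpm[k]
    d <- abs(cpg_pos[k] - pos[i])
    w <- wf(d, m)
    if (any(w < 0 | w > 1)) stop("weight function returned values outside [0,1]")
    if (signal_weighted_cf) w <- w * rpm[k]
    cfc <- tapply(w, i, sum)
    cf[idx[as.integer(names(cfc))]] <- as.numeric(cfc)
    # genome features, batched per chromosome
    s <- pmax(1, reg_start); e <- pmin(len, pos + m)
    v <- Biostrings::Views(genome[[ch]], start = s, end = e)
    gcv <- rowSums(Biostrings::letterFrequency(v, c("G", "C")))
    gc[idx] <- gcv / (2 * m)
    cnt <- findInterval(e - 1, cpg_pos) - findInterval(s - 1, cpg_pos)
    dens[idx] <- cnt / (2 * m)
    if (!is.null(cons) && ch %in% names(cons)) {
      r <- cons[[ch]]
      cs <- c(0, cumsum(as.numeric(r)))
      ce <- pmin(length(r), e)
      cons_v[idx] <- (cs[ce + 1] - cs[s]) / (2 * m)
    }
  }
  out <- cbind(X, cf = cf, gc = gc, cpg_density = dens, cons = cons_v)
  colnames(out) <- c(sprintf("x%04d", seq_len(2 * m)),
                     "cf", "gc", "cpg_density", "cons")
  rownames(out) <- keys
  attr(out, "m") <- m
  out
}

#' Write a feature table as TSV (stable column names, one header row)
#' @param features Matrix from [mesic_features()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(site = rownames(features), features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a feature table written by [write_features()]
#' @param path File path.
#' @return Numeric matrix with site rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site
  attr(m, "m") <- (ncol(m) - 4) / 2
  m
}
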