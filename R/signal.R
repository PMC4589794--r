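#' Extend MeDIP-seq reads to the library fragment length
#'
#' Each read is replaced by an interval of exactly `length` bp anchored at its
#' 5' end in strand orientation (start fixed for `+`, end fixed for `-`), then
#' clipped to chromosome bounds.  Reads with unknown strand are treated as
#' `+` with a warning.
#'
#' @param reads GRanges of aligned reads (nonredundant, uniquely mapped).
#' @param length Fragment length in bp (default 200, the average sonicated
#'   fragment size of a typical MeDIP library).
#' @return GRanges of extended (possibly clipped) intervals.
#' @export
extend_reads <- function(reads, length = 200) {
  stopifnot(length >= 1)
  str <- as.character(GenomicRanges::strand(reads))
  if (any(str == "*")) {
    warning(sum(str == "*"), " reads with unknown strand treated as '+'")
    GenomicRanges::strand(reads)[str == "*"] <- "+"
  }
  out <- suppressWarnings(GenomicRanges::resize(reads, width = length,
                                                fix = "start"))
  suppressWarnings(IRanges::trim(out))
}

#' Build a per-base RPM signal track from extended reads
#'
#' Coverage pileup scaled to reads-per-million mapped:
#' `RPM = raw coverage * 1e6 / total reads`.  Duplicating every read leaves
#' the track unchanged; absent clipping, the raw coverage sums to
#' `n_reads * fragment_length`.
#'
#' @param reads GRanges of (already extended) reads with seqlengths set, or
#'   pass `seqlengths`.
#' @param seqlengths Optional named chromosome lengths.
#' @return An object of class `medip_track`: list with `rpm` (an RleList of
#'   per-base values), `total_reads`, and `seqlengths`.
#' @export
build_signal <- function(reads, seqlengths = NULL) {
  if (length(reads) == 0) stop("empty alignment")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(reads) <- names(seqlengths)
    GenomeInfoDb::seqlengths(reads) <- seqlengths
  }
  sl <- GenomeInfoDb::seqlengths(reads)
  if (any(is.na(sl))) stop("seqlengths required to build a signal track")
  cov <- GenomicRanges::coverage(reads)
  n <- length(reads)
  structure(list(rpm = cov * (1e6 / n), total_reads = n, seqlengths = sl),
            class = "medip_track")
}

#' @export
print.medip_track <- function(x, ...) {
  cat("MeDIP RPM signal track\n")
  cat("  chromosomes:", paste(names(x$seqlengths), collapse = ", "), "\n")
  cat("  total mapped reads:", x$total_reads, "\n")
  invisible(x)
}

# RPM values at 1-based positions on one chromosome (0 outside bounds).
track_values <- function(track, chrom, pos) {
  r <- track$rpm[[chrom]]
  out <- numeric(length(pos))
  ok <- pos >= 1 & pos <= length(r)
  if (any(ok)) out[ok] <- as.numeric(r[pos[ok]])
  out
}

#' Windowed signal/methylation summary
#'
#' Tiles the genome into non-overlapping windows and reports, for every
#' window containing at least one CpG site, the mean RPM over the window,
#' the mean reference 5mC over its CpGs, and the CpG count (the window's CpG
#' density).  This is the summary used to expose the CpG-density-dependent
#' bias of raw MeDIP signal.
#'
#' @param track A `medip_track`.
#' @param sites CpG sites (GRanges).
#' @param truth Numeric vector of per-site 5mC levels aligned with `sites`.
#' @param window Window size in bp (default 1000).
#' @return data.frame with columns chrom, start (1-based), end, mean_rpm,
#'   mean_5mc, cpg_count.
#' @export
window_summary <- function(track, sites, truth, window = 1000) {
  stopifnot(window >= 1, length(truth) == length(sites))
  tiles <- GenomicRanges::tileGenome(track$seqlengths, tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  hits <- GenomicRanges::findOverlaps(sites, tiles, ignore.strand = TRUE)
  w <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(w))
  mean_5mc <- tapply(truth[S4Vectors::queryHits(hits)], w, mean)
  cpg_count <- tapply(w, w, length)
  tl <- tiles[keep]
  v <- IRanges::Views(track$rpm,
                      methods::as(tl, "IntegerRangesList"))
  mean_rpm <- unlist(lapply(v, IRanges::viewMeans), use.names = FALSE)
  # Views over an RleList follow seqlevel order; tiles are already sorted.
  data.frame(chrom = as.character(GenomicRanges::seqnames(tl)),
             start = GenomicRanges::start(tl), end = GenomicRanges::end(tl),
             mean_rpm = as.numeric(mean_rpm),
             mean_5mc = as.numeric(mean_5mc),
             cpg_count = as.integer(cpg_count), row.names = NULL)
}

#' Group summary windows by CpG density
#'
#' Assigns each window to one of up to `n_groups` density groups
#' (equal-frequency bins on CpG count, duplicates merged), the layout used to
#' visualise density-dependent bias.
#'
#' @param ws Output of [window_summary()].
#' @param n_groups Target number of groups (default 18).
#' @return `ws` with an added integer `density_group` column.
#' @export
window_density_groups <- function(ws, n_groups = 18) {
  qs <- unique(stats::quantile(ws$cpg_count,
                               probs = seq_len(n_groups) / n_groups,
                               type = 1))
  grp <- cut(ws$cpg_count, breaks = c(-Inf, qs), labels = FALSE)
  ws$density_group <- as.integer(grp)
  ws
}

#' Write an RPM track as bedGraph
#' @param track A `medip_track`.
#' @param path Output path.
#' @export
write_signal_bedgraph <- function(track, path) {
  gr <- methods::as(track$rpm, "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  rtracklayer::export.bedGraph(gr[S4Vectors::mcols(gr)$score != 0], path)
}
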