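#' Enumerate CpG sites in a genome
#'
#' Scans every sequence for forward-strand `CG` dinucleotides and returns one
#' width-1 range per occurrence, anchored on the C.  Because CpG methylation
#' is symmetric, downstream code keys both strands of a CpG to this position.
#'
#' @param genome A [Biostrings::DNAStringSet] (or a named character vector of
#'   sequences, which is coerced).  Sequences must contain only A/C/G/T/N
#'   after uppercasing.
#' @return A [GenomicRanges::GRanges] of width-1 sites sorted by
#'   (chrom, pos), with `seqlengths` set; the `elements` metadata column is
#'   an empty [IRanges::CharacterList] until [classify_sites()] fills it.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chrT = "ACGTCGA"))
#' enumerate_cpg_sites(gen)
#' @export
enumerate_cpg_sites <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    chr <- toupper(as.character(genome))
    bad <- regexpr("[^ACGTN]", chr)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1]
      stop(sprintf("non-ACGTN character '%s' in sequence %s at position %d",
                   substring(chr[i], bad[i], bad[i]),
                   names(chr)[i] %||% as.character(i), bad[i]))
    }
    genome <- Biostrings::DNAStringSet(chr)
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must have unique names")
  af <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(bad > 0)) {
    ch <- names(genome)[which(bad > 0)[1]]
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    pos <- which(!s %in% c("A", "C", "G", "T", "N"))[1]
    stop(sprintf("non-ACGTN character '%s' in sequence %s at position %d",
                 s[pos], ch, pos))
  }
  hits <- Biostrings::vmatchPattern("CG", genome)
  grl <- lapply(names(genome), function(ch) {
    ir <- hits[[ch]]
    GenomicRanges::GRanges(rep(ch, length(ir)),
                           IRanges::IRanges(IRanges::start(ir), width = 1))
  })
  gr <- sort(do.call(c, grl))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
  S4Vectors::mcols(gr)$elements <- IRanges::CharacterList(
    rep(list(character(0)), length(gr)))
  gr
}

#' Build the 12 genomic-element category ranges from an annotation set
#'
#' Categories follow the usual UCSC-style definitions: CpG islands are merged;
#' shores are the 2 kb flanks of islands minus the islands; shelves the next
#' 2 kb minus islands and shores; promoters span TSS -2 kb / +1 kb in
#' transcription orientation; 5'/3' UTRs are the exonic parts outside the CDS;
#' introns are the gene span minus exons; repeats are split by class
#' (SINE/LINE/LTR).  "others" is never materialised here - it is assigned by
#' [classify_sites()] to sites matching no category.
#'
#' @param ann A list with components `cgi` (GRanges), `genes` (a gene table
#'   `data.frame`, see [read_gene_table()]) and `repeats` (GRanges with a
#'   `class` metadata column).  Any component may be missing.
#' @param seqlengths Named integer vector of chromosome lengths used to clip
#'   out-of-bounds intervals (with a warning).
#' @param shore_flank,shelf_flank Flank widths in bp (defaults 2000).
#' @param promoter_up,promoter_down Promoter window relative to the TSS in
#'   transcription orientation (defaults 2000 upstream, 1000 downstream).
#' @return A named [GenomicRanges::GRangesList] over the 11 stored categories.
#' @export
element_ranges <- function(ann, seqlengths = NULL,
                           shore_flank = 2000, shelf_flank = 2000,
                           promoter_up = 2000, promoter_down = 1000) {
  out <- list()
  empty <- GenomicRanges::GRanges()
  clip <- function(gr, warn = TRUE) {
    if (length(gr) == 0 || is.null(seqlengths)) return(gr)
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    if (warn && any(GenomicRanges::start(gr) < 1 |
            GenomicRanges::end(gr) > seqlengths[as.character(
              GenomicRanges::seqnames(gr))])) {
      warning("annotation intervals extend beyond chromosome bounds; clipped")
    }
    suppressWarnings(IRanges::trim(gr))
  }
  cgi <- if (!is.null(ann$cgi)) GenomicRanges::reduce(clip(ann$cgi)) else empty
  out$CGI <- cgi
  # flanks are carved out of each other: shore excludes CGI, shelf excludes
  # both; flank zones legitimately run past contig ends, hence warn = FALSE
  shore_zone <- GenomicRanges::reduce(clip(suppressWarnings(
    cgi + shore_flank), warn = FALSE))
  out$shore <- GenomicRanges::setdiff(shore_zone, cgi)
  shelf_zone <- GenomicRanges::reduce(clip(suppressWarnings(
    cgi + (shore_flank + shelf_flank)), warn = FALSE))
  out$shelf <- GenomicRanges::setdiff(shelf_zone,
                                      GenomicRanges::union(cgi, out$shore))

  if (!is.null(ann$genes) && nrow(ann$genes) > 0) {
    g <- ann$genes
    tx <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$txStart + 1, g$txEnd),
                                 strand = g$strand)
    out$promoter <- clip(suppressWarnings(GenomicRanges::promoters(
      tx, upstream = promoter_up, downstream = promoter_down)),
      warn = FALSE)
    parse_block <- function(starts, ends, i) {
      s <- as.integer(strsplit(starts[i], ",")[[1]])
      e <- as.integer(strsplit(ends[i], ",")[[1]])
      GenomicRanges::GRanges(g$chrom[i], IRanges::IRanges(s + 1, e),
                             strand = g$strand[i])
    }
    exons <- do.call(c, lapply(seq_len(nrow(g)), function(i)
      parse_block(g$exonStarts, g$exonEnds, i)))
    out$exon <- clip(exons)
    out$intron <- GenomicRanges::setdiff(
      GenomicRanges::reduce(tx, ignore.strand = TRUE),
      GenomicRanges::reduce(exons, ignore.strand = TRUE))
    # UTRs: exonic sequence outside the CDS, 5'/3' by strand
    utr5 <- empty; utr3 <- empty
    for (i in seq_len(nrow(g))) {
      if (g$cdsStart[i] >= g$cdsEnd[i]) next  # non-coding: no UTRs
      left <- GenomicRanges::GRanges(g$chrom[i],
               IRanges::IRanges(g$txStart[i] + 1, g$cdsStart[i]))
      right <- GenomicRanges::GRanges(g$chrom[i],
               IRanges::IRanges(g$cdsEnd[i] + 1, g$txEnd[i]))
      ex <- parse_block(g$exonStarts, g$exonEnds, i)
      if (g$strand[i] == "+") {
        utr5 <- c(utr5, GenomicRanges::intersect(left, ex, ignore.strand = TRUE))
        utr3 <- c(utr3, GenomicRanges::intersect(right, ex, ignore.strand = TRUE))
      } else {
        utr5 <- c(utr5, GenomicRanges::intersect(right, ex, ignore.strand = TRUE))
        utr3 <- c(utr3, GenomicRanges::intersect(left, ex, ignore.strand = TRUE))
      }
    }
    out$UTR5 <- clip(utr5)
    out$UTR3 <- clip(utr3)
  } else {
    out$promoter <- empty; out$exon <- empty; out$intron <- empty
    out$UTR5 <- empty; out$UTR3 <- empty
  }

  reps <- ann$repeats
  if (!is.null(reps) && length(reps) > 0) {
    cls <- as.character(S4Vectors::mcols(reps)$class)
    unknown <- !cls %in% c("SINE", "LINE", "LTR")
    if (any(unknown))
      message(sum(unknown), " repeat intervals with unknown class ignored")
    for (k in c("SINE", "LINE", "LTR"))
      out[[k]] <- clip(reps[!is.na(cls) & cls == k])
  } else {
    out$SINE <- empty; out$LINE <- empty; out$LTR <- empty
  }
  GenomicRanges::GRangesList(
    out[c("CGI", "shore", "shelf", "UTR5", "promoter", "exon", "intron",
          "UTR3", "SINE", "LINE", "LTR")])
}

#' Assign genomic-element categories to CpG sites
#'
#' Populates the `elements` metadata column of each site with every category
#' whose intervals overlap it.  Categories overlap by construction (a CpG in
#' an island inside an exon is both `CGI` and `exon`); `CGI`/`shore`/`shelf`
#' are mutually exclusive because the flanks are carved out of each other;
#' `others` is assigned, alone, to sites matching nothing else.
#'
#' @param sites GRanges from [enumerate_cpg_sites()].
#' @param ann Annotation list (see [element_ranges()]), or a precomputed
#'   `GRangesList` of category ranges.
#' @param ... Passed to [element_ranges()] (flank and promoter widths).
#' @return `sites` with the `elements` CharacterList filled in.  Idempotent.
#' @export
classify_sites <- function(sites, ann, ...) {
  er <- if (methods::is(ann, "GRangesList")) ann
        else element_ranges(ann, seqlengths = GenomeInfoDb::seqlengths(sites), ...)
  lab <- matrix(FALSE, length(sites), length(er),
                dimnames = list(NULL, names(er)))
  for (k in names(er))
    lab[, k] <- IRanges::overlapsAny(sites, er[[k]], ignore.strand = TRUE)
  el <- apply(lab, 1, function(r) names(er)[r], simplify = FALSE)
  none <- lengths(el) == 0
  el[none] <- list("others")
  S4Vectors::mcols(sites)$elements <- IRanges::CharacterList(el)
  sites
}

#' Read a UCSC-style gene table
#'
#' Tab-separated with header columns `name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonStarts, exonEnds`; coordinates 0-based half-open,
#' exon blocks comma-separated (UCSC knownGene dialect).
#'
#' @param path File path.
#' @return A `data.frame` with those columns.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  need <- c("name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  g
}

#' Write a gene table (inverse of [read_gene_table()])
#' @param genes Gene table data.frame.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
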