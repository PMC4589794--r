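#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic methylome / MeDIP-seq
#' generator, with defaults chosen to mirror the data regime the estimator
#' targets: a 30 kb toy genome with CpG islands of >= 5x background CpG
#' density, element-conditional methylation mixtures (unimodal low in
#' islands, bimodal at promoters, multimodal in introns, unimodal high in
#' CpG-poor contexts), neighbour-correlated levels, 200 bp MeDIP fragments
#' captured in proportion to their summed methylated-CpG content, a
#' 2e5-read library, and 50x BS/TAB coverage with non-conversion rates
#' 0.5% / 2.2%.  Unknown arguments are rejected.
#'
#' @param seed Master seed; fully determines all outputs.
#' @param genome_length Toy genome length in bp (>= 10000).
#' @param chrom Chromosome name.
#' @param background_cpg_spacing,cgi_cpg_spacing Mean gap in bp between
#'   consecutive CpGs outside / inside islands (defaults 40, 7).
#' @param fragment_length,read_length MeDIP fragment and read lengths
#'   (defaults 200, 50).
#' @param library_size Number of MeDIP reads (default 2e5).
#' @param capture_background Baseline capture weight per fragment
#'   (`epsilon`; default 0.05).
#' @param dropout Optional data.frame(start, end): fragments overlapping
#'   these intervals are never captured (models assay dropout).
#' @param force_levels Optional data.frame(start, end, level) overriding the
#'   simulated methylome inside the intervals (planted fixtures).
#' @param coverage Mean per-site BS/TAB read depth (default 50).
#' @param nonconversion_bs,nonconversion_tab Non-conversion rates (0.005,
#'   0.022).
#' @param hmc_fraction Fraction of methylated sites carrying 5hmC
#'   (default 0.05).
#' @param hmc_level_range 5hmC level range at those sites.
#' @param neighbor_corr_length Length scale (bp) of the latent correlation
#'   kernel linking neighbouring CpGs (default 200).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, genome_length = 30000, chrom = "chrS",
                       background_cpg_spacing = 40, cgi_cpg_spacing = 7,
                       fragment_length = 200, read_length = 50,
                       library_size = 2e5, capture_background = 0.05,
                       dropout = NULL, force_levels = NULL, coverage = 50,
                       nonconversion_bs = 0.005, nonconversion_tab = 0.022,
                       hmc_fraction = 0.05, hmc_level_range = c(0.05, 0.25),
                       neighbor_corr_length = 200) {
  stopifnot(genome_length >= 10000, library_size >= 1,
            nonconversion_bs >= 0, nonconversion_bs <= 1,
            nonconversion_tab >= 0, nonconversion_tab <= 1,
            hmc_fraction >= 0, hmc_fraction <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Proportional element layout of the toy genome: two genes (one per strand)
# with UTR/exon/intron structure, a CGI at each TSS plus one intergenic CGI,
# and one SINE/LINE/LTR block each.  Fractions of genome_length.
sim_layout <- function(L) {
  gene <- function(t0, t1, strand) {
    span <- t1 - t0
    ex_rel <- rbind(c(0, .18), c(.3, .38), c(.5, .58), c(.75, 1))
    ex <- round(L * (t0 + ex_rel * span))
    list(t0 = round(L * t0), t1 = round(L * t1), strand = strand,
         cds0 = round(L * (t0 + .10 * span)),
         cds1 = round(L * (t0 + .85 * span)),
         ex_start = ex[, 1], ex_end = ex[, 2])
  }
  g1 <- gene(.08, .34, "+")
  g2 <- gene(.52, .78, "-")
  # for the minus-strand gene the TSS is at t1; its CGI sits there
  cgi <- round(L * rbind(c(.075, .105), c(.44, .47), c(.765, .795)))
  reps <- data.frame(start = round(L * c(.36, .80, .86)),
                     end = round(L * c(.39, .84, .89)),
                     class = c("SINE", "LINE", "LTR"))
  list(genes = list(g1, g2), cgi = cgi, repeats = reps)
}

#' Simulate the toy genome, annotations and conservation track
#'
#' Builds a random DNA sequence containing CpG dinucleotides only where the
#' generator plants them: at mean spacing `cgi_cpg_spacing` inside CpG
#' islands and `background_cpg_spacing` elsewhere (every stray CG arising
#' from the random background is destroyed first, so CpG density is fully
#' controlled).  Gene models, repeat blocks and a smooth conservation track
#' (elevated over exons and islands) complete the annotation set.
#'
#' @param cfg A [sim_config()].
#' @return list(genome = DNAStringSet, ann = list(cgi, genes, repeats),
#'   cons = RleList).
#' @export
simulate_genome <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1))
  L <- cfg$genome_length
  lay <- sim_layout(L)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(.3, .2, .2, .3))
  # destroy accidental CG dinucleotides
  is_cg <- which(base[-L] == "C" & base[-1] == "G")
  base[is_cg + 1] <- sample(c("A", "T"), length(is_cg), replace = TRUE)
  # plant CpGs segment by segment
  cgi_gr <- IRanges::IRanges(lay$cgi[, 1], lay$cgi[, 2])
  in_cgi <- IRanges::coverage(cgi_gr, width = L) > 0
  place <- function(from, to, spacing) {
    if (to - from < spacing) return(integer(0))
    n_max <- ceiling((to - from) / max(spacing - 2, 1)) + 10
    gaps <- pmax(2, round(stats::rexp(n_max, 1 / spacing)))
    p <- from + cumsum(gaps)
    p[p <= to - 1]
  }
  cpg <- integer(0)
  bounds <- sort(unique(c(1, lay$cgi[, 1], lay$cgi[, 2] + 1, L)))
  for (i in seq_len(length(bounds) - 1)) {
    seg <- c(bounds[i], bounds[i + 1] - 1)
    sp <- if (as.logical(in_cgi[seg[1]])) cfg$cgi_cpg_spacing
          else cfg$background_cpg_spacing
    cpg <- c(cpg, place(seg[1], seg[2], sp))
  }
  cpg <- cpg[cpg >= 2 & cpg <= L - 1]
  cpg <- cpg[c(TRUE, diff(cpg) >= 2)]
  base[cpg] <- "C"; base[cpg + 1] <- "G"
  genome <- Biostrings::DNAStringSet(structure(paste(base, collapse = ""),
                                               names = cfg$chrom))
  # annotations
  cgi <- GenomicRanges::GRanges(cfg$chrom, cgi_gr)
  genes <- do.call(rbind, lapply(seq_along(lay$genes), function(i) {
    g <- lay$genes[[i]]
    data.frame(name = paste0("gene", i), chrom = cfg$chrom,
               strand = g$strand, txStart = g$t0 - 1, txEnd = g$t1,
               cdsStart = g$cds0 - 1, cdsEnd = g$cds1,
               exonStarts = paste(g$ex_start - 1, collapse = ","),
               exonEnds = paste(g$ex_end, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  reps <- GenomicRanges::GRanges(cfg$chrom,
            IRanges::IRanges(lay$repeats$start, lay$repeats$end),
            class = lay$repeats$class)
  # conservation: elevated over exons and islands, smoothed noise elsewhere
  elev <- IRanges::coverage(c(cgi_gr, IRanges::IRanges(
    unlist(lapply(lay$genes, `[[`, "ex_start")),
    unlist(lapply(lay$genes, `[[`, "ex_end")))), width = L) > 0
  noise <- stats::filter(stats::rnorm(L, 0, 0.25), rep(1 / 25, 25),
                         circular = TRUE)
  cons_v <- clamp01(0.15 + 0.55 * as.numeric(elev) + as.numeric(noise))
  cons <- methods::as(stats::setNames(list(S4Vectors::Rle(cons_v)),
                                      cfg$chrom), "RleList")
  list(genome = genome, ann = list(cgi = cgi, genes = genes, repeats = reps),
       cons = cons)
}

# Element-conditional beta-mixture parameters (weights, shape1, shape2).
sim_mixtures <- function() {
  list(CGI      = list(p = 1, a = 1.5, b = 10),
       promoter = list(p = c(.5, .5), a = c(1.5, 10), b = c(10, 1.5)),
       shore    = list(p = c(.4, .6), a = c(2, 8), b = c(8, 2)),
       intron   = list(p = c(.25, .25, .5), a = c(2, 15, 10),
                       b = c(10, 15, 2)),
       default  = list(p = 1, a = 6, b = 1.5))
}

# Priority used to pick the generating element for multi-label sites.
sim_priority <- c("CGI", "promoter", "shore", "intron", "UTR5", "UTR3",
                  "exon", "shelf", "SINE", "LINE", "LTR", "others")

#' Simulate per-CpG 5mC levels
#'
#' Levels are drawn from element-conditional beta mixtures through a
#' Gaussian-copula construction: a latent Gaussian process with
#' exponential-decay correlation over genomic distance (length scale
#' `neighbor_corr_length`) is pushed through each element's mixture quantile
#' function, giving exact mixture marginals plus the neighbour correlation
#' real methylomes show.  `force_levels` intervals are applied last.
#'
#' @param cfg A [sim_config()].
#' @param sites Classified CpG sites (GRanges with `elements`).
#' @return list(level = 5mC vector, hmc = 5hmC vector) aligned with `sites`.
#' @export
simulate_methylome <- function(cfg, sites) {
  set.seed(derive_seed(cfg$seed, 2))
  n <- length(sites)
  pos <- GenomicRanges::start(sites)
  # latent correlated uniforms
  S <- exp(-abs(outer(pos, pos, "-")) / cfg$neighbor_corr_length)
  diag(S) <- diag(S) + 1e-8
  z <- as.numeric(t(chol(S)) %*% stats::rnorm(n))
  u <- stats::pnorm(z)
  # generating element per site
  el <- as.list(S4Vectors::mcols(sites)$elements)
  prim <- vapply(el, function(e) sim_priority[min(match(e, sim_priority))],
                 character(1))
  mix <- sim_mixtures()
  lev <- numeric(n)
  for (e in unique(prim)) {
    mx <- mix[[e]] %||% mix$default
    i <- which(prim == e)
    cum <- cumsum(mx$p)
    comp <- findInterval(u[i], c(0, utils::head(cum, -1)))
    lo <- c(0, utils::head(cum, -1))[comp]
    u_loc <- (u[i] - lo) / mx$p[comp]
    lev[i] <- stats::qbeta(pmin(pmax(u_loc, 1e-12), 1 - 1e-12),
                           mx$a[comp], mx$b[comp])
  }
  if (!is.null(cfg$force_levels)) {
    for (r in seq_len(nrow(cfg$force_levels))) {
      f <- cfg$force_levels[r, ]
      lev[pos >= f$start & pos <= f$end] <- f$level
    }
  }
  meth <- lev > 0.5
  has_hmc <- meth & stats::rbinom(n, 1, cfg$hmc_fraction) == 1
  hmc <- numeric(n)
  hmc[has_hmc] <- stats::runif(sum(has_hmc), cfg$hmc_level_range[1],
                               cfg$hmc_level_range[2])
  hmc <- pmin(hmc, 1 - lev)
  list(level = lev, hmc = hmc)
}

#' Simulate a MeDIP-seq read set
#'
#' Fragments of `fragment_length` bp are sampled with probability
#' proportional to `epsilon + sum(5mC levels of the CpGs they cover)` -
#' antibody capture driven by methylated-CpG content, with a small
#' background rate for unmethylated fragments.  Each fragment yields one
#' `read_length`-bp read from a random end (so 5'-anchored extension back to
#' the fragment length reconstructs it).  Fragments overlapping a configured
#' `dropout` interval are never captured.
#'
#' @param cfg A [sim_config()].
#' @param truth Per-site 5mC levels.
#' @param sites CpG sites (GRanges).
#' @return GRanges of reads (with seqlengths); empty when nothing is
#'   capturable.
#' @export
simulate_medip <- function(cfg, truth, sites) {
  set.seed(derive_seed(cfg$seed, 3))
  L <- cfg$genome_length; fl <- cfg$fragment_length; rl <- cfg$read_length
  lvl <- numeric(L)
  lvl[GenomicRanges::start(sites)] <- truth
  cs <- c(0, cumsum(lvl))
  n_s <- L - fl + 1
  s_all <- seq_len(n_s)
  w <- cs[s_all + fl] - cs[s_all] + cfg$capture_background
  if (!is.null(cfg$dropout)) {
    for (r in seq_len(nrow(cfg$dropout))) {
      d <- cfg$dropout[r, ]
      w[s_all + fl - 1 >= d$start & s_all <= d$end] <- 0
    }
  }
  sl <- stats::setNames(L, cfg$chrom)
  if (sum(w) <= 0) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    return(gr)
  }
  starts <- sample.int(n_s, cfg$library_size, replace = TRUE, prob = w)
  minus <- stats::runif(cfg$library_size) < 0.5
  rs <- ifelse(minus, starts + fl - rl, starts)
  gr <- GenomicRanges::GRanges(cfg$chrom,
          IRanges::IRanges(rs, width = rl),
          strand = ifelse(minus, "-", "+"))
  GenomeInfoDb::seqlengths(gr) <- sl
  sort(gr)
}

#' Simulate BS-seq and TAB-seq count tables
#'
#' Per site, read depths are Poisson with the configured mean; BS C-counts
#' are binomial with success probability `5mC + 5hmC` plus non-conversion
#' leakage, TAB C-counts binomial at `5hmC` plus its leakage.
#'
#' @param cfg A [sim_config()].
#' @param truth,hmc Per-site 5mC / 5hmC levels.
#' @param sites CpG sites.
#' @return list(bs, tab): pileup data.frames (chrom, pos, strand, count_c,
#'   count_t).
#' @export
simulate_bisulfite <- function(cfg, truth, hmc, sites) {
  set.seed(derive_seed(cfg$seed, 4))
  n <- length(sites)
  pos <- GenomicRanges::start(sites)
  mk <- function(p_true, rate) {
    N <- stats::rpois(n, cfg$coverage)
    p <- clamp01(p_true) * (1 - rate) + rate
    nc <- stats::rbinom(n, N, p)
    data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
               pos = pos, strand = "+", count_c = nc, count_t = N - nc,
               stringsAsFactors = FALSE)
  }
  list(bs = mk(truth + hmc, cfg$nonconversion_bs),
       tab = mk(hmc, cfg$nonconversion_tab))
}

#' Simulate a complete dataset
#'
#' Runs genome, annotation, methylome, MeDIP and bisulfite simulation under
#' one master seed and returns everything the estimator consumes.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `mesic_dataset`: config, genome, ann, cons,
#'   classified sites, truth/hmc vectors, reads, bs/tab tables.
#' @export
simulate_mesic_data <- function(cfg = sim_config()) {
  gen <- simulate_genome(cfg)
  sites <- classify_sites(enumerate_cpg_sites(gen$genome), gen$ann)
  me <- simulate_methylome(cfg, sites)
  reads <- simulate_medip(cfg, me$level, sites)
  bt <- simulate_bisulfite(cfg, me$level, me$hmc, sites)
  structure(list(config = cfg, genome = gen$genome, ann = gen$ann,
                 cons = gen$cons, sites = sites, truth = me$level,
                 hmc = me$hmc, reads = reads, bs = bt$bs, tab = bt$tab),
            class = "mesic_dataset")
}

#' @export
print.mesic_dataset <- function(x, ...) {
  cat("Synthetic MeDIP-seq dataset\n")
  cat("  genome:", x$config$genome_length, "bp;", length(x$sites),
      "CpG sites\n")
  cat("  reads:", length(x$reads), " BS/TAB coverage:",
      x$config$coverage, "x\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Produces `ref.fa`, `cgi.bed`, `genes.txt`, `rmsk.bed`, `cons.bedGraph`,
#' `reads.bed`, `bs.tsv`, `tab.tsv` and `truth_true.tsv` under `dir`.
#'
#' @param data A `mesic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesic_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(data$genome, fp("ref.fa"))
  rtracklayer::export.bed(data$ann$cgi, fp("cgi.bed"))
  reps <- data$ann$repeats
  S4Vectors::mcols(reps)$name <- S4Vectors::mcols(reps)$class
  rtracklayer::export.bed(reps, fp("rmsk.bed"))
  write_gene_table(data$ann$genes, fp("genes.txt"))
  cons_gr <- methods::as(data$cons, "GRanges")
  names(S4Vectors::mcols(cons_gr)) <- "score"
  rtracklayer::export.bedGraph(cons_gr, fp("cons.bedGraph"))
  rtracklayer::export.bed(data$reads, fp("reads.bed"))
  utils::write.table(data$bs, fp("bs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$tab, fp("tab.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(data$sites)),
    pos = GenomicRanges::start(data$sites),
    level_5mc = data$truth, level_5hmc = data$hmc)
  utils::write.table(truth, fp("truth_true.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
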