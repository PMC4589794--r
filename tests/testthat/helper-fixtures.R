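# Shared fixtures, built once per test run.

.fixtures <- new.env()

cl01_eval <- function(x) pmin(1, pmax(0, x))

# default-condition simulated dataset (30 kb genome, 2e5 reads, 50x BS/TAB)
default_sim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_mesic_data(sim_config(seed = seed))
  .fixtures[[key]]
}

# larger fixture (~2000 CpG sites) for null-correlation checks, where the
# default 30 kb genome leaves too few independent regions
large_sim <- function(seed = 4) {
  key <- paste0("lsim", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_mesic_data(
      sim_config(seed = seed, genome_length = 60000))
  .fixtures[[key]]
}

# small hand-built genome with a couple of planted CpGs for feature tests
toy_genome <- function(seq = NULL, name = "chrT") {
  if (is.null(seq)) {
    set.seed(42)
    base <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                   prob = c(.3, .2, .2, .3))
    cg <- which(base[-2000] == "C" & base[-1] == "G")
    base[cg + 1] <- "T"
    for (p in seq(25, 1950, by = 37)) { base[p] <- "C"; base[p + 1] <- "G" }
    seq <- paste(base, collapse = "")
  }
  Biostrings::DNAStringSet(stats::setNames(seq, name))
}

# random read set over a genome, as GRanges with seqlengths
random_reads <- function(n, genome, width = 50, seed = 1) {
  set.seed(seed)
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  ch <- sample(names(sl), n, replace = TRUE)
  st <- sapply(sl[ch] - width, function(m) sample.int(m, 1))
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = width),
          strand = sample(c("+", "-"), n, replace = TRUE))
  GenomeInfoDb::seqlengths(gr) <- sl
  sort(gr)
}

# independent per-site element oracle used against classify_sites()
brute_force_labels <- function(pos, ann, L,
                               shore_flank = 2000, shelf_flank = 2000,
                               promoter_up = 2000, promoter_down = 1000) {
  # plain-arithmetic reimplementation on 1-based inclusive intervals
  cgi <- cbind(GenomicRanges::start(ann$cgi), GenomicRanges::end(ann$cgi))
  in_any <- function(p, iv) nrow(iv) > 0 &&
    any(p >= iv[, 1] & p <= iv[, 2])
  labels <- character(0)
  in_cgi <- in_any(pos, cgi)
  if (in_cgi) labels <- c(labels, "CGI")
  near <- function(d) nrow(cgi) > 0 && any(
    pos >= pmax(1, cgi[, 1] - d) & pos <= pmin(L, cgi[, 2] + d))
  if (!in_cgi && near(shore_flank)) labels <- c(labels, "shore")
  if (!in_cgi && !near(shore_flank) && near(shore_flank + shelf_flank))
    labels <- c(labels, "shelf")
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    tx0 <- g$txStart[i] + 1; tx1 <- g$txEnd[i]
    ex0 <- as.integer(strsplit(g$exonStarts[i], ",")[[1]]) + 1
    ex1 <- as.integer(strsplit(g$exonEnds[i], ",")[[1]])
    in_ex <- any(pos >= ex0 & pos <= ex1)
    if (g$strand[i] == "+") {
      prom <- c(tx0 - promoter_up, tx0 + promoter_down - 1)
      utr5 <- c(tx0, g$cdsStart[i])
      utr3 <- c(g$cdsEnd[i] + 1, tx1)
    } else {
      prom <- c(tx1 - promoter_down + 1, tx1 + promoter_up)
      utr5 <- c(g$cdsEnd[i] + 1, tx1)
      utr3 <- c(tx0, g$cdsStart[i])
    }
    if (pos >= prom[1] && pos <= prom[2]) labels <- c(labels, "promoter")
    if (in_ex) {
      labels <- c(labels, "exon")
      if (g$cdsStart[i] < g$cdsEnd[i]) {
        if (pos >= utr5[1] && pos <= utr5[2]) labels <- c(labels, "UTR5")
        if (pos >= utr3[1] && pos <= utr3[2]) labels <- c(labels, "UTR3")
      }
    }
    if (pos >= tx0 && pos <= tx1 && !in_ex) {
      # intron only where no exon of any gene covers the site
      all_ex <- lapply(seq_len(nrow(g)), function(j) rbind(
        as.integer(strsplit(g$exonStarts[j], ",")[[1]]) + 1,
        as.integer(strsplit(g$exonEnds[j], ",")[[1]])))
      covered <- any(vapply(all_ex, function(e)
        any(pos >= e[1, ] & pos <= e[2, ]), logical(1)))
      if (!covered) labels <- c(labels, "intron")
    }
  }
  reps <- ann$repeats
  if (length(reps) > 0) {
    cls <- as.character(S4Vectors::mcols(reps)$class)
    for (k in c("SINE", "LINE", "LTR")) {
      iv <- cbind(GenomicRanges::start(reps[cls == k]),
                  GenomicRanges::end(reps[cls == k]))
      if (in_any(pos, iv)) labels <- c(labels, k)
    }
  }
  if (length(labels) == 0) labels <- "others"
  sort(unique(labels))
}
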