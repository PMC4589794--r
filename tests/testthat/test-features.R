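# brute-force per-base oracle for one site's signal vector and cf
oracle_site <- function(pos, seq, dense_rpm, m, wfun) {
  x <- numeric(2 * m); cf <- 0
  for (i in seq_len(2 * m)) {
    g <- pos - m + i
    if (g < 1 || g + 1 > nchar(seq)) next
    if (substring(seq, g, g + 1) == "CG") {
      x[i] <- dense_rpm[g]
      cf <- cf + wfun(abs(g - pos), m)
    }
  }
  list(x = x, cf = cf)
}

test_that("the feature region spans m-1 bp upstream and m bp downstream", {
  r <- feature_region(1000, 200)
  expect_equal(c(r$start, r$end), c(801, 1200))
  expect_equal(r$end - r$start + 1, 400)
  r1 <- feature_region(7, 1)
  expect_equal(c(r1$start, r1$end), c(7, 8))
})

test_that("feature table has width 2m+4 with the documented column order", {
  d <- default_sim()
  track <- build_signal(extend_reads(d$reads, 200))
  f <- mesic_features(d$sites[1:5], track, d$genome, d$cons, m = 200)
  expect_equal(ncol(f), 404)
  expect_equal(colnames(f)[c(1, 400, 401:404)],
               c("x0001", "x0400", "cf", "gc", "cpg_density", "cons"))
  f50 <- mesic_features(d$sites[1:5], track, d$genome, d$cons, m = 50)
  expect_equal(ncol(f50), 104)
})

test_that("signal features and coupling factor match the brute-force oracle", {
  d <- default_sim()
  track <- build_signal(extend_reads(d$reads, 200))
  seq <- as.character(d$genome[[1]])
  dense <- as.numeric(track$rpm[[1]])
  m <- 60
  set.seed(31)
  idx <- sample(length(d$sites), 100)
  f <- mesic_features(d$sites[idx], track, d$genome, d$cons, m = m)
  wlin <- function(d_, m_) pmax(0, 1 - d_ / m_)
  pos <- GenomicRanges::start(d$sites)[idx]
  for (j in seq_along(idx)) {
    o <- oracle_site(pos[j], seq, dense, m, wlin)
    expect_equal(unname(f[j, seq_len(2 * m)]), o$x)
    expect_equal(unname(f[j, "cf"]), o$cf)
  }
})

test_that("genome features match independent character-count oracles", {
  d <- default_sim()
  seq <- as.character(d$genome[[1]])
  cons_dense <- as.numeric(d$cons[[1]])
  m <- 60
  set.seed(33)
  idx <- sample(length(d$sites), 100)
  f <- mesic_features(d$sites[idx], NULL, d$genome, d$cons, m = m)
  pos <- GenomicRanges::start(d$sites)[idx]
  for (j in seq_along(idx)) {
    s <- max(1, pos[j] - (m - 1)); e <- min(nchar(seq), pos[j] + m)
    chars <- strsplit(substring(seq, s, e), "")[[1]]
    expect_equal(unname(f[j, "gc"]), sum(chars %in% c("G", "C")) / (2 * m))
    ncg <- sum(chars[-length(chars)] == "C" & chars[-1] == "G")
    expect_equal(unname(f[j, "cpg_density"]), ncg / (2 * m))
    expect_equal(unname(f[j, "cons"]), sum(cons_dense[s:e]) / (2 * m))
  }
  # degenerate sequences
  g2 <- Biostrings::DNAStringSet(c(t1 = strrep("AT", 300),
                                   t2 = strrep("CG", 300)))
  gf_at <- genome_features(300, g2, "t1", m = 50)
  expect_equal(gf_at$gc, 0)
  expect_equal(gf_at$cpg_density, 0)
  # site-centred 400 bp window on a pure CG lattice: all-GC, 199 whole CGs
  gf_cg <- genome_features(301, g2, "t2", m = 200)
  expect_equal(gf_cg$gc, 1)
  expect_equal(gf_cg$cpg_count, 199)
  expect_equal(gf_cg$cpg_density, 199 / 400)
})

test_that("coupling factor boundary weights and monotonicity", {
  # only the site's own CpG: cf = w(0) = 1
  expect_equal(coupling_factor(500, cpg_pos = 500, m = 200), 1)
  # second CpG exactly at distance m contributes weight 0 under linear decay
  expect_equal(coupling_factor(500, cpg_pos = c(500, 700), m = 200), 1)
  # adding CpGs never decreases cf, for any admissible weight
  for (w in list("linear", "exponential", "tricube")) {
    set.seed(40)
    base <- sort(sample(300:700, 10))
    cf1 <- coupling_factor(500, base, m = 200, weight = w)
    cf2 <- coupling_factor(500, sort(c(base, 444)), m = 200, weight = w)
    expect_gte(cf2, cf1)
  }
  expect_error(coupling_factor(500, c(500, 600), m = 200,
                               weight = function(d, m) d * 2),
               "outside")
})

test_that("signal and genome features are independent", {
  d <- default_sim()
  idx <- seq(1, length(d$sites), by = 10)
  f0 <- mesic_features(d$sites[idx], NULL, d$genome, d$cons, m = 100)
  track <- build_signal(extend_reads(d$reads, 200))
  f1 <- mesic_features(d$sites[idx], track, d$genome, d$cons, m = 100)
  expect_true(all(f0[, 1:200] == 0))
  expect_equal(f0[, c("cf", "gc", "cpg_density", "cons")],
               f1[, c("cf", "gc", "cpg_density", "cons")])
})

test_that("features are translation-equivariant", {
  pad <- 500
  seq <- as.character(toy_genome()[[1]])
  gA <- Biostrings::DNAStringSet(c(chrT = seq))
  gB <- Biostrings::DNAStringSet(c(chrT = paste0(strrep("A", pad), seq)))
  reads <- random_reads(60, gA, seed = 13)
  slB <- c(chrT = nchar(seq) + pad)
  readsB <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(GenomicRanges::start(reads) + pad,
                     GenomicRanges::end(reads) + pad),
    strand = GenomicRanges::strand(reads), seqlengths = slB)
  consA <- methods::as(stats::setNames(
    list(S4Vectors::Rle(runif(nchar(seq)))), "chrT"), "RleList")
  consB <- methods::as(stats::setNames(
    list(S4Vectors::Rle(c(numeric(pad), as.numeric(consA[[1]])))), "chrT"),
    "RleList")
  sA <- enumerate_cpg_sites(gA)
  keep <- GenomicRanges::start(sA) > 150 & GenomicRanges::start(sA) < 1850
  sA <- sA[keep]
  sB <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(GenomicRanges::start(sA) + pad, width = 1),
    seqlengths = slB)
  fA <- mesic_features(sA, build_signal(extend_reads(reads, 200)),
                       gA, consA, m = 100)
  fB <- mesic_features(sB, build_signal(extend_reads(readsB, 200)),
                       gB, consB, m = 100)
  expect_equal(unname(fA), unname(fB))
})

test_that("assembly is deterministic and rejects duplicate sites", {
  d <- default_sim()
  track <- build_signal(extend_reads(d$reads, 200))
  idx <- 1:50
  f1 <- mesic_features(d$sites[idx], track, d$genome, d$cons, m = 50)
  f2 <- mesic_features(d$sites[idx], track, d$genome, d$cons, m = 50)
  expect_identical(f1, f2)
  tf <- tempfile(); write_features(f1, tf)
  f3 <- read_features(tf)
  expect_equal(unname(f1), unname(f3), tolerance = 1e-12)
  expect_error(
    mesic_features(c(d$sites[1], d$sites[1]), track, d$genome, d$cons),
    "duplicate")
})
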