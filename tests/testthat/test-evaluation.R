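test_that("concordance is the fraction of pairs agreeing within threshold", {
  x <- runif(50)
  expect_equal(concordance(x, x), 1)
  t0 <- runif(200, 0.05, 0.65)
  expect_equal(concordance(t0 + 0.3, t0), 0)
  expect_error(concordance(numeric(0), numeric(0)))
  # loop oracle on random pairs
  set.seed(3)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    p <- runif(n); t <- runif(n)
    cnt <- 0
    for (j in seq_len(n)) if (abs(p[j] - t[j]) < 0.25) cnt <- cnt + 1
    expect_equal(concordance(p, t), cnt / n)
  }
})

test_that("pcc is Pearson r with affine invariance and guards", {
  t0 <- runif(100)
  expect_equal(pcc(2 * t0 - 0.1, t0), 1)
  expect_equal(pcc(-t0, t0), -1)
  expect_warning(r <- pcc(rep(0.4, 10), runif(10)), "zero variance")
  expect_true(is.na(r))
  # textbook-formula oracle
  set.seed(4)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- runif(n); y <- runif(n) + 0.3 * x
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pcc(x, y), num / den, tolerance = 1e-12)
  }
})

test_that("density-stratified error recovers overall metrics in one bin", {
  d <- default_sim()
  set.seed(6)
  pred <- cl01_eval(d$truth + rnorm(length(d$truth), 0, 0.1))
  tab1 <- density_stratified_error(pred, d$truth, d$sites,
                                   min_bin = length(d$sites))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$concordance, concordance(pred, d$truth))
  expect_equal(tab1$median_abs_diff, median(abs(pred - d$truth)))

  # per-bin brute force
  tab <- density_stratified_error(pred, d$truth, d$sites, min_bin = 100)
  expect_true(all(tab$n >= 100))
  pos <- GenomicRanges::start(d$sites)
  dens <- sapply(pos, function(p) sum(pos >= p - 500 & pos <= p + 500))
  for (r in seq_len(nrow(tab))) {
    i <- dens >= tab$density_min[r] & dens <= tab$density_max[r]
    expect_equal(tab$n[r], sum(i))
    expect_equal(tab$median_abs_diff[r], median(abs(pred[i] - d$truth[i])))
    expect_equal(tab$concordance[r], concordance(pred[i], d$truth[i]))
  }
  # density-independent error: flat per-bin medians
  expect_lt(diff(range(tab$median_abs_diff)), 0.02)
})

test_that("no-read discrimination matches the exhaustive U-statistic", {
  # disjoint distributions: p near 0
  r <- noread_discrimination(c(runif(30, 0, .2), runif(30, .8, 1)),
                             rep(c(0, 1), each = 30))
  expect_lt(r$p_value, 1e-6)
  # identical distributions: one-sided p around 0.5
  set.seed(9)
  v <- runif(40)
  r2 <- noread_discrimination(c(v, v), rep(c(0, 1), each = 40))
  expect_gt(r2$p_value, 0.3)
  # rank-sum statistic equals brute-force pair counting on small groups
  for (i in 1:100) {
    un <- round(runif(sample(3:8, 1)), 2)
    me <- round(runif(sample(3:8, 1)), 2)
    r3 <- noread_discrimination(c(un, me),
                                c(rep(0, length(un)), rep(1, length(me))))
    u <- sum(outer(un, me, ">")) + 0.5 * sum(outer(un, me, "=="))
    expect_equal(unname(r3$statistic), u)
  }
  # empty group: skipped
  r4 <- noread_discrimination(runif(5), rep(1, 5))
  expect_true(isTRUE(r4$skipped))
})

test_that("regional aggregation equals per-instance brute force", {
  d <- default_sim()
  inst <- unlist(element_ranges(d$ann,
    seqlengths = GenomeInfoDb::seqlengths(d$sites)))
  set.seed(11)
  vals <- runif(length(d$sites))
  agg <- regional_aggregate(vals, d$sites, inst)
  pos <- GenomicRanges::start(d$sites)
  for (r in sample(nrow(agg), 20)) {
    i <- pos >= agg$start[r] & pos <= agg$end[r]
    expect_equal(agg$n_cpg[r], sum(i))
    expect_equal(agg$mean_value[r], mean(vals[i]))
  }
  # single-CpG instances and constant values
  single <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(pos[5], width = 1))
  expect_equal(regional_aggregate(vals, d$sites, single)$mean_value, vals[5])
  cst <- regional_aggregate(rep(0.42, length(d$sites)), d$sites, inst)
  expect_true(all(abs(cst$mean_value - 0.42) < 1e-12))
  # relabelling (reordering) instances only permutes rows
  perm <- sample(length(inst))
  agg2 <- regional_aggregate(vals, d$sites, inst[perm])
  o1 <- agg[order(agg$start, agg$end, agg$n_cpg), ]
  o2 <- agg2[order(agg2$start, agg2$end, agg2$n_cpg), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
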