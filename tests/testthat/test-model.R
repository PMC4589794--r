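cl01 <- function(x) pmin(1, pmax(0, x))

# small synthetic feature tables keyed like real ones (m = 10 -> 24 columns)
fake_features <- function(n, m = 10, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n * (2 * m + 4)), n)
  colnames(f) <- c(sprintf("x%04d", seq_len(2 * m)),
                   "cf", "gc", "cpg_density", "cons")
  rownames(f) <- paste0("c:", seq_len(n))
  attr(f, "m") <- m
  f
}
all_one_element <- function(n, e = "CGI") {
  IRanges::CharacterList(rep(list(e), n))
}

test_that("training split is reproducible with the stated fraction", {
  sp <- select_training_sites(1:100, frac = 0.25, seed = 3)
  expect_length(sp$train, 25)
  expect_length(sp$test, 75)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, select_training_sites(1:100, frac = 0.25, seed = 3))
  expect_false(identical(sp$train,
                         select_training_sites(1:100, seed = 4)$train))
  expect_error(select_training_sites(1:100, frac = 1), "degenerate")
  expect_error(select_training_sites(1:30), "element too small")
})

test_that("a constant target trains (with a warning) and predicts the constant", {
  f <- fake_features(120)
  y <- rep(0.5, 120)
  expect_warning(
    fit <- mesic(f, y, all_one_element(120), eligible = rep(TRUE, 120),
                 elements_used = "CGI", ntree = 50, seed = 2),
    "constant target")
  p <- predict(fit, f, all_one_element(120))
  expect_true(all(abs(p - 0.5) < 1e-9))
})

test_that("a planted coupling-factor signal is recovered on held-out sites", {
  f <- fake_features(600, seed = 5)
  y <- cl01(f[, "cf"]^2 * 0.9 + 0.05)
  fit <- mesic(f, y, all_one_element(600), eligible = rep(TRUE, 600),
               elements_used = "CGI", ntree = 200, seed = 7)
  s <- summary(fit)
  expect_gt(s$pcc[s$element == "CGI"], 0.9)
})

test_that("permuted labels give no held-out correlation", {
  f <- fake_features(2000, seed = 6)
  set.seed(9)
  y <- sample(cl01(f[, "cf"]))
  fit <- mesic(f, y, all_one_element(2000), eligible = rep(TRUE, 2000),
               elements_used = "CGI", ntree = 100, seed = 8)
  expect_lt(abs(summary(fit)$pcc[1]), 0.1)
})

test_that("multi-element sites get the unweighted mean of element predictions", {
  n <- 300
  f <- fake_features(n, seed = 10)
  el <- as.list(rep(c("CGI", "exon"), each = n / 2))
  y <- rep(c(0.2, 0.6), each = n / 2)
  suppressWarnings(
    fit <- mesic(f, y, IRanges::CharacterList(el),
                 eligible = rep(TRUE, n), elements_used = c("CGI", "exon"),
                 ntree = 50, seed = 3))
  both <- fake_features(5, seed = 11)
  rownames(both) <- paste0("b:", 1:5)
  p_cgi <- predict(fit, both, all_one_element(5, "CGI"))
  p_ex <- predict(fit, both, all_one_element(5, "exon"))
  p_both <- predict(fit, both, all_one_element(5, c("CGI", "exon")))
  expect_equal(as.numeric(p_both), as.numeric((p_cgi + p_ex) / 2),
               tolerance = 1e-9)
  expect_equal(as.numeric(p_cgi), rep(0.2, 5), tolerance = 1e-6)
  expect_equal(as.numeric(p_both), rep(0.4, 5), tolerance = 1e-6)
  # a site with no modelled element is skipped with a count
  p_na <- predict(fit, both, all_one_element(5, "LINE"))
  expect_true(all(is.na(p_na)))
  expect_equal(attr(p_na, "n_skipped"), 5)
})

test_that("predictions are finite, in [0,1], and invariant to row order", {
  f <- fake_features(400, seed = 12)
  y <- cl01(f[, "gc"])
  fit <- mesic(f, y, all_one_element(400), eligible = rep(TRUE, 400),
               elements_used = "CGI", ntree = 100, seed = 1)
  zero <- fake_features(3, seed = 13); zero[] <- 0
  rownames(zero) <- paste0("z:", 1:3)
  pz <- predict(fit, zero, all_one_element(3))
  expect_true(all(is.finite(pz) & pz >= 0 & pz <= 1))
  perm <- sample(nrow(f))
  p1 <- predict(fit, f, all_one_element(400))
  p2 <- predict(fit, f[perm, ], all_one_element(400))
  expect_equal(as.numeric(p1[rownames(f)[perm]]), as.numeric(p2))
})

test_that("refitting with the same seed reproduces identical predictions", {
  f <- fake_features(300, seed = 14)
  y <- cl01(f[, "cf"])
  el <- all_one_element(300)
  fit1 <- mesic(f, y, el, eligible = rep(TRUE, 300), elements_used = "CGI",
                ntree = 100, seed = 21)
  fit2 <- mesic(f, y, el, eligible = rep(TRUE, 300), elements_used = "CGI",
                ntree = 100, seed = 21)
  expect_identical(fit1$splits, fit2$splits)
  expect_equal(predict(fit1, f, el), predict(fit2, f, el))
})

test_that("prediction rejects a mismatched feature schema", {
  f <- fake_features(200, seed = 15)
  fit <- mesic(f, cl01(f[, "cf"]), all_one_element(200),
               eligible = rep(TRUE, 200), elements_used = "CGI",
               ntree = 50, seed = 1)
  bad <- f[, c(2:ncol(f), 1)]
  expect_error(predict(fit, bad, all_one_element(200)), "schema")
})

test_that("alternative learners recover a planted linear signal", {
  f <- fake_features(600, seed = 16)
  beta <- c(runif(6, -0.3, 0.3))
  y <- as.numeric(cl01(0.5 + f[, 1:6] %*% beta))
  el <- all_one_element(600)
  elig <- rep(TRUE, 600)
  fit_mlr <- mesic(f, y, el, eligible = elig, elements_used = "CGI",
                   learner = "mlr", seed = 2)
  expect_gt(summary(fit_mlr)$pcc[1], 0.95)
  fit_rf <- mesic(f, y, el, eligible = elig, elements_used = "CGI",
                  ntree = 200, seed = 2)
  expect_lt(abs(summary(fit_mlr)$pcc[1] - summary(fit_rf)$pcc[1]), 0.25)
  skip_if_not_installed("e1071")
  fit_svr <- mesic(f, y, el, eligible = elig, elements_used = "CGI",
                   learner = "svr", seed = 2)
  expect_gt(summary(fit_svr)$pcc[1], 0.8)
})

test_that("held-out accuracy does not degrade with more training data", {
  pccs <- sapply(1:5, function(s) {
    small <- fake_features(250, seed = 100 + s)
    big <- fake_features(4000, seed = 200 + s)
    y_s <- cl01(small[, "cf"] * 0.8 + rnorm(250, 0, 0.05))
    y_b <- cl01(big[, "cf"] * 0.8 + rnorm(4000, 0, 0.05))
    f1 <- mesic(small, y_s, all_one_element(250), eligible = rep(TRUE, 250),
                elements_used = "CGI", ntree = 100, seed = s)
    f2 <- mesic(big, y_b, all_one_element(4000), eligible = rep(TRUE, 4000),
                elements_used = "CGI", ntree = 100, seed = s)
    summary(f2)$pcc[1] - summary(f1)$pcc[1]
  })
  expect_gte(mean(pccs), -0.02)  # within simulation noise
})
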