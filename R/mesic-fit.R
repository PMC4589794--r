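#' Reproducible training/test split of eligible sites
#'
#' Selects `floor(frac * n)` of the indices as training set, the rest as
#' test set, deterministically under `seed`.
#'
#' @param ids Vector of eligible site identifiers (or indices).
#' @param frac Training fraction (default 0.25).
#' @param seed Integer seed.
#' @param min_sites Minimum number of eligible sites (default 50).
#' @return list(train, test) of disjoint subsets of `ids`.
#' @export
select_training_sites <- function(ids, frac = 0.25, seed = 1,
                                  min_sites = 50) {
  n <- length(ids)
  if (n < min_sites) stop("element too small: ", n, " eligible sites")
  n_train <- floor(frac * n)
  if (n_train < 1 || n_train >= n)
    stop("training fraction ", frac, " yields a degenerate split")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  tr <- sort(sample.int(n, n_train))
  list(train = ids[tr], test = ids[-tr])
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
    envir = globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Fit genomic-element-stratified methylation models
#'
#' The central fitting function.  For each genomic-element category with
#' enough eligible CpG sites, a random-forest regression (500 trees; each
#' tree grown on a 70% bootstrap sample; 30% of features tried per split) is
#' trained on a random 25% of that element's sites to predict reference 5mC
#' levels from the 404-dimensional feature vectors; the remaining 75% serve
#' as held-out test set.  Eligibility means a defined reference level and at
#' least one MeDIP read mapping to the feature region.  Repeat-class
#' elements are excluded by default (their MeDIP signal is unreliable);
#' include them via `elements_used`.
#'
#' @param features Feature matrix from [mesic_features()] (rows = sites).
#' @param truth Numeric vector of reference 5mC levels aligned with rows
#'   (`NA` = failed filters).
#' @param elements List/CharacterList of element labels per site.
#' @param eligible Optional logical vector; default requires non-`NA` truth
#'   and any nonzero signal feature (at least one read over the region) -
#'   pass your own vector to use exact read overlap.
#' @param elements_used Element categories to model (default the eight CGI-
#'   and gene-related categories).
#' @param learner `"rf"` (default), `"mlr"` or `"svr"`.
#' @param train_frac Training fraction per element (default 0.25).
#' @param ntree,sample_frac,mtry_frac Forest size and per-tree sampling
#'   fractions (defaults 500, 0.7, 0.3).
#' @param min_sites Minimum eligible sites per element (default 50); smaller
#'   elements are skipped with a message.
#' @param seed Master seed; per-element seeds are derived from it.
#' @return An object of class `mesic`: element models, train/test site keys,
#'   held-out predictions, feature schema, and the call.
#' @seealso [predict.mesic()], [summary.mesic()]
#' @export
mesic <- function(features, truth, elements, eligible = NULL,
                  elements_used = MESIC_GENE_ELEMENTS,
                  learner = c("rf", "mlr", "svr"),
                  train_frac = 0.25, ntree = 500, sample_frac = 0.7,
                  mtry_frac = 0.3, min_sites = 50, seed = 1) {
  learner <- match.arg(learner)
  stopifnot(nrow(features) == length(truth),
            nrow(features) == length(elements))
  keys <- rownames(features)
  if (is.null(keys)) stop("feature matrix must carry site rownames")
  m <- attr(features, "m") %||% ((ncol(features) - 4) / 2)
  if (is.null(eligible)) {
    sig <- rowSums(features[, seq_len(2 * m), drop = FALSE]) > 0
    eligible <- !is.na(truth) & sig
  }
  el_list <- as.list(elements)
  models <- list(); splits <- list()
  hold <- list()
  for (e in elements_used) {
    idx <- which(eligible & vapply(el_list, function(x) e %in% x, logical(1)))
    if (length(idx) < min_sites) {
      message("skipping element ", e, ": only ", length(idx),
              " eligible sites")
      next
    }
    sp <- select_training_sites(idx, frac = train_frac,
                                seed = derive_seed(seed,
                                  match(e, MESIC_ELEMENTS)),
                                min_sites = min_sites)
    old <- .Random.seed_get()
    set.seed(derive_seed(seed, 100 + match(e, MESIC_ELEMENTS)))
    fit <- fit_learner(features[sp$train, , drop = FALSE], truth[sp$train],
                       learner = learner, ntree = ntree,
                       sample_frac = sample_frac, mtry_frac = mtry_frac)
    .Random.seed_set(old)
    pred_test <- predict_learner(fit, features[sp$test, , drop = FALSE])
    models[[e]] <- fit
    splits[[e]] <- list(train = keys[sp$train], test = keys[sp$test])
    hold[[e]] <- data.frame(site = keys[sp$test], element = e,
                            pred = pred_test, truth = truth[sp$test],
                            stringsAsFactors = FALSE)
  }
  if (length(models) == 0) stop("no element had enough eligible sites")
  structure(list(
    models = models, splits = splits,
    holdout = do.call(rbind, c(hold, list(make.row.names = FALSE))),
    schema = colnames(features), m = m, learner = learner,
    params = list(train_frac = train_frac, ntree = ntree,
                  sample_frac = sample_frac, mtry_frac = mtry_frac,
                  min_sites = min_sites, elements_used = elements_used),
    seed = seed, call = match.call()), class = "mesic")
}

#' Predict single-CpG 5mC levels
#'
#' Each site is scored by every element model it belongs to and the
#' unweighted mean of those predictions, clamped to `[0, 1]`, is the final
#' estimate.  Sites belonging to no modelled element get `NA` (their count
#' is attached as the `n_skipped` attribute).  Sites with zero reads in the
#' feature region still receive predictions.
#'
#' @param object A fitted `mesic` object.
#' @param features Feature matrix with the training schema.
#' @param elements Element labels per row of `features`.
#' @param ... Unused.
#' @return Named numeric vector of predictions (names = site keys).
#' @export
predict.mesic <- function(object, features, elements, ...) {
  if (!identical(colnames(features), object$schema))
    stop("feature schema mismatch between training and prediction input")
  el_list <- as.list(elements)
  n <- nrow(features)
  acc <- numeric(n); cnt <- integer(n)
  for (e in names(object$models)) {
    idx <- which(vapply(el_list, function(x) e %in% x, logical(1)))
    if (!length(idx)) next
    p <- predict_learner(object$models[[e]],
                         features[idx, , drop = FALSE])
    acc[idx] <- acc[idx] + p
    cnt[idx] <- cnt[idx] + 1L
  }
  out <- ifelse(cnt > 0, clamp01(acc / pmax(cnt, 1L)), NA_real_)
  names(out) <- rownames(features)
  attr(out, "n_skipped") <- sum(cnt == 0)
  out
}

#' @export
print.mesic <- function(x, ...) {
  cat("Element-stratified single-CpG methylation model (", x$learner,
      " learner)\n", sep = "")
  cat("  features:", length(x$schema), "(m =", x$m, ")\n")
  cat("  elements:", paste(names(x$models), collapse = ", "), "\n")
  cat("  trees:", x$params$ntree, " train fraction:", x$params$train_frac,
      "\n")
  invisible(x)
}

#' Held-out performance summary per element
#'
#' @param object A fitted `mesic` object.
#' @param threshold Concordance threshold (default 0.25).
#' @param ... Unused.
#' @return data.frame (class `summary.mesic`) with per-element and overall
#'   n_train, n_test, held-out Pearson correlation and concordance.
#' @export
summary.mesic <- function(object, threshold = 0.25, ...) {
  h <- object$holdout
  per <- lapply(names(object$models), function(e) {
    d <- h[h$element == e, ]
    data.frame(element = e,
               n_train = length(object$splits[[e]]$train),
               n_test = nrow(d),
               pcc = pcc(d$pred, d$truth),
               concordance = concordance(d$pred, d$truth, threshold))
  })
  out <- do.call(rbind, per)
  out <- rbind(out, data.frame(element = "overall",
    n_train = sum(out$n_train), n_test = nrow(h),
    pcc = pcc(h$pred, h$truth),
    concordance = concordance(h$pred, h$truth, threshold)))
  class(out) <- c("summary.mesic", "data.frame")
  out
}

#' @export
print.summary.mesic <- function(x, ...) {
  cat("Held-out performance by genomic element\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
residuals.mesic <- function(object, ...) {
  r <- object$holdout$pred - object$holdout$truth
  names(r) <- object$holdout$site
  r
}

#' Held-out predicted vs. reference methylation scatter
#' @param x A fitted `mesic` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mesic <- function(x, ...) {
  h <- x$holdout
  graphics::plot(h$truth, h$pred, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "reference 5mC level", ylab = "predicted 5mC level",
                 pch = 16, cex = 0.4, col = "#00000044", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
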