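#' Run the full estimation pipeline on a dataset
#'
#' Extends reads, builds the RPM track, assembles feature vectors, fits the
#' element-stratified models on a training split of eligible sites, and
#' evaluates predictions on the held-out sites (those used for training by
#' no element model).  Training labels may differ from the evaluation truth
#' (used by the label-noise harness).
#'
#' @param data A `mesic_dataset` (or any list with `genome`, `cons`,
#'   `sites`, `truth`, `reads`).
#' @param reads Read set (default `data$reads`); the subsampling harness
#'   passes subsets.
#' @param train_truth Labels used for fitting (default the clean truth).
#' @param m Feature-region half-size (default 200).
#' @param extension Read extension length (default 200).
#' @param seed Master seed for split and forest randomness.
#' @param ... Passed to [mesic()] (learner, ntree, ...).
#' @return list: `fit` (mesic object), `track`, `features`, `eligible`,
#'   `pred` (all-site predictions), `test_keys`, and `metrics`
#'   (held-out pcc, concordance, n).
#' @export
mesic_run <- function(data, reads = data$reads, train_truth = NULL,
                      m = 200, extension = 200, seed = 1, ...) {
  sites <- data$sites
  ext <- extend_reads(reads, extension)
  track <- build_signal(ext, seqlengths = stats::setNames(
    Biostrings::width(data$genome), names(data$genome)))
  feats <- mesic_features(sites, track, data$genome, data$cons, m = m)
  reg <- suppressWarnings(IRanges::trim(GenomicRanges::resize(
    sites, width = 2 * m, fix = "center")))
  covered <- GenomicRanges::countOverlaps(reg, ext,
                                          ignore.strand = TRUE) > 0
  truth <- data$truth
  if (is.null(train_truth)) train_truth <- truth
  eligible <- !is.na(truth) & covered
  elements <- S4Vectors::mcols(sites)$elements
  fit <- mesic(feats, train_truth, elements, eligible = eligible,
               seed = seed, ...)
  pred <- predict(fit, feats, elements)
  trained <- unique(unlist(lapply(fit$splits, `[[`, "train")))
  keys <- rownames(feats)
  test <- eligible & !(keys %in% trained) & !is.na(pred)
  metrics <- list(pcc = pcc(pred[test], truth[test]),
                  concordance = concordance(pred[test], truth[test]),
                  n = sum(test))
  list(fit = fit, track = track, features = feats, eligible = eligible,
       covered = covered, pred = pred, test_keys = keys[test],
       metrics = metrics)
}

#' Sequencing-depth robustness harness
#'
#' Retrains and re-evaluates the full pipeline on random read subsets from
#' 100% down to 10% of the library, several repetitions per fraction, and
#' reports per-run and per-fraction mean/SD of held-out PCC and concordance.
#'
#' @param data A `mesic_dataset`.
#' @param fractions Read fractions (default 1.0 down to 0.1 by 0.1).
#' @param reps Repetitions per fraction (default 10).
#' @param seed Master seed.
#' @param ... Passed to [mesic_run()].
#' @return list(runs, summary): per-run data.frame and per-fraction
#'   aggregate.
#' @export
subsample_reads_harness <- function(data, fractions = seq(1, 0.1, by = -0.1),
                                    reps = 10, seed = 1, ...) {
  n <- length(data$reads)
  rows <- list()
  for (f in fractions) {
    k <- round(f * n)
    if (k < 1) { warning("fraction ", f, " yields zero reads; skipped")
                 next }
    for (r in seq_len(reps)) {
      s <- derive_seed(seed, round(1000 * f) * 100 + r)
      old <- .Random.seed_get()
      set.seed(s)
      sub <- if (k == n) data$reads else data$reads[sample.int(n, k)]
      .Random.seed_set(old)
      run <- mesic_run(data, reads = sub, seed = seed, ...)
      rows[[length(rows) + 1]] <- data.frame(
        fraction = f, rep = r, pcc = run$metrics$pcc,
        concordance = run$metrics$concordance, n = run$metrics$n)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$fraction), function(d)
    data.frame(fraction = d$fraction[1], mean_pcc = mean(d$pcc),
               sd_pcc = stats::sd(d$pcc),
               mean_concordance = mean(d$concordance),
               sd_concordance = stats::sd(d$concordance))))
  list(runs = runs, summary = agg[order(-agg$fraction), ])
}

#' Label-noise robustness harness
#'
#' Replaces the training labels of a growing fraction of CpG sites with
#' uniform random values on `[0, 1]`, retrains, and evaluates against the
#' clean truth; the noise draw is repeated `reps` times per fraction.
#'
#' @param data A `mesic_dataset`.
#' @param noise_fracs Noise fractions (default 0 to 1 by 0.05).
#' @param reps Repetitions (fresh noise draws) per fraction (default 1).
#' @param seed Master seed.
#' @param ... Passed to [mesic_run()].
#' @return list(runs, summary): per-run data.frame(noise, rep, pcc,
#'   concordance, n) and per-fraction mean/SD aggregate.
#' @export
label_noise_harness <- function(data, noise_fracs = seq(0, 1, by = 0.05),
                                reps = 1, seed = 1, ...) {
  n <- length(data$truth)
  rows <- list()
  for (f in noise_fracs) {
    for (r in seq_len(reps)) {
      tr <- data$truth
      k <- round(f * n)
      if (k > 0) {
        old <- .Random.seed_get()
        set.seed(derive_seed(seed, 7000 + round(1000 * f) * 20 + r))
        i <- sample.int(n, k)
        tr[i] <- stats::runif(k)
        .Random.seed_set(old)
      }
      run <- mesic_run(data, train_truth = tr, seed = seed, ...)
      rows[[length(rows) + 1]] <- data.frame(
        noise = f, rep = r, pcc = run$metrics$pcc,
        concordance = run$metrics$concordance, n = run$metrics$n)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$noise), function(d)
    data.frame(noise = d$noise[1], mean_pcc = mean(d$pcc),
               sd_pcc = stats::sd(d$pcc),
               mean_concordance = mean(d$concordance),
               sd_concordance = stats::sd(d$concordance))))
  list(runs = runs, summary = agg[order(agg$noise), ])
}

#' Pipeline configuration with full default snapshot
#'
#' All tunables of [run_pipeline()] with the estimator's standard defaults.
#' Unknown keys in `overrides` are rejected.
#'
#' @param overrides Named list of overrides.
#' @return list of class `mesic_config`.
#' @export
mesic_config <- function(overrides = list()) {
  cfg <- list(seed = 1, m = 200, extension = 200, ntree = 500,
              train_frac = 0.25, sample_frac = 0.7, mtry_frac = 0.3,
              learner = "rf", min_sites = 50,
              concordance_threshold = 0.25, min_cov = 4, p_bs = 0.005,
              p_tab = 0.022, fdr = 0.01,
              dmr = list(window = 1000, step = 500, min_cpg = 5,
                         pcc_max = 0.25, fdr = 0.05),
              sim = list(), input_dir = NULL, outdir = "mesic_out")
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "mesic_config"
  cfg
}

#' Load a dataset written by [write_mesic_data()]
#'
#' @param dir Directory containing `ref.fa`, `cgi.bed`, `genes.txt`,
#'   `rmsk.bed`, `cons.bedGraph`, `reads.bed`, `bs.tsv`, `tab.tsv` (and
#'   optionally `truth_true.tsv`).
#' @return A `mesic_dataset`-shaped list (truth derived from BS/TAB unless
#'   `truth_true.tsv` is present and `use_true_levels` is set).
#' @param use_true_levels Read planted levels instead of deriving from
#'   counts (default `FALSE`).
#' @export
read_mesic_data <- function(dir, use_true_levels = FALSE) {
  fp <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  genome <- Biostrings::readDNAStringSet(fp("ref.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  cgi <- rtracklayer::import.bed(fp("cgi.bed"))
  reps <- rtracklayer::import.bed(fp("rmsk.bed"))
  S4Vectors::mcols(reps)$class <- S4Vectors::mcols(reps)$name
  genes <- read_gene_table(fp("genes.txt"))
  cons_gr <- rtracklayer::import.bedGraph(fp("cons.bedGraph"))
  GenomeInfoDb::seqlevels(cons_gr) <- names(sl)
  GenomeInfoDb::seqlengths(cons_gr) <- sl
  cons <- GenomicRanges::coverage(cons_gr, weight = "score")
  reads <- rtracklayer::import.bed(fp("reads.bed"))
  GenomeInfoDb::seqlevels(reads) <- names(sl)
  GenomeInfoDb::seqlengths(reads) <- sl
  ann <- list(cgi = cgi, genes = genes, repeats = reps)
  sites <- classify_sites(enumerate_cpg_sites(genome), ann)
  bs <- read_pileup(fp("bs.tsv"))
  tab <- read_pileup(fp("tab.tsv"))
  truth <- NULL
  tt <- file.path(dir, "truth_true.tsv")
  if (use_true_levels && file.exists(tt)) {
    tdf <- utils::read.table(tt, header = TRUE, sep = "\t")
    truth <- tdf$level_5mc[match(
      site_key(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites)),
      site_key(tdf$chrom, tdf$pos))]
  }
  structure(list(genome = genome, ann = ann, cons = cons, sites = sites,
                 truth = truth, reads = reads, bs = bs, tab = tab),
            class = "mesic_dataset")
}

#' Run the end-to-end pipeline and write artifacts
#'
#' simulate (or load) -> annotate -> signal -> ground truth -> features ->
#' train -> predict -> evaluate, logging per-stage row counts and writing
#' `sites.bed`, `signal.bedGraph`, `truth.tsv`, `features.tsv`,
#' `pred.bedGraph`, `pred.tsv`, `report.json` and the resolved config under
#' `cfg$outdir`.
#'
#' @param cfg A [mesic_config()] (or overrides list).
#' @return list(run, report), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = mesic_config()) {
  if (!inherits(cfg, "mesic_config")) cfg <- mesic_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) message("[mesic] ", ...)
  if (is.null(cfg$input_dir)) {
    scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    data <- simulate_mesic_data(scfg)
    stage("simulate: ", length(data$sites), " CpG sites, ",
          length(data$reads), " reads")
  } else {
    data <- read_mesic_data(cfg$input_dir)
    stage("load: ", length(data$sites), " CpG sites, ",
          length(data$reads), " reads from ", cfg$input_dir)
  }
  if (is.null(data$truth)) {
    rec <- methylation_table(data$bs, data$tab)
    rec <- binomial_filter(compute_betas(rec), p_bs = cfg$p_bs,
                           p_tab = cfg$p_tab, fdr = cfg$fdr,
                           min_cov = cfg$min_cov)
    rec <- derive_5mc(rec)
    keys <- site_key(as.character(GenomicRanges::seqnames(data$sites)),
                     GenomicRanges::start(data$sites))
    data$truth <- rec$level_5mc[match(keys, site_key(rec$chrom, rec$pos))]
    stage("truth: ", sum(!is.na(data$truth)), " of ", length(keys),
          " CpG sites pass filters")
    write_methylation_table(rec, file.path(cfg$outdir, "truth.tsv"))
  }
  run <- mesic_run(data, m = cfg$m, extension = cfg$extension,
                   seed = cfg$seed, learner = cfg$learner,
                   train_frac = cfg$train_frac, ntree = cfg$ntree,
                   sample_frac = cfg$sample_frac, mtry_frac = cfg$mtry_frac,
                   min_sites = cfg$min_sites)
  stage("train: elements ", paste(names(run$fit$models), collapse = ", "))
  stage("evaluate: held-out PCC ", round(run$metrics$pcc, 3),
        ", concordance ", round(run$metrics$concordance, 3),
        " (n=", run$metrics$n, ")")
  # artifacts
  sites_bed <- data$sites
  rtracklayer::export.bed(sites_bed, file.path(cfg$outdir, "sites.bed"))
  write_signal_bedgraph(run$track, file.path(cfg$outdir, "signal.bedGraph"))
  write_features(run$features, file.path(cfg$outdir, "features.tsv"))
  ok <- !is.na(run$pred)
  pred_gr <- data$sites[ok]
  S4Vectors::mcols(pred_gr) <- NULL
  S4Vectors::mcols(pred_gr)$score <- unname(run$pred[ok])
  rtracklayer::export.bedGraph(pred_gr,
                               file.path(cfg$outdir, "pred.bedGraph"))
  utils::write.table(
    data.frame(site = rownames(run$features), pred = unname(run$pred)),
    file.path(cfg$outdir, "pred.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  smry <- summary(run$fit, threshold = cfg$concordance_threshold)
  report <- list(overall = run$metrics,
                 per_element = as.data.frame(smry),
                 n_sites = length(data$sites),
                 n_reads = length(data$reads))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(run = run, report = report, data = data))
}
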