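#' Merge BS-seq and TAB-seq pileup tables into per-CpG methylation records
#'
#' Counts on the two strands of one CpG are pooled onto the forward-strand C
#' (CpG methylation is symmetric): a record on the minus strand at `pos` is
#' assigned to the CpG whose C sits at `pos - 1`.
#'
#' @param bs,tab data.frames with columns `chrom, pos, strand, count_c,
#'   count_t` (`pos` 1-based position of the measured cytosine).  BS-seq
#'   counts C (methylated, 5mC+5hmC) vs T; TAB-seq counts C
#'   (hydroxymethylated) vs T.
#' @return data.frame keyed by (chrom, pos) with pooled counts `n_c, n_t`
#'   (BS) and `n_hc, n_ht` (TAB); sites absent from an assay get zero counts.
#' @export
methylation_table <- function(bs, tab) {
  pool <- function(d, cn) {
    stopifnot(all(c("chrom", "pos", "strand", "count_c", "count_t") %in%
                  names(d)))
    if (any(d$count_c < 0 | d$count_t < 0)) stop("negative counts")
    pos <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
    key <- site_key(d$chrom, pos)
    cc <- tapply(d$count_c, key, sum)
    tt <- tapply(d$count_t, key, sum)
    out <- data.frame(key = names(cc), a = as.integer(cc), b = as.integer(tt),
                      stringsAsFactors = FALSE)
    names(out)[2:3] <- cn
    out
  }
  b <- pool(bs, c("n_c", "n_t"))
  t <- pool(tab, c("n_hc", "n_ht"))
  m <- merge(b, t, by = "key", all = TRUE)
  for (col in c("n_c", "n_t", "n_hc", "n_ht"))
    m[[col]][is.na(m[[col]])] <- 0L
  parts <- do.call(rbind, strsplit(m$key, ":", fixed = TRUE))
  m$chrom <- parts[, 1]
  m$pos <- as.integer(parts[, 2])
  m <- m[order(m$chrom, m$pos),
         c("chrom", "pos", "n_c", "n_t", "n_hc", "n_ht")]
  rownames(m) <- NULL
  m
}

#' Compute beta values from BS/TAB counts
#'
#' `beta_bs = n_c / (n_c + n_t)` and `beta_tab = n_hc / (n_hc + n_ht)`;
#' zero-coverage betas are `NA`.
#'
#' @param records data.frame from [methylation_table()].
#' @return `records` with `beta_bs` and `beta_tab` columns added.
#' @export
compute_betas <- function(records) {
  if (any(records$n_c < 0 | records$n_t < 0 | records$n_hc < 0 |
          records$n_ht < 0)) stop("negative counts")
  nb <- records$n_c + records$n_t
  nt <- records$n_hc + records$n_ht
  records$beta_bs <- ifelse(nb > 0, records$n_c / nb, NA_real_)
  records$beta_tab <- ifelse(nt > 0, records$n_hc / nt, NA_real_)
  records
}

#' Coverage and binomial non-conversion filtering
#'
#' A C call at an unmethylated cytosine can arise from failed bisulfite
#' conversion alone.  For each record and assay, the upper-tail binomial
#' p-value `P[X >= n_c]` with `X ~ B(n_c + n_t, p)` (p = the assay's
#' non-conversion rate) tests whether the observed C counts exceed that
#' noise floor; p-values are Benjamini-Hochberg adjusted per assay and betas
#' failing the FDR threshold are treated as 0 downstream (no evidence of
#' methylation / hydroxymethylation beyond non-conversion).  `pass_filters`
#' records the coverage criterion: at least `min_cov` reads in both assays.
#'
#' @param records data.frame with counts (betas added if absent).
#' @param p_bs,p_tab Non-conversion rates (defaults 0.005 and 0.022).
#' @param fdr FDR threshold (default 0.01).
#' @param min_cov Minimum per-assay coverage (default 4).
#' @param adjust If `FALSE`, threshold raw p-values instead of BH q-values.
#' @return `records` with `pval_bs, qval_bs, sig_bs, pval_tab, qval_tab,
#'   sig_tab, pass_filters` columns.
#' @export
binomial_filter <- function(records, p_bs = 0.005, p_tab = 0.022,
                            fdr = 0.01, min_cov = 4, adjust = TRUE) {
  stopifnot(p_bs > 0, p_bs < 1, p_tab > 0, p_tab < 1)
  if (is.null(records$beta_bs)) records <- compute_betas(records)
  upper_tail <- function(k, n, p) {
    out <- rep(NA_real_, length(k))
    ok <- n > 0
    # P[X >= k] = 1 - P[X <= k-1]
    out[ok] <- stats::pbinom(k[ok] - 1, n[ok], p, lower.tail = FALSE)
    out
  }
  records$pval_bs <- upper_tail(records$n_c, records$n_c + records$n_t, p_bs)
  records$pval_tab <- upper_tail(records$n_hc, records$n_hc + records$n_ht,
                                 p_tab)
  records$qval_bs <- stats::p.adjust(records$pval_bs, method = "BH")
  records$qval_tab <- stats::p.adjust(records$pval_tab, method = "BH")
  if (adjust) {
    records$sig_bs <- !is.na(records$qval_bs) & records$qval_bs <= fdr
    records$sig_tab <- !is.na(records$qval_tab) & records$qval_tab <= fdr
  } else {
    records$sig_bs <- !is.na(records$pval_bs) & records$pval_bs <= fdr
    records$sig_tab <- !is.na(records$pval_tab) & records$pval_tab <= fdr
  }
  records$pass_filters <- (records$n_c + records$n_t) >= min_cov &
    (records$n_hc + records$n_ht) >= min_cov
  records
}

#' Derive 5mC levels by BS - TAB subtraction
#'
#' BS-seq measures 5mC + 5hmC; TAB-seq measures 5hmC alone.  The 5mC level is
#' `beta_bs - beta_tab`, clamped to `[0, 1]`.  Betas whose binomial test did
#' not reach significance are taken as 0 (indistinguishable from
#' non-conversion noise); records failing the coverage filter get `NA` and
#' are counted in the `n_skipped` attribute.
#'
#' @param records Output of [binomial_filter()].
#' @param zero_nonsignificant Replace non-significant betas by 0 before
#'   subtracting (default `TRUE`).
#' @return `records` with a `level_5mc` column; attribute `n_skipped` holds
#'   the number of records failing filters.
#' @export
derive_5mc <- function(records, zero_nonsignificant = TRUE) {
  need <- c("beta_bs", "beta_tab", "pass_filters")
  if (!all(need %in% names(records)))
    stop("run compute_betas() and binomial_filter() first")
  b_bs <- records$beta_bs
  b_tab <- records$beta_tab
  if (zero_nonsignificant) {
    b_bs <- ifelse(records$sig_bs, b_bs, 0)
    b_tab <- ifelse(records$sig_tab, b_tab, 0)
  }
  lev <- clamp01(b_bs - b_tab)
  lev[!records$pass_filters] <- NA_real_
  records$level_5mc <- lev
  attr(records, "n_skipped") <- sum(!records$pass_filters)
  records
}

#' Read a BS/TAB pileup TSV (chrom, pos, strand, count_c, count_t)
#' @param path File path.
#' @return data.frame.
#' @export
read_pileup <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a methylation record table as TSV
#' @param records data.frame.
#' @param path Output path.
#' @export
write_methylation_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
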