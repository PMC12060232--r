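# Window-level population differentiation used to nominate candidate genes
# inside QTLs. Per-SNP F_ST uses the Hudson estimator; window-wide F_ST is
# the ratio of summed numerators to summed denominators (not the mean of
# per-SNP ratios), alongside the maximum single-SNP value per window.

#' Hudson per-SNP F_ST components
#'
#' `numerator = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `denominator = p1(1-p2) + p2(1-p1)`, with `p` the alternate-allele
#' frequency and `n` the allele sample size per population. SNPs
#' monomorphic in both populations get components (0, 0) and are excluded
#' from ratios.
#'
#' @param p1,p2 Allele frequencies (vectors).
#' @param n1,n2 Allele sample sizes (>= 2; scalars or vectors).
#' @return Data.frame with `num`, `den`, and `fst` (NA where `den` is 0).
#' @export
snp_fst <- function(p1, p2, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("allele sample sizes must be >= 2", call. = FALSE)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  num[mono] <- 0; den[mono] <- 0
  data.frame(num = num, den = den,
             fst = ifelse(den > 0, num / den, NA_real_))
}

# Extract biallelic-SNP allele frequencies per population from a vcfR object
# or a prepared data.frame(arm, pos, p1, p2, n1, n2).
snp_freq_table <- function(snps, pops = NULL) {
  if (is.data.frame(snps)) {
    stopifnot(all(c("arm", "pos", "p1", "p2", "n1", "n2") %in% names(snps)))
    return(snps)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  }
  if (is.character(snps)) snps <- vcfR::read.vcfR(snps, verbose = FALSE)
  fix <- vcfR::getFIX(snps)
  gt <- vcfR::extract.gt(snps, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  n_skipped <- sum(!biallelic)
  if (n_skipped) message(sprintf("window_fst: %d non-biallelic record(s) skipped",
                                 n_skipped))
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  stopifnot(!is.null(pops), all(colnames(gt) %in% names(pops)))
  dose <- function(x) {
    alt <- vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
      a <- a[a %in% c("0", "1")]
      if (!length(a)) NA_real_ else sum(a == "1") / length(a) * 2
    }, numeric(1))
    alt
  }
  tab <- lapply(unique(pops), function(pp) {
    cols <- colnames(gt)[pops[colnames(gt)] == pp]
    m <- apply(gt[, cols, drop = FALSE], 1, dose)
    m <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
    n_alleles <- rowSums(!is.na(m)) * 2
    list(p = rowSums(m, na.rm = TRUE) / pmax(n_alleles, 1), n = n_alleles)
  })
  data.frame(arm = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             p1 = tab[[1]]$p, p2 = tab[[2]]$p,
             n1 = tab[[1]]$n, n2 = tab[[2]]$n,
             stringsAsFactors = FALSE)
}

#' Window-wide and maximum-SNP F_ST
#'
#' For each window of `map`, `fst_fullwin` is the ratio of summed Hudson
#' numerators to summed denominators over the window's SNPs, and
#' `fst_maxsnp` is the largest per-SNP ratio among SNPs with a positive
#' denominator. For single-SNP windows the two coincide. Windows with no
#' usable SNP are missing. Reported values are clipped to \[0, 1\]; the raw
#' ratios are kept in `fst_fullwin_raw` / `fst_maxsnp_raw`.
#'
#' @param snps A VCF path, a `vcfR` object (with `pops` a named vector of
#'   population labels per sample), or a data.frame with columns `arm`,
#'   `pos`, `p1`, `p2`, `n1`, `n2`. VCF positions are 1-based and converted
#'   to the map's 0-based half-open windows.
#' @param map Window map.
#' @param pops Named character vector assigning samples to two populations
#'   (VCF input only).
#' @return Data.frame of class `fst_windows`: one row per window.
#' @export
window_fst <- function(snps, map, pops = NULL) {
  ft <- snp_freq_table(snps, pops)
  if (!is.data.frame(snps)) ft$pos <- ft$pos - 1  # VCF 1-based -> 0-based
  comp <- snp_fst(ft$p1, ft$p2, ft$n1, ft$n2)
  out <- data.frame(window_id = map$window_id, arm = map$arm,
                    start = map$start, end = map$end,
                    n_snps_used = 0L,
                    fst_fullwin_raw = NA_real_, fst_maxsnp_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (a in unique(map$arm)) {
    m_idx <- which(map$arm == a)
    s_idx <- which(ft$arm == a)
    if (!length(s_idx)) next
    wi <- findInterval(ft$pos[s_idx], map$start[m_idx])
    inside <- wi >= 1L & ft$pos[s_idx] < map$end[m_idx][pmax(wi, 1L)]
    for (k in unique(wi[inside])) {
      rows <- s_idx[inside & wi == k]
      usable <- rows[comp$den[rows] > 0]
      i <- m_idx[k]
      out$n_snps_used[i] <- length(usable)
      if (!length(usable)) next
      out$fst_fullwin_raw[i] <- sum(comp$num[usable]) / sum(comp$den[usable])
      out$fst_maxsnp_raw[i] <- max(comp$fst[usable])
    }
  }
  out$fst_fullwin <- pmin(pmax(out$fst_fullwin_raw, 0), 1)
  out$fst_maxsnp <- pmin(pmax(out$fst_maxsnp_raw, 0), 1)
  class(out) <- c("fst_windows", "data.frame")
  out
}

#' Recombination-eligible intervals for the D. melanogaster arms
#'
#' Regions with recombination rates generally above 0.5 cM/Mb, inside which
#' selection signatures are expected to be localized enough for gene-scale
#' outlier mapping. Shipped as package defaults for [flag_outliers()].
#'
#' @return Data.frame with columns `arm`, `start`, `end` (bp).
#' @export
dmel_recomb_intervals <- function() {
  data.frame(
    arm = c("X", "2L", "2R", "3L", "3R"),
    start = c(2300000, 500000, 5200000, 600000, 6900000),
    end = c(21400000, 17500000, 20800000, 17700000, 26600000),
    stringsAsFactors = FALSE
  )
}

#' Flag per-arm top-percentile F_ST outlier windows
#'
#' Eligibility is restricted to windows whose midpoint falls inside the
#' high-recombination intervals. Per statistic and per arm, windows at or
#' above the top `top_fraction` quantile are flagged (ties at the threshold
#' are all flagged); a window is an outlier if flagged by any statistic,
#' including an optional user-supplied extra statistic (e.g. a haplotype
#' statistic computed elsewhere). Arms with fewer than 100 eligible windows
#' fall back to flagging the maximum, with a warning.
#'
#' @param results An `fst_windows` data.frame.
#' @param top_fraction Per-arm tail fraction (default 0.01).
#' @param recomb_intervals Eligible intervals per arm
#'   (default [dmel_recomb_intervals()]).
#' @param extra_stat Optional numeric vector (aligned to `results` rows) of
#'   an additional statistic entering the outlier union.
#' @return `results` with logical columns `eligible`,
#'   `outlier_fullwin`, `outlier_maxsnp`, `outlier_extra`, `outlier`.
#' @export
flag_outliers <- function(results, top_fraction = 0.01,
                          recomb_intervals = dmel_recomb_intervals(),
                          extra_stat = NULL) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  mid <- (results$start + results$end) / 2
  results$eligible <- FALSE
  for (i in seq_len(nrow(recomb_intervals))) {
    hit <- results$arm == recomb_intervals$arm[i] &
      mid >= recomb_intervals$start[i] & mid < recomb_intervals$end[i]
    results$eligible[hit] <- TRUE
  }
  flag_one <- function(values) {
    out <- rep(FALSE, nrow(results))
    for (a in unique(results$arm)) {
      sel <- results$eligible & results$arm == a & !is.na(values)
      if (!any(sel)) next
      v <- values[sel]
      k <- floor(sum(sel) * top_fraction)
      if (sum(sel) < 100L || k < 1L) {
        warning(sprintf("arm %s: only %d eligible windows; flagging the maximum",
                        a, sum(sel)))
        thr <- max(v)
      } else {
        thr <- sort(v, decreasing = TRUE)[k]   # k-th largest; ties inclusive
      }
      out[sel] <- v >= thr
    }
    out
  }
  results$outlier_fullwin <- flag_one(results$fst_fullwin)
  results$outlier_maxsnp <- flag_one(results$fst_maxsnp)
  results$outlier_extra <- if (!is.null(extra_stat)) flag_one(extra_stat)
    else rep(FALSE, nrow(results))
  results$outlier <- results$outlier_fullwin | results$outlier_maxsnp |
    results$outlier_extra
  results
}
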