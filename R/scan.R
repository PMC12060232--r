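# Additive single-locus genome scan.
#
# The per-window model is the Gaussian linear regression y = b0 + b * g with
# g the numeric ancestry dosage (0/1/2); the LOD score is the log10
# likelihood ratio of this model against the intercept-only model, which for
# Gaussian ML reduces to (n/2) * log10(RSS_null / RSS_model). With complete
# genotypes the whole profile is computed from sufficient statistics in a
# handful of matrix products; windows with missing calls fall back to a
# per-window complete-case fit.

# LOD + slope profile across the columns of `geno` for one phenotype vector.
# Returns list(lod, b, n, degenerate). Columns in `skip` get lod = 0, b = NA.
lod_profile <- function(geno, y, skip = NULL) {
  nw <- ncol(geno)
  lod <- numeric(nw); b <- rep(NA_real_, nw)
  n_used <- integer(nw); degen <- logical(nw)
  do <- setdiff(seq_len(nw), skip)
  has_na <- anyNA(geno[, do, drop = FALSE])
  if (!has_na) {
    n <- length(y)
    yc <- y - mean(y)
    syy <- sum(yc * yc)
    gc_mean <- colMeans(geno[, do, drop = FALSE])
    sgy <- as.numeric(crossprod(geno[, do, drop = FALSE], yc))
    sgg <- colSums(geno[, do, drop = FALSE]^2) - n * gc_mean^2
    ok <- sgg > 1e-12
    bb <- ifelse(ok, sgy / sgg, NA_real_)
    rss1 <- pmax(syy - ifelse(ok, sgy^2 / sgg, 0), 0)
    ll <- numeric(length(do))
    if (syy <= 0) {
      ll[] <- 0                      # constant phenotype: ratio is 1
    } else {
      ll <- ifelse(!ok, 0,
                   ifelse(rss1 <= syy * 1e-14, Inf,
                          (n / 2) * log10(syy / rss1)))
    }
    lod[do] <- pmax(ll, 0)
    b[do] <- bb
    n_used[do] <- n
    degen[do] <- !ok
  } else {
    for (j in do) {
      g <- geno[, j]
      keep <- !is.na(g)
      gj <- g[keep]; yj <- y[keep]
      n <- length(yj)
      n_used[j] <- n
      if (n < 3L || stats::var(gj) < 1e-12) { degen[j] <- TRUE; next }
      yc <- yj - mean(yj); gc <- gj - mean(gj)
      syy <- sum(yc^2); sgg <- sum(gc^2); sgy <- sum(gc * yc)
      b[j] <- sgy / sgg
      rss1 <- max(syy - sgy^2 / sgg, 0)
      lod[j] <- if (syy <= 0) 0 else if (rss1 <= syy * 1e-14) Inf else
        max((n / 2) * log10(syy / rss1), 0)
    }
  }
  list(lod = lod, b = b, n = n_used, degenerate = degen)
}

#' Additive single-locus LOD genome scan
#'
#' Fits `trait ~ dosage` at every non-excluded window by least squares and
#' reports the LOD score, the per-allele effect coefficient `b`, and the
#' complete-case sample size. A window with zero genotype variance gets
#' LOD 0 and a `degenerate` flag; a perfect fit is reported as `Inf` with a
#' warning. Affine transformations of the phenotype leave all LODs unchanged.
#'
#' @param geno Dosage matrix (RILs x windows) or a `ril_panel`.
#' @param phenotype Numeric phenotype vector, named by RIL id or in row
#'   order.
#' @param summary Optional [window_summary()]; its `skew_excluded` windows
#'   are skipped.
#' @param map Optional window map; if supplied, `arm` and `cM` columns are
#'   carried into the result.
#' @return Data.frame of class `scan_result`: window_id, arm, cM, n, b, lod,
#'   p (NA until [genomewide_p()]), excluded, degenerate.
#' @examples
#' g <- matrix(c(0, 0, 2, 2), 4, 1, dimnames = list(NULL, "w1"))
#' scan_additive(g, c(0.1, -0.1, 0.9, 1.1))  # b = 0.5, LOD ~ 2.83
#' @export
scan_additive <- function(geno, phenotype, summary = NULL, map = NULL) {
  if (inherits(geno, "ril_panel")) {
    if (is.null(map)) map <- geno$map
    geno <- geno$geno
  }
  al <- align_phenotype(geno, phenotype)
  excluded <- if (!is.null(summary)) {
    summary$skew_excluded[match(colnames(geno), summary$window_id)]
  } else rep(FALSE, ncol(geno))
  excluded[is.na(excluded)] <- FALSE
  prof <- lod_profile(al$geno, al$y, skip = which(excluded))
  if (any(is.infinite(prof$lod))) {
    warning("perfect fit at one or more windows; LOD reported as Inf")
  }
  out <- data.frame(
    window_id = colnames(geno),
    arm = if (!is.null(map)) map$arm[match(colnames(geno), map$window_id)] else NA_character_,
    cM = if (!is.null(map)) map$cM[match(colnames(geno), map$window_id)] else NA_real_,
    n = prof$n,
    b = prof$b,
    lod = ifelse(excluded, NA_real_, prof$lod),
    p = NA_real_,
    excluded = excluded,
    degenerate = prof$degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation null distribution of the genome-wide maximum LOD
#'
#' Shuffles phenotype values against whole genotype rows (preserving LD
#' among windows), rescans all non-excluded windows, and records the
#' genome-wide maximum LOD per permutation.
#'
#' @inheritParams scan_additive
#' @param n_perm Number of permutations (>= 1).
#' @param seed Root seed.
#' @return Object of class `null_dist`: list with sorted `stat`, `n_perm`,
#'   `seed`, `label`.
#' @export
permutation_null <- function(geno, phenotype, summary = NULL, n_perm = 1000L,
                             seed = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  al <- align_phenotype(geno, phenotype)
  excluded <- if (!is.null(summary)) {
    which(summary$skew_excluded[match(colnames(geno), summary$window_id)])
  } else integer(0)
  scorer <- if (!anyNA(al$geno)) max_lod_scorer(al$geno, excluded) else
    function(y) max(lod_profile(al$geno, y, skip = excluded)$lod, 0)
  with_seed(seed, {
    stat <- vapply(seq_len(n_perm), function(i) scorer(sample(al$y)), numeric(1))
    structure(list(stat = sort(stat), n_perm = as.integer(n_perm),
                   seed = seed, label = "max additive LOD"),
              class = "null_dist")
  })
}

# Closure computing the genome-wide max LOD for complete-data panels, with
# genotype sufficient statistics hoisted out of the permutation loop.
max_lod_scorer <- function(geno, skip = integer(0)) {
  do <- setdiff(seq_len(ncol(geno)), skip)
  G <- geno[, do, drop = FALSE]
  storage.mode(G) <- "double"
  n <- nrow(G)
  gmean <- colMeans(G)
  sgg <- colSums(G^2) - n * gmean^2
  ok <- sgg > 1e-12
  function(y) {
    yc <- y - mean(y)
    syy <- sum(yc * yc)
    if (syy <= 0) return(0)
    sgy <- as.numeric(crossprod(G, yc))
    r2 <- ifelse(ok, sgy^2 / (sgg * syy), 0)
    r2max <- min(max(r2), 1)
    if (r2max >= 1 - 1e-14) return(Inf)
    max(-(n / 2) * log10(1 - r2max), 0)
  }
}

# Genome-wide empirical P: proportion of null max statistics >= the observed
# value. `estimator = "raw"` permits P = 0 when the observation exceeds every
# permutation; "add_one" gives the (r + 1)/(n + 1) variant.
null_p <- function(obs, null, estimator = c("raw", "add_one")) {
  estimator <- match.arg(estimator)
  stat <- null$stat
  r <- length(stat) - findInterval(obs, stat, left.open = TRUE)
  if (estimator == "raw") r / length(stat) else (r + 1) / (length(stat) + 1)
}

#' Attach genome-wide permutation P-values to a scan
#'
#' `P(window) = proportion of null maxima >= window LOD`; with the default
#' raw estimator a P-value of 0 means the observed LOD was more extreme than
#' every permutation.
#'
#' @param scan A `scan_result`.
#' @param null A `null_dist` from [permutation_null()].
#' @param estimator "raw" (default) or "add_one" for (r + 1)/(n + 1).
#' @return The scan with its `p` column populated.
#' @export
genomewide_p <- function(scan, null, estimator = c("raw", "add_one")) {
  stopifnot(inherits(null, "null_dist"), length(null$stat) > 0)
  ok <- !scan$excluded & !is.na(scan$lod)
  scan$p[ok] <- null_p(scan$lod[ok], null, match.arg(estimator))
  scan
}

#' QTL heritability from a LOD score
#'
#' `h2 = 1 - 10^(-2 * LOD / n)`, the proportion of phenotypic variance
#' explained by the single-window model; identical to the regression R^2 of
#' the same fit.
#'
#' @param lod LOD score (>= 0; Inf allowed).
#' @param n Sample size used in the fit.
#' @return Heritability in \[0, 1\].
#' @export
qtl_h2 <- function(lod, n) {
  if (any(lod < 0, na.rm = TRUE)) stop("lod must be >= 0", call. = FALSE)
  stopifnot(all(n >= 1))
  1 - 10^(-2 * lod / n)
}

#' Call QTL peaks from a scan with genome-wide P-values
#'
#' Applies, in order: (1) putative QTLs are windows with `p < alpha`
#' (strict); (2) putative peaks are putative QTLs that are local LOD maxima
#' (a plateau of tied LODs counts once, represented by its first window);
#' (3) on each arm, if two peaks are not separated by an intervening window
#' with LOD below the minor peak's LOD minus `lod_drop`, the minor peak is
#' removed (pairs processed in descending minor-peak LOD and re-evaluated
#' after each removal); (4) any peak within `min_sep_cM` (genetic midpoints)
#' of a higher-LOD peak is removed; (5) each surviving peak's confidence
#' interval is the maximal contiguous same-arm run of windows with LOD above
#' peak LOD minus `lod_drop`.
#'
#' @param scan A `scan_result` with P-values populated.
#' @param map Window map.
#' @param alpha Genome-wide significance cutoff (default 0.10).
#' @param lod_drop LOD support-interval drop (default 1.5).
#' @param min_sep_cM Minimum genetic separation between peaks (default 10).
#' @return Data.frame of class `qtl_calls`: one row per QTL with peak
#'   window, CI bounds (window ids and bp span), peak LOD, P, effect `b`,
#'   and `h2`. Empty (zero rows) when no window passes `alpha`.
#' @export
call_qtl_peaks <- function(scan, map, alpha = 0.10, lod_drop = 1.5,
                           min_sep_cM = 10) {
  if (all(is.na(scan$p))) stop("scan has no P-values; run genomewide_p()", call. = FALSE)
  ord <- match(map$window_id, scan$window_id)
  lod <- scan$lod[ord]
  p <- scan$p[ord]
  arm <- map$arm
  cm <- map$cM
  usable <- !is.na(lod)

  empty <- data.frame(peak = character(0), arm = character(0),
                      ci_from = character(0), ci_to = character(0),
                      ci_start = numeric(0), ci_end = numeric(0),
                      lod = numeric(0), p = numeric(0), b = numeric(0),
                      h2 = numeric(0), n = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("qtl_calls", "data.frame")

  sig <- which(!is.na(p) & p < alpha)
  if (!length(sig)) return(empty)

  # local maxima among significant windows; plateaus collapse to their first
  # window (ties within a plateau are one candidate peak)
  is_peak <- vapply(sig, function(i) {
    lo <- i; hi <- i
    while (lo > 1L && arm[lo - 1L] == arm[i] && usable[lo - 1L] &&
           lod[lo - 1L] == lod[i]) lo <- lo - 1L
    while (hi < length(lod) && arm[hi + 1L] == arm[i] && usable[hi + 1L] &&
           lod[hi + 1L] == lod[i]) hi <- hi + 1L
    if (lo != i) return(FALSE)          # plateau represented by first window
    left_ok <- lo == 1L || arm[lo - 1L] != arm[i] || !usable[lo - 1L] ||
      lod[lo - 1L] < lod[i]
    right_ok <- hi == length(lod) || arm[hi + 1L] != arm[i] ||
      !usable[hi + 1L] || lod[hi + 1L] < lod[i]
    left_ok && right_ok
  }, logical(1))
  peaks <- sig[is_peak]
  if (!length(peaks)) return(empty)

  # rule 3: 1.5-LOD valley requirement between same-arm peak pairs
  repeat {
    removed <- FALSE
    if (length(peaks) > 1L) {
      pairs <- utils::combn(sort(peaks), 2)
      minor_lod <- apply(pairs, 2, function(pr) min(lod[pr]))
      for (k in order(minor_lod, decreasing = TRUE)) {
        i <- pairs[1, k]; j <- pairs[2, k]
        if (!(i %in% peaks) || !(j %in% peaks)) next
        if (arm[i] != arm[j]) next
        between <- seq(i + 1L, length.out = max(j - i - 1L, 0L))
        minor <- if (lod[i] <= lod[j]) i else j
        valley <- any(usable[between] & lod[between] < lod[minor] - lod_drop)
        if (!length(between) || !valley) {
          peaks <- setdiff(peaks, minor)
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }

  # rule 4: genetic-distance pruning against stronger peaks
  keep <- peaks[order(-lod[peaks], cm[peaks])]
  final <- integer(0)
  for (i in keep) {
    near <- any(arm[final] == arm[i] & abs(cm[final] - cm[i]) < min_sep_cM)
    if (!near) final <- c(final, i)
  }
  final <- sort(final)

  calls <- lapply(final, function(i) {
    thr <- lod[i] - lod_drop
    lo <- i; hi <- i
    while (lo > 1L && arm[lo - 1L] == arm[i] && usable[lo - 1L] &&
           lod[lo - 1L] > thr) lo <- lo - 1L
    while (hi < length(lod) && arm[hi + 1L] == arm[i] && usable[hi + 1L] &&
           lod[hi + 1L] > thr) hi <- hi + 1L
    data.frame(peak = map$window_id[i], arm = arm[i],
               ci_from = map$window_id[lo], ci_to = map$window_id[hi],
               ci_start = map$start[lo], ci_end = map$end[hi],
               lod = lod[i], p = p[i], b = scan$b[ord][i],
               h2 = qtl_h2(lod[i], scan$n[ord][i]), n = scan$n[ord][i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Pairwise trait correlations
#'
#' Pearson correlation on pairwise-complete observations, with the usual
#' t-test P-value. Pairs with fewer than 3 complete observations are left
#' missing and flagged.
#'
#' @param traits Data.frame or matrix of trait values (RILs x traits).
#' @return List with matrices `r`, `p`, `n`, and logical `insufficient`.
#' @export
correlate_traits <- function(traits) {
  traits <- as.matrix(traits)
  k <- ncol(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(traits), colnames(traits)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(traits[, c(i, j)])
    n[i, j] <- sum(ok)
    if (n[i, j] < 3L) next
    ct <- stats::cor.test(traits[ok, i], traits[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- if (i == j) NA_real_ else ct$p.value
  }
  list(r = r, p = p, n = n, insufficient = n < 3L)
}

#' Scan the residuals of one trait regressed on another
#'
#' Ordinary least-squares residuals of `traitA` on `traitB` (shared RILs
#' only) are mapped with [scan_additive()]; used to ask whether two
#' correlated traits carry QTL signal beyond their correlation.
#'
#' @inheritParams scan_additive
#' @param traitA,traitB Named numeric vectors.
#' @return A `scan_result` of the residual trait.
#' @export
map_residuals <- function(traitA, traitB, geno, summary = NULL, map = NULL) {
  shared <- intersect(names(traitA), names(traitB))
  if (length(shared) < 3L) stop("need >= 3 shared RILs", call. = FALSE)
  a <- traitA[shared]; b <- traitB[shared]
  if (stats::var(b) < 1e-12) stop("traitB is constant", call. = FALSE)
  res <- stats::residuals(stats::lm(a ~ b))
  # residuals that are pure rounding error (traitA an affine image of
  # traitB) are zapped so the downstream scan sees a constant phenotype
  res[abs(res) < 1e-9 * stats::sd(a)] <- 0
  names(res) <- shared
  scan_additive(geno, res, summary = summary, map = map)
}
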