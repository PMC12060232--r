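# Two-locus interaction scan.
#
# The interaction LOD for a window pair compares the full model
# y ~ g1 + g2 + g1:g2 against the additive model y ~ g1 + g2, both fit by
# least squares with numeric dosages; the interaction is the single-df
# product term g1 * g2. LOD = (n/2) * log10(RSS_additive / RSS_full). The
# profile of one focal window against all partners is computed in closed
# form from sufficient statistics (3x3 normal equations solved by adjugate,
# elementwise across partners), so permutation nulls stay tractable.

# Per-partner sufficient statistics that do not depend on the phenotype.
interaction_precompute <- function(geno, focal, partners) {
  G <- geno[, partners, drop = FALSE]
  storage.mode(G) <- "double"
  f <- as.numeric(geno[, focal])
  n <- length(f)
  fc <- f - mean(f)
  H <- G * f                                   # product predictor, per partner
  pbar <- colMeans(G)
  hbar <- colMeans(H)
  list(
    G = G, H = H, fc = fc, n = n,
    s11 = sum(fc^2),
    s12 = as.numeric(crossprod(G, fc)),
    s13 = as.numeric(crossprod(H, fc)),
    s22 = colSums(G^2) - n * pbar^2,
    s23 = colSums(G * H) - n * pbar * hbar,
    s33 = colSums(H^2) - n * hbar^2
  )
}

# Vector of interaction LODs for one phenotype against every partner.
interaction_profile_fast <- function(pc, y) {
  yc <- y - mean(y)
  syy <- sum(yc^2)
  nw <- length(pc$s22)
  if (syy <= 0) return(list(lod = numeric(nw), degenerate = rep(TRUE, nw)))
  s1y <- sum(pc$fc * yc)
  s2y <- as.numeric(crossprod(pc$G, yc))
  s3y <- as.numeric(crossprod(pc$H, yc))
  s11 <- pc$s11; s12 <- pc$s12; s13 <- pc$s13
  s22 <- pc$s22; s23 <- pc$s23; s33 <- pc$s33
  n <- pc$n

  det2 <- s11 * s22 - s12^2
  scale2 <- pmax(s11 * s22, 1e-300)
  ok2 <- det2 > 1e-10 * scale2
  ess2 <- ifelse(ok2, (s22 * s1y^2 - 2 * s12 * s1y * s2y + s11 * s2y^2) / det2,
                 if (s11 > 1e-12) s1y^2 / s11 else 0)
  rss_add <- pmax(syy - ess2, 0)

  A <- s22 * s33 - s23^2
  B <- s13 * s23 - s12 * s33
  C <- s12 * s23 - s13 * s22
  D <- s11 * s33 - s13^2
  E <- s12 * s13 - s11 * s23
  F <- s11 * s22 - s12^2
  det3 <- s11 * A + s12 * B + s13 * C
  scale3 <- pmax(s11 * s22 * s33, 1e-300)
  ok3 <- det3 > 1e-10 * scale3
  ess3 <- (A * s1y^2 + D * s2y^2 + F * s3y^2 +
             2 * (B * s1y * s2y + C * s1y * s3y + E * s2y * s3y)) / det3
  rss_full <- pmax(syy - ess3, 0)

  lod <- numeric(nw)
  good <- ok3 & rss_add > syy * 1e-14
  lod[good] <- pmax((n / 2) * log10(rss_add[good] / pmax(rss_full[good], 0)), 0)
  lod[good & rss_full <= syy * 1e-14] <- Inf
  list(lod = lod, degenerate = !ok3)
}

#' Interaction LOD score for one window pair
#'
#' @param geno Dosage matrix or `ril_panel`.
#' @param phenotype Phenotype vector (named by RIL or in row order).
#' @param w1,w2 The two window ids (order is irrelevant; the statistic is
#'   symmetric).
#' @return The interaction LOD (0, with attribute `degenerate = TRUE`, when
#'   the product term is collinear with the additive terms).
#' @export
interaction_lod <- function(geno, phenotype, w1, w2) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  if (identical(w1, w2)) stop("w1 and w2 must differ", call. = FALSE)
  al <- align_phenotype(geno, phenotype)
  keep <- !is.na(al$geno[, w1]) & !is.na(al$geno[, w2])
  if (sum(keep) < 4L) stop("need >= 4 RILs complete at both windows", call. = FALSE)
  pc <- interaction_precompute(al$geno[keep, , drop = FALSE], w1, w2)
  pr <- interaction_profile_fast(pc, al$y[keep])
  structure(pr$lod, degenerate = pr$degenerate)
}

# Resolve a focal window and its excluded partner range from either a
# qtl_calls row (CI excluded), a window id (only itself excluded), or a
# list(focal=, exclude=).
resolve_focal <- function(geno, qtl) {
  wins <- colnames(geno)
  if (inherits(qtl, "qtl_calls") || (is.data.frame(qtl) && "peak" %in% names(qtl))) {
    if (nrow(qtl) != 1L) stop("supply a single QTL row", call. = FALSE)
    i <- match(qtl$ci_from, wins); j <- match(qtl$ci_to, wins)
    list(focal = qtl$peak, exclude = wins[i:j])
  } else if (is.list(qtl) && !is.null(qtl$focal)) {
    list(focal = qtl$focal, exclude = union(qtl$exclude %||% character(0), qtl$focal))
  } else {
    list(focal = qtl, exclude = qtl)
  }
}

#' Interaction scan of a focal QTL against the rest of the genome
#'
#' Computes the interaction LOD between the focal QTL's peak window and
#' every eligible partner: all windows outside the focal QTL's confidence
#' interval that are not skew-excluded. Records the genome-wide maximum and
#' its partner.
#'
#' @inheritParams interaction_lod
#' @param qtl A one-row [call_qtl_peaks()] result (its CI is excluded), a
#'   focal window id, or `list(focal =, exclude =)`.
#' @param summary Optional [window_summary()]; skew-excluded windows are
#'   ineligible partners.
#' @return Object of class `interaction_scan`: list with `focal`, `lod`
#'   (named per-partner vector), `max_lod`, `max_partner`, `p` (NA until
#'   [interaction_p()]), `degenerate` partner flags.
#' @export
interaction_scan <- function(geno, phenotype, qtl, summary = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  al <- align_phenotype(geno, phenotype)
  fx <- resolve_focal(al$geno, qtl)
  partners <- eligible_partners(al$geno, fx, summary)
  if (!length(partners)) stop("no eligible partner windows", call. = FALSE)
  pr <- scan_partners(al$geno, al$y, fx$focal, partners)
  imax <- which.max(pr$lod)
  structure(list(focal = fx$focal, excluded = fx$exclude,
                 lod = stats::setNames(pr$lod, partners),
                 degenerate = stats::setNames(pr$degenerate, partners),
                 max_lod = pr$lod[imax], max_partner = partners[imax],
                 p = NA_real_),
            class = "interaction_scan")
}

eligible_partners <- function(geno, fx, summary = NULL) {
  partners <- setdiff(colnames(geno), fx$exclude)
  if (!is.null(summary)) {
    bad <- summary$window_id[summary$skew_excluded]
    partners <- setdiff(partners, bad)
  }
  setdiff(partners, fx$focal)
}

# Complete-data fast path or per-partner complete-case fallback.
scan_partners <- function(geno, y, focal, partners) {
  cols <- geno[, c(focal, partners), drop = FALSE]
  if (!anyNA(cols)) {
    pc <- interaction_precompute(geno, focal, partners)
    interaction_profile_fast(pc, y)
  } else {
    lod <- numeric(length(partners)); degen <- logical(length(partners))
    for (k in seq_along(partners)) {
      keep <- !is.na(geno[, focal]) & !is.na(geno[, partners[k]])
      if (sum(keep) < 4L) { degen[k] <- TRUE; next }
      pc <- interaction_precompute(geno[keep, , drop = FALSE], focal, partners[k])
      pr <- interaction_profile_fast(pc, y[keep])
      lod[k] <- pr$lod; degen[k] <- pr$degenerate
    }
    list(lod = lod, degenerate = degen)
  }
}

#' Permutation null for the genome-wide maximum interaction LOD
#'
#' Per permutation the phenotype is shuffled, the focal window is held
#' fixed, the full interaction scan is rerun against all eligible partners,
#' and the genome-wide maximum interaction LOD is kept. Shuffling destroys
#' the focal main effect along with any interaction, which makes this null
#' conservative when the focal main effect is strong.
#'
#' @inheritParams interaction_scan
#' @param n_perm Number of permutations.
#' @param seed Root seed.
#' @return A `null_dist` (sorted maxima).
#' @export
interaction_null <- function(geno, phenotype, qtl, summary = NULL,
                             n_perm = 1000L, seed = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  al <- align_phenotype(geno, phenotype)
  fx <- resolve_focal(al$geno, qtl)
  partners <- eligible_partners(al$geno, fx, summary)
  complete <- !anyNA(al$geno[, c(fx$focal, partners), drop = FALSE])
  pc <- if (complete) interaction_precompute(al$geno, fx$focal, partners)
  with_seed(seed, {
    stat <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(al$y)
      if (complete) max(interaction_profile_fast(pc, yp)$lod, 0)
      else max(scan_partners(al$geno, yp, fx$focal, partners)$lod, 0)
    }, numeric(1))
    structure(list(stat = sort(stat), n_perm = as.integer(n_perm),
                   seed = seed, label = "max interaction LOD"),
              class = "null_dist")
  })
}

#' Genome-wide interaction P-value
#'
#' `P = proportion of null maxima >= the observed genome-wide maximum
#' interaction LOD`; 0 means the observation exceeded every permutation.
#'
#' @param scan An `interaction_scan` (or a numeric max LOD).
#' @param null A `null_dist` from [interaction_null()].
#' @param estimator "raw" or "add_one".
#' @return The scan with `p` set (or the numeric P if `scan` is numeric).
#' @export
interaction_p <- function(scan, null, estimator = c("raw", "add_one")) {
  stopifnot(inherits(null, "null_dist"), length(null$stat) > 0)
  estimator <- match.arg(estimator)
  if (is.numeric(scan)) return(null_p(scan, null, estimator))
  scan$p <- null_p(scan$max_lod, null, estimator)
  scan
}
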