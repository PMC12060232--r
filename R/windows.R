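#' Summarize per-SNP diploid ancestry calls into window genotypes
#'
#' Each window's dosage for a RIL is the most frequent non-missing per-SNP
#' call among SNPs falling in `[start, end)` on the window's arm (majority
#' call across any ancestry breakpoint inside the window). An exact tie is
#' broken toward the lower dosage (toward ancestral ancestry). A window with
#' no covered SNPs is missing. SNPs outside every window are ignored; their
#' count is reported via a message.
#'
#' @param calls Data.frame of per-SNP calls with columns `ril`, `arm`, `pos`
#'   (bp), `call` (0/1/2 or NA).
#' @param map Window map (columns window_id, arm, start, end).
#' @return Integer dosage matrix, RILs x windows, aligned to `map`.
#' @export
summarize_windows <- function(calls, map) {
  stopifnot(all(c("ril", "arm", "pos", "call") %in% names(calls)))
  assert_dosage(calls$call, "per-SNP call")
  rils <- sort(unique(calls$ril))
  geno <- matrix(NA_integer_, nrow = length(rils), ncol = nrow(map),
                 dimnames = list(rils, map$window_id))
  dropped <- 0L
  for (a in unique(map$arm)) {
    m <- map[map$arm == a, , drop = FALSE]
    cc <- calls[calls$arm == a, , drop = FALSE]
    if (!nrow(cc)) next
    # windows within an arm are nonoverlapping and sorted, so interval
    # membership reduces to a cut on start positions plus an end check
    wi <- findInterval(cc$pos, m$start)
    inside <- wi >= 1L & cc$pos < m$end[pmax(wi, 1L)]
    dropped <- dropped + sum(!inside)
    cc <- cc[inside, , drop = FALSE]
    wi <- wi[inside]
    if (!nrow(cc)) next
    tab <- table(factor(cc$ril, levels = rils),
                 factor(m$window_id[wi], levels = m$window_id),
                 factor(cc$call, levels = 0:2))
    for (k in seq_len(ncol(tab))) {
      counts <- matrix(tab[, k, ], nrow = dim(tab)[1],
                       dimnames = list(dimnames(tab)[[1]], NULL))
      tot <- rowSums(counts)
      # which.max on the 0/1/2 columns breaks ties toward the lower dosage
      best <- max.col(counts, ties.method = "first") - 1L
      geno[rownames(counts)[tot > 0L], colnames(tab)[k]] <-
        best[tot > 0L]
    }
  }
  dropped_outside <- dropped + sum(!calls$arm %in% map$arm)
  if (dropped_outside > 0L) {
    message(sprintf("summarize_windows: %d SNP call(s) outside all windows ignored",
                    dropped_outside))
  }
  geno
}

#' Merge adjacent windows with identical genotype columns
#'
#' Maximal runs of adjacent same-arm windows whose dosage columns are
#' identical across all RILs (including the missingness pattern) collapse to
#' a single window spanning their union; `n_snps` are summed and the merged
#' window's cM is the midpoint of the run's cM range. Applying the operation
#' twice is a no-op, and no RIL's dosage changes at any retained window.
#'
#' @param geno Dosage matrix aligned to `map`.
#' @param map Window map.
#' @return List with merged `geno` and `map`.
#' @export
merge_identical_adjacent <- function(geno, map) {
  stopifnot(ncol(geno) == nrow(map))
  if (ncol(geno) <= 1L) return(list(geno = geno, map = map))
  same <- vapply(seq_len(ncol(geno) - 1L), function(j) {
    map$arm[j] == map$arm[j + 1L] &&
      identical(unname(geno[, j]), unname(geno[, j + 1L]))
  }, logical(1))
  grp <- cumsum(c(TRUE, !same))
  keep <- !duplicated(grp)
  new_map <- map[keep, , drop = FALSE]
  new_map$end <- tapply(map$end, grp, function(x) x[length(x)])
  new_map$n_snps <- as.integer(tapply(map$n_snps, grp, sum))
  new_map$cM <- as.numeric(tapply(map$cM, grp, function(x) (x[1] + x[length(x)]) / 2))
  rownames(new_map) <- NULL
  new_geno <- geno[, keep, drop = FALSE]
  colnames(new_geno) <- new_map$window_id
  list(geno = new_geno, map = new_map)
}

#' Per-window ancestry summary and skew filter
#'
#' Computes, per window, the derived-ancestry proportion (mean dosage / 2
#' over non-missing RILs), the heterozygote and missing fractions, and flags
#' windows whose ancestry bias reaches `threshold` for either ancestry
#' (derived proportion >= threshold or <= 1 - threshold). Flagged windows
#' are excluded from all scans: a panel-wide bias of 90% or more leaves one
#' genotype class too thin for a stable single-window model fit. Windows
#' with zero non-missing calls are excluded and flagged `all_missing`.
#'
#' @param geno Dosage matrix.
#' @param threshold Exclusion threshold, in (0.5, 1\]; the boundary is
#'   excluded ("90% or greater" at the default 0.9).
#' @return Data.frame of class `window_summary` with one row per window.
#' @export
window_summary <- function(geno, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  assert_dosage(geno)
  n_ok <- colSums(!is.na(geno))
  derived <- colMeans(geno, na.rm = TRUE) / 2
  het <- colMeans(geno == 1L, na.rm = TRUE)
  out <- data.frame(
    window_id = colnames(geno),
    derived_prop = ifelse(n_ok > 0L, derived, NA_real_),
    het_frac = ifelse(n_ok > 0L, het, NA_real_),
    missing_frac = 1 - n_ok / nrow(geno),
    all_missing = n_ok == 0L,
    stringsAsFactors = FALSE
  )
  # symmetric form (max of the two ancestry proportions) avoids the
  # floating-point asymmetry of comparing against 1 - threshold
  out$skew_excluded <- out$all_missing |
    (!is.na(out$derived_prop) &
       pmax(out$derived_prop, 1 - out$derived_prop) >= threshold)
  class(out) <- c("window_summary", "data.frame")
  out
}
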