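#' Fisher's combined probability test
#'
#' Combines k independent P-values as `X = -2 * sum(ln p)`, referred to a
#' chi-square distribution with `2k` degrees of freedom. With k = 1 the
#' combined P equals the input. Exact zeros (attainable under the raw
#' permutation P-value convention) are replaced by `1 / (2 * n_perm)` with a
#' warning, since `ln 0` is undefined; supply `n_perm` to enable this.
#'
#' @param pvalues Numeric vector of P-values in \[0, 1\], nonempty.
#' @param n_perm Number of permutations behind the P-values (used only to
#'   floor exact zeros).
#' @return List with `statistic` (X), `df`, and `p` (combined P).
#' @examples
#' fisher_combined(c(0.736, 0.699, 0.714, 0.244, 0.322, 0.672, 0.444,
#'                   0.941, 0.183, 0.208, 0.853, 0.476, 0.273))$p  # ~0.763
#' @export
fisher_combined <- function(pvalues, n_perm = NULL) {
  if (!length(pvalues)) stop("empty P-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(pvalues == 0)) {
    if (is.null(n_perm)) {
      stop("exact-zero P-value: supply n_perm to floor it at 1/(2*n_perm)",
           call. = FALSE)
    }
    warning(sprintf("replacing %d zero P-value(s) by 1/(2*%d)",
                    sum(pvalues == 0), n_perm))
    pvalues[pvalues == 0] <- 1 / (2 * n_perm)
  }
  X <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = X, df = df,
       p = stats::pchisq(X, df = df, lower.tail = FALSE))
}

#' Smallest number of low P-values whose removal restores a median of 0.5
#'
#' Under the no-epistasis null, interaction P-values are uniform with median
#' 0.5; a depressed median hints at a subset of true signals. This reports
#' the smallest `m` such that removing the `m` lowest P-values leaves a
#' median `>= target`, together with the full median trajectory for every
#' `m` (so other closeness rules can be applied). If even removing all but
#' one value never reaches `target`, `m` is `length(pvalues) - 1` and the
#' `reached` flag is FALSE.
#'
#' @param pvalues Nonempty numeric vector of P-values.
#' @param target Median target (default 0.5).
#' @return List with `m`, `reached`, and `trajectory` (data.frame of m and
#'   the median after removing the m lowest values).
#' @export
median_removal_count <- function(pvalues, target = 0.5) {
  if (!length(pvalues)) stop("empty P-value list", call. = FALSE)
  s <- sort(pvalues)
  ms <- 0:(length(s) - 1L)
  meds <- vapply(ms, function(m) stats::median(s[(m + 1L):length(s)]), numeric(1))
  hit <- which(meds >= target)
  m <- if (length(hit)) ms[hit[1]] else ms[length(ms)]
  list(m = m, reached = length(hit) > 0,
       trajectory = data.frame(m = ms, median = meds))
}
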