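# Simulation-based power analyses: additive QTL detection, epistasis
# detection against a genome-wide max interaction LOD null, and the
# meta-analysis resampling check.

power_grid_row <- function(label, value, det, n_sim, alpha) {
  power <- det / n_sim
  data.frame(grid_var = label, value = value, n_sim = n_sim,
             detections = det, power = power,
             se = sqrt(power * (1 - power) / n_sim), alpha = alpha,
             stringsAsFactors = FALSE)
}

#' Power of the additive genome scan across an effect-size grid
#'
#' Per simulation, a causal window is drawn uniformly from the panel's
#' non-excluded windows (preserving realistic ancestry skew and
#' heterozygosity per draw), a phenotype `Normal(mu, sigma) + a * g` is
#' simulated, its LOD at the causal window is scored against the genome-wide
#' max-LOD permutation null, and detection is `P <= alpha`. Power is
#' reported per additive effect `a` and, secondarily, binned by the realized
#' per-simulation heritability `h2 = 1 - 10^(-2 * LOD / n)`.
#'
#' @param geno Dosage matrix or `ril_panel`.
#' @param summary A [window_summary()] of the panel.
#' @param null A `null_dist` from [permutation_null()] built on the same
#'   panel.
#' @param effects Vector of additive effects `a` (trait units per allele).
#' @param n_sim Simulations per effect.
#' @param mu,sigma Phenotype mean and residual SD.
#' @param alpha Genome-wide detection threshold on P (detection is
#'   `P <= alpha`).
#' @param h2_bins Break points for the secondary h2 binning.
#' @param seed Root seed.
#' @return List with `grid` (per-effect power with binomial SE), `by_h2`
#'   (per-h2-bin power), and `sims` (per-simulation a, window, lod, h2, p).
#' @export
qtl_power_grid <- function(geno, summary, null, effects, n_sim = 500L,
                           mu = 0, sigma = 0.75, alpha = 0.10,
                           h2_bins = seq(0, 0.4, by = 0.02), seed = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  if (!length(effects)) stop("effects grid is empty", call. = FALSE)
  usable <- colnames(geno)[!summary$skew_excluded[match(colnames(geno),
                                                        summary$window_id)]]
  n <- nrow(geno)
  with_seed(seed, {
    sims <- lapply(seq_along(effects), function(e) {
      a <- effects[e]
      win <- sample(usable, n_sim, replace = TRUE)
      lod <- numeric(n_sim)
      for (i in seq_len(n_sim)) {
        g <- geno[, win[i]]
        y <- stats::rnorm(n, mu, sigma) + a * g
        gc <- g - mean(g); yc <- y - mean(y)
        r2 <- sum(gc * yc)^2 / (sum(gc^2) * sum(yc^2))
        lod[i] <- -(n / 2) * log10(1 - min(r2, 1))
      }
      data.frame(a = a, window = win, lod = lod,
                 h2 = qtl_h2(lod, n),
                 p = null_p(lod, null), stringsAsFactors = FALSE)
    })
    sims <- do.call(rbind, sims)
    sims$detected <- sims$p <= alpha
    grid <- do.call(rbind, lapply(split(sims, sims$a), function(d) {
      power_grid_row("a", d$a[1], sum(d$detected), nrow(d), alpha)
    }))
    bins <- cut(sims$h2, breaks = h2_bins, include.lowest = TRUE)
    by_h2 <- do.call(rbind, lapply(split(sims, bins), function(d) {
      if (!nrow(d)) return(NULL)
      out <- power_grid_row("h2_bin", mean(d$h2), sum(d$detected), nrow(d), alpha)
      out
    }))
    rownames(grid) <- rownames(by_h2) <- NULL
    list(grid = grid, by_h2 = by_h2, sims = sims)
  })
}

#' Null distribution of the max interaction LOD under an additive-only model
#'
#' Per simulation the phenotype is `Normal(mu, sigma) + a * g_focal`
#' (additive only: 1x effect for heterozygotes, 2x for derived homozygotes);
#' the genome-wide maximum interaction LOD of the focal window against all
#' partners outside `exclude` is recorded. The resulting distribution is the
#' reference for [epistasis_power()].
#'
#' @inheritParams interaction_scan
#' @param focal Focal window id.
#' @param exclude Window ids excluded as partners (the focal QTL's
#'   confidence interval); the focal itself is always excluded.
#' @param base List with `a`, `mu`, `sigma` (the focal QTL's additive model).
#' @param n_sim Number of null simulations.
#' @param seed Root seed.
#' @return A `null_dist` of genome-wide max interaction LODs.
#' @export
epistasis_null_distribution <- function(geno, focal, exclude = focal, base,
                                        summary = NULL, n_sim = 500L,
                                        seed = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  stopifnot(all(c("a", "mu", "sigma") %in% names(base)), base$sigma > 0)
  fx <- list(focal = focal, exclude = union(exclude, focal))
  partners <- eligible_partners(geno, fx, summary)
  pc <- interaction_precompute(geno, focal, partners)
  g <- as.numeric(geno[, focal])
  n <- length(g)
  with_seed(seed, {
    stat <- vapply(seq_len(n_sim), function(i) {
      y <- stats::rnorm(n, base$mu, base$sigma) + base$a * g
      max(interaction_profile_fast(pc, y)$lod, 0)
    }, numeric(1))
    structure(list(stat = sort(stat), n_perm = as.integer(n_sim),
                   seed = seed, label = "max interaction LOD (null sims)"),
              class = "null_dist")
  })
}

#' Power to detect epistasis across a grid of interaction factors
#'
#' Per simulation at each interaction factor `I`, a phenotype is generated
#' with [simulate_epistatic_phenotype()] (focal effect multiplied by 1,
#' `(1+I)/2`, or `I` for partner dosage 0/1/2); the test statistic is the
#' genome-wide maximum interaction LOD of the focal window (matching the
#' null's statistic; set `statistic = "at_partner"` to score the LOD at the
#' true partner instead). `P` is the proportion of null values at or above
#' the statistic, and power is the proportion of simulations with
#' `P < alpha`.
#'
#' @inheritParams epistasis_null_distribution
#' @param partner True interacting window (outside `exclude`).
#' @param null A `null_dist` from [epistasis_null_distribution()].
#' @param I_grid Vector of interaction factors.
#' @param alpha Detection threshold (default 0.05, strict inequality).
#' @param statistic "max" (genome-wide maximum) or "at_partner".
#' @return List with `grid` (per-I power and binomial SE) and `sims`
#'   (per-simulation I, statistic, p).
#' @export
epistasis_power <- function(geno, focal, partner, exclude = focal, base, null,
                            I_grid, summary = NULL, n_sim = 200L,
                            alpha = 0.05, statistic = c("max", "at_partner"),
                            seed = NULL) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  if (!length(I_grid)) stop("I grid is empty", call. = FALSE)
  statistic <- match.arg(statistic)
  fx <- list(focal = focal, exclude = union(exclude, focal))
  if (partner %in% fx$exclude) {
    stop("partner window must lie outside the excluded interval", call. = FALSE)
  }
  partners <- eligible_partners(geno, fx, summary)
  pc <- interaction_precompute(geno, focal, partners)
  gf <- as.numeric(geno[, focal])
  gp <- as.numeric(geno[, partner])
  n <- length(gf)
  ipartner <- match(partner, partners)
  with_seed(seed, {
    sims <- lapply(I_grid, function(I) {
      mult <- c(1, (1 + I) / 2, I)[gp + 1L]
      stat <- vapply(seq_len(n_sim), function(i) {
        y <- stats::rnorm(n, base$mu, base$sigma) + mult * base$a * gf
        prof <- interaction_profile_fast(pc, y)$lod
        if (statistic == "max") max(prof, 0) else prof[ipartner]
      }, numeric(1))
      data.frame(I = I, stat = stat, p = null_p(stat, null),
                 stringsAsFactors = FALSE)
    })
    sims <- do.call(rbind, sims)
    sims$detected <- sims$p < alpha
    grid <- do.call(rbind, lapply(split(sims, sims$I), function(d) {
      power_grid_row("I", d$I[1], sum(d$detected), nrow(d), alpha)
    }))
    rownames(grid) <- NULL
    list(grid = grid, sims = sims)
  })
}

#' Resampling power of the Fisher meta-analysis
#'
#' For each interaction-effect condition, draws `k` interaction P-values
#' with replacement from that condition's simulated P-value pool and
#' reports (1) how often the Fisher combined P is at or below the observed
#' combined P and (2) how often at least one drawn P-value falls below the
#' observed minimum P.
#'
#' @param sim_p_by_I Named list: per condition, a nonempty vector of
#'   simulated interaction P-values.
#' @param k Number of QTLs combined per resample (>= 1).
#' @param observed_fisher_p Observed Fisher combined P to beat.
#' @param observed_min_p Observed minimum interaction P to beat.
#' @param n_resample Resamples per condition.
#' @param n_perm Permutation count used to floor zero P-values inside
#'   Fisher's statistic.
#' @param seed Root seed.
#' @return Data.frame with one row per condition: `prop_fisher_le` and
#'   `prop_min_lt`.
#' @export
meta_power <- function(sim_p_by_I, k = 13L, observed_fisher_p,
                       observed_min_p, n_resample = 1000L, n_perm = 1000L,
                       seed = NULL) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  stopifnot(length(sim_p_by_I) > 0, all(lengths(sim_p_by_I) > 0))
  with_seed(seed, {
    rows <- lapply(seq_along(sim_p_by_I), function(i) {
      pool <- pmax(sim_p_by_I[[i]], 1 / (2 * n_perm))
      hits_f <- 0L; hits_m <- 0L
      for (r in seq_len(n_resample)) {
        draw <- sample(pool, k, replace = TRUE)
        if (fisher_combined(draw)$p <= observed_fisher_p) hits_f <- hits_f + 1L
        if (min(draw) < observed_min_p) hits_m <- hits_m + 1L
      }
      data.frame(condition = names(sim_p_by_I)[i] %||% as.character(i),
                 k = k, n_resample = n_resample,
                 prop_fisher_le = hits_f / n_resample,
                 prop_min_lt = hits_m / n_resample,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
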