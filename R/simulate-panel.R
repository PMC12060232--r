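#' Default chromosome-arm layout for a synthetic Drosophila RIL panel
#'
#' Five arms (X, 2L, 2R, 3L, 3R) with window counts chosen so the default
#' panel has ~1,000 nonoverlapping ancestry windows of ~19 kb, and arm genetic
#' lengths close to the standard D. melanogaster linkage map.
#'
#' @return A data.frame with columns `arm`, `n_windows`, `cM_length`,
#'   `bp_length`.
#' @export
default_arms <- function() {
  data.frame(
    arm       = c("X", "2L", "2R", "3L", "3R"),
    n_windows = c(210L, 200L, 190L, 190L, 210L),
    cM_length = c(66, 55, 52, 47, 55),
    bp_length = c(22400000, 23000000, 21100000, 24500000, 27900000),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic RIL panel
#'
#' Describes a biparental recombinant-inbred-line panel genotyped as diploid
#' ancestry dosages (0 = ancestral-population homozygote, 1 = heterozygote,
#' 2 = derived-population homozygote) in ordered genomic windows. Defaults
#' emulate the Ethiopia-Zambia panel: 278 RILs, mean derived ancestry 0.68,
#' residual window heterozygosity 0.0871, megabase-scale ancestry tracts.
#'
#' @param n_rils Number of RILs (>= 2).
#' @param arms Arm layout as returned by [default_arms()].
#' @param derived_ancestry Target panel-mean derived-ancestry proportion,
#'   in (0, 1).
#' @param heterozygosity Target fraction of windows left heterozygous after
#'   inbreeding, in \[0, 1).
#' @param effective_meioses Expected ancestry breakpoints per Morgan per RIL;
#'   controls tract length (tract scale is 100/effective_meioses cM).
#' @param seed Root seed for [simulate_panel()].
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_rils = 278L, arms = default_arms(),
                         derived_ancestry = 0.68, heterozygosity = 0.0871,
                         effective_meioses = 12, seed = 1L) {
  stopifnot(is.data.frame(arms),
            all(c("arm", "n_windows", "cM_length") %in% names(arms)))
  if (n_rils < 2L) stop("n_rils must be >= 2", call. = FALSE)
  if (nrow(arms) < 1L || any(arms$n_windows < 1L) || any(arms$cM_length <= 0)) {
    stop("each arm needs >= 1 window and positive cM length", call. = FALSE)
  }
  if (derived_ancestry <= 0 || derived_ancestry >= 1) {
    stop("derived_ancestry must lie in (0, 1)", call. = FALSE)
  }
  if (heterozygosity < 0 || heterozygosity >= 1) {
    stop("heterozygosity must lie in [0, 1)", call. = FALSE)
  }
  if (effective_meioses < 0) stop("effective_meioses must be >= 0", call. = FALSE)
  if (is.null(arms$bp_length)) arms$bp_length <- arms$n_windows * 19000
  structure(list(n_rils = as.integer(n_rils), arms = arms,
                 derived_ancestry = derived_ancestry,
                 heterozygosity = heterozygosity,
                 effective_meioses = effective_meioses,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# Window map implied by an arm layout: equal-width windows per arm, bp
# coordinates 0-based half-open, cM positions at window genetic midpoints,
# nominal 1,000 ancestry-informative SNPs per window.
build_window_map <- function(arms) {
  maps <- lapply(seq_len(nrow(arms)), function(i) {
    nw <- arms$n_windows[i]
    bp_w <- floor(arms$bp_length[i] / nw)
    start <- (seq_len(nw) - 1L) * bp_w
    cm_per_window <- arms$cM_length[i] / nw
    data.frame(
      window_id = sprintf("%s_w%04d", arms$arm[i], seq_len(nw)),
      arm = arms$arm[i],
      start = start,
      end = start + bp_w,
      cM = (seq_len(nw) - 0.5) * cm_per_window,
      n_snps = 1000L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, maps)
}

#' Simulate a RIL panel as an ancestry-dosage matrix plus window map
#'
#' Each RIL's genome is a homozygous mosaic of the two parental ancestries,
#' generated as a Markov tract process along the genetic (cM) axis:
#' breakpoints arrive as a Poisson process with rate `effective_meioses` per
#' Morgan, and each new tract is derived-ancestry with probability calibrated
#' so the realized panel mean matches `derived_ancestry` after the
#' heterozygosity overlay. Residual heterozygosity, mimicking incomplete
#' inbreeding, is added as contiguous runs of dosage-1 windows covering on
#' average a `heterozygosity` fraction of each RIL's windows.
#'
#' @param config A [panel_config()].
#' @return A list of class `ril_panel` with elements `geno` (integer matrix,
#'   RILs x windows, values 0/1/2) and `map` (window map data.frame with
#'   columns window_id, arm, start, end, cM, n_snps).
#' @examples
#' panel <- simulate_panel(panel_config(n_rils = 20, seed = 42))
#' mean(panel$geno) / 2  # close to the 0.68 derived-ancestry target
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  map <- build_window_map(config$arms)
  h <- config$heterozygosity
  # Tract ancestry probability adjusted for the het overlay, which pulls the
  # panel mean toward 0.5: E[dosage]/2 = (1 - h) p' + h / 2.
  p_tract <- (config$derived_ancestry - h / 2) / (1 - h)
  p_tract <- min(max(p_tract, 0), 1)
  lambda <- config$effective_meioses

  with_seed(config$seed, {
    geno <- matrix(0L, nrow = config$n_rils, ncol = nrow(map),
                   dimnames = list(sprintf("RIL_%04d", seq_len(config$n_rils)),
                                   map$window_id))
    for (a in unique(map$arm)) {
      idx <- which(map$arm == a)
      cm <- map$cM[idx]
      d_cm <- diff(cm)
      # Stay probability between adjacent window midpoints under the Poisson
      # breakpoint process; after a breakpoint, ancestry is redrawn.
      p_stay <- exp(-lambda * d_cm / 100)
      for (r in seq_len(config$n_rils)) {
        # Run-length formulation of the Markov tract process: windows sharing
        # a tract (no intervening breakpoint) share one ancestry draw.
        redraw <- if (length(idx) > 1L) stats::runif(length(d_cm)) > p_stay else logical(0)
        tract <- cumsum(c(1L, as.integer(redraw)))
        draws <- stats::rbinom(max(tract), 1L, p_tract)
        geno[r, idx] <- 2L * draws[tract]
      }
    }
    if (h > 0) {
      geno <- overlay_het_tracts(geno, map, h)
    }
    structure(list(geno = geno, map = map), class = "ril_panel")
  })
}

# Heterozygous residue as contiguous runs: per RIL, geometric-length tracts
# (mean 5 windows) are dropped at uniform positions until the expected
# per-RIL heterozygous fraction reaches `h`.
overlay_het_tracts <- function(geno, map, h, mean_tract = 5) {
  nw <- ncol(geno)
  arm_of <- map$arm
  n_target <- h * nw
  for (r in seq_len(nrow(geno))) {
    covered <- 0
    guard <- 0L
    while (covered < n_target && guard < 10L * nw) {
      guard <- guard + 1L
      len <- 1L + stats::rgeom(1L, 1 / mean_tract)
      at <- sample.int(nw, 1L)
      run <- at:min(nw, at + len - 1L)
      run <- run[arm_of[run] == arm_of[at]]  # do not cross arm boundaries
      fresh <- run[geno[r, run] != 1L]
      geno[r, fresh] <- 1L
      covered <- covered + length(fresh)
    }
  }
  geno
}

#' Simulate a phenotype with a single additive QTL
#'
#' `y_i = Normal(mu, sigma) + a * g_i`, where `g_i` is the ancestry dosage at
#' `window` (0/1/2): no dominance, 1x effect for heterozygotes, 2x for
#' derived homozygotes.
#'
#' @param panel A `ril_panel` or a dosage matrix.
#' @param window Window id (column name) or column index of the causal window.
#' @param a Additive effect per derived allele, in trait units.
#' @param mu,sigma Trait mean and residual standard deviation (sigma > 0).
#' @param seed Root seed.
#' @return Named numeric vector of phenotypes (RILs missing a genotype at
#'   `window` are dropped).
#' @export
simulate_additive_phenotype <- function(panel, window, a, mu = 0, sigma = 0.75,
                                        seed = NULL) {
  geno <- if (inherits(panel, "ril_panel")) panel$geno else panel
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  g <- geno[, window]
  keep <- !is.na(g)
  g <- g[keep]
  with_seed(seed, {
    y <- stats::rnorm(length(g), mean = mu, sd = sigma) + a * g
    names(y) <- rownames(geno)[keep]
    y
  })
}

#' Simulate a phenotype with an epistatic modifier of a focal QTL
#'
#' The focal additive effect `a` is scaled per RIL by the genotype at a
#' partner window through the interaction factor `I`: multiplier 1 when the
#' partner is ancestral homozygous (dosage 0), `(1 + I)/2` when heterozygous,
#' and `I` when derived homozygous. `I = 1` recovers the purely additive
#' model; `I = 0` is masking epistasis; negative `I` is sign epistasis;
#' `I > 1` is positive (synergistic) epistasis.
#'
#' @inheritParams simulate_additive_phenotype
#' @param focal,partner Window ids of the focal QTL and the interacting
#'   window (must differ).
#' @param I Interaction factor. The explored range in this package's power
#'   analyses is \[-2, 4\]; values outside trigger a warning, not an error.
#' @return Named numeric phenotype vector.
#' @export
simulate_epistatic_phenotype <- function(panel, focal, partner, a, I,
                                         mu = 0, sigma = 0.75, seed = NULL) {
  geno <- if (inherits(panel, "ril_panel")) panel$geno else panel
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (identical(focal, partner)) {
    stop("focal and partner windows must differ", call. = FALSE)
  }
  if (I < -2 || I > 4) {
    warning("interaction factor I outside the calibrated range [-2, 4]")
  }
  gf <- geno[, focal]
  gp <- geno[, partner]
  keep <- !is.na(gf) & !is.na(gp)
  gf <- gf[keep]; gp <- gp[keep]
  mult <- c(1, (1 + I) / 2, I)[gp + 1L]
  with_seed(seed, {
    y <- stats::rnorm(length(gf), mean = mu, sd = sigma) + mult * a * gf
    names(y) <- rownames(geno)[keep]
    y
  })
}

#' Simulate phenotypes for the same RILs across several environments
#'
#' Per environment `e`, `y = Normal(mu_e, sigma) + a_e * g`; all RILs appear
#' in every environment. Used to exercise reaction-norm and
#' genotype-by-environment tests.
#'
#' @inheritParams simulate_additive_phenotype
#' @param effects_by_env Data.frame with columns `env`, `mu`, `a` (one row
#'   per environment, >= 2 environments).
#' @return Long-format data.frame with columns `ril`, `env`, `phenotype`.
#' @export
simulate_gxe_phenotypes <- function(panel, window, effects_by_env, sigma,
                                    seed = NULL) {
  geno <- if (inherits(panel, "ril_panel")) panel$geno else panel
  stopifnot(is.data.frame(effects_by_env),
            all(c("env", "mu", "a") %in% names(effects_by_env)))
  if (nrow(effects_by_env) < 2L) {
    stop("need >= 2 environments", call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  g <- geno[, window]
  keep <- !is.na(g)
  g <- g[keep]
  rils <- rownames(geno)[keep]
  with_seed(seed, {
    out <- lapply(seq_len(nrow(effects_by_env)), function(i) {
      data.frame(
        ril = rils,
        env = effects_by_env$env[i],
        phenotype = stats::rnorm(length(g), effects_by_env$mu[i], sigma) +
          effects_by_env$a[i] * g,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Simulate a biallelic SNP genotype matrix for two populations
#'
#' Per-population alternate-allele frequencies may be scalars or length
#' `n_snps` vectors; diploid genotypes are drawn binomially. Provides test
#' input for the window F_ST scan.
#'
#' @param n_pop1,n_pop2 Diploid sample sizes (>= 2 each).
#' @param n_snps Number of SNPs (>= 1).
#' @param p1,p2 Alternate-allele frequencies per population.
#' @param seed Root seed.
#' @return List with `geno` (individuals x SNPs dosage matrix) and `pop`
#'   (character vector "pop1"/"pop2").
#' @export
simulate_snp_matrix <- function(n_pop1, n_pop2, n_snps, p1, p2, seed = NULL) {
  if (n_pop1 < 2L || n_pop2 < 2L) {
    stop("need >= 2 individuals per population", call. = FALSE)
  }
  if (n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  p1 <- rep_len(p1, n_snps); p2 <- rep_len(p2, n_snps)
  with_seed(seed, {
    g1 <- sapply(seq_len(n_snps), function(j) stats::rbinom(n_pop1, 2L, p1[j]))
    g2 <- sapply(seq_len(n_snps), function(j) stats::rbinom(n_pop2, 2L, p2[j]))
    geno <- rbind(matrix(g1, nrow = n_pop1), matrix(g2, nrow = n_pop2))
    rownames(geno) <- c(sprintf("p1_%03d", seq_len(n_pop1)),
                        sprintf("p2_%03d", seq_len(n_pop2)))
    colnames(geno) <- sprintf("snp%05d", seq_len(n_snps))
    list(geno = geno, pop = rep(c("pop1", "pop2"), c(n_pop1, n_pop2)))
  })
}

#' Mask a fraction of dosage calls as missing
#'
#' Simulators emit complete matrices; this utility introduces missingness for
#' robustness tests of the complete-case handling in the scans.
#'
#' @param geno Dosage matrix.
#' @param rate Fraction of cells set to NA, in \[0, 1\].
#' @param seed Root seed.
#' @return The matrix with NAs introduced.
#' @export
mask_dosages <- function(geno, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    drop <- which(stats::runif(length(geno)) < rate)
    geno[drop] <- NA
    geno
  })
}
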