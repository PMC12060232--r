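#' Reaction-norm table at a QTL window
#'
#' Mean phenotype, sample size, and standard error per genotype class
#' (dosage 0/1/2) and environment. Empty cells (e.g. no heterozygotes in an
#' environment) are reported with `n = 0` and missing mean/SE.
#'
#' @param geno Dosage matrix or `ril_panel`.
#' @param phenotypes Long data.frame with columns `ril`, `env`, `phenotype`.
#' @param window Window id.
#' @return Data.frame: genotype, env, n, mean, se.
#' @export
reaction_norm <- function(geno, phenotypes, window) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  stopifnot(all(c("ril", "env", "phenotype") %in% names(phenotypes)))
  if (!window %in% colnames(geno)) stop("window not found", call. = FALSE)
  g <- geno[, window]
  d <- phenotypes[phenotypes$ril %in% rownames(geno), , drop = FALSE]
  d$genotype <- g[d$ril]
  d <- d[!is.na(d$genotype), , drop = FALSE]
  cells <- expand.grid(genotype = 0:2, env = unique(phenotypes$env),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n <- 0L; cells$mean <- NA_real_; cells$se <- NA_real_
  for (i in seq_len(nrow(cells))) {
    v <- d$phenotype[d$genotype == cells$genotype[i] & d$env == cells$env[i]]
    cells$n[i] <- length(v)
    if (length(v)) cells$mean[i] <- mean(v)
    if (length(v) > 1L) cells$se[i] <- stats::sd(v) / sqrt(length(v))
  }
  cells
}

#' Genotype-by-environment interaction test at a QTL window
#'
#' Fixed-effects linear model `phenotype ~ genotype + env + genotype:env`
#' with genotype entered as the numeric dosage (default) or as a factor;
#' the reported test is the F-test of the interaction term(s), obtained by
#' comparing the full model to the additive genotype + environment model.
#' RILs measured in several environments contribute one record per
#' environment.
#'
#' @inheritParams reaction_norm
#' @param genotype "numeric" (dosage; 1-df interaction for two
#'   environments) or "categorical".
#' @return List: `coefficient` (interaction coefficient; numeric coding
#'   only), `F`, `df`, `p`, and the fitted `model`.
#' @export
gxe_test <- function(geno, phenotypes, window,
                     genotype = c("numeric", "categorical")) {
  if (inherits(geno, "ril_panel")) geno <- geno$geno
  genotype <- match.arg(genotype)
  if (!window %in% colnames(geno)) stop("window not found", call. = FALSE)
  d <- phenotypes[phenotypes$ril %in% rownames(geno), , drop = FALSE]
  d$g <- geno[, window][d$ril]
  d <- d[!is.na(d$g) & !is.na(d$phenotype), , drop = FALSE]
  if (length(unique(d$env)) < 2L) stop("need >= 2 environments", call. = FALSE)
  if (length(unique(d$g)) < 2L) stop("need >= 2 genotype classes", call. = FALSE)
  if (genotype == "categorical") d$g <- factor(d$g)
  d$env <- factor(d$env)
  full <- stats::lm(phenotype ~ g * env, data = d)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient design: some genotype x environment cells are empty",
         call. = FALSE)
  }
  additive <- stats::lm(phenotype ~ g + env, data = d)
  an <- stats::anova(additive, full)
  coef_int <- if (genotype == "numeric" && nlevels(d$env) == 2L) {
    unname(stats::coef(full)[length(stats::coef(full))])
  } else NA_real_
  list(coefficient = coef_int,
       F = an$F[2], df = c(an$Df[2], an$Res.Df[2]), p = an$`Pr(>F)`[2],
       model = full)
}
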