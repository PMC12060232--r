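test_that("panel simulation is deterministic and hits its calibration targets", {
  cfg <- panel_config(n_rils = 120, seed = 5)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)

  # calibration over seeds, at a reduced panel size for speed
  stats <- sapply(1:8, function(s) {
    p <- simulate_panel(panel_config(n_rils = 120, seed = s))
    c(derived = mean(p$geno) / 2, het = mean(p$geno == 1))
  })
  expect_true(all(abs(stats["derived", ] - 0.68) < 0.03))
  expect_true(all(abs(stats["het", ] - 0.0871) < 0.02))
})

test_that("degenerate panel configurations behave as limits predict", {
  # zero heterozygosity target: all dosages homozygous
  p <- simulate_panel(panel_config(n_rils = 30, heterozygosity = 0, seed = 2))
  expect_true(all(p$geno %in% c(0L, 2L)))

  # no breakpoints: each arm of each RIL is one tract
  p0 <- simulate_panel(panel_config(n_rils = 40, heterozygosity = 0,
                                    effective_meioses = 0, seed = 3))
  for (a in unique(p0$map$arm)) {
    cols <- p0$map$window_id[p0$map$arm == a]
    expect_true(all(apply(p0$geno[, cols], 1, function(r) length(unique(r)) == 1L)))
  }

  expect_error(panel_config(n_rils = 1), "n_rils")
  expect_error(panel_config(derived_ancestry = 1), "derived_ancestry")
  bad_arms <- data.frame(arm = "2L", n_windows = 0L, cM_length = 50)
  expect_error(panel_config(arms = bad_arms), "arm")
})

test_that("dosage correlation decays with genetic distance", {
  p <- simulate_panel(panel_config(n_rils = 200, seed = 11))
  cols <- p$map$window_id[p$map$arm == "2L"]
  g <- p$geno[, cols]
  cm <- p$map$cM[match(cols, p$map$window_id)]
  ref <- 1L
  d <- cm - cm[ref]
  r <- apply(g, 2, cor, y = g[, ref])
  near <- mean(r[d > 0 & d < 5])
  mid <- mean(r[d >= 5 & d < 20])
  far <- mean(r[d >= 30])
  expect_gt(near, mid)
  expect_gt(mid, far)
})

test_that("additive phenotype simulation matches its generative model", {
  p <- small_panel()
  w <- colnames(p$geno)[10]
  y1 <- simulate_additive_phenotype(p, w, a = 0.4, seed = 21)
  expect_identical(y1, simulate_additive_phenotype(p, w, a = 0.4, seed = 21))
  expect_error(simulate_additive_phenotype(p, w, a = 1, sigma = 0),
               "sigma")

  # null effect: overall mean near mu
  y0 <- simulate_additive_phenotype(p, w, a = 0, mu = 2, sigma = 0.5, seed = 4)
  expect_lt(abs(mean(y0) - 2), 3 * 0.5 / sqrt(length(y0)))

  # a = 0.5 at large n: homozygote class difference approaches 2a
  big <- simulate_panel(panel_config(n_rils = 4000, seed = 9))
  wb <- colnames(big$geno)[50]
  yb <- simulate_additive_phenotype(big, wb, a = 0.5, seed = 13)
  g <- big$geno[names(yb), wb]
  expect_lt(abs((mean(yb[g == 2]) - mean(yb[g == 0])) - 1.0), 0.1)
})

test_that("epistatic phenotype applies the interaction-factor multipliers", {
  p <- small_panel()
  wins <- colnames(p$geno)
  f <- wins[5]; q <- wins[80]
  expect_error(simulate_epistatic_phenotype(p, f, f, a = 1, I = 0), "differ")
  expect_warning(simulate_epistatic_phenotype(p, f, q, a = 1, I = 5, seed = 1),
                 "range")

  # I = 1 reproduces the additive simulator exactly under the same seed
  y_add <- simulate_additive_phenotype(p, f, a = 0.3, seed = 17)
  y_epi <- simulate_epistatic_phenotype(p, f, q, a = 0.3, I = 1, seed = 17)
  expect_equal(y_add, y_epi)

  # masking (I = 0): zero focal contribution where the partner is derived
  # homozygous, half where heterozygous -- verified against the generative
  # noise by differencing two seeds-matched simulations
  y0 <- simulate_epistatic_phenotype(p, f, q, a = 10, I = 0, sigma = 1, seed = 3)
  noise <- simulate_epistatic_phenotype(p, f, q, a = 0, I = 0, sigma = 1, seed = 3)
  gf <- p$geno[names(y0), f]; gp <- p$geno[names(y0), q]
  contrib <- y0 - noise
  expect_equal(unname(contrib[gp == 2]), rep(0, sum(gp == 2)))
  expect_equal(unname(contrib[gp == 1]), unname(0.5 * 10 * gf[gp == 1]))
  expect_equal(unname(contrib[gp == 0]), unname(10 * gf[gp == 0]))
})

test_that("gxe simulator produces per-environment effects it was given", {
  p <- small_panel(n_rils = 150)
  w <- colnames(p$geno)[30]
  eff <- data.frame(env = c("15C", "25C"), mu = c(1, 0), a = c(0.6, 0.1))
  d <- simulate_gxe_phenotypes(p, w, eff, sigma = 0.3, seed = 8)
  expect_setequal(unique(d$env), c("15C", "25C"))
  expect_true(all(table(d$ril) == 2))
  expect_error(simulate_gxe_phenotypes(p, w, eff[1, , drop = FALSE], 0.3),
               "environments")

  # recovered slopes per environment approximate the generative ones
  g <- p$geno[, w]
  for (i in 1:2) {
    sub <- d[d$env == eff$env[i], ]
    fit <- lm(sub$phenotype ~ g[sub$ril])
    expect_lt(abs(coef(fit)[2] - eff$a[i]), 4 * summary(fit)$coefficients[2, 2])
  }
})

test_that("snp matrix simulator matches closed-form Hudson expectations", {
  expect_error(simulate_snp_matrix(1, 5, 10, 0.5, 0.5), "individuals")
  expect_error(simulate_snp_matrix(5, 5, 0, 0.5, 0.5), "n_snps")
  sm <- simulate_snp_matrix(40, 40, 400, p1 = 0.8, p2 = 0.2, seed = 6)
  expect_identical(sm, simulate_snp_matrix(40, 40, 400, 0.8, 0.2, seed = 6))
  p1 <- colMeans(sm$geno[sm$pop == "pop1", ]) / 2
  p2 <- colMeans(sm$geno[sm$pop == "pop2", ]) / 2
  est <- snp_fst(p1, p2, 80, 80)
  closed <- snp_fst(0.8, 0.2, 80, 80)$fst
  expect_lt(abs(mean(est$fst, na.rm = TRUE) - closed), 0.05)
})

test_that("masking utility introduces approximately the requested missingness", {
  p <- small_panel()
  m <- mask_dosages(p$geno, 0.2, seed = 44)
  expect_identical(m, mask_dosages(p$geno, 0.2, seed = 44))
  expect_lt(abs(mean(is.na(m)) - 0.2), 0.02)
  expect_true(all(m[!is.na(m)] %in% 0:2))
})
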