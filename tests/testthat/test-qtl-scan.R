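test_that("additive scan reproduces the hand-worked least-squares example", {
  g <- matrix(c(0, 0, 2, 2), 4, 1, dimnames = list(NULL, "w1"))
  s <- scan_additive(g, c(0.1, -0.1, 0.9, 1.1))
  expect_equal(s$b, 0.5)
  expect_equal(s$lod, 2 * log10(1.04 / 0.04), tolerance = 1e-12)
  expect_equal(s$n, 4L)
})

test_that("scan handles degenerate inputs as documented", {
  g <- cbind(w1 = c(0, 0, 2, 2), w2 = c(1, 1, 1, 1))
  # constant phenotype: LOD 0 everywhere
  s0 <- scan_additive(g, rep(3, 4))
  expect_equal(s0$lod, c(0, 0))
  # zero genotype variance: LOD 0 with degenerate flag
  s1 <- scan_additive(g, c(0.1, -0.1, 0.9, 1.1))
  expect_true(s1$degenerate[2])
  expect_equal(s1$lod[2], 0)
  # perfect fit: Inf sentinel with warning
  expect_warning(s2 <- scan_additive(g[, 1, drop = FALSE], c(0, 0, 1, 1)),
                 "perfect")
  expect_identical(s2$lod, Inf)
})

test_that("LOD is invariant to affine phenotype transforms; b flips sign under negation", {
  p <- small_panel()
  y <- simulate_additive_phenotype(p, colnames(p$geno)[7], a = 0.3, seed = 2)
  s <- scan_additive(p, y)
  s_aff <- scan_additive(p, -2.5 * y + 7)
  expect_equal(s_aff$lod, s$lod, tolerance = 1e-9)
  expect_equal(s_aff$b, -2.5 * s$b, tolerance = 1e-9)
  # h2 is unchanged under negation, as is the LOD
  expect_equal(qtl_h2(s_aff$lod, s_aff$n), qtl_h2(s$lod, s$n), tolerance = 1e-9)
})

test_that("scan LODs agree with the lm oracle on random instances, with and without missingness", {
  set.seed(301)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    g <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4,
                dimnames = list(NULL, paste0("w", 1:4)))
    y <- rnorm(n) + 0.3 * g[, 2]
    s <- scan_additive(g, y)
    for (j in 1:4) {
      if (s$degenerate[j]) next
      expect_equal(s$lod[j], lod_oracle(g[, j], y), tolerance = 1e-9)
    }
  }
  # complete-case path: mask some calls and re-check
  set.seed(302)
  g <- matrix(sample(0:2, 200, replace = TRUE), 50, 4,
              dimnames = list(NULL, paste0("w", 1:4)))
  g[sample(length(g), 30)] <- NA
  y <- rnorm(50) + 0.4 * ifelse(is.na(g[, 1]), 0, g[, 1])
  s <- scan_additive(g, y)
  for (j in 1:4) {
    expect_equal(s$lod[j], lod_oracle(g[, j], y), tolerance = 1e-9)
  }
})

test_that("permutation null is deterministic and genomewide_p hits its boundaries", {
  p <- small_panel(n_rils = 40, windows_per_arm = 20)
  y <- rnorm(40)
  n1 <- permutation_null(p$geno, y, n_perm = 50, seed = 77)
  n2 <- permutation_null(p$geno, y, n_perm = 50, seed = 77)
  expect_identical(n1$stat, n2$stat)
  expect_length(n1$stat, 50)
  expect_false(is.unsorted(n1$stat))
  expect_error(permutation_null(p$geno, y, n_perm = 0), "n_perm")

  null <- structure(list(stat = sort(c(1, 2, 3, 4)), n_perm = 4L,
                         seed = 1L, label = "max additive LOD"),
                    class = "null_dist")
  expect_equal(null_p(5, null), 0)        # beyond every permutation
  expect_equal(null_p(1, null), 1)        # at the smallest null value
  expect_equal(null_p(2.5, null), 0.5)    # at the median
  expect_equal(null_p(5, null, "add_one"), 1 / 5)
})

test_that("null-phenotype genome-wide P-values are approximately uniform", {
  p <- small_panel(n_rils = 50, windows_per_arm = 30, seed = 12)
  set.seed(401)
  null <- permutation_null(p$geno, rnorm(50), n_perm = 400, seed = 402)
  ps <- replicate(150, {
    y <- rnorm(50)
    s <- genomewide_p(scan_additive(p$geno, y), null)
    min(s$p, na.rm = TRUE)  # P at the genome-wide max LOD
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("peak calling applies the valley, separation, and CI rules", {
  # minor peak removed: intervening LOD 2.5 >= 3.4 - 1.5
  map <- make_map(5, cM_step = 3)
  s <- make_scan(c(1.0, 3.6, 2.5, 3.4, 1.0), c(0.5, 0.02, 0.2, 0.04, 0.5), map)
  q <- call_qtl_peaks(s, map)
  expect_equal(nrow(q), 1L)
  expect_equal(q$peak, map$window_id[2])

  # two QTLs kept: intervening 1.8 < 3.5 - 1.5 and peaks > 10 cM apart
  map2 <- make_map(5, cM_step = 6)
  s2 <- make_scan(c(1.0, 3.6, 1.8, 3.5, 1.0), c(0.5, 0.02, 0.3, 0.04, 0.5), map2)
  q2 <- call_qtl_peaks(s2, map2)
  expect_equal(q2$peak, map2$window_id[c(2, 4)])

  # same LODs but peaks 6 cM apart: the weaker peak falls to the 10-cM rule
  map3 <- make_map(5, cM_step = 3)
  q3 <- call_qtl_peaks(make_scan(c(1.0, 3.6, 1.8, 3.5, 1.0),
                                 c(0.5, 0.02, 0.3, 0.04, 0.5), map3), map3)
  expect_equal(q3$peak, map3$window_id[2])

  # CI: contiguous windows with LOD > peak - 1.5
  map4 <- make_map(5, cM_step = 1)
  s4 <- make_scan(c(2.0, 2.2, 3.6, 2.2, 1.9), c(0.5, 0.3, 0.01, 0.3, 0.5), map4)
  q4 <- call_qtl_peaks(s4, map4)
  expect_equal(q4$ci_from, map4$window_id[2])
  expect_equal(q4$ci_to, map4$window_id[4])
  expect_equal(q4$ci_start, map4$start[2])
  expect_equal(q4$ci_end, map4$end[4])

  # nothing significant -> empty call set, not an error
  q5 <- call_qtl_peaks(make_scan(rep(1, 5), rep(0.5, 5), map4), map4)
  expect_equal(nrow(q5), 0L)

  # strict inequality at the alpha boundary
  q6 <- call_qtl_peaks(make_scan(c(1, 3, 1, 1, 1), c(0.5, 0.10, 0.5, 0.5, 0.5),
                                 map4), map4)
  expect_equal(nrow(q6), 0L)

  # appending zero-LOD windows does not change the calls
  map7 <- make_map(8, cM_step = 1)
  s7 <- make_scan(c(2.0, 2.2, 3.6, 2.2, 1.9, 0, 0, 0),
                  c(0.5, 0.3, 0.01, 0.3, 0.5, 1, 1, 1), map7)
  q7 <- call_qtl_peaks(s7, map7)
  expect_equal(q7$peak, q4$peak)
  expect_equal(q7$ci_to, q4$ci_to)
})

test_that("h2 formula matches its limits and the single-window regression R2", {
  expect_equal(qtl_h2(0, 100), 0)
  expect_equal(qtl_h2(Inf, 100), 1)
  expect_error(qtl_h2(-1, 100), "lod")

  g <- matrix(c(0, 0, 2, 2), 4, 1, dimnames = list(NULL, "w1"))
  y <- c(0.1, -0.1, 0.9, 1.1)
  s <- scan_additive(g, y)
  r2 <- summary(lm(y ~ g[, 1]))$r.squared
  expect_equal(qtl_h2(s$lod, s$n), r2, tolerance = 1e-12)
})

test_that("trait correlations and residual mapping behave as constructed", {
  p <- small_panel(n_rils = 80)
  w <- colnames(p$geno)[25]
  tA <- simulate_additive_phenotype(p, w, a = 0.6, seed = 31)
  tB <- rnorm(80); names(tB) <- rownames(p$geno)

  tr <- correlate_traits(cbind(A = tA, B = tB[names(tA)], negA = -tA))
  expect_equal(unname(diag(tr$r)), c(1, 1, 1))
  expect_equal(tr$r["A", "negA"], -1)
  expect_true(tr$p["A", "B"] >= 0 && tr$p["A", "B"] <= 1)

  # fewer than 3 complete pairs -> flagged missing
  short <- cbind(A = c(1, 2, NA, NA), B = c(NA, NA, 1, 2))
  tr2 <- correlate_traits(short)
  expect_true(tr2$insufficient["A", "B"])
  expect_true(is.na(tr2$r["A", "B"]))

  # residuals of a trait on itself are zero -> all LODs zero
  expect_error(map_residuals(tA, setNames(rep(1, 80), names(tA)), p$geno),
               "constant")
  sr <- map_residuals(tA, tA, p$geno)
  expect_true(all(sr$lod == 0))

  # traitA = traitB + QTL effect: residual scan peaks at the causal window
  tC <- tB[names(tA)] + 0.8 * p$geno[names(tA), w]
  names(tC) <- names(tA)
  sres <- map_residuals(tC, tB, p$geno)
  expect_equal(sres$window_id[which.max(sres$lod)], w)
})
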