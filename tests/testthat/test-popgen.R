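test_that("per-SNP Hudson F_ST matches closed forms", {
  expect_error(snp_fst(0.5, 0.5, 1, 10), "sample sizes")
  # identical frequencies at large n: near zero
  expect_lt(abs(snp_fst(0.4, 0.4, 1000, 1000)$fst), 0.01)
  # fixed difference: exactly 1
  expect_equal(snp_fst(1, 0, 20, 20)$fst, 1)
  # worked closed form: p1=0.8, p2=0.2, n1=n2=9
  r <- snp_fst(0.8, 0.2, 9, 9)
  expect_equal(r$num, (0.8 - 0.2)^2 - 2 * (0.8 * 0.2 / 8), tolerance = 1e-12)
  expect_equal(r$den, 0.8 * 0.8 + 0.2 * 0.2, tolerance = 1e-12)
  expect_equal(r$fst, r$num / r$den, tolerance = 1e-12)
  # monomorphic in both populations: components (0, 0), fst undefined
  m <- snp_fst(0, 0, 10, 10)
  expect_equal(c(m$num, m$den), c(0, 0))
  expect_true(is.na(m$fst))
})

test_that("window F_ST is a ratio of sums, not a mean of ratios", {
  map <- make_map(2)
  # three SNPs in window 1, none in window 2
  ft <- data.frame(arm = "2L", pos = c(100, 5000, 15000),
                   p1 = c(0.9, 0.5, 0.4), p2 = c(0.1, 0.5, 0.6),
                   n1 = 40, n2 = 40)
  res <- window_fst(ft, map)
  comp <- snp_fst(ft$p1, ft$p2, ft$n1, ft$n2)
  expect_equal(res$fst_fullwin_raw[1], sum(comp$num) / sum(comp$den),
               tolerance = 1e-12)
  expect_equal(res$fst_maxsnp_raw[1], max(comp$fst), tolerance = 1e-12)
  # ratio-of-sums differs from mean-of-ratios on this construction
  expect_false(isTRUE(all.equal(res$fst_fullwin_raw[1], mean(comp$fst))))
  expect_true(is.na(res$fst_fullwin_raw[2]))
  expect_equal(res$n_snps_used, c(3L, 0L))

  # single-SNP window: FullWin equals MaxSNP exactly
  one <- window_fst(ft[1, ], map)
  expect_equal(one$fst_fullwin_raw[1], one$fst_maxsnp_raw[1])
  expect_equal(one$fst_fullwin_raw[1], comp$fst[1])
})

test_that("window F_ST reads VCF genotypes", {
  skip_if_not_installed("vcfR")
  sm <- simulate_snp_matrix(6, 6, 20, p1 = 0.9, p2 = 0.1, seed = 131)
  map <- make_map(2)
  pos <- sort(sample(1:37000, 20))
  vcf <- tempfile(fileext = ".vcf")
  gts <- apply(sm$geno, c(1, 2), function(d) c("0/0", "0/1", "1/1")[d + 1])
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(sm$geno)), collapse = "\t"))
  for (j in 1:20) {
    lines <- c(lines, paste(c("2L", pos[j], ".", "A", "T", ".", "PASS", ".",
                              "GT", gts[, j]), collapse = "\t"))
  }
  writeLines(lines, vcf)
  pops <- setNames(sm$pop, rownames(sm$geno))
  res <- window_fst(vcf, map, pops)
  expect_gt(sum(res$n_snps_used), 0)
  # strong differentiation simulated: window-wide Fst should be high
  expect_gt(max(res$fst_fullwin, na.rm = TRUE), 0.3)

  # VCF-derived frequencies agree with the simulated dosage matrix
  ft <- data.frame(arm = "2L", pos = pos - 1,
                   p1 = colMeans(sm$geno[sm$pop == "pop1", ]) / 2,
                   p2 = colMeans(sm$geno[sm$pop == "pop2", ]) / 2,
                   n1 = 12, n2 = 12)
  res2 <- window_fst(ft, map)
  expect_equal(res$fst_fullwin_raw, res2$fst_fullwin_raw, tolerance = 1e-9)
})

test_that("outlier flagging respects eligibility, ties, and input order", {
  map <- make_map(200)
  res <- data.frame(window_id = map$window_id, arm = "2L",
                    start = map$start, end = map$end, n_snps_used = 10L,
                    fst_fullwin_raw = seq(0, 1, length.out = 200),
                    fst_maxsnp_raw = seq(0, 1, length.out = 200))
  res$fst_fullwin <- res$fst_fullwin_raw
  res$fst_maxsnp <- res$fst_maxsnp_raw
  iv <- data.frame(arm = "2L", start = 0, end = 200 * 19000)
  fl <- flag_outliers(res, recomb_intervals = iv)
  # 200 eligible windows at 1%: exactly 2 flagged per statistic absent ties
  expect_equal(sum(fl$outlier_fullwin), 2L)
  expect_equal(which(fl$outlier), c(199L, 200L))

  # windows outside the eligible interval are never flagged
  iv2 <- data.frame(arm = "2L", start = 0, end = 100 * 19000)
  fl2 <- flag_outliers(res, recomb_intervals = iv2)
  expect_false(any(fl2$outlier[101:200]))
  expect_true(any(fl2$outlier[1:100]))

  # all values tied: every eligible window sits at the threshold and is flagged
  res_tie <- res
  res_tie$fst_fullwin <- res_tie$fst_maxsnp <- 0.5
  fl3 <- flag_outliers(res_tie, recomb_intervals = iv)
  expect_true(all(fl3$outlier[fl3$eligible]))

  # order invariance
  perm <- sample(nrow(res))
  fl4 <- flag_outliers(res[perm, ], recomb_intervals = iv)
  expect_equal(fl4$outlier[order(perm)], fl$outlier)

  # small arm: warning (once per statistic) and at least one window flagged
  expect_warning(expect_warning(
    fl5 <- flag_outliers(res[1:30, ], recomb_intervals = iv), "eligible"))
  expect_gte(sum(fl5$outlier), 1L)

  # user-supplied extra statistic joins the union rule
  extra <- rep(0, 200); extra[5] <- 10
  fl6 <- flag_outliers(res, recomb_intervals = iv, extra_stat = extra)
  expect_true(fl6$outlier[5])
})
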