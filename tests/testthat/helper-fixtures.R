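# Shared fixtures and independent oracles. The oracles go through stats::lm
# so that every closed-form scan path is checked against a generic fitter.

small_panel <- function(n_rils = 60, windows_per_arm = 40, seed = 99,
                        arms = c("2L", "2R", "3L")) {
  layout <- data.frame(arm = arms,
                       n_windows = windows_per_arm,
                       cM_length = 50,
                       bp_length = windows_per_arm * 19000)
  simulate_panel(panel_config(n_rils = n_rils, arms = layout, seed = seed))
}

# Independent single-window LOD oracle: generic lm fit, RSS ratio.
lod_oracle <- function(g, y) {
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(resid(lm(y ~ g))^2)
  (n / 2) * log10(rss0 / rss1)
}

# Independent interaction LOD oracle: two lm fits, RSS ratio.
interaction_oracle <- function(g1, g2, y) {
  n <- length(y)
  rss_add <- sum(resid(lm(y ~ g1 + g2))^2)
  rss_full <- sum(resid(lm(y ~ g1 * g2))^2)
  (n / 2) * log10(rss_add / rss_full)
}

# Minimal scan_result for hand-constructed peak-calling examples.
make_scan <- function(lods, ps, map) {
  out <- data.frame(window_id = map$window_id, arm = map$arm, cM = map$cM,
                    n = 100L, b = 0.1, lod = lods, p = ps,
                    excluded = FALSE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

make_map <- function(n, arm = "2L", cM_step = 1) {
  data.frame(window_id = sprintf("%s_w%04d", arm, seq_len(n)), arm = arm,
             start = (seq_len(n) - 1) * 19000, end = seq_len(n) * 19000,
             cM = seq_len(n) * cM_step, n_snps = 1000L,
             stringsAsFactors = FALSE)
}
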