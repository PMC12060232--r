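---
title: "Methods: additive QTL scans, epistasis tests, and power analysis for ancestry-window RIL panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive QTL scans, epistasis tests, and power analysis for ancestry-window RIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqtl)
```

## The mapping design

rilqtl analyzes biparental recombinant inbred line (RIL) panels in which
each line's genome is a mosaic of two parental ancestries — here modeled on
two *Drosophila melanogaster* panels crossing a derived population
(Ethiopia or France) to an ancestral-range Zambian line. Genotypes are not
SNPs but *ancestry windows*: nonoverlapping intervals (~19 kb, nominally
1,000 ancestry-informative SNPs each) carrying a diploid ancestry dosage

* 0 — homozygous ancestral (Zambian) ancestry,
* 1 — heterozygous,
* 2 — homozygous derived ancestry.

Windows, not SNPs, are the unit of every test: they moderate the number of
model fits while remaining far narrower than the megabase-scale ancestry
tracts that recombination and inbreeding leave in a RIL.

## Additive single-locus scan

At each window the phenotype is modeled as a Gaussian linear regression on
the numeric dosage, `y = b0 + b g + e`. The LOD score is the base-10 log
likelihood ratio of this model against the intercept-only model; for
Gaussian maximum likelihood this is

```
LOD = (n / 2) * log10(RSS_null / RSS_model)
```

with both models fit by least squares (the ML solution under Gaussian
errors). The additive (numeric-dosage) coding is deliberate: residual
heterozygosity in these panels is low (5–9% of windows), so a categorical
three-genotype model would routinely meet near-empty heterozygote classes.

Windows with an ancestry bias of 90% or greater toward either ancestry are
excluded before scanning (`window_summary()`); with 278–328 RILs, a 90/10
split leaves the minor genotype class too thin for a stable fit. "Ancestry
bias" is measured as the dosage mean divided by 2, i.e. heterozygotes count
half toward each ancestry; the filter is exactly symmetric in the two
ancestries.

Genome-wide significance uses the standard permutation approach: trait
values are shuffled against whole genotype rows (preserving inter-window
LD), the genome-wide maximum LOD is recorded per permutation, and each
window's P-value is the proportion of null maxima at or above its LOD. The
raw proportion is reported, so P = 0 is attainable and means "more extreme
than every permutation"; the `(r+1)/(n+1)` estimator is available via
`estimator = "add_one"`.

Peak calling (`call_qtl_peaks()`) proceeds in five steps: windows with
P below 0.10 (strict) are putative QTLs; putative QTLs that are local LOD
maxima are putative peaks; a minor peak not separated from another peak by
a window with LOD below (minor LOD − 1.5) is removed; any peak within
10 cM of a stronger peak is removed; and each surviving peak's confidence
interval is the maximal contiguous run of windows with LOD above
(peak LOD − 1.5). Two tie-break rules are deliberate choices where the
procedure is otherwise underdetermined: a plateau of exactly tied LODs
counts as a single candidate peak represented by its first window, and
peak-pair pruning processes pairs in descending minor-peak LOD with
re-evaluation after every removal, which makes the outcome independent of
input order. The 10-cM separation is measured between window genetic
midpoints, the same midpoint convention used for window cM positions
throughout.

QTL heritability is `h2 = 1 - 10^(-2 LOD / n)`, which is algebraically the
regression R² of the same single-window fit.

## Two-locus epistasis scan

For a focal QTL, every window outside the QTL's confidence interval (and
not skew-excluded) is tested as a partner by comparing

```
y ~ g1 + g2 + g1:g2    versus    y ~ g1 + g2
```

by least squares; the interaction is the single-degree-of-freedom product
of numeric dosages, and the interaction LOD is `(n/2) log10(RSS_add /
RSS_full)`. The statistic is exactly symmetric in the two windows. The
null distribution fixes the focal window, shuffles the phenotype, rescans
all partners, and keeps the genome-wide maximum interaction LOD; the
observed maximum is scored against it. Because shuffling destroys the
focal main effect along with any interaction, this null is conservative
when the focal main effect is strong — a property worth keeping in mind
when interpreting borderline P-values.

Both scans are computed from closed-form sufficient statistics (the 3×3
normal equations solved by adjugate, elementwise across partners), so a
full permutation null over ~1,000 windows costs well under a second for a
278-RIL panel. Degenerate partners — zero variance, or a product term
collinear with the additive terms (e.g. no RIL carries derived alleles at
both windows) — get interaction LOD 0 with a flag rather than an error.
Windows with missing calls drop to a per-window complete-case path; the
test suite checks both paths against generic `lm()` fits at 1e-9.

## Meta-analysis

Interaction P-values from independent QTLs are combined with Fisher's
method: `X = -2 Σ ln p ~ χ²(2k)`. QTLs for correlated traits whose
intervals overlap are first reduced to the top-LOD member per overlap
group (`meta_input_pvalues()`). Exact-zero P-values (possible under the
raw convention) are floored at `1/(2 n_perm)` with a warning before
taking logs. As a complementary diagnostic, `median_removal_count()`
reports how many of the lowest P-values must be removed before the median
of the remainder reaches 0.5 — the null median of uniform P-values —
formalizing "near 0.50" as "median ≥ 0.5" while also returning the full
median trajectory so users can apply their own closeness rule.

The package ships the empirical QTL catalog of the two Drosophila panels
(`example_qtl_catalog()`): 14 QTLs for pigmentation, wing length, ethanol
resistance, and courtship song, with the two overlapping stripe-ratio QTLs
forming one overlap group. Combining the 13 representative interaction
P-values gives a Fisher combined P of 0.763, and the smallest single
interaction P-value is 0.183 — no evidence of epistasis involving these
adaptive loci.

## Synthetic panels

`simulate_panel()` generates panels with the statistical structure the
analysis assumes, so that every stage runs without the sequenced panels.
Each RIL's genome per arm is a homozygous ancestry mosaic from a Markov
tract process along the cM axis: breakpoints arrive as a Poisson process
with rate `effective_meioses` per Morgan, and each tract's ancestry is an
independent Bernoulli draw. Residual heterozygosity from incomplete
inbreeding is overlaid as contiguous dosage-1 runs (mean five windows)
covering the target fraction of each RIL's genome — heterozygous tracts,
not i.i.d. flips, matching how real residual heterozygosity clusters. The
tract ancestry probability is adjusted to `(p - h/2)/(1 - h)` so the
realized panel-mean derived proportion hits the target despite the
heterozygosity overlay pulling it toward 0.5.

Defaults are the Ethiopia-panel conditions: 278 RILs, derived-ancestry
proportion 0.68, window heterozygosity 0.0871, ~1,000 windows of ~19 kb
across five arms (X, 2L, 2R, 3L, 3R) with arm genetic lengths near the
standard fly linkage map. `effective_meioses = 12` is a calibration
choice, not an observed quantity: the generating pedigree's effective
meiosis count is not identifiable from the published panel summaries, and
12 per Morgan yields ~8-cM (megabase-scale) tracts with strong local and
negligible cross-arm dosage correlation, the linkage scale the analyses
assume. A realistic panel is the point; pedigree-explicit breeding
simulation is deliberately out of scope because the scans depend only on
marginal ancestry proportions, heterozygosity, and tract-scale linkage.

What the generator does *not* emulate matters for interpretation: no
segregation distortion beyond the global ancestry skew, no
window-to-window variation in skew (real panels have some windows near the
exclusion boundary), no missing data (use `mask_dosages()` to add it), no
genotyping error, and cM maps that are uniform within arms. Passing power
and calibration tests on these panels therefore demonstrates the
statistical machinery, not the idiosyncrasies of any real panel.

Phenotype simulators follow the generative models of the analyses:
`simulate_additive_phenotype()` adds `a·g` to Gaussian noise;
`simulate_epistatic_phenotype()` scales the focal effect by the partner
genotype through the interaction factor `I` (multiplier 1, `(1+I)/2`, `I`
for partner dosage 0/1/2), so `I = 1` is purely additive, `I = 0` masks
the focal effect, `I < 0` reverses its sign, and `I > 1` amplifies it.
All simulators take one root seed and are bit-reproducible.

## Power analyses

Additive power (`qtl_power_grid()`): per simulation a causal window is
drawn uniformly from the non-excluded windows — preserving realistic skew
and heterozygosity per draw — a phenotype with mean 0 and SD 0.75 is
simulated for each additive effect on the grid 0.05–0.5, and the LOD at
the causal window is scored against the panel's permutation null;
detection is P ≤ 0.1. Power is reported per effect and binned by realized
per-simulation h², since the per-draw genotype distribution makes the
same `a` produce a range of variance explained. On the default panel the
h²-binned curve crosses 0.8 well below h² = 0.1, matching expectation:
h² = 0.1 at n = 278 implies LOD ≈ 6.4 against genome-wide thresholds
near 2.8.

Epistasis power (`epistasis_null_distribution()` + `epistasis_power()`):
the base model uses a real mapped QTL's parameters — additive effect
0.035, trait mean 0.3485, trait SD 0.0697 (an abdominal pigmentation QTL
of intermediate strength). The null is built from additive-only
simulations recording the genome-wide max interaction LOD versus the
focal window; epistatic simulations at each `I` are scored against it and
power is the fraction with P < 0.05. The simulated statistic is the
genome-wide maximum (like-for-like with the null); scoring the LOD at the
true partner instead is available via `statistic = "at_partner"`. Power
exceeds 80% for sign epistasis (I = −2) and for positive epistasis
amplifying the focal effect 2.5-fold, and decays quickly toward the null
level at I = 1 — so a negative scan rules out strong epistasis but says
little about weak modulation.

Meta-analysis power (`meta_power()`) resamples k interaction P-values per
condition and reports how often the Fisher combined P beats an observed
value and how often the minimum beats an observed minimum; under uniform
inputs these have the closed forms `p_obs` and `1 - (1 - p_min)^k`, which
the tests verify.

Default simulation sizes (1,000 permutations, 500 null simulations,
100–200 simulations per grid point) are desk-scale choices: binomial
standard errors at these sizes are ~0.03 on a power estimate, adequate for
a power curve read at the 0.8 line. All sizes are arguments.

## G×E and differentiation scans

`gxe_test()` fits the fixed-effects model `phenotype ~ genotype +
environment + genotype:environment` with numeric dosage (categorical
available behind a flag) and reports the interaction F-test from the
two-model comparison; RILs measured in both environments contribute one
record per environment, matching a fixed-effects reading of the model (no
RIL random effect). `reaction_norm()` tabulates cell means and SEs per
genotype × environment.

`window_fst()` computes Hudson-estimator F_ST per SNP — numerator
`(p1-p2)² - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
`p1(1-p2) + p2(1-p1)` — and summarizes windows two ways: the ratio of
summed components (window-wide) and the maximum single-SNP ratio. The
ratio-of-sums is used rather than the mean of per-SNP ratios, the standard
choice for block estimators. The Hudson form is a deliberate estimator
choice, documented so users comparing against other conventions
(Weir–Cockerham, Nei) know what they are looking at. `flag_outliers()`
restricts eligibility to shipped high-recombination intervals (selection
signals in low-recombination regions lack gene-scale resolution), flags
the per-arm top 1% per statistic with ties included at the threshold, and
takes the union across statistics, optionally including a user-supplied
haplotype statistic computed elsewhere.

## Numerical conventions

* Coordinates are 0-based half-open (BED-like) on disk and in memory; VCF
  positions are converted on read.
* Majority-call window summarization breaks exact ties toward the lower
  dosage (toward ancestral ancestry).
* The skew filter uses `max(p, 1-p) >= threshold`, which is exactly
  symmetric and avoids floating-point asymmetry at the 0.9 boundary.
* Perfect single-window fits report LOD = Inf with a warning; constant
  phenotypes give LOD 0 everywhere.
* RILs missing a genotype at a tested window are dropped for that window
  only (complete-case per window, and per pair for interaction tests).
* All randomness flows from explicit root seeds; derived stage seeds stay
  within 32-bit integer range.

## A worked run

```{r pipeline, eval = FALSE}
panel <- simulate_panel(panel_config(n_rils = 278, seed = 1))
y <- simulate_additive_phenotype(panel, "2L_w0100", a = 0.3, seed = 2)
man <- run_pipeline(panel$geno, y, panel$map, out_dir = "run",
                    n_perm = 1000, seed = 3)
man$n_qtls
```

The manifest written alongside the stage tables records the package
version, seeds, settings, input checksums, and timings, and suffices to
reproduce every numeric output.
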