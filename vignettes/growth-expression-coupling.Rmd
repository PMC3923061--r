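---
title: "Linking gene expression to growth phenotype across yeast strain panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene expression to growth phenotype across yeast strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthexpr)
library(dplyr)
```

## The problem

When budding-yeast cells are moved between environments, growth rate and
gene expression move together in well-characterized ways: ribosomal-protein
(RP) and ribosome-biogenesis (Ribi) transcripts track growth rate, and the
environmental stress response (ESR) moves against it. Whether the same
coupling holds *across related wild strains growing in one environment* is a
different question, and answering it requires a chain of fairly specific
computational steps: custom-array probe normalization, growth-rate
estimation from plate-reader OD curves, and correlation of predefined
gene-group expression profiles against per-strain phenotypes.

`growthexpr` implements that chain for a study design of two species
(*S. cerevisiae*, *S. paradoxus*) with twelve strains each, grown on glucose
and on the pentose xylulose — a carbon source that enters metabolism through
the pentose phosphate pathway (PPP) after phosphorylation by xylulokinase,
and which spreads the strains' growth rates far more widely than glucose
does. Because the package is validated without access to any real arrays, it
ships a synthetic-cohort generator whose ground truth embeds the quantities
the analysis is supposed to recover.

## The synthetic cohort

`cohort_config()` fixes the study conditions; `simulate_cohort()` generates
every artifact deterministically from the seed.

* **Array design.** Each of the (default) 2000 genes gets 3–4 probes, each
  printed 3–4 times. One probe per gene sits at the gene's 3' end
  (`dx = 0`, called P_last); the others sit at distinct distances `dx` up to
  1200 bp.
* **Phenotypes.** True growth rates are log-normal per condition with mean
  0.45 /h, CV 0.13 on glucose and mean 0.15 /h, CV 0.29 on xylulose — the
  dispersion contrast that motivates using xylulose at all. Log-normal keeps
  every rate positive; no particular distribution is implied by the design,
  and the CV is what matters downstream.
* **Coupled expression.** For a configured coupling $(g, p, \rho)$ the
  group's per-strain mean shift is built as
  $s\,(\rho z + \sqrt{1-\rho^2}\,\varepsilon)$ with $z$ the standardized
  phenotype, $\varepsilon$ iid standard normal and $s$ = 0.5 log2 units, so
  the *expected* Pearson correlation between group mean expression and
  phenotype is exactly $\rho$. The default configuration couples the
  amino-acid-biosynthesis (GCN4 regulon) group to xylulose growth rate with
  $\rho = -0.79$ and leaves every other group uncoupled. Individual genes
  add 0.25 log2 units of independent noise around the group mean, so a
  20–120-gene group attenuates the realized correlation by well under 1%.
* **Probe intensities.** On the log2 scale a placement reads
  `true expression − amplitude·dx/max(dx) + probe offset + placement noise`.
  The linear-in-`dx` attenuation (default amplitude 1.0 log2 over the
  widest spacing) mimics reverse-transcription fall-off toward the 5' end;
  its functional form is a package choice — only monotone decay matters to
  the correction, which is nonparametric.
* **Growth curves.** Three phases — flat lag (2 h), exponential at the true
  rate, saturation at OD 1.5 — sampled every 30 min for 30 h, multiplied by
  log-normal noise with CV 0.02 and unit mean.

What the generator deliberately does **not** emulate: dye-swap and spatial
array artifacts, background fluorescence, scanner saturation, diauxic or
biphasic growth, and cross-condition correlation of a strain's rates.
Passing tests on this cohort therefore validate the *computational chain*,
not robustness to every pathology of real arrays and plate readers.

## Probe-to-gene normalization

`normalize_experiment()` composes six stages, each exported on its own:

1. `median_over_replicates()` — median over a probe's 3–4 placements
   (midpoint rule for even counts).
2. `compute_dx_dy()` — per sample and gene, `dy` is the log2 ratio of each
   probe to its gene's P_last probe; paired with the probe's `dx`.
3. `fit_positional_bias()` — Lowess (span 0.3, 3 robustifying iterations)
   of `dy` on `dx`, pooled across all genes of a sample. Pooling is
   necessary: a single gene contributes 2–3 pairs, far too few for a local
   fit. The curve is evaluated on the unique-`dx` grid, interpolated
   linearly between points, held constant beyond the range, and anchored so
   the offset at `dx = 0` is exactly zero. A `pool = "batch"` mode fits one
   curve across all samples instead.
4. `apply_bias_correction()` — subtracts the fitted offset at each probe's
   `dx`; since the trend is an attenuation (negative `dy` at large `dx`),
   subtracting it raises distal probes back up.
5. `summarize_gene_intensity()` — per-gene median over its corrected
   probes.
6. `percentile_normalize()` — quantile normalization to the mean-quantile
   reference: each column's rank-ordered values are replaced by the
   across-column mean at that rank. Ties get the mean of the reference
   values their ranks span; missing values are rank-excluded and preserved,
   with unequal column sizes matched by linear interpolation on fractional
   ranks. The reference is the arrays' own pooled distribution — nothing
   external is imported.

Log base 2 is used throughout, the microarray convention. The two channels
of a two-colour array are treated as independent samples, since in this
design they carry different strains (and sometimes different sugars); no
between-channel MA-loess is applied, and no background subtraction or
spatial correction is attempted.

`compute_log_ratios()` then subtracts matched glucose from xylulose log2
values per gene and strain; a value missing on either carbon source is
missing in the ratio.

On synthetic cohorts with amplitude-1.0 bias and realistic noise the
pipeline's per-sample output correlates at >0.99 with the generator truth,
and the residual `dy`-vs-`dx` trend after correction is below 10% of the
injected amplitude.

## Growth-rate estimation

Rates come from the slope of $\ln(\mathrm{OD})$ versus time over the
curve's log-linear portion. "Linear portion" needs an operational rule;
the package uses the easy-linear strategy standard for plate-reader data
(Hall et al. 2014, *Mol Biol Evol* 31:232): score the slope in every
sliding window of `h` points, locate the maximal-slope window, accept
every window whose slope reaches at least 95% of that maximum (`quota`),
and refit a single least-squares line over the union of the accepted
windows. Lag and saturation points never enter the fit, because any small
window touching them has a visibly diluted slope — on a noiseless
lag/exponential/plateau curve the recovered window is the exact
exponential segment. The sliding width defaults to
$h = \max(w_{\min}, \lceil n/6 \rceil)$ with $w_{\min} = 5$ points (2.5 h
at 30-min sampling): tying the width to sampling density keeps the
single-window slope noise from dominating the maximum on densely sampled
curves, which would otherwise hand the fit to a lucky short window and
bias slow growers upward. The fit is flagged `low_confidence` when its
$R^2$ falls below `r2_min = 0.99` or when no window has positive slope
(the best-$R^2$ minimal window is then reported). We considered the
simpler rule "longest contiguous window with $R^2 \ge 0.99$ and positive
slope", but on long series a global $R^2$ threshold is insensitive to a
few flat lag points (three lag points among twenty exponential ones still
fit at $R^2 = 0.990$), which depresses fast growers' slopes by 5–10% and
compresses the cohort dispersion; the quota rule has no such blind spot.
`fit_growth_rate()` reports the natural-log slope, $t_d = \ln 2 / \mu$,
and the window; doubling time is base-invariant, so the choice of natural
log is cosmetic. All windows are scored in O(1) via cumulative sums.

`cohort_dispersion()` is the sample CV (n−1 standard deviation over mean),
invariant to rescaling all rates. At 24 strains the sample CV of
log-normal rates runs slightly below its population value (median ≈ 0.283
for a true 0.29); this is a property of the statistic at small n, not of
the estimation chain, and the recovered dispersions sit within a few
thousandths of that finite-sample value.

## Group profiles and phenotype correlations

Gene groups (RP, Ribi, ESR induced/repressed, proteasome,
amino-acid biosynthesis, glycolysis+fermentation, PPP, TCA, respiratory
chain) load from standard GMT via `read_gmt()`; a small synthetic fixture
ships in `inst/extdata/`. Before profiling, `filter_min_strains()` drops
genes observed in fewer than `k = 14` of the 24 strains; the filter is
global, not per-group. `group_mean_profile()` is the unweighted mean over
the group's genes per strain, excluding missing entries per strain.

All correlations are Pearson with pairwise-complete deletion and a
two-sided t-test p-value ($n-2$ df); significance is called at
$\alpha = 0.01$ with no multiple-testing correction, matching the single
fixed threshold the analysis is designed around — `scan_groups()` adds a
Bonferroni column for transparency but does not gate on it. The scan ranks
groups by $|r|$ (ties alphabetically) and flags the strongest significant
anti-correlation. Two classification helpers round out the module:
`classify_ppp_genes()` labels pathway genes by correlation sign at
threshold ±0.3 and induction sign at log-difference ±0.2 (values exactly
at a threshold classify as uncorrelated/unchanged — strict inequalities),
and `classify_condition_bimodal()` applies a quadrant rule at
$\theta = 0.5$ log2 to separate RP-modulated from AA-modulated conditions;
$\theta$ is a package choice with no external reference value.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 42)
run <- run_pipeline(cfg, out_dir = tempfile("run"))
run$dispersion      # estimated growth-rate CV per carbon source
run$scan            # group scan: AA_biosynthesis flagged anti-correlated
autoplot(run$scan)
```

`run_pipeline()` executes simulate → normalize → growth → correlate →
report, writes TSV artifacts plus a JSON summary and a YAML copy of the
resolved configuration beside them, reuses existing stage outputs unless
`force = TRUE`, and is byte-reproducible under a fixed seed.

## Problem sizes and numerical choices

The validation suite runs its Monte-Carlo checks at 200 cohorts for
coupling recovery (24 strains; 100 conditions for the mutant-panel case)
and growth-dispersion recovery, and 500 cohorts for the null-scan
false-positive rate — sizes at which the medians' sampling error is several
times smaller than the tolerances being checked. Degenerate inputs are
errors, not silent results: empty probe tables, genes lacking a P_last
probe in a sample (skipped with a warning), columns with fewer than two
observed values, zero-variance correlation inputs, non-positive OD, and
non-positive fitted slopes. Lowess needs at least 10 pairs; the error
advises pooling across samples. Ties in the window search and the group
scan are broken deterministically so that reruns are identical.

## Known limitations

* The slope-quota window rule cannot reject a boundary point that happens
  to lie within a few percent of the exponential line (e.g. the first
  saturation sample when the cap almost coincides with the line); such
  points are statistically indistinguishable from the linear portion and
  their inclusion moves the slope by well under 1%.
* Quantile normalization assumes mostly-balanced expression changes; when
  one group moves with a phenotype in one direction, the forced common
  distribution leaks a small opposite-signed common-mode shift into every
  other gene. The leaked amplitude is tiny (hundredths of a log2 unit at
  the default 6% coupled fraction), but because a group-mean profile
  averages away per-gene noise, the leak can still register as a sizable
  *correlation* for otherwise-null groups in the scan of normalized data.
  Interpret secondary hits accordingly (inspect the profile amplitude, not
  only `r`); the false-positive control tests are run on unnormalized
  expression, where the scan holds its nominal error rate.
* The generator draws each condition's phenotypes independently, so
  cross-condition analyses (e.g. glucose-rate vs xylulose-rate) carry no
  signal by construction.
* `simulate_condition_set()` reuses the cohort machinery with one coupled
  group; it does not emulate mutant-specific expression signatures beyond
  that coupling.
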