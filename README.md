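# growthexpr

Tools for asking whether gene expression tracks growth phenotype **across
related yeast strains**, the way it famously does across environments.
The motivating design: 24 wild budding-yeast strains (12 *S. cerevisiae*,
12 *S. paradoxus*) profiled on custom two-colour 60K microarrays while
growing on glucose and on the pentose **xylulose** — a naturally rare sugar
that enters metabolism through the pentose phosphate pathway and spreads
the strains' growth rates widely (inter-strain std/mean ≈ 0.29, versus
≈ 0.13 on glucose). The package implements the full computational chain for
such a study and a synthetic-cohort generator with known ground truth so
that every stage is testable without the original arrays.

## What it computes

**Probe-to-gene normalization** (`normalize_experiment()`), for arrays
where each gene carries 3–4 probes, each printed 3–4 times:

1. median over a probe's replicate placements;
2. per gene, distances `dx` of each probe to the gene's 3′-most probe
   (P_last) paired with `dy = log2(I_probe / I_Plast)`;
3. Lowess fit of the `dy`-vs-`dx` trend (the 3′-positional bias left by
   reverse transcription), pooled across genes, anchored to 0 at `dx = 0`;
4. subtraction of the fitted trend from all probe log2 intensities;
5. per-gene median over corrected probes;
6. percentile (quantile) normalization so all samples share one value
   distribution.

**Growth-rate estimation** (`fit_growth_rate()`): the slope μ of ln(OD)
versus time over the log-linear portion of each growth curve, located by
the easy-linear sliding-window rule (maximal-slope window, 95% slope quota,
union refit); doubling time t_d = ln 2 ⁄ μ. `cohort_dispersion()` gives the
inter-strain std/mean.

**Group/phenotype correlation** (`group_mean_profile()`, `scan_groups()`):
per-strain mean log2 expression (or xylulose/glucose log-ratio) of
predefined gene groups — ribosomal proteins (RP), ribosome biogenesis
(Ribi), environmental stress response (ESR), amino-acid biosynthesis
(GCN4 regulon), PPP, TCA, respiratory chain, … — correlated against
phenotypes with Pearson's r, two-sided t-test p-values and an α = 0.01
significance call; genes observed in fewer than 14 of the 24 strains are
filtered first (`filter_min_strains()`). `classify_ppp_genes()` labels
pathway genes by correlation sign (threshold ±0.3) and induction sign
(log-difference ±0.2); `profile_similarity()` compares strain profiles to
reference-condition profiles; `classify_condition_bimodal()` separates
RP-modulated from AA-modulated conditions.

**Synthetic cohorts** (`simulate_cohort()`): array design, log-normal
strain phenotypes, expression with configurable group/phenotype couplings
(target Pearson ρ embedded by construction), probe intensities with linear
3′ decay, and three-phase OD curves sampled every 30 min — all
deterministic functions of one seed.

## Worked example

```r
library(growthexpr)

cfg <- cohort_config(n_genes = 1000,
                     group_sizes = c(RP = 60, Ribi = 75, AA_biosynthesis = 60,
                                     PPP = 15, TCA = 20, RC = 30),
                     seed = 42)
run <- run_pipeline(cfg, out_dir = "demo_run")
run
#> <growthexpr_run>
#>   outputs in: demo_run
#>   growth-rate CV [glucose]: 0.126
#>   growth-rate CV [xylulose]: 0.285
#>   strongest group correlation: AA_biosynthesis (r = -0.80, p = 2.5e-06)
```

The estimated growth-rate dispersions recover the configured contrast
(0.13 on glucose, 0.29 on xylulose), and the scan of group log-ratio
profiles against the xylulose growth rate:

```r
dplyr::select(run$scan, group, r, n, p_value, significant)
#>             group       r  n  p_value significant
#> 1 AA_biosynthesis -0.8016 24 2.50e-06        TRUE
#> 2            Ribi  0.5931 24 2.25e-03        TRUE
#> 3              RP  0.5425 24 6.17e-03        TRUE
#> 4             TCA  0.4942 24 1.41e-02       FALSE
#> 5              RC  0.2871 24 1.74e-01       FALSE
#> 6             PPP  0.0693 24 7.48e-01       FALSE
```

recovers the amino-acid-biosynthesis coupling that the generator embedded
(ρ = −0.79) through the entire probe-level pipeline. The smaller
positive r of the uncoupled RP/Ribi groups is the documented common-mode
leak of quantile normalization (tiny in amplitude, visible as correlation
because group means average out gene noise); see the methods vignette
(`vignettes/growth-expression-coupling.Rmd`) for the model, parameter and
limitation discussion.

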