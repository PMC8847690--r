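---
title: "Multi-trait GWAS meta-analysis, empirical significance and colocalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GWAS meta-analysis, empirical significance and colocalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pleioscan implements a complete discovery cascade for pleiotropic GWAS
loci from summary statistics alone: N-weighted multivariate meta-analysis
of correlated traits, an empirical experiment-wide significance threshold,
locus definition with pleiotropy and novelty filters, and Bayesian
colocalization of trait–trait and trait–molecular-QTL signals. This
vignette is the package's account of the underlying models, the choices
that were genuinely open, and what the synthetic-data experiments do and
do not establish.

## The multivariate association statistic

Each trait contributes a per-variant signed Z-score, harmonized so that
every trait's score refers to the same effect allele. For a scan over
traits $1..K$ with sample sizes $N_i$, the combined statistic is

$$ Z_{multi} \;=\; \frac{\sum_i \sqrt{N_i}\, z_i}
   {\sqrt{\sum_{ij} \sqrt{N_i N_j}\, R_{ij}}} $$

where $R$ is the correlation of the traits' Z-scores under the null. The
numerator is the usual sample-size-weighted meta-analysis; the denominator
inflates the variance for the correlation that sample overlap and shared
polygenic background induce between the traits' statistics. At $R = I$
and equal $N$ this reduces to $\sum z_i / \sqrt K$; at perfect correlation
it returns the common $z$ unchanged (no information gain). Case-control
traits enter with the effective sample size $4/(1/N_{cases} +
1/N_{controls})$.

$R$ is estimated as the Pearson correlation of the z columns over all
shared variants. That estimate is inflated when strong signals are
present (they correlate across traits by construction); a null-restricted
estimate (variants with $|z| < 1.96$ in both traits) is available via
`estimate_z_correlation(panel, null_restrict = 1.96)`. The all-variants
estimate is the default because the threshold-resampling model is defined
in terms of the correlation of the statistics actually scanned; the
choice is configurable and the tests exercise both.

The scan design is fixed by `enumerate_scans()`: a core disease pair, one
trivariate scan per risk factor (core + risk), and one bivariate scan of
the first core trait with each risk factor — nine traits yield fifteen
scans.

## Experiment-wide significance by max-|Z| resampling

Scans over overlapping trait sets are strongly dependent, so a Bonferroni
correction across scans is conservative. The package instead estimates
the family-wise $\alpha = 0.05$ threshold empirically: draw $S$ sets of
$M$ independent $K$-vectors from $\mathrm{MVN}(0, R_{scan})$, where
$R_{scan}$ is the correlation between the scans' multivariate statistics
(estimated over the intersection of their variants); keep each set's most
extreme $|Z|$; report the 95th percentile of the $S$ maxima as
$z^\star$, with $p^\star$ its two-sided tail. Study-scale defaults are
$S = 10^4$, $M = 10^6$; tests and the acceptance script use scaled-down
sizes ($M = 10^4$, $S = 2{\times}10^3$) where independent-test
configurations admit a Šidák closed form $1 - 0.95^{1/(KM)}$ as an
oracle.

Numerical choices, fixed for determinism:

* the max is over $|z|$ (two-sided convention, consistent with the
  reference z↔p pair the threshold reproduces);
* quantiles use linear interpolation between order statistics (type 7);
* sampling is chunked so memory is bounded at any $M$, and fully
  reproducible from the seed;
* $R$ is repaired to the nearest correlation matrix by eigenvalue
  clipping and rescaling; inputs with eigenvalues below $-0.1$ are
  refused rather than silently repaired;
* the MVN square root is taken by eigendecomposition rather than
  Cholesky so that degenerate (perfectly correlated) scan sets still
  sample correctly.

At this scale the 95th-percentile estimate itself carries Monte-Carlo
noise: on the p scale the relative standard error is roughly
$z^\star\,\sigma_q \approx 10\%$ per run for $K{=}15$. Oracle comparisons
therefore average replicate thresholds rather than judging one draw.

## Loci and the filter cascade

Variants below the per-scan genome-wide threshold are grouped greedily:
the most significant unclaimed variant becomes a sentinel and claims all
variants within 1 Mb plus any variant in LD at $r^2 > 0.2$ regardless of
distance; ties break by (chromosome, position). A sentinel's locus is
then screened by:

1. **pleiotropy** — every scan trait nominally associated at the
   sentinel ($p < 5\times10^{-3}$, strict);
2. **no single-trait driver** — no scan trait genome-wide significant at
   the sentinel ($p > 5\times10^{-8}$, strict);
3. **HLA exclusion** — the locus window must not intersect
   chr6:25,000,000–34,000,000 (GRCh37, conventional extended-MHC bounds;
   the source text names only "the HLA region");
4. **novelty** — no locus member within 500 kb of, or in $r^2 > 0.2$
   with, a known-association catalog entry for any scan trait. Trait
   matching is exact-string on a controlled vocabulary; no ontology
   mapping is attempted. The 500 kb member-wise rule is the stricter of
   the two phrasings the source material uses, applied to all members.

Loci surviving the filters are merged across scans by single-linkage
clustering (identical sentinels collapse first, then sentinels within
1 Mb on one chromosome merge transitively); the representative is the
lowest multivariate p. Tiers: *nominal* at $p_{multi} < 5\times10^{-8}$,
*experiment-wide* below the resampled $p^\star$.

## Colocalization

Evidence for a shared causal variant uses per-variant Wakefield
approximate Bayes factors: with $V = se^2$, $W$ the prior variance of the
true effect and $r = W/(W{+}V)$,
$\log \mathrm{ABF} = \tfrac12\log(1-r) + r z^2/2$. Prior effect SDs are
0.15 for quantitative traits and 0.2 (log-odds) for case-control traits;
per-variant configuration priors are $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ (pairwise) and $10^{-4}/10^{-6}/10^{-7}$ for
configurations tying a variant to one/two/three traits. These are the
published defaults of the underlying approach; none are printed in the
reference analysis, and all are configurable. Note the ABFs are
calibrated for trait-scale `beta`/`se`; the pipeline reconstructs
$se = 1/\sqrt{2N\,maf(1-maf)}$ from the panel rather than feeding bare
unit-variance z-scores, which would flatten every Bayes factor.

Pairwise hypotheses H0–H4 are summed over single-causal-variant
configurations with log-sum-exp (the H3 distinct-pair sum uses the
identity $\sum_{i\ne j} = \sum_i\sum_j - \sum_{i=j}$ via a log-space
difference). The trivariate engine enumerates all 15 sharing
configurations of three traits — each trait null or associated,
associated traits partitioned among shared causal variants — scoring
multi-group configurations over distinct variant assignments by
inclusion–exclusion. Windows are 500 kb centered on the sentinel,
boundary variants included; posteriors are validated against brute-force
enumeration to $10^{-10}$ on small windows.

The decision quantity is the conditional probability of colocalization,
$PP4/(PP3{+}PP4)$ — for three traits, the full-sharing posterior over the
five configurations in which every trait carries a signal (the
trivariate analogue is defined here by that reading; the reference
analysis only states it by example). Verdicts: colocalized at $\ge 0.8$,
borderline in $(0.5, 0.8)$, otherwise distinct; both-zero numerators are
flagged undefined rather than coerced.

**Allelic heterogeneity.** A second independent signal in the window
violates the single-causal assumption and drags the conditional
probability down. Where the reference workflow relied on visual regional
plots, the package uses an automated proxy: any in-window variant with
single-trait $p < 10^{-5}$ and $r^2 < 0.1$ with the sentinel triggers
approximate conditional analysis,
$z_{adj} = (z - r\,z_{cond})/\sqrt{1-r^2}$ with signed $r$, after which
colocalization is retried. Conditioning at $|r| \ge 1 - 10^{-6}$ is
refused as collinear.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure the analysis
assumes, not human genetics: AR(1) LD blocks ($corr = \rho^{|i-j|}$,
default $\rho = 0.8$) spaced 2 Mb apart (beyond the locus radius, so
blocks are independent loci; 100 blocks per synthetic chromosome), an
exchangeable cross-trait null correlation (default 0.3) for sample
overlap, uniform allele frequencies on (0.05, 0.5), and planted causal
variants: the per-trait Z-mean is $\Sigma \lambda_t$, noise has the
separable covariance (within-trait $\Sigma$) × (cross-trait overlap
matrix) — the simplest structure consistent with both marginals, and the
generator's core assumption. Effects are back-filled as
$se = 1/\sqrt{2N\,maf(1-maf)}$, $\beta = z\,se$; case-control traits are
simulated directly on the z scale with effective-N back-fill (no
liability-scale model). Planted loci default to per-trait non-centrality
5.5; trait-specific loci use the same default so that rejection by the
pleiotropy filter, not signal starvation, is what removes them.

What passing tests therefore show: the estimators recover generator
parameters, the threshold is calibrated under its own sampling model, and
the cascade's verdicts track the generator's truth tables. What they do
not show: robustness to real LD (long-range, MAF-coupled), trait
architectures with polygenic confounding, mis-specified overlap
correction, or catalog vocabulary mismatches.

## Calibration experiments and problem sizes

Two whole-pipeline experiments are exposed as functions so every reported
rate is recomputed at run time:

* `fwer_experiment()` — global-null panels with **independent** variants
  (the threshold models $M$ independent MVN draws, so calibration is
  assessed under its own model; with LD the threshold is conservative by
  design, exactly as a genome-wide $M$ is at study scale). Defaults: 400
  replicates, 2000 variants, 3 scans, 300 resampling sets. Expected
  exceedance ~5%.
* `recovery_experiment()` — panels with three planted shared loci, two
  trait-specific loci and one catalog-known locus at non-centrality 5.5,
  scored for exact recovery of the three shared loci as novel.

The recovery experiment measures a structural property worth stating
plainly: the filter cascade demands every single-trait sentinel p inside
$(5\times10^{-8}, 5\times10^{-3})$ — a window only 2.64 standard
deviations wide on the z scale. A unit-variance sentinel score lands in
any such window with probability at most $\Phi(1.32)-\Phi(-1.32) \approx
0.81$ per trait, so a two-trait locus passes with probability at most
~0.66 and three loci jointly at most ~0.29, at *any* effect size; at
non-centrality 5.5 the per-locus pass rate is ~0.23 and exact three-locus
recovery is ~1%. High exact-set recovery under these filters is thus
impossible in principle, not a tuning failure; the experiment reports the
measured rate rather than obscuring it. Practically this means the
published-style cascade trades sensitivity for specificity: loci whose
single-trait evidence drifts above genome-wide significance are
deliberately surrendered to the single-trait studies.

Default test problem sizes (panels of 750–10,000 variants, resampling at
$M = 10^4$, $S \le 2{\times}10^3$, 100–400 replicates) were chosen so the
whole suite exercises every stage at desk scale; the study-scale defaults
remain available on the function interfaces.

## Known limitations

* Single causal variant per trait per window is inherent to the
  colocalization model; the conditional-analysis rescue handles one
  secondary signal, not general multi-signal fine-mapping (no SuSiE-style
  decomposition, no credible sets).
* The novelty screen is exact-string on trait labels; real catalog trait
  vocabularies require curation upstream.
* No liftover: all positions are assumed GRCh37.
* Direction concordance for QTL colocalization is computed on signs
  only; effect-unit normalization across QTL datasets is out of scope.
* The generator plants no MAF–LD coupling and no heritability-partitioned
  architecture; calibration statements are conditional on its separable
  covariance model.
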