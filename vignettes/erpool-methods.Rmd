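---
title: "Models and methods behind erpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erpool)
```

`erpool` analyses replicated evolve-and-resequence (E&R) experiments on
Pool-Seq data and simulates them. This vignette is the package's account of
the underlying models, the parameters that matter, the numerical choices we
made where the design was genuinely open, and the limits of what the
synthetic data can show. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The population-genetic model

Each locus is biallelic and unlinked. One generation consists of a
deterministic selection update with genotype fitnesses
$w_{11} = 1 + s$, $w_{12} = 1 + hs$, $w_{22} = 1$,

$$p' \;=\; \frac{p\,(p\,w_{11} + q\,w_{12})}{p^2 w_{11} + 2pq\,w_{12} + q^2},$$

followed by binomial sampling of $2N_e$ gametes. $N_e$ is the *drift*
size, deliberately decoupled from the census size $N$: in fly-cage
experiments the census is controlled (1,250 here) while the realized
$N_e$ is much smaller and replicate-specific; the census only matters for
pool composition. Frequencies 0 and 1 are absorbing. `ne = Inf` gives the
deterministic trajectory, which is the reference path for
selection-coefficient estimation.

Pooled sequencing adds two more binomial layers
(`pool_sequence()`): $2n$ chromosomes into the pool at the population
frequency, then $R$ reads at the pool frequency. The frequency estimate
therefore has variance
$p(1-p)\left[\tfrac{1}{2n} + \left(1 - \tfrac{1}{2n}\right)\tfrac1R\right]$,
which the test suite checks against simulation, and which reappears in the
$N_e$ estimator's sampling correction.

A *secondary* (dilution) experiment founds new replicates at
$p_{D0} = m\,p_{\text{evolved}} + (1-m)\,p_{\text{ancestral}}$ — mixing is
modelled on allele frequencies, i.e. individuals contribute proportionally
and the family structure of the reconstituted ancestral population is
ignored. The deterministic-range language of dilution planning
(`plan_dilution()`, default target window 0.25–0.75 for the D0
frequencies) relies on exactly this linear model, so the planner and the
simulator agree by construction.

## Synthetic data: what it emulates, and what it does not

`simulate_experiment()` produces the study conditions used throughout the
tests: three replicates at census 1,250, founder frequencies on the grid
$k/852$ (two alleles from each of 426 founding lines; fixation classes
excluded), 56–261× coverages are representable via per-sample means with
Poisson cell-level variation (default mean 80×), additive selection on a
chosen SNP subset, and an optional secondary phase with its own replicate
set and $N_e$ values.

Deliberate simplifications:

* **No linkage.** Variants drift independently (an optional
  `block_size > 1` makes groups share one trajectory for hitchhiking
  demonstrations, but it is off by default). Real selective sweeps drag
  megabase-scale SNP blocks; passing tests on unlinked data say nothing
  about how wide a real selection signature is.
* **No recombination, no haplotypes, autosomes only.** An X-linked locus
  would need a 3/4 drift scaling that we expose nowhere.
* **Stationary coverage model.** Real libraries have correlated,
  GC-dependent depth; here depth is exchangeable across SNPs, which is
  also what the matched-null construction assumes.

Randomness is streamed per (replicate, phase, stage) from one root seed,
so a fixed seed reproduces every count exactly; subsetting variants does,
however, change the draws of the remaining ones (vectorised generation was
chosen over per-variant substreams, whose millions of re-seedings dominate
runtime at genome scale).

## The candidate scan

Within a replicate, ancestral-vs-evolved allele counts are compared by a
two-sided Fisher's exact test (minimum-likelihood tail: the p value sums
hypergeometric probabilities not exceeding the observed table's, the
convention of `stats::fisher.test`, implemented as vectorised enumeration
so that genome scans and their simulated nulls stay fast). Across
replicates we use the Mantel–Haenszel chi-square with hypergeometric
stratum moments and no continuity correction; at Pool-Seq depths the
correction is negligible and conventions differ. A single stratum reduces
to $(N-1)/N$ times the Pearson chi-square — the standard MH definition.
Degenerate tables (a zero margin) yield $p = 1$ with a flag rather than an
error, and p values are floored at the smallest positive double so that
$-\log_{10}$ transforms stay finite. Tests consume raw integer counts;
pseudo-counts exist only on the frequency side.

### Coverage weighting

Deeper-covered SNPs carry more information per test, so raw p values are
re-budgeted by an independent-hypothesis-weighting-style procedure
(`learn_weights()`): the mean per-SNP coverage is split into `n_bins = 5`
equal-occupancy groups; group weights are searched on a simplex grid
(step 0.25) under the budget constraint (occupancy-weighted mean weight
exactly 1, restored after the grid by rescaling) to maximise discoveries
at the working level; and weights are cross-fitted over `n_folds = 5`
folds, so an item is never weighted by a rule that saw it. The published
IHW convex optimiser is intentionally replaced by this grid search: the
contract that matters downstream — budgeted, covariate-driven,
cross-fitted weights — is preserved in a dependency-free, exhaustively
testable form. With an uninformative covariate the cross-fit keeps the
weighted tail at its nominal size (a property test asserts the 1 % tail
stays within [0.005, 0.02] on uniform p values). Fewer than `10 * n_bins`
items trigger an all-ones fallback.

### Empirical FDR from matched neutral simulations

The null model is *the experiment itself without selection*:
`simulate_neutral_matched()` re-simulates every SNP neutrally from its
observed starting frequency (pseudo-count stabilised), at the replicate's
estimated $N_e$, resampling the starting counts at the observed starting
coverage (sequencing noise must enter the null at both ends, or the null
would be anti-conservatively narrow) and pool-sequencing the final
generation at the observed final coverage. Each of the `M = 10` null sets
is pushed through the *identical* test-and-weighting machinery; since the
null tables are item-matched, each null item inherits the cross-fit fold
of its observed twin, making the two pipelines procedurally
indistinguishable.

At a threshold $t$, with $T(t)$ null exceedances pooled over the $M$ sets
and $n(t)$ observed exceedances,

$$\widehat{\mathrm{FDR}}(t) \;=\; \min\!\left(1,\;
  \frac{q_{\Gamma}\!\left(0.95,\, T(t)+1\right)/M}{\max(1, n(t))}\right),$$

where $q_\Gamma(\cdot)$ is the gamma quantile giving the exact one-sided
Poisson upper confidence bound on the null mean (Garwood bound). The
upper bound, not the plain ratio, is the operative design choice: because
candidates are declared at the *largest* threshold passing the cutoff,
downward noise in a plug-in ratio systematically leaks false discoveries
at the declaration boundary; with only ten simulated null sets this is
measurable. The bound's level is exposed (`level`, default 0.95;
`level = 0` recovers the plug-in ratio). Per-item q values are the
monotone step-down envelope $q(t) = \min_{t' \ge t} \widehat{\mathrm{FDR}}(t')$
and declaration (`declare_candidates()`) takes the largest threshold with
$q \le \alpha$, reported jointly at 1 % and 5 %.

One practical consequence of conservativeness: the smallest attainable
estimate at a threshold with $n$ observed exceedances is
$q_\Gamma(0.95, 1)/(M\,n) \approx 3/(Mn)$, so a 1 % declaration requires
roughly $n \ge 30$ candidates when $M = 10$. Small screens should either
report at 5 % or raise `n_null_sets`.

## Estimators

**Pseudo-counts.** $\hat p = (\text{alt} + 0.5)/(R + 1)$ (Laplace-half),
isolated in `pseudo_count_freq()` so the recipe can be swapped; zero
coverage is a missing cell, never a zero frequency.

**Temporal $N_e$** (`estimate_ne()`). Per SNP,
$F_c = (p_0 - p_t)^2/(z - p_0 p_t)$ with $z = (p_0+p_t)/2$, aggregated as
a ratio of sums. Sampling noise is removed through
$1/S = 1/(2n) + 1/R - 1/(2nR)$ per time point, with two refinements over
the textbook linearisation, both verified against independent simulation:
the final-time noise term is scaled by the drift-reduced terminal
heterozygosity (solving $F = \bar F - 1/S_0 - (1-F)/S_t$), and the
corrected $F$ is inverted through the exact relation
$E[F] = 1 - (1 - \tfrac{1}{2N_e})^t$ rather than $N_e = t/(2F)$, which
overshoots by ~20 % once $t/N_e$ is no longer small (at $t = 60$,
$N_e \approx 200$ — precisely the regime of a 60–70-generation fly
experiment). Plan-II sampling is assumed (pooled individuals are not
returned; census $\gg$ pool is not required since the pool here *is* the
census). A non-positive corrected $F$ means no drift signal beyond
sampling noise and is reported as an infinite estimate with a flag, not an
error. Fewer than 100 informative SNPs trigger a variance warning.

**Selection coefficients** (`estimate_s()`). For additive selection the
continuous-time logit of $p$ is linear with slope $s/2$; in discrete
generations the increment is $\log(1 + s/2)$ at low frequency. We fit a
least-squares slope $b$ of $\mathrm{logit}(p_t)$ on generations and invert
$\hat s = 2(e^b - 1)$. This estimator is essentially exact for
$s \lesssim 0.1$ but acquires a deterministic *downward* bias of ~8–11 %
by $s = 0.3$, because the recursion's logit increment declines as $p$
rises; the test suite pins both regimes. We keep the logit-linear form
deliberately: it is the field's convention for two-time-point data, and
an exact-recursion inverse would report systematically larger values for
strong sweeps, breaking comparability. Only $h = 0.5$ is supported —
other dominance values have no closed-form logit-linear inverse and are
refused loudly.

## Secondary-experiment validation

`run_secondary()` re-runs the identical scan on the dilution phase
(D0 vs. D30), then summarises repeatability for the primary candidates
(`concordance_summary()`): Pearson correlation and sign concordance of the
paired AFCs, a normal-theory 99 % probability ellipse
(Mahalanobis$^2$ at the $\chi^2_2$ quantile) around the focal SNPs, and a
*separation score* — the fraction of focal SNPs outside the 99 % ellipse
of a matched neutral cloud (one neutral realisation of both phases, per
the single-simulation comparison convention; more via
`simulate_neutral_matched()`). Sign concordance and separation are the
meaningful validation metrics; the within-candidate Pearson correlation is
range-restricted almost by construction. The ellipse requires at least
three non-collinear points and degenerates loudly otherwise.

## Numerical and degenerate-input conventions

* Sync positions are 1-based; BED masks 0-based half-open; the conversion
  lives inside `filter_snps()` only.
* The coverage-quantile filter is applied per sample against that sample's
  own genome-wide distribution; one aberrant library suffices to remove a
  SNP (conservative against copy-number artifacts). Being rank-based it is
  exactly idempotent only on coverage distributions with ties at the
  threshold — true of sequencing-like fixtures, not of continuous ones.
* The multi-mapper concordance filter tests mapper × {ref, alt} tables of
  per-mapper pooled counts (the claim is about *the SNP's frequency* per
  mapper, not per library), chi-square by default, exact when any expected
  cell is below 5, BH across SNPs; the test choice is a convention we fix,
  not something the procedure's description determines.
* Alt alleles in sync parsing are the globally most frequent
  non-reference base, ties broken alphabetically — stable across samples
  and replicates.
* FET two-tail ties use the `1 + 10^{-7}` relative tolerance, matching
  `stats::fisher.test`.
* Weight grids break objective ties toward the all-ones vector (smallest
  $\sum_g |w_g - 1|$), so uninformative covariates do not acquire
  arbitrary extreme weights.
* Fractional estimated $N_e$ values are rounded once to an integer gamete
  count $2N_e$ before drift sampling.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely from code at sizes
chosen to make Monte-Carlo assertions sharp but cheap: drift-variance and
neutrality properties at 8,000–20,000 trajectories; the FDR study on
10,100 SNPs × 3 replicates with `M = 10` null sets over 20 seeds; the
$N_e$ recovery at 1,000 SNPs × 50 runs for each of $N_e \in \{100, 200,
500\}$ and at 206; calibration of the tests' own null at 10,000
drift-free SNPs. The exhaustive FET sweep covers every 2×2 table with
both row margins ≤ 30 against a `choose()`-based enumeration oracle.

## Known limitations

* No GLM/time-series modelling of more than two time points per phase; the
  tests are strictly two-sample contrasts.
* No drift-aware likelihood for $s$ (slopes ignore the sampling variance
  structure), and no confidence intervals beyond the slope's.
* The empirical FDR needs its null to be *matched*; if real data violate
  the coverage-exchangeability or unlinked-SNP assumptions, the estimate
  inherits that gap — on real genomes the candidate unit is a linked
  region, not a SNP.
* Haplotype reconstruction and fine mapping are out of scope; a secondary
  experiment validates that selection acts in a region, it does not narrow
  the region.
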