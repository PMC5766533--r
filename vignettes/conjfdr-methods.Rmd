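---
title: "Cross-trait conditional and conjunction FDR: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait conditional and conjunction FDR: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two genome-wide association studies (GWAS) of distinct phenotypes may share
causal variants (pleiotropy) even when neither study alone pins those
variants down. Working only from per-SNP summary statistics — a signed
z-score and a two-sided p-value per variant and trait — this package

1. visualizes shared polygenic architecture through *stratified Q-Q plots*
   (the p-values of trait 1 within nested strata of increasing association
   with trait 2) and tests the strata for fold enrichment with an LD-score
   regression;
2. identifies specific shared loci with the *conjunction FDR*, a symmetric
   two-dimensional extension of the empirical tail-area FDR, followed by
   LD clumping of discoveries into independent loci.

All estimation is empirical: no parametric model is fitted to the effect
size distribution.

## Estimators

### Tail-area FDR

Under the standard two-group view, each SNP is either null or associated.
The tail-area FDR of a p-value $p_i$ is the probability of being null given
a p-value at most $p_i$. With null proportion $\pi_0$ fixed at its
conservative upper bound of 1,

$$\widehat{\mathrm{FDR}}(p_i) \;=\; \frac{p_i}{\hat F(p_i)},\qquad
  \hat F(p_i) = \tfrac1N\,\#\{j : p_j \le p_i\},$$

clamped to $(0, 1]$. All counts are inclusive ($\le$), so the estimator is
well defined at duplicated p-values and every SNP is a member of its own
conditioning set.

### Conditional FDR

The conditional FDR of trait 1 given trait 2 replaces the marginal
empirical cdf with the cdf inside the stratum of SNPs at least as
significant in trait 2:

$$\widehat{\mathrm{condFDR}}(p_{1i} \mid p_{2i}) \;=\;
  \frac{p_{1i}\,\#\{j : p_{2j}\le p_{2i}\}}
       {\#\{j : p_{1j}\le p_{1i} \wedge p_{2j}\le p_{2i}\}}.$$

If the stratum is enriched for trait-1 signal, the conditional cdf exceeds
the marginal one and the condFDR drops below the marginal FDR — the power
gain from pleiotropy. `cond_fdr()` computes this exactly for every SNP in
$O(N\log N)$ (a Fenwick-tree sweep) and is tested for exact equality
against an $O(N^2)$ brute-force counting oracle.

### Conjunction FDR

The conjunction FDR estimates the probability that a SNP is null for
*either* trait (or both). It is the maximum of the two conditional FDRs
taken in both orientations:

$$\widehat{\mathrm{conjFDR}}_i = \max\bigl(
  \widehat{\mathrm{condFDR}}(p_{1i}\mid p_{2i}),\,
  \widehat{\mathrm{condFDR}}(p_{2i}\mid p_{1i})\bigr).$$

The maximum makes the statistic symmetric in the traits and means low
values require joint support; a discovery driven by one trait alone cannot
pass. The default discovery threshold is conjFDR < 0.01 — one expected
false positive among 100 reported findings.

### LD-aware estimation: random pruning and surfaces

Correlated SNPs (linkage disequilibrium, LD) distort empirical cdfs: a
single causal variant drags a whole block of correlated neighbours into the
tail. Following standard practice the estimators are therefore fitted on
randomly pruned SNP subsets: SNPs are visited in random order and kept only
if their $r^2$ with every already-kept SNP is at most 0.8 (one random
representative per greedy-transitive LD block), and the procedure is
repeated for 100 random orders (`build_prune_ensemble()`).

For each pruning mask, the condFDR estimator is evaluated at the nodes of a
two-dimensional grid of $-\log_{10}p$ breakpoints (default 201 equally
spaced points spanning 0–20, i.e. 0.1 spacing, which resolves
genome-wide-significant tails at modest cost); node values are averaged
across masks, monotonized along the primary axis by cumulative minimum (so
discovery sets are nested in significance; the conditioning axis is left
untouched), and per-SNP values — including SNPs that were pruned away —
are assigned by bilinear interpolation in $-\log_{10}p$ space
(`build_fdr_surface()`, `lookup_surface()`). Nodes beyond the data support
take the nearest supported value (flat extension). Whether the original
analyses interpolated on a grid or evaluated the estimator per SNP is not
documented anywhere we know of; node evaluation plus interpolation was
chosen because it makes ensemble averaging well defined for pruned-away
SNPs. With a single all-SNPs mask and grid nodes placed on the data, the
surface reproduces the exact per-SNP estimator to interpolation tolerance.

## Pre-processing model

**Harmonization.** Both tables are aligned to a common reference SNP set:
allele pairs equal to the reference are kept as-is, swapped pairs flip the
z sign, strand-complement pairs are complemented first, and
strand-ambiguous SNPs (A/T, C/G) are dropped outright since allele
frequencies are not assumed available to resolve them. Irreconcilable
allele pairs are dropped with a count.

**Genomic control.** The inflation factor is
$\hat\lambda = \mathrm{median}(z^2)/0.4549$ (the denominator is the median
of a 1-df chi-square), clamped below at 1 so correction never inflates
significance; z-scores are divided by $\sqrt{\hat\lambda}$ and p-values
recomputed. The correction is idempotent.

**Sample overlap.** Shared control subjects induce correlation between the
two traits' z-scores at null SNPs. The null correlation $\rho$ is estimated
from SNPs with $|z| < 2$ in both traits after one random pruning pass.
Restricting a bivariate normal to the box $|z_1|,|z_2| < t$ attenuates its
sample correlation (at $t = 2$ a true $\rho = 0.3$ yields roughly 0.24), so
the raw estimate is debiased by inverting the exact truncated-normal
correlation curve, computed by one-dimensional quadrature of conditional
normal moments. The pair is then whitened with the symmetric inverse square
root of $\begin{pmatrix}1&\rho\\\rho&1\end{pmatrix}$, which maps a
unit-variance correlated pair to an uncorrelated unit-variance pair while
treating the traits exchangeably — exchangeability is what the symmetric
conjunction statistic requires. The original analyses cite an external
adjustment method without printing formulas; this whitening construction is
this package's own, and it is validated by simulation (a planted null
correlation of 0.3 is removed to $|r| < 0.02$ at 50,000 SNPs). A full
bivariate LD-score-intercept treatment of overlap is a known alternative
and was deliberately not implemented.

**Region exclusion.** Long-range high-LD regions distort the empirical
model fit, so the extended MHC (chr6:29,528,318–33,373,649, hg19) is
excluded by default *before* the surfaces are fitted, and the model is
refitted on the remainder; the nicotinic acetylcholine receptor cluster
(chr15:78,686,690–79,231,478) is available as a second canonical exclusion.
Coordinates are 1-based inclusive internally; the BED reader converts from
0-based half-open.

## Enrichment analysis

Stratified Q-Q curves plot observed $-\log_{10}p_1$ quantiles against
$-\log_{10}$ of the uniform plotting positions $(i-\tfrac12)/n$ within
nested strata $p_2 < 1, 0.1, 0.01, 0.001$. Because pruning masks differ in
size, each mask's curve is interpolated onto a fixed theoretical grid
before averaging; curves end at the sparsest mask's extreme plotting
position, because beyond it the empirical quantile function has no support.
Strata under 50 SNPs are flagged unstable but still emitted. Curve emission
is truncated at $-\log_{10}p = 7.3$ (genome-wide significance) to highlight
the polygenic component; truncation affects display only, never FDR
estimation.

Fold enrichment of a stratum is tested by weighted least squares of $z^2$
on an intercept, the total LD score, and the stratum-restricted LD score
(per-SNP sum of $r^2$ to stratum members). Writing $b_t, b_s$ for the two
slopes, the stratum's heritability share over its SNP share is

$$E = \frac{M\,(b_t + b_s)}{M\,b_t + m_s\,b_s},$$

with $M$ panel SNPs and $m_s$ stratum SNPs. Standard errors come from a
200-block delete-one jackknife over contiguous SNP blocks; the p-value is
one-sided for $E > 1$ and Bonferroni-adjusted (default factor 12: four
secondary traits times three proper strata). When the overall LD-score
slope is not positive and at least twice its jackknife standard error, the
ratio is undefined-stable and the result is flagged non-informative rather
than returning a spurious fold change. The regression framework the
original analyses cite prints no formulas; the two-predictor stratified
regression with jackknife errors is this package's concrete instantiation,
validated by recovering a planted 2× per-SNP-heritability stratum within
three standard errors. Strata are used nested (not disjoint), matching the
nested strata of the Q-Q display.

## The synthetic-data generator

`simulate_panel()` and `simulate_gwas_pair()` generate the structures the
analysis assumes, with ground truth:

* **Block LD.** `m_blocks` blocks of `block_size` SNPs; within a block the
  signed correlation at distance $k$ is $\rho_{LD}^k$ (so $r^2$ decays as
  $\rho_{LD}^{2k}$); blocks are independent and laid across 22 synthetic
  chromosomes (2 Mb apart from 20 Mb, SNPs 5 kb apart), so default panels
  place blocks inside the MHC span on chromosome 6.
* **Causal mixture.** Each SNP is shared-causal, trait-1-only,
  trait-2-only, or null with probabilities `pi_shared`, `pi_1`, `pi_2`,
  remainder. Shared effect sizes are bivariate normal with correlation
  `effect_corr`; values below 1 produce both concordant and discordant
  effect directions, as observed at real pleiotropic loci. Per-trait
  effect variances satisfy $\sum \mathrm{var} = h^2$; combinations implying
  per-causal variance above 1 are rejected.
* **Marginal z-scores.** The infinitesimal mapping
  $E[z] = \sqrt{n}\,R\,\beta$ with $R$ the block correlation matrix, plus
  noise drawn blockwise from $N(0, R)$ (one Cholesky factor per block
  template keeps simulation cost near-linear), cross-trait noise
  correlation `rho_overlap` (shared controls), and a final
  $\sqrt{\lambda}$ inflation. Everything is deterministic given the seed.

The generator does **not** model allele-frequency spectra, case-control
liability scales, or recombination maps; passing tests therefore
demonstrate correctness of the estimators under the generative assumptions
the method itself makes, not robustness to every feature of real GWAS data.

## Simulation studies and their conditions

The package ships its evaluation experiments as functions so that tests,
scripts, and documentation run identical conditions.

* **Null calibration** (`study_null_calibration()`): 100 replicates of
  fully null, independent pairs on 20,000 SNPs in 25-SNP blocks
  ($\rho_{LD} = 0.9$). Every conjFDR < 0.01 call is false; the mean false
  discovery proportion stays at or below 0.02.
* **Recovery** (`study_recovery()`): the conjunction's documented advantage
  over single-trait analysis lives where per-trait association is real but
  individually sub-threshold and most causal variants are shared. The
  study fixes 10,000 SNPs in 5-SNP blocks, 0.3% shared causal variants,
  0.1% private per trait, shared effect correlation 0.95, and per-trait
  $h^2 = 0.0096$ at $n = 50{,}000$ — a per-causal noncentrality near 12
  ($|z| \approx 3.5$), below reliable single-trait discovery. Discoveries
  are clumped ($r^2 > 0.2$) into loci; a locus is true if any member lies
  in a block containing a shared causal variant. Conjunction calling is
  required to keep locus-level FDP at or below 0.2 and to recover more
  distinct shared blocks than marginal tail-FDR calling on either trait at
  the same nominal 0.01 level. With dense architectures or strong effects
  this ordering reverses — marginal empirical cdfs adapt to abundant
  signal — which is itself informative: the conjunction buys its false
  discovery control with respect to *shared* loci, and its power advantage
  is specific to sparse, genuinely pleiotropic architectures.
* **Q-Q ordering** (`study_qq_ordering()`): a dense shared architecture
  (5% shared causals, $h^2 = 0.1$) must give stratum deflections monotone
  in conditioning stringency at every theoretical quantile beyond 2 (a
  0.1 slack in $-\log_{10}$ units is allowed for the sparsest stratum,
  whose curve is an average over a few hundred SNPs); under independence
  the between-strata gap must shrink with problem size, measured on the
  fixed quantile range $[0, 2]$ that both sizes populate — at each curve's
  own support edge the $-\log_{10}$ extreme order statistic has
  scale-free noise, so a comparison there would not converge.
* **Enrichment recovery** (`study_enrichment_recovery()`): 20 replicates
  on 50,000 SNPs; a planted 2× stratum and a random stratum must be
  recovered within three (pooled) standard errors of 2 and 1.

## Numerical choices and degenerate inputs

* p-values at or below $10^{-300}$ are clamped there before any log
  transform; p-values of exactly 0 are treated the same way.
* When a row carries both z and p and they disagree by more than 0.05 in
  $-\log_{10}$ units, z wins and p is recomputed: z carries the effect
  sign that downstream harmonization needs.
* Clumping ties are fully specified (ascending conjFDR, then trait-1 p,
  then SNP id) so outputs are deterministic.
* Duplicate LD pair rows with conflicting $r^2$ raise an error naming the
  pair; consistent duplicates are tolerated. Pairs absent from the file
  are $r^2 = 0$, the standard sparse windowed-LD dialect.
* All stage seeds derive from the single run seed; rerunning a
  configuration writes byte-identical tables.
* Empty discovery sets, empty strata, and zero-heritability traits return
  typed empty tables or non-informative flags rather than errors.

## Known limitations

* $\pi_0 = 1$ and inclusive counting make all FDR estimates conservative;
  no mixture model is fitted.
* The overlap correction assumes the null z pair is bivariate normal after
  genomic control; gross model violations (e.g. uncorrected stratification)
  are not detected.
* LD blocks are operationalized by greedy transitive pruning at
  $r^2 > 0.8$; no external block map or physical-distance window is used.
* The enrichment regression attributes heritability through two
  annotations only (genome, stratum); overlapping annotation models are
  out of scope.
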