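---
title: "Methods and design notes for divscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for divscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical models `divscape` implements, the
choices made where the methodology left room, and what the package's
synthetic-data tests do and do not demonstrate about real data. It is a
design document; the numerical examples it refers to are the ones the
test suite and `scripts/acceptance.R` actually compute.

## Diversity and inbreeding estimators

For a set of diploid individuals scored at $L$ codominant loci, all
per-locus quantities are computed from gene copies (two per non-missing
genotype): allelic richness $A_\ell$ (count of distinct alleles), Shannon
index $I_\ell = -\sum_a p_a \ln p_a$, expected heterozygosity
$He_\ell = 1 - \sum_a p_a^2$, and observed heterozygosity $Ho_\ell$ (the
fraction of scored genotypes that are heterozygous). Multilocus values
are unweighted means across loci and the reported `sd` is the standard
deviation across loci. Two decisions deserve comment:

* **$He$ estimator.** The default is the plug-in $1 - \sum p^2$; the
  small-sample factor $2n/(2n-1)$ is available behind `unbiased = TRUE`.
  The plug-in form is the default because it is the common ground among
  the popular SSR toolkits and because the bootstrap correction (below)
  already standardizes sample sizes before values are compared across
  sites.
* **$F_{IS}$ definition.** The multilocus inbreeding coefficient is the
  ratio of multilocus means, $F_{IS} = 1 - \bar{Ho}/\bar{He}$, not a
  variance-components (Weir–Cockerham) estimator and not a mean of
  per-locus ratios. Ratio-of-means is stable when individual loci have
  small $He$ and keeps the identity $F_{IS} = 1 - Ho/He$ exact at the
  multilocus level, which the tests exploit. Its permutation test
  shuffles allele copies among individuals within the population,
  per locus: this destroys the genotypic association that produces
  heterozygote deficit or excess while preserving allele frequencies
  exactly, and the two-sided p-value uses the $(x+1)/(n+1)$ continuity
  rule so $p > 0$ always.

A locus scored in fewer than `min_ind` individuals in a group is dropped
from that group's multilocus means (with a message); an all-missing
locus is flagged absent rather than silently contributing zeros.

## Differentiation

Pairwise $F_{ST}$ follows Nei: per locus, $H_S$ is the mean of the two
within-population expected heterozygosities and $H_T$ the expected
heterozygosity of the mean (pooled) frequencies; loci are combined as a
ratio of sums, $\sum_\ell (H_T - H_S) / \sum_\ell H_T$, which is more
stable than averaging per-locus ratios when some loci have low
diversity. Raw values (including small negatives from sampling noise)
are retained; truncation into $[0, 1]$ happens only in the display
matrix.

One property matters for simulation studies: with only two populations,
$H_T$ is computed from the mean of two frequency vectors, so only half
of the among-population variance is visible to the estimator. Under a
Balding–Nichols model with differentiation $F$, the expectation of a
*pairwise* Nei $G_{ST}$ is approximately $(F/2)/(1 - F/2)$ — about 0.08
at $F = 0.15$ — while the *multi-population* (global) value, which the
package also reports, has expectation $\approx F(1 - 1/r)$ for $r$
populations and recovers $F$ closely at $r = 10$. The test suite asserts
both behaviours; treating a pairwise $G_{ST}$ as an estimate of the
generating $F$ would be a misreading of the estimator, not a bug in it.

AMOVA is the classical two-level codominant treatment: squared
inter-individual distances are allele-difference counts per locus (0, 1
or 2, via shared multiset counts), summed over loci, with pairwise
deletion of missing loci and rescaling by $L/L_{\text{observed}}$. Sums
of squares come from the distance matrix ($SS = \sum_{i<j} d^2_{ij}/n$
within each grouping), variance components from the mean squares via the
average-sample-size coefficient $n_0$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_b)$ is tested by permuting
individuals among populations. The sums of squares are cross-checked in
the tests against an independent distance-based ANOVA partition
(`vegan::adonis2` on the embedded distances).

## Grid-based diversity mapping

Trees are replicated into all 30 arc-second cells whose centers lie
within a circle of 10 arc-minutes diameter around the tree. Membership
is evaluated in geographic degree space, matching the arc-minute
phrasing of the procedure; at the low latitudes this workflow targets
(within ~10° of the equator) the longitudinal distortion is at most
about 2%, which is far below the cell-to-cell variability of the mapped
statistics. The grid is snapped to the global lattice aligned to integer
degrees, so cell boundaries are a property of the coordinate system and
not of the data layout, and cell extent is half-open
$[\text{west}, \text{east}) \times (\text{south}, \text{north}]$ so
every point belongs to exactly one cell.

Unequal per-cell sample sizes are corrected by averaging each statistic
over `n_boot = 1000` subsamples of the minimum per-cell size
(`subsample = 3`). Subsampling is **without replacement** (rarefaction):
with-replacement resampling would inflate homozygosity at small $n$ and,
more importantly, would break the exact identity between corrected and
uncorrected values at minimum-size cells, which rarefaction guarantees
by construction (`n == subsample` returns the plain statistic with
`sd = 0`). A `replace = TRUE` flag exists for sensitivity analyses.
Per-cell $F_{IS}$ is computed from each subsample's own $Ho$ and $He$
rather than from site-level values, consistent with treating the cell's
subsample as the unit of estimation; cells sharing an identical
contributing tree set reuse a single bootstrap run (keyed on the
id-sorted tree set), which also makes the maps exactly invariant to the
input order of trees.

Locally common alleles are classified once from the full dataset: an
allele is LCA when it occurs in strictly fewer than 25% of the sampled
populations and exceeds 5% frequency in at least one population where it
occurs. Both thresholds are strict inequalities; occupancy is counted
over sampling sites (the natural unit when sites are the populations).
The mapped LCA statistic is the count of classified alleles present in
the cell's tree set divided by the number of loci, and it is
bootstrap-corrected like any other statistic.

## Admixture model and cluster-number selection

The admixture ancestry likelihood is maximized by EM rather than MCMC:
responsibilities are computed per allele copy,
$r_{i\ell ck} \propto Q_{ik} P_{k\ell a}$, then $Q$ rows update to the
mean responsibility over the individual's $2 L_i$ scored copies and $P$
rows to responsibility-weighted allele tallies. This is the same model
STRUCTURE samples, and its per-replicate maximized log-likelihoods play
the role of "Ln P(D)" in the Evanno table; a reader for external
STRUCTURE results files is provided so real MCMC runs can feed
`evanno_delta_k()` unchanged. The EM choice trades posterior uncertainty
for determinism and desk-scale runtime; multiple seeded restarts
(default 10 per $K$, mirroring the usual 10 repetitions) stand in for
chain-to-chain variability. Numerical choices: Laplace smoothing
$\alpha = 0.01$ on the $P$ update prevents zero-frequency lock-in (and
bounds the log-likelihood away from $-\infty$ for rare alleles);
convergence is declared at $|\Delta \log L| < 10^{-6}$ or 500
iterations; the log-likelihood trace is retained and is asserted
non-decreasing in the tests (up to smoothing-level jitter).

$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$ is computed exactly as the
Evanno table prescribes, defined only for interior $K$; a zero replicate
sd is flagged as undefined rather than silently producing infinities,
and ties in the arg-max resolve to the smallest $K$ (parsimony). Because
EM restarts on the same data co-converge, replicate sds are small and
$\Delta K$ values are numerically large; the *selection* (arg-max) is
what is validated, and it recovers the generating $K = 3$ in all 25
simulation replicates of the acceptance run at $F = 0.15$.

Label switching across replicates is undone by aligning each replicate's
$Q$ columns to the best-log-likelihood replicate, maximizing
$\sum Q^{\text{ref}} Q^{\text{perm}}$ — exhaustively over permutations up
to $K = 7$, greedily above. Averaging aligned replicates removes
replicate scatter but not estimation bias shared by all replicates; the
tests therefore validate the averaging property on label-switched noisy
replicates of a known ancestry matrix, and validate the EM's accuracy
separately (≥ 90% assignment accuracy on three-cluster data with
best-of-10 restarts).

## Suitability framework

The evaluation machinery, not the base learners, is the substance here.
Two reference learners ship — a percentile envelope (suitability = the
fraction of variables inside the presence $[p5, p95]$ range) and an
L2-regularized logistic regression (`glmnet`, $\alpha = 0$, fixed
$\lambda = 10^{-3}$ for determinism) — and any other learner can be
registered, since the published workflow ran eleven algorithms at
package defaults.

* **Background design**: uniform over the cells of the presence convex
  hull buffered by 10% of the hull's largest axis (the maximum pairwise
  presence distance), at most one point per cell, up to 10,000,
  excluding presence cells.
* **Calibrated AUC**: 4-fold cross-validation; per fold, each test
  presence is greedily matched (without replacement, in order of its
  distance to the nearest training presence) to the test-fold background
  point with the closest such distance; then
  $cAUC = AUC_{\text{model}} - (AUC_{\text{null}} - 0.5)$, capped into
  $[0,1]$ with the raw value retained. The geographic null scores by
  rank-normalized proximity to training presences, so its own $cAUC$ is
  0.5 identically — the algebraic anchor the tests assert exactly. The
  fold count and the 5-repeat default of `cauc_iterations()` are
  package choices (the source workflow specifies 20 null iterations,
  which `retain_models()` honours, but not its fold scheme).
* **Retention and search**: one-sided Mann–Whitney tests of each model's
  per-iteration cAUC against the null's (all-tied samples report
  $p = 1$); every subset of the retained models containing the anchor is
  scored on shared folds as the cAUC-weighted mean of member scores
  ($2^{m-1}$ combinations; a guard refuses $m > 16$). Weights are raw
  mean cAUCs normalized to sum 1; recentring by $-0.5$ before weighting
  is a documented alternative left to the caller, as raw weights match
  the published description most literally. Since the anchor-only subset
  is in the search space, the selected ensemble's cAUC never falls below
  the anchor's.
* **Thresholding and consensus**: the cutoff maximizes training
  sensitivity plus specificity over observed scores (ties to the lowest
  candidate); scenario projections are binarized at that cutoff and
  combined as optimistic (suitable in ≥ 1 scenario) or pessimistic
  (≥ half, i.e. ≥ 16 of 31) consensus maps.

Distances throughout (matching, the null model, hull buffering) are in
decimal degrees, consistent with the mapping module.

## Synthetic data: what it emulates and what it does not

`simulate_genotypes()` reproduces the sampling design the estimators
face: 100 diploid trees in 12 sites of 3–14 individuals, 12 loci with
13–28 alleles, ancestral frequencies from a symmetric Dirichlet, cluster
frequencies Balding–Nichols ($\mathrm{Dir}(p(1-F)/F)$, mean $p$,
variance $F p (1-p)$), four ancestral clusters assigned to sites
round-robin, moderate admixture (Dirichlet ancestry with extra weight 2
on the site's own cluster, concentration 0.3), inbreeding injected at
the genotype-draw stage through the conditional second-copy distribution
$(1-F_{IS}) p + F_{IS}\,\delta$, 2% missingness, and sites scattered
over ~8° × 8° so distant sites never share neighborhood cells.
Defaults that the source design does not pin down were chosen once:
$F = 0.15$ (moderate differentiation, consistent with ~10% AMOVA
among-site variance), $F_{IS} = 0$ (the study system shows essentially
none). Negative $F_{IS}$ requests that would need negative conditional
probabilities are clipped with a warning. This is a draw-level model,
not a forward-time or coalescent simulation: it has no linkage,
mutation, drift history or isolation-by-distance, so passing tests
certify estimator arithmetic and recovery behaviour, not realism of any
demographic inference.

`simulate_landscape()` produces standardized smoothed Gaussian fields
(toroidal smoothing keeps the variance stationary; smoothing radius 5
cells), sharing 30% of their variance through a common field so layers
are correlated like real climate/terrain stacks, a logistic true
suitability $\mathrm{plogis}(\beta_0 + X\beta)$, and 151 presence cells
sampled proportional to suitability. The default coefficients
$\beta = (4, -3, 2, 0)$, $\beta_0 = -4$ were fixed once so that the
niche signal is strong and sparse: the true-suitability model attains a
held-out AUC of about 0.87 against uniform background under these
defaults, leaving headroom for fitted learners to clear 0.8, and one
layer is deliberately irrelevant so variable-screening behaviour is
observable. Real presence data add sampling bias, positional error and
non-logistic responses that this generator does not attempt.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise every code path with stable statistics: diversity
bootstraps at 1,000 replicates; permutation tests at 99–999; $\Delta K$
recovery over 25 simulations of 150 individuals with $K = 1..5$ and 3
restarts; F/Fis recovery over 50 replicates; 100 × 100 landscape grids
with up to 1,000 background points; the exhaustive ensemble search
demonstrated at $m = 11$ (1,024 combinations) and $m = 14$ (8,192).
Seeds are explicit arguments everywhere; derived seeds are small integer
offsets of the caller's seed. Reported p-values are never 0 by the
continuity rule; $F_{ST}$ negatives are preserved internally; all-NA and
degenerate inputs (monomorphic populations, single-score thresholds,
zero-sd $\Delta K$ denominators, perfectly collinear predictors) are
flagged or errored with named messages rather than propagating NaN.

## Known limitations

* Degree-space geometry: at latitudes beyond ~±20° the circular
  neighborhoods and distance matching become noticeably anisotropic; a
  geodesic backend would be needed there.
* The EM admixture fitter reports point estimates only; replicate
  spread across restarts understates uncertainty relative to MCMC
  posteriors, which mainly affects the magnitude (not the arg-max) of
  $\Delta K$.
* Raster I/O is single-band ESRI ASCII; multi-band or compressed
  formats must be converted upstream.
* Pairwise Nei $G_{ST}$ under-measures absolute differentiation by
  construction (see above); use the global estimate or model-based
  estimators when the parameter itself is of interest.
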