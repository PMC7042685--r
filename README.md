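# divscape

Landscape genetics of microsatellite diversity and ensemble habitat
suitability modeling, in one reproducible R workflow.

`divscape` is written for conservation geneticists working on fragmented
tree populations (its motivating system is a multipurpose tree of
seasonally dry tropical forest sampled at a dozen sites) who need to go
from a table of diploid SSR genotypes with coordinates to (i) per-site
diversity and inbreeding estimates, (ii) maps of genetic diversity over a
landscape, (iii) an estimate of the number of genetic clusters and each
tree's ancestry, and (iv) habitat-suitability surfaces suitable for
interpreting that genetic structure against past, present and future
climate. Every stage also runs on built-in synthetic data with known
truth, so the whole pipeline is testable offline.

## What it computes

**Diversity and differentiation.** For a sample set, per locus:
allelic richness *A*, Shannon index *I* = −Σ *p* ln *p*, expected
heterozygosity *He* = 1 − Σ *p*², observed heterozygosity *Ho*;
multilocus values are unweighted means over loci and the inbreeding
coefficient is the ratio of means, *F*<sub>IS</sub> = 1 − H̄o/H̄e, with a
permutation test that shuffles allele copies within the population.
Differentiation uses Nei's *F*<sub>ST</sub> = (*H*<sub>T</sub> −
*H*<sub>S</sub>)/*H*<sub>T</sub> (ratio of sums across loci; pairwise and
global), and a two-level AMOVA on allele-difference distances with a
permutation test of Φ<sub>ST</sub>.

**Diversity mapping.** Each georeferenced tree is replicated into every
30 arc-second grid cell whose center falls inside a 10 arc-minute
diameter circle around it. Because cells then hold unequal numbers of
trees, each per-cell statistic is bootstrap-corrected: the mean over
1,000 subsamples of the minimum sample size (3 trees), drawn without
replacement, so minimum-size cells are exact. Mapped statistics include
*A*, *I*, *He*, *Ho*, *F*<sub>IS</sub> and the richness of locally
common alleles (LCA: alleles found in fewer than 25% of the sampled
populations that exceed 5% frequency where they occur).

**Genetic structure.** The admixture ancestry model — each individual a
mixture over *K* clusters (ancestry *Q*), each cluster with its own
allele frequencies *P* — fit by an EM maximizer of the likelihood
*L* = Σ log Σ<sub>k</sub> *Q*<sub>ik</sub> *P*<sub>kla</sub> with
multiple seeded restarts; the number of clusters is selected by the
Evanno Δ*K* statistic (|second difference of the mean log-likelihood|
divided by the replicate sd), which also accepts log-likelihood tables
from external STRUCTURE runs.

**Habitat suitability.** Background points are drawn inside the convex
hull of the presences buffered by 10% of its largest axis (one per cell,
up to 10,000); predictors are pruned by iterative VIF (< 5); soil
variables reported per depth interval can be collapsed by
thickness-weighted means. Base learners (a BIOCLIM-style envelope and a
ridge logistic regression ship; others plug in via a registry) are
evaluated by calibrated AUC — the AUC on distance-matched test data minus
the geographic null model's inflation (AUC<sub>null</sub> − 0.5) — and
retained only when Mann–Whitney tests show them beating the null over
repeated iterations. All 2^(m−1) ensembles containing an anchor model are
scored (cAUC-weighted member means) and the best is thresholded at
maximum sensitivity + specificity; multi-scenario projections combine
into optimistic (≥ 1 scenario) and pessimistic (≥ half) consensus maps.

## Worked example

```r
library(divscape)
sim <- simulate_genotypes(seed = 42)   # 100 trees, 12 sites, 12 SSR loci
G <- sim$genotypes
site_stats(G, "site_03")
#> site_stats (site_03, n=14): A=8.75 I=1.92 He=0.82 Ho=0.83 Fis=-0.012

tab <- diversity_table(G, n_boot = 1000, subsample = 3, seed = 42)
#>       pop  n    A   He   Ho   Fis A_corr He_corr Fis_corr
#> 1 site_01  3 3.83 0.65 0.69 -0.07   3.83    0.65    -0.07
#> 2 site_02  7 5.83 0.74 0.76 -0.04   3.75    0.65    -0.17
#> 3 site_03 14 8.75 0.82 0.83 -0.01   4.15    0.70    -0.19
#> 4 site_04 10 7.50 0.78 0.80 -0.02   3.98    0.68    -0.17

amova(G, n_perm = 999, seed = 1)
#> AMOVA (two-level)
#>   among populations:  sigma2 = 0.5882 (  6.4%)
#>   within populations: sigma2 = 8.6694 ( 93.6%)
#>   Phi_ST = 0.0635, permutation p = 0.001 (999 permutations)

run <- run_admixture(G, 1:5, restarts = 3, seed = 1, max_iter = 300, tol = 1e-4)
evanno_delta_k(run$logliks)
#>   K     mean      sd n_rep     Lp Lpp_abs delta_k
#> 1 1 -4980.96  0.0000     3     NA      NA      NA
#> 2 2 -4625.76  0.6940     3 355.20   76.57  110.33
#> 3 3 -4347.13  0.6707     3 278.63  139.27  207.66
#> 4 4 -4207.78 11.7313     3 139.35   13.21    1.13
#> 5 5 -4081.64  8.6313     3 126.14      NA      NA
#> best K (max deltaK, ties to smallest): 3
```

Reading the output: the larger sites show the usual sample-size
inflation of raw allelic richness (8.75 alleles/locus at n = 14 vs 3.83
at n = 3), which the bootstrap correction removes (`A_corr` ≈ 3.8–4.2
everywhere). The AMOVA places ~6% of variation among sites, and Δ*K*
peaks at *K* = 3 on this draw — the generator's four ancestral clusters
are admixed by default, and blurred cluster boundaries depress the
supported *K*, exactly the caution that applies to real admixed data.

The full pipeline (diversity table, F_ST, AMOVA, rasters, admixture,
suitability ensemble, JSON manifest) runs as
`run_pipeline(G, "out/", pipeline_config(seed = 1), landscape = ...)`.

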