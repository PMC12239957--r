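---
title: "Models and methods behind genovuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genovuln}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

genovuln assesses the climate vulnerability of a structured wild population
along two axes: the *genetic* axis (how much deleterious variation a recent
bottleneck left behind, and where the genome tracks climate) and the
*ecological* axis (how habitat suitability shifts under future climates).
This vignette explains each model, its assumptions, the tunable parameters
that matter, and the numerical choices made where the design was open.

## The synthetic-data generator

### Demography and selection

`simulate_genotypes()` runs a forward Wright–Fisher simulation at
allele-frequency resolution: every site is an independent locus (free
recombination), and each generation applies deterministic diploid selection
and recurrent mutation followed by binomial drift at the current effective
size. Two populations split `t_split` generations ago; population A passes
through a bottleneck of size `ne_bottleneck` between `t_bottleneck` and
`t_recovery` generations before present, while B keeps the ancestral size.
Present-day diploid genotypes are then drawn from the final frequencies
(optionally with inbreeding, which elevates homozygosity without changing
allele frequencies).

Default conditions (chosen once, as the study conditions every downstream
test assumes):

* `ne_ancestral = 1000`, `ne_bottleneck = 10` — a 0.01× collapse, the
  "severe bottleneck" regime.
* bottleneck from 120 to 20 generations ago (100 generations), with full
  recovery afterwards — recent enough that load signatures are fresh.
* `t_split = 400` generations — strong but incomplete differentiation
  (genome-wide Fst on the order of 0.2–0.4 at these sizes).
* `mu = 1e-4` per site per generation. This is deliberately a *desk-scale*
  rate: each simulated site stands in for a larger functional locus, so
  recurrent mutation keeps the deleterious classes segregating at
  mutation–selection–drift balance inside a genome of only a few thousand
  sites. With a literal per-base rate nothing deleterious would segregate
  at this genome size.
* selection: synonymous and intergenic sites are neutral;
  `s_missense = -0.02` with additive dominance (h = 0.5), so missense
  variants are efficiently selected in the large population
  (`2*Ne*h*s = -20`) but drift freely during the bottleneck
  (`2*N*h*s = -0.2`); `s_lof = -0.15` with `h_lof = 0.02`, i.e. strongly
  recessive with a substantial homozygous cost. Recessivity is what makes
  the bottleneck *purge* LOF variation — homozygotes are exposed when
  drift raises frequencies — while still letting carriers reach
  frequencies at which homozygotes appear in a sample. A single additive
  lethal assumption would remove LOF variation everywhere and generate
  neither purging contrast nor homozygous LOF genotypes.

These defaults jointly reproduce, at desk scale, the canonical
post-bottleneck pattern: lower heterozygosity in A, moderately deleterious
variants increased in relative frequency (drift overwhelming selection),
high-impact variants relatively purged, and load shifted from masked to
realized. They are parameters of the generator, not of the estimators; all
are exposed in `sim_params()`.

Conservation scores are drawn with class means increasing in `|s|`
(intergenic ≈ −2, synonymous ≈ −1, missense ≈ 2.9, LOF ≈ 5.4, SD 1.5), so
the GERP ≥ 4 rule captures mostly LOF and radical missense sites. Grantham
scores for missense sites are uniform on 5–215 (the real distribution is
skewed lower; only the ≥ 150 threshold matters downstream). Two outgroup
columns carry the true ancestral allele with independent error
`outgroup_error = 0.02`, so polarization exclusions are exercised.

### Landscape, cline and niche

`simulate_landscape()` builds each climate variable as a linear gradient
along the cline axis plus a smooth low-order Fourier noise field; future
scenarios add a constant per-variable shift on identical geometry. All
coordinates are WGS84 decimal degrees, grids are addressed north-first, and
per-sample values come from bilinear interpolation.
`embed_adaptive_cline()` rewrites `n_causal` intergenic loci so each
individual's derived-allele probability is `plogis(steepness * z(env))` —
the ledger of causal loci is the ground truth for power measurements.
`embed_sweep()` fixes the derived allele across a window in population A
only, emulating a completed hard sweep. `simulate_occurrences()` samples
presence records proportional to a Gaussian niche in the focal variable
(optimum at the 35% quantile, breadth 12% of the range) — narrow enough
that an ensemble SDM can clear the TSS > 0.8 / AUC > 0.9 gates, which a
species spread evenly over the climate space could never do.

What the generator does *not* emulate: linkage and recombination maps,
background selection, spatially autocorrelated sampling, GC-biased gene
conversion, reference bias, or genotyping error beyond missingness. Passing
tests therefore demonstrate correctness of the estimators and the expected
direction of demographic effects — not robustness to every artefact of real
resequencing data.

## Polarization and annotation

The ancestral allele is the majority across observed outgroup alleles; a
1–1 tie (or no observation) is `UNRESOLVED` and the site is excluded rather
than guessed. A single observed outgroup resolves a site — a documented
choice where the majority rule is silent. Dosages are flipped (`2 − g`)
where the ancestral allele is ALT; polarizing twice restores the input.
Missense sites with Grantham ≥ 150 are "harmful missense" throughout; the
threshold is inclusive and configurable. GERP deleteriousness uses an
inclusive threshold of 4.

## Load statistics

`l_ab()`/`r_ab()` implement the normalised burden ratio given in the
README. Numerical choices:

* Frequencies use called alleles only; sites with no calls in either
  population are excluded.
* The jackknife deletes one of 100 contiguous positional blocks (class and
  intergenic sites blocked jointly in genome order, equal site counts per
  block); SD is the standard delete-one jackknife estimate. Fewer
  polymorphic sites than blocks reduces the block count with a warning.
* A zero intergenic normaliser yields `NA` with a warning, never a silent 0.

Per-individual counts divide both the total derived count and twice the
homozygous-derived genotype count by the individual's derived synonymous
count; an individual with no derived synonymous alleles gets `NA` rather
than an arbitrary denominator. Masked and realized loads both divide by the
individual's number of called genotypes — the two denominators are worded
differently in common usage ("called genotypes" vs "all called sites"), so
the package implements them identically by default and offers
`denominator = "genome_wide"` as the alternative reading.

## Selection scan

`windowed_fst()` computes Weir–Cockerham variance components per SNP from
genotype dosages and sums them over 50 kb windows at 25 kb steps (ratio of
sums — the weighted estimator used by standard VCF tooling); the Hudson
estimator is available behind a flag. Windows are 0-based half-open;
chromosomes shorter than one window are skipped; windows with fewer than
`min_snps = 3` SNPs are flagged rather than dropped. Window π divides the
summed per-site average pairwise difference by the window length in bp, so
unobserved positions count as invariant — the convention of sliding-window
diversity scans. The top-1% cut takes everything at or above the empirical
99th percentile, ties included. `intersect_candidates()` consumes window or
gene identifier sets from any number of methods (composite-likelihood scans
are inputs, not reimplemented here) and reports Venn counts plus the
at-least-k intersection.

## Genotype–environment association

Collinearity is handled by iterative VIF pruning (remove the worst until
all VIFs ≤ 10; exact ties break by variable name so results are independent
of column order).

The ordination arm fits `vegan::rda()` of mean-imputed, centred dosages on
the pruned variables, keeps axes significant under 999 row permutations at
P < 0.05, and flags SNPs whose loading is more than 2 SD from the mean of
any significant axis (per-axis SD; the pooled alternative is less
sensitive when axes differ in scale).

The latent-factor arm is a deterministic stand-in for MCMC latent-factor
mixed models, whose run-combination rules do not reproduce cleanly. Its
design required care on two fronts:

1. *Factors must not swallow the signal.* The K leading principal axes of
   the raw dosage matrix can align with a strong multi-locus cline and
   absorb exactly the association being tested. Factors are therefore
   estimated in two stages: first from the genotype matrix with the tested
   variables projected out (which cannot contain the environmental
   direction), then — after provisionally flagging associated SNPs — from a
   PCA of the remaining, putatively neutral SNPs. The final test adjusts
   for those factors.
2. *Small-sample calibration.* With tens of individuals and binomial
   dosages, analytic F-test p-values are visibly miscalibrated even when
   the true population labels are supplied as covariates. The scan
   therefore applies genomic-inflation-factor calibration (divide the
   1-df chi-square quantiles by the median-based lambda) before FDR
   adjustment — the default practice of modern latent-factor association
   software. Raw p-values are reported alongside.

Only SNPs flagged by both arms are candidates, mirroring the conservative
two-method intersection design. On the bundled fixtures this recovers
≥ 90% of embedded causal loci with essentially no false positives, while
the structure-only fixture yields calibrated p-values and near-zero
discoveries.

The GEA fixtures themselves (`gea_fixture()`) sample both populations
across the whole environmental gradient. When climate is collinear with
ancestry no structure-corrected test is identifiable — any method must
either absorb the signal or inflate — so the calibration and power claims
are made under the design in which they are meaningful; the confounded
default fixture is used to demonstrate *why* K matters (K = 0 inflates).

## Genomic offset

Both turnover models expose the same contract: monotone non-decreasing
per-variable transforms, evaluated by `predict()`, with extrapolation
clamped to the training range.

* `fit_turnover_forest()`: per candidate SNP, a bootstrap ensemble of
  `rpart` regression trees of population allele frequency on climate
  (depth 3, 25 trees). Each primary split's variance reduction is deposited
  at its split value on its variable's axis; sums are weighted by the SNP's
  out-of-bag R² (non-positive fits dropped) and accumulated into a
  piecewise-constant cumulative-importance curve — monotone by
  construction.
* `fit_dissimilarity_spline()`: pairwise Fst rescaled to [0, 1] and
  regressed on per-variable monotone spline basis differences with
  non-negative coefficients (`pracma::lsqnonneg`, so negativity is
  impossible rather than clipped); knots at the min/median/max of each
  variable. The link is kept identity on the rescaled Fst — adequate over
  [0, 1] and transparent.

Offsets are Euclidean distances in the transformed space: local (same
cell), forward (minimum over cells within a great-circle cap of 100, 250,
500, 1000 km or unlimited; haversine on a 6371 km sphere; the focal cell is
always in the pool, so forward ≤ local and smaller caps can only raise the
offset), and reverse (minimum over all present cells, uncapped). Distances
are computed by direct per-row differencing rather than the algebraic
cross-product expansion, which loses ~8 digits to cancellation when
climates nearly match. The RGB composite min–max scales local, forward and
reverse into the red, green and blue bands; constant bands scale to zero
with a warning.

## Ensemble suitability and vulnerability

Presences are greedily thinned at 5 arc-minutes (~9.3 km) and backgrounds
sampled uniformly from non-presence cells. Five member families (GLM, GAM,
random forest, SVM with radial kernel, gradient-boosted trees) stand in
for the usual ensemble roster; each is evaluated by mean validation AUC
(rank-based) and TSS (max sensitivity + specificity − 1) over ten 70/30
subsampling replicates and admitted only above the TSS > 0.8, AUC > 0.9
gates. Because no weighting scheme is canonical, accepted members are
TSS-weighted by default (equal weights behind a flag). The ensemble's
suitability threshold for habitat-area accounting defaults to its
TSS-maximising threshold; cell areas are latitude-corrected
(`(111.32 km · res)² · cos(lat)`). Vulnerability is the plain per-cell
difference `V_E = S_future − S_present`.

## Problem sizes and runtime

The default genome is 2,700 sites on four 2-Mb chromosomes with 15 + 15
diploids; the GEA fixtures use 880 sites; offset law checks run on 10×10
grids against brute-force double loops; the end-to-end pipeline uses a
21×21 climate grid and 800–2000 background points. These sizes were chosen
so the full test suite and the acceptance script each complete in a few
minutes on a laptop core while keeping every direction-of-effect check
comfortably powered.

## Known limitations

* Free recombination means no linked selection, no haplotype structure,
  and jackknife blocks that are effectively independent — real data have
  fewer independent blocks than sites.
* The latent-factor scan's GIF calibration targets the median; heavy
  polygenic signal would deflate power slightly, and fully confounded
  designs remain unidentifiable (as for any method).
* The forest turnover model uses in-package trees rather than the extensive
  machinery of dedicated gradient-forest software (no per-species density
  weighting, no R²-threshold curves); importance curves agree in shape on
  the bundled fixtures.
* Ensemble members are generic classifiers; no claim is made of
  reproducing specific presence-only algorithms such as maximum-entropy
  models.
* CSV-grid rasters carry geometry in their headers but no CRS metadata;
  everything is assumed WGS84.
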