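---
title: "Testing convergence of wing transparency under predator vision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing convergence of wing transparency under predator vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Müllerian co-mimics share a warning signal because predators generalise
across lookalike prey. In several Neotropical butterfly and moth
communities the shared pattern includes *transparent* wing patches, which
raises two questions this package is built to answer on any comparable
dataset: (1) do co-mimetic species converge in how their transparent
patches look *to a bird*, beyond what shared ancestry explains, and
(2) which wing structures (scales, nanostructures, membrane) carry that
convergence and how do they set the degree of transparency?

The unit community the package's defaults emulate is 62 species in 10
mimicry rings, each species measured at five analogous wing spots over
300-700 nm.

## From spectra to perceived contrasts

Specular transmittance spectra are smoothed by local quadratic (loess,
tricube-weight) regression and resampled onto a fixed 1-nm grid from 300
to 700 nm; all integrals are trapezoid rules on that grid, which makes
every downstream number reproducible. The smoothing span (0.25) and the
clamp-negative-values-to-zero-after-smoothing policy are package
defaults, recorded in the output, not values inherited from any
instrument: smoothing spans are rarely reported, and clamping after (not
before) smoothing preserves the noise structure the smoother sees.

Perception is modelled with the receptor-noise-limited framework. For a
receptor with spectral sensitivity $S_i(\lambda)$ under illuminant
$I(\lambda)$, a wing viewed against the sky yields quantum catch

$$Q_i = \int_{300}^{700} T(\lambda)\, I(\lambda)\, S_i(\lambda)\,
  d\lambda, \qquad f_i = \ln Q_i.$$

No von Kries normalisation is applied because it cancels in the
log-ratio contrasts. Receptor noise follows neural-noise density
scaling, $e_i = \omega \sqrt{\eta_{\mathrm{ref}} / \eta_i}$, with the
reference receptor the most abundant cone class (ties broken towards the
longest peak wavelength). Chromatic contrast between stimuli $a$ and $b$
is the standard quadratic form in $\Delta f_i = f_i(a) - f_i(b)$; for a
tetrachromat

$$dS^2 = \frac{\sum_{i<j} \big(\prod_{k \neq i,j} e_k\big)^2
  (\Delta f_j - \Delta f_i)^2}{\sum_i \big(\prod_{k \neq i} e_k\big)^2},$$

and achromatic contrast is
$dL = |\ln(Q_{\mathrm{ach}}(a)/Q_{\mathrm{ach}}(b))| / \omega_{\mathrm{ach}}$.
Both are in just-noticeable differences. The package ships two
tetrachromatic visual systems with the conventional avian parameters —
relative cone densities 1:1.9:2.7:2.7 (UV-sensitive model) and
1:0.7:1:1.4 (violet-sensitive model), Weber fractions 0.1 (chromatic)
and 0.2 (achromatic) — and two parametric forest illuminants
(`large_gap`, a broad daylight-like curve; `forest_shade`, the same
curve filtered through a green 550-nm canopy window at a quarter of the
irradiance). The cone curves are Govardovskii-type A1 pigment templates
at configurable peak wavelengths (371/448/503/563 nm and
406/450/503/566 nm by default); measured curves and illuminants can be
supplied as CSV and override the templates. The achromatic channel is
the longest-wavelength single cone by default; a double-cone curve can
be supplied and selected by label, and the choice is recorded in the
output, since the field is split on this convention.

## The convergence tests

For each spot, visual system and illuminant, contrasts between all
unordered species pairs form a symmetric table (1891 pairs for 62
species). Two one-sided permutation tests are run, following the
pairwise-randomisation design:

* **Similarity at random.** The observed mean contrast over co-mimetic
  pairs is compared with the mean of equally many pairs drawn at random
  from all pairs (10,000 draws by default). Small p: co-mimics look more
  alike than random species pairs.
* **Convergence given the phylogeny.** Contrast is regressed (OLS) on
  patristic distance over all pairs; the observed mean *residual* over
  co-mimetic pairs is compared with random residual draws. Small p:
  co-mimics are more alike than their phylogenetic distance predicts.

Per-ring variants restrict the observed statistic to the focal ring's
pairs and draw the same number of pairs for the null. Discrete
structural traits (scale type, nanostructure type, and their combination,
the *structural syndrome*) use the count of co-mimetic pairs sharing a
level, with a binomial-GLM (response-residual) variant for the
phylogenetic correction; nanostructure density uses pairwise absolute
differences through the same two continuous tests. Holm correction is
applied within each test series — one series is a fixed combination of
correction, layer, spot, visual system and illuminant, adjusted across
rings (global tests are adjusted across spots within a series); the
family label is stored per row so users can re-group, because the
series definition is a convention, not mathematics.

Numerical conventions: ties count as "as extreme" (inclusive
comparisons), which is conservative; p-values are reported both as raw
null proportions and as $(\text{count}+1)/(n+1)$, and the latter drives
decisions so no test can report p = 0. Every test records its seed and
randomisation count. The pairwise regressions treat the 1891 pairs as
independent observations — exactly as the published design does — which
is a documented limitation, not an accident: no Mantel-style correction
is applied.

### Calibration of the randomisation, exactly as designed

The pairwise randomisation is exact when the co-mimetic pairs form a
uniform random subset of all pairs (a property the test suite checks
with iid pair values). Real ring assignments are partitions, so the
global co-mimetic set covers every species in a balanced way while the
null draws unbalanced subsets with higher-variance means: the global
test is therefore mildly *conservative* (empirical size about 0.025 at
a nominal 0.05 on Brownian null communities of 40 species in 5 rings).
This is a property of the published procedure itself; the package
reproduces it rather than re-weighting the null.

### A known limit of the residual correction

Under Brownian evolution the expected pairwise distance grows with the
*square root* of patristic distance, so an OLS line through the
distance-distance cloud sits above the truth at small distances. When
mimicry rings coincide with clades, co-mimetic pairs concentrate at
small patristic distances and inherit systematically negative residuals,
so the corrected test retains some excess rejection under a pure
shared-ancestry scenario. Simulations with rings painted on clades show
the correction removes most, but not all, of the confound (uncorrected
rejection around 0.8 at $\alpha = 0.05$; corrected around 0.2-0.3 rather
than the nominal 0.05). Users should read per-ring "convergent" verdicts
for clade-like rings with this in mind.

## Phylogenetic signal

* **Pagel's λ** — profile ML over the off-diagonal scaling of the
  Brownian covariance, bounded to [0, 1], likelihood-ratio p against
  λ = 0 (χ², 1 df). Star-like trees are flagged and reported as λ = 0,
  p = 1.
* **Blomberg's K** — the observed-to-expected ratio of tip variance to
  phylogenetically corrected variance; permutation p from tip shuffles
  of the phylogenetic mean squared error.
* **δ statistic** (multistate traits) — an equal-rates Mk model is
  fitted by ML (pruning likelihood), marginal ancestral state
  probabilities are computed at every internal node by the standard
  two-pass algorithm, each node is summarised by its normalised Shannon
  entropy, and a Metropolis-Hastings sampler fits a Beta model to the
  entropies (exponential priors, lognormal proposals; 10,000 iterations,
  10% burn-in, thinning 10 by default). δ is the posterior-mean ratio of
  the two Beta parameters: confident reconstructions (low entropies)
  give large δ. Because no two implementations of this statistic agree
  on absolute scale, inference always goes through the tip-randomisation
  null distribution of δ rather than its absolute value.
* **Fritz & Purvis' D** (binary traits) — nodal values by unweighted
  daughter means, dispersion scaled between its tip-permutation
  (D = 1) and threshold-Brownian (D = 0) expectations, with both
  p-values reported. The threshold-Brownian replicates match the
  observed prevalence exactly by construction.
* **Phylogenetic ANOVA** — ordinary one-way F with a null distribution
  of F values recomputed on Brownian simulations along the tree (rate
  set to the phylogenetic mean square of the observed trait), groups
  held fixed.

Polytomies are accepted everywhere and used as-is (no forced
bifurcation).

## PGLS and model selection

The structure-transparency link is fitted by GLS with residual
covariance $\sigma^2 C(\lambda)$, λ profiled by ML over [0, 1] (or
fixed). Design matrices use treatment coding with the alphabetically
first level as reference and unscaled continuous predictors. All
subsets of the declared main effects and interactions are enumerated
under two constraints: *marginality* (an interaction brings all the
terms it implies; the triple interaction of scale density, length and
width brings all three mains and the three pairwise products) and
*exclusions* (variables too collinear to co-occur; the shipped default
excludes nanostructure type and nanostructure density from the same
model, since density is strongly structured by type). Models within 2
AICc units of the minimum are retained, with
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ and $k$ counting
coefficients + σ² (+ λ when estimated) — the parameter-counting
convention is stated because published AICc values rarely state theirs,
and only within-analysis differences matter. $R^2_{\mathrm{adj}}$ is
computed from whitened sums of squares against the intercept-only GLS
null under the same covariance (the GLS, not OLS, null — the other
defensible choice changes only the absolute value, not model ranking).
Classical equivalences are enforced by tests: λ = 0 equals OLS; λ = 1
on an ultrametric tree reproduces the independent-contrasts slope.

## What the synthetic generator does and does not emulate

`generate_study()` builds a complete bundle: a unit-depth Yule tree, a
ring assignment (either random with the community's ring-size census —
13/10/8/7/6/5/4/4/3/2 across ten rings, 213 co-mimetic pairs — or
painted on the largest monophyletic clades to create the
shared-ancestry confound), spectra, and structural traits.

Species mean transmittance evolves by Ornstein-Uhlenbeck towards
ring-specific optima on terminal branches (internal branches track the
community mean optimum), with `alpha = 0` collapsing exactly to the
Brownian null. Defaults: `sigma2 = 0.06`, ring optima evenly spaced
within (0, 1), and `alpha` derived so adjacent optima sit two
stationary standard deviations apart — the weakest separation one
would still call distinct ring phenotypes (`alpha = 3` per tree depth
for five rings, about 14 for the ten-ring community). Because regimes
can only act on terminal branches when rings are not monophyletic,
species with very short terminal branches stay near the ancestral
mean: individual ten-ring bundles can therefore fail to show global
convergence for some seeds, much as real communities show convergence
for some spots and rings but not others. Each
spectrum is the species mean plus a fixed spot offset (±0.06 across
five spots), a random linear spectral tilt (±0.1 across the band,
giving spectra mild colour), and 1% Gaussian measurement noise, clipped
to [0.001, 1] because real spectrophotometers never read exactly zero.
Discrete traits follow an equal-rates Mk process with a ring-typical
override applied per species with probability 0.7 when convergence is
on; nanostructure density follows the same OU-with-ring-optima logic.
Nanostructure density and transmittance optima increase together across
rings, mirroring the empirical direction (denser nanostructures,
more transparency).

The spectral model is a linear tilt, not thin-film physics: it carries
the statistical structure the tests consume (level convergence, mild
spectral shape variation) but none of the interference structure of
real membranes. Passing calibration on these bundles therefore
demonstrates the statistics, not the optics: type-I error near 0.05 on
null bundles, power above 0.8 for the corrected test under the default
OU separation, and the partial confound resistance described above.

## Problem sizes and reproducibility

Simulation-based checks in the test suite use 40-64-species trees with
200-500 replicates per calibration and 199 randomisations per test; the
acceptance script runs the full 62-species bundle with the published
10,000 randomisations. Every stochastic function takes a single integer
seed and is bit-reproducible from (inputs, parameters, seed);
`run_all()` derives all stage seeds from one master seed.

## Worked example

```r
library(clearwing)

bundle <- generate_study(study_config(seed = 42))
run <- run_all(bundle, n_rand = 1000, seed = 42, per_ring = TRUE)

print(run)
head(report(run$convergence))
print(run$pgls)
```

## Limitations

Beyond the residual-correction caveat above: ocular media corrections
and background-contrast viewing (wing seen against a leaf) are out of
scope; the δ statistic's absolute scale is sampler-dependent (use its
randomisation p); the per-ring tests inherit the low power of small
rings (two- and three-species rings are rarely significant at any
realistic effect size); and the PGLS assumes Gaussian residuals on the
transmittance scale.
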