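---
title: "Kin signatures in primate song phrases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin signatures in primate song phrases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songkin)
```

## The scientific question

Family-living singing primates such as the indri (*Indri indri*) produce
choral songs whose most distinctive portions are *descending phrases* of
two or three frequency-descending units (DP2, DP3). Three questions drive
the analyses this package implements:

1. Does the acoustic dissimilarity of song phrases covary with genetic
   distance between individuals (overall, and separately per sex)?
2. Are phrases of a parent and its same-role offspring (father–son,
   mother–daughter, and the cross categories) more similar than phrases of
   unrelated adult–offspring pairs?
3. Do phrases carry an individual signature, and do they advertise group
   membership?

Field data of this kind — pitch contours traced from song recordings and
microsatellite genotypes from fecal DNA — are not publicly deposited, so
the package ships a synthetic-data module that generates pedigrees,
Mendelian genotypes and phrase datasets with known, tunable effect
structure. Every statistical claim the test suite makes is a claim about
recovery of *planted* structure, or about calibration under a null the
generator makes true by construction.

## Acoustic features

A phrase is an ordered set of units with start/end times and an f0 contour
(plus, optionally, a per-unit Q50 — the frequency at the upper limit of the
second quartile of spectral energy). Per phrase the package computes:

* **Temporal set** — unit durations `dur_unit_k`, inter-unit intervals
  `dur_int_k`, inter-onset intervals `ioi_k` (`= dur_unit_k + dur_int_k`,
  an identity the tests verify exhaustively), and total duration. Seconds;
  translation-invariant.
* **Frequency set** — per unit: `f0mean` (time-weighted trapezoidal mean —
  robust to uneven contour sampling, unlike the raw sample mean), `f0max`,
  `f0min`, `f0start`, `f0end`, `ptmax`/`ptmin` (percent of unit duration
  elapsed at the pitch extrema; ties resolve to the earliest sample, which
  makes extraction deterministic), and `Q50` (passed through, or computed
  from a supplied energy spectrum by linear interpolation inside the
  crossing bin).

## Dimensionality reduction and dissimilarity

Each phrase type × parameter set (four combinations) is reduced
separately: variables are z-scored, the correlation matrix
eigendecomposed, and components with eigenvalue > 1 retained (Kaiser
criterion). We interpret the original workflow's "factor analysis" as
unrotated PCA with Kaiser retention — the outputs are called principal
components and component scores throughout — and expose varimax rotation
as an option (off by default). Scores are the standardized
(regression-type) component scores; unit variance per component makes the
Euclidean phrase distances scale-free. Loadings carry a deterministic sign
convention (largest-magnitude loading positive).

Phrase distances are averaged over all cross pairs to the individual
level; matrices are min–max normalized to [0, 1] before testing. The
diagonal is excluded everywhere. Because the Pearson correlation and the
permutation distribution are invariant under affine rescaling, restricting
to a subgroup (e.g. one sex) commutes with normalization — a property the
tests assert. Per-sex analyses reuse the all-individual component scores
rather than refitting per sex.

## Relatedness

Pairwise relatedness is estimated from six co-dominant microsatellite loci
(the default panel mirrors a published indri marker set, allele sizes
stepping by the 2 bp repeat motif across each locus's fragment-size range;
observed population frequencies are unavailable, so defaults are uniform).

* **Moment estimators**: Queller–Goodnight (ratio-of-sums over loci,
  direction-averaged), Li's similarity index, Lynch–Ritland (reference
  weights, direction-averaged), and a Wang-type similarity-category moment
  estimator. For the latter, the probabilities of the allele-sharing
  categories (identical genotypes; homozygote vs heterozygote sharing its
  allele; one shared allele) are exact linear functions of the IBD
  coefficients (k1, k2); the package computes the coefficients by exact
  enumeration over genotype pairs (tests verify them against closed forms)
  and solves the moment system by weighted least squares across loci with
  weights 1/(2a2 − a3). Linearity in the observed category indicators
  makes all four estimators exactly unbiased, which Monte-Carlo tests
  confirm at 3 standard errors.
* **Dyadic maximum likelihood**: per dyad the product over loci of the
  genotype-pair likelihood is maximized over (k0, k1, k2) on the simplex
  by grid search (default resolution 0.01; ties resolve to the
  least-related maximizer, making results deterministic); r̂ = k2 + k1/2.
  The estimate lies in [0, 1] by construction — and therefore carries the
  well-known *positive boundary bias* of constrained likelihood
  estimators: with six loci, chance allele sharing can push r̂ above the
  truth but never below 0, so the mean over truly unrelated dyads is
  ≈ 0.06, over parent–offspring dyads ≈ 0.53. The acceptance suite asserts
  strict 3·SE recovery for *both* routes and the dyadic-ML assertions for
  parent–offspring, half-sib and unrelated dyads fail by those margins;
  this is a property of the estimator class, not an implementation defect
  (a brute-force fine-grid oracle confirms the likelihood is maximized
  exactly). The moment route satisfies recovery in all four categories.

The original study selected a triadic likelihood estimator; its internals
are not restated in accessible form, and this package deliberately scopes
to the dyadic member of the same likelihood family — the
estimator-comparison harness (simulate 100 dyads per known category —
parent–offspring, full-sib, half-sib, unrelated, all by explicit Mendelian
construction — apply every registered estimator, rank by pooled
correlation with truth) is estimator-agnostic, and a fifth moment
estimator can be registered as a plain function.

For testing against acoustics, relatedness is converted to a distance:
d = 1 − (min–max normalized r̂), so both matrices point in the
dissimilarity direction and positive Mantel correlations mean "more
related, more similar".

## Permutation tests

**Mantel tests** correlate the off-diagonal entries of two labeled
symmetric matrices; the null simultaneously permutes rows and columns of
one matrix. P-values use the plus-one rule (exceedances + 1)/(n + 1) —
valid for any permutation count and never zero — with 9999 permutations by
default and a one-tailed (greater) alternative, since the hypotheses are
directional; negative observed correlations are reported as-is. An exact
variant enumerates all n! permutations for small n and serves as the
oracle: the sampled test run over the complete permutation set reproduces
the enumerated p exactly.

**Kin-category tests** restrict the acoustic similarity matrix
(1 − normalized dissimilarity) to the parents × offspring rectangle of one
role pair (e.g. fathers × sons) and correlate it with the binary true-pair
matrix. The null permutes *offspring identities only*, parents fixed: the
question is whether an offspring resembles its own parent more than other
parents' same-role offspring do, and the parent set is part of the design.
"Unrelated adult–offspring pairs" are all non-parental dyads of the given
roles. A practical consequence: with `k` permutable offspring the
permutation space has `k!` atoms, so designs with fewer than ~4 offspring
cannot reach p ≤ 0.05 at all; the calibration experiments therefore use
the fixed seven-group reference pedigree (`reference_pedigree()`, five
sons) rather than re-drawing random offspring sexes per replicate.

**pDFA** (permuted discriminant function analysis) tests classification of
phrases to a *test factor* (individual; group) while respecting a *control
factor* (song; individual) whose levels make phrases non-independent.
Blocks are test × control cells, so a chorus song shared by several
individuals contributes one block per singer. For each of `n_selections`
(default 100) balanced selections, every test level contributes `quota`
control levels to training (default: the minimum control-level count over
test levels, minus one — always leaving held-out data); a Fisher
discriminant classifier (pooled within-class scatter, whitening,
nearest-centroid with uniform priors — chance is 1/k; a singular scatter
is ridge-regularized with an escalating constant) is scored on training
and held-out phrases and rates are averaged. The null permutes test-level
labels over whole blocks and recomputes the *averaged* rates with fresh
selections, which keeps the observed and null statistics exchangeable and
the p-values uniform under the null — the property the calibration
experiments verify. Training rates exceed testing rates (resubstitution
optimism); the testing phase is the inferential one.

## The synthetic generator

Each individual carries a latent mean vector over the generative
parameters (durations, intervals, f0 landmarks, pt positions, Q50): base
value + sex offset (females higher-pitched and slightly longer by
default) + heritable deviation + group effect; each phrase adds residual
noise and is rendered as unit boundaries plus a piecewise-linear contour
through the landmarks. Feature extraction inverts the rendering exactly
when the residual SD is zero and the landmark values are physically
consistent (f0max above f0start/f0end etc.); outside that region the
renderer clamps deterministically.

Offspring deviations follow `h · (parental deviation) + sqrt(1 − h²) ·
noise`, with `h` separate for the temporal and frequency sets, and either
mid-parent or sex-path (father→son, mother→daughter) transmission. The
defaults are deliberately null and symmetric — `h = 0`, group SD 0 (the
reference analysis found no group signal), symmetric transmission —
so no conclusion is baked into the generator. Default sampling depth is 5
songs × 9 phrases = 45 phrases per individual per phrase type, matching
the reference study's ≈ 46 phrases per individual, with a minimum of 4
phrases per individual per type enforced by the cohort filter (applied per
type, so DP2 and DP3 cohorts can differ).

What the generator does *not* emulate: within-song temporal coordination
between singers, age/ontogeny effects, recording noise and pitch-tracking
error, genotyping error and allelic dropout, and realistic allele
frequency spectra. Passing tests therefore demonstrate that the methods
recover the planted structure under idealized field-like sampling — not
that the biological effects exist in any real population.

## Calibration experiments and problem sizes

The acceptance suite (and `scripts/acceptance.R`) measures, at these
sizes:

* Mantel type-I error: 200 replicate pairs of independent 20×20 distance
  matrices, 999 permutations — rejection ≈ 5%.
* Estimator recovery: 1000 dyads per category, Queller–Goodnight and
  dyadic ML (see the bias discussion above).
* Kin-signal recovery: father→son temporal transmission `h = 0.8`
  (sex-path) on the reference pedigree; the father–son kin-category Mantel
  on DP3 temporal parameters is significant at α = 0.05 in well over 80%
  of 50 replicates, and with `h = 0` the p-values pass a KS uniformity
  test over 100 replicates. DP3 is the designated phrase type for this
  check because its temporal set spans five free generative dimensions
  versus three for DP2, and the power of the offspring-permutation test
  scales with the number of independent heritable parameters.
* pDFA: with individual SD and sex offsets zero the generator makes
  phrases fully exchangeable — testing-phase p-values are uniform and
  rejection stays within 3 binomial SEs of 5% (100 replicates; 3
  selections, 99 permutations — reduced from the defaults to keep the
  experiment at scale, exchangeability being unaffected by those sizes);
  the default generator's individual signature yields testing accuracy far
  above chance with p ≤ 0.05; with zero group effect the group-membership
  pDFA is non-significant in ≥ 90% of 50 replicates.
* End-to-end: two `run_all()` invocations with one seed produce
  byte-identical report files.

## Numerical and design choices

* Seeds propagate deterministically from a single global seed to every
  stochastic stage; seeded functions restore the caller's RNG state.
* Matrix symmetry is validated at 1e-12; permutation-count comparisons use
  a 1e-12 slack so ties count as exceedances (conservative).
* Degenerate inputs fail loudly and by name: constant variables in PCA,
  constant off-diagonals in Mantel inputs, groups reduced to a single
  individual in the group pDFA, phrases violating the unit-structure
  invariants.
* The grid for the dyadic ML scans in order of increasing r, so flat
  likelihoods resolve toward unrelatedness.
* `run_all()` writes long-format CSV tables shaped like the reference
  report tables (Mantel by subgroup; kin categories; pDFA rates), a JSON
  manifest embedding the full configuration and seed, and a log of skipped
  analyses (e.g. a sex with fewer than 4 genotyped individuals).

## Known limitations

* The triadic likelihood estimator and genotyping-error models are out of
  scope; the dyadic ML boundary bias is documented rather than corrected
  (no bias-corrected or unconstrained ML variant is provided).
* Q50 is the only spectral feature; there is no jitter/shimmer analogue.
* The pDFA assumes every test level spans at least two control levels;
  designs violating this are rejected rather than approximated.
* With the reference pedigree's four daughters, mother–daughter
  kin-category tests have a permutation floor of 1/24 and essentially no
  power; this mirrors the small-sample reality of the study design rather
  than a removable software limit.
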