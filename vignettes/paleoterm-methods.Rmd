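---
title: "Methods behind paleoterm: extinction chronology and palaeoenvironment reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind paleoterm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoterm)
```

`paleoterm` bundles the statistical machinery used to build a local
extinction chronology from radiocarbon-dated bone records and to place it
against quantitative palaeoenvironmental reconstructions from the same
stratigraphies: pollen- and vole-based summer temperature estimates, pollen
biomization, and palynological diversity. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical choices, in the
spirit of the long-form methods vignettes of packages like `vegan` or
`DESeq2`.

## Radiocarbon calibration

A radiocarbon determination $y \pm \sigma$ (in ^14^C yr BP) is converted to a
posterior over calendar ages $t$ (cal BP, before AD 1950, larger = older)
against a calibration curve with mean $\mu(t)$ and one-sigma error $s(t)$:

$$p(t) \;\propto\; \exp\!\left(-\frac{(y - \mu(t))^2}
  {2(\sigma^2 + s(t)^2)}\right)$$

evaluated on a regular calendar grid (default 1 yr), truncated where the
density falls below $10^{-12}$ of its peak, and renormalized. The curve is
interpolated linearly in both $\mu$ and $s$ between grid knots — the standard
practice, and the choice that makes the fine-grid oracle tests exact.
`hpdInterval()` returns the highest-posterior-density region: the smallest
set of grid cells whose mass reaches the requested level (default 95%,
matching the 2-sigma ranges conventionally reported), as maximal contiguous
intervals. Calibration-curve plateaus produce multimodal densities whose HPD
region splits into disjoint intervals; this is behaviour, not error.
`pointEstimate()` defines the median as the smallest grid age with cumulative
mass at least 0.5 and breaks mode ties toward the older age, so every
reported number is reproducible to the grid step. No reservoir or offset
corrections are applied.

```{r calib}
curve <- genCalCurve(span = 12000, wiggleAmplitude = 30, seed = 1)
d <- calibrate(10250, 60, curve)
pointEstimate(d, "median")
hpdInterval(d, 0.95)
```

## Terminal (last-appearance) dates from sighting series

Dated records of one taxon rarely include its true last survivor, so the
terminal date must be extrapolated beyond the youngest record. Two
complementary estimators are provided.

### GRIWM: Gaussian-resampled inverse-weighted McInerny

With point ages sorted youngest first ($t_1 \le \dots \le t_n$, cal BP), each
older record $i \ge 2$ defines a sighting rate over the span back to the
youngest record, $\lambda_i = (i-1)/(t_i - t_1)$, and a McInerny-style
terminal extension below the youngest record,

$$T_i = t_1 - \frac{\log \alpha}{\log(1 - \lambda_i)},$$

the age by which, at rate $\lambda_i$, the probability of no further
sighting has dropped to $\alpha$ (default 0.05). A rate of one sighting per
year or more gives zero extension. Candidates are combined with normalized
inverse-span weights $w_i \propto 1/(t_i - t_1)$, so records close to the
youngest dominate. Dating uncertainty enters by resampling: each record's
age is redrawn from Normal(mean, sd) — or from its full calibrated density
when supplied — for 10,000 iterations (the method's published default), and
the estimate is the median of the resampled terminals with
$(\alpha/2, 1-\alpha/2)$ quantile bounds. Exact ties are broken by a
deterministic 0.5-yr jitter so every span is positive. All of this is
reproducible bit-for-bit from the seed.

Two properties worth knowing. First, the estimator is translation
equivariant: shifting all ages by a constant shifts the estimate exactly.
Second, its confidence interval is *not* a credible interval with nominal
coverage: in simulations with uniform recovery (window 5000 yr, n = 15,
dating error 100 yr) the 95% interval covers the true extinction time in
roughly half the replicates — a known characteristic of the method, which
trades coverage for a narrow, data-driven interval. The test suite asserts
the coverage fraction is stable across seeds rather than nominal. Deleting
the oldest record can move the terminal date in either direction (the
deleted record contributes both a candidate and a weight), so no
monotonicity under record deletion is claimed.

### The uniform-phase boundary model

The phase model treats the dated records as a deposition phase: true ages
$\theta_j$ are uniform between an unknown start and end boundary, and
observations add Gaussian dating error,

$$\theta_j \sim U(e, s), \qquad y_j \sim N(\theta_j, \sigma_j),$$

with a uniform prior on $(s, e)$ over a broad box subject to $s \ge e$,
optionally multiplied by the span penalty $1/(s-e)$ (`spanPrior =
"jeffreys"`). The posterior of the end boundary is the last-appearance
estimate. The sampler is a Gibbs scheme in which every conditional is drawn
exactly: each $\theta_j$ is a truncated Gaussian on $[e, s]$ (inverse-CDF
draw), and each boundary conditional is a truncated power law in the span,
$(s-e)^{-(n+p)}$, invertible in closed form. There is no tuning, the
acceptance rate is 1, and convergence is monitored with split R-hat over 4
chains (values above 1.1 flag the result, they never raise). Defaults are
20,000 post-burn-in draws after 2,000 burn-in per chain.

With a single record and the plain uniform prior the span posterior is
log-uniform and the boundaries spread over the prior box; the Jeffreys span
penalty concentrates them at the record. Both options are exposed because
the choice genuinely matters only for very small n.

In 200 simulated series (n = 20, window 3000 yr, dating error 50 yr) the
95% end-boundary interval covers the true end in about 97% of replicates,
and the sampler agrees with a two-parameter grid-integration oracle (which
marginalizes the $\theta_j$ analytically) to within two grid steps on small
series. The tests run these checks at reduced chain lengths (2,000–8,000
draws), which the exact-Gibbs sampler makes sufficient.

```{r phase}
s <- genSightings(trueExtinction = 12000, window = 3000, n = 20,
  datingSd = 50, seed = 1)$series
p <- phaseFit(s, iterations = 4000, burnin = 1000, chains = 2, seed = 1)
boundaryEstimate(p)
```

## The vole thermometer

The vole thermometer converts the composition of a vole assemblage into a
July mean temperature: each species' modern temperature optimum is weighted
by its percentage among the counted, non-excluded vole species and the
products are summed and divided by 100. The default optimum table is the
standard seven-taxon set (Clethrionomys 15, Arvicola 17.5, *Microtus
arvalis* 21, *M. agrestis* 19, *Lasiopodomys gregalis* 10, *M. oeconomus*
12.5, Dicrostonyx 7.5 °C), with the azonal mountain species *Microtus
nivalis* excluded from both numerator and denominator. Species-level names
map to the genus-level optima through a synonym table, because published
optimum tables mix ranks. Taxa that are neither tabulated nor excluded are
dropped from the denominator with a warning rather than silently diluting
the estimate. Assemblages under 10 individuals are flagged `low-n` — the
formula is noise-dominated below that, and the cutoff is this package's
choice, made once. The estimate is always bounded by the optima of the
species present, is invariant to count rescaling, and ignores excluded
species at any abundance.

## Pollen–climate transfer functions

### WA-PLS

Weighted-averaging partial least squares calibrates species percentages
against a climate variable. Percentages are recomputed over the
included-taxon sum and square-root transformed by default (variance
stabilization for proportion data). Component 1 is two-way weighted
averaging with *inverse* deshrinking — the regression of observed climate on
the WA estimates, weighted by sample totals — and later components repeat
the weighted-averaging cycle on the climate residuals, orthogonalized
against earlier components. The implementation stores per-component
cumulative taxon coefficients, so a prediction is a weighted average of one
coefficient vector plus the training mean; in-sample predictions reproduce
the fitted values exactly, and the component-1 equality with an
independently coded WA oracle is asserted to 1e-8. Inverse deshrinking is
the default (classical deshrinking would regress estimates on observations);
the difference is a linear rescaling and inverse is the common default.

Model selection follows the standard validation suite: leave-one-out
cross-validation reports per-component r², RMSEP and maximum bias (the
largest absolute mean residual over 10 equal-width intervals of the
gradient); a component is accepted over the previous one only when its
squared LOO errors are significantly smaller under a paired sign-flip
randomization test (p < 0.05, p computed as (r+1)/(n+1)) *and* RMSEP
actually decreases, stopping at the first failure. Sample-specific errors
come from 1,000 bootstrap cycles, combining the spread of bootstrap
predictions (s1) with the out-of-bag prediction error (s2) as
$\sqrt{s_1^2 + s_2^2}$.

### MAT

The modern analogue technique predicts by inverse-distance-weighted
averaging of the climate of the k = 6 most similar modern spectra. The
dissimilarity is the chord distance: Euclidean distance between
square-rooted proportion vectors (the squared-chord variant is an option).
Analogues whose distance exceeds a threshold are discarded as bad analogues;
`matThreshold()` estimates a threshold as a chosen quantile of the distance
distribution of random training-sample pairs (the quantile and pair count
are explicit parameters — no field-wide default is assumed). A zero-distance
analogue returns that analogue's climate exactly. When all six analogues
exceed the threshold the sample is flagged `no-analogue` with a missing
estimate — filtering happens after the six are selected, so the retained
count is data.

### Reconstruction significance

`reconstructionSignificance()` implements the random-environment test: the
proportion of fossil-assemblage variance explained by the reconstruction
(redundancy analysis of the transformed fossil spectra constrained on the
reconstruction) is compared against reconstructions from models trained on
permuted climate values, with p = (count of random ≥ real + 1)/(n + 1) and
999 randomizations by default. The method matters here: weighted-averaging
predictions are linear functionals of the fossil composition, so when the
fossil spectra lie along a single compositional gradient — exactly what the
synthetic generator produces — even random-environment WA models track that
gradient and the test has essentially no power. MAT null models average
*randomized* climate over composition-chosen analogues and do not inherit
the gradient, so the MAT-based test (the default) retains power; on the
synthetic benchmark a genuinely climate-driven sequence gives p = 0.001 at
999 randomizations. Real fossil data with richer structure behave less
extremely, but the asymmetry is worth knowing when interpreting
WA-PLS-based significance tests.

## Biomization

Biome assignment follows the affinity-score scheme: taxa above a 0.5%
threshold contribute the square root of their percentage to every plant
functional type (PFT) they belong to, PFT scores sum into biome scores
according to a biome × PFT membership matrix, and the sample is assigned to
the biome with the maximal score. Ties go to the biome defined by the fewest
PFTs (the more specific biome — the convention of the original scheme);
remaining ties keep matrix order. When the winner is temperate forest and
the arboreal pollen sum is below 70%, the assignment is overridden to wooded
steppe; the override is applied to temperate forest only. The arboreal sum
is computed from per-taxon flags in the PFT matrix over the same percentage
basis as the scores, so the taxon→PFT→biome matrices are data, not code —
the package ships only toy fixtures, and published matrices are supplied by
the user as CSV.

## Diversity

Palynological richness is Hurlbert rarefaction — the expected number of taxa
in a random draw of `baseN` grains without replacement, computed through
`vegan::rarefy` — with the downcore default `baseN` set to the minimum
sample total, the standard choice for comparable values along a core (the
base actually used should be reported alongside the values). Rarefaction
requires raw counts; percentage matrices are rejected. Evenness defaults to
Pielou's J (H'/log S; undefined and flagged for single-taxon samples), with
the Hill N2/N1 ratio as the alternative. No published index is implied —
the index used is recorded in the output.

## The synthetic-data generators

Every stage is testable without downloads because the generators produce
each input with known ground truth: a monotone calibration curve with
seeded sinusoidal wiggles (and an optional rippled plateau whose 14C-age
re-crossings make plateau determinations calibrate to multimodal densities);
sighting series with uniform recovery over a known existence window and
Gaussian dating error — the same data model the phase estimator assumes, so
phase coverage checks are exact-model checks; and modern/fossil pollen data
from Gaussian species responses (optima uniform on the climate range,
common tolerance) with multinomial counting noise. The benchmark defaults —
40 taxa, optima over 5–25 °C, tolerance 2 °C, 150 samples of 300 grains —
are the package's standard test conditions. Each generator derives an
independent RNG stream from (master seed, generator name), so adding a
generator never perturbs existing fixtures, and every generator is a pure
function of (parameters, seed).

What the generators deliberately do not emulate: taphonomic loss beyond
uniform recovery, age-depth distortion, spatial structure in the training
set, secondary (non-climatic) compositional gradients, and non-multinomial
overdispersion of pollen counts. Passing tests therefore demonstrate
correctness of the algorithms under their own assumptions, not robustness
to violations of them; with real data the transfer-function errors will be
larger than the benchmark's ~0.3–0.5 °C.

## Numerical choices and degenerate inputs

* Ages are years cal BP throughout; smaller = younger. Depths are cm,
  positive downward.
* Densities must sum to 1 within 1e-9 (validity-checked); constructors
  renormalize.
* A constant training climate supports exactly one WA-PLS component (the
  constant); more components are a degeneracy error. Taxa with zero total
  abundance are dropped with a warning.
* GRIWM requires n ≥ 2 and non-identical ages; the phase model accepts
  n = 1 (see the span-prior note above).
* The phase sampler's prior box spans the observed range padded by 10 times
  the largest dating error plus half the range — broad enough to be
  uninformative at every problem size in the tests, and recorded in the
  result's settings.
* Problem sizes in the test suite (chain lengths of 2,000–8,000, 200
  simulation replicates, LOO at n = 150) were chosen as the smallest sizes
  at which the assertions are statistically stable; they are the package's
  own choices.

## Pipeline and reproducibility

`runPipeline()` executes the configured stages in dependency order from a
single YAML (or list) configuration with one explicit seed, writes one CSV
per stage, and records a JSON manifest with MD5 checksums of every input
and output, all settings and seeds, and all accumulated warnings (dropped
taxa, low-count assemblages, non-convergence — never silent). Identical
(config, inputs, seed) give byte-identical outputs; a stage error is
recorded, its dependants are skipped, and completed outputs remain. Unknown
configuration keys are rejected before any computation, as are missing input
files.
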