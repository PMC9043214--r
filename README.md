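# paleoterm

Statistical tools for late-Quaternary **extinction chronology** and
**quantitative palaeoenvironment reconstruction** in R, aimed at
palaeoecologists working with radiocarbon-dated bone records and microfossil
(pollen, small-mammal) assemblage counts.

When did a taxon disappear from a region, and what was the environment doing
at the time? The package answers the first question with two estimators
applied to a series of dated records, and the second with the standard
reconstruction toolkit applied to assemblage counts:

* **Radiocarbon calibration** against IntCal-style curves: posterior
  densities over calendar ages, highest-posterior-density (HPD) intervals,
  median/mode/mean point estimates.
* **GRIWM** (Gaussian-resampled inverse-weighted McInerny): with ages sorted
  youngest first, each record *i* yields a sighting rate
  λᵢ = (i−1)/(tᵢ−t₁) and a candidate terminal date
  Tᵢ = t₁ − log(α)/log(1−λᵢ); candidates are combined with weights
  wᵢ ∝ 1/(tᵢ−t₁) and dating error enters by resampling (10,000 iterations),
  giving a median terminal date with quantile bounds.
* **Uniform-phase boundary model** (Bayesian): true ages uniform between an
  unknown start and end boundary, observations Gaussian around them; an
  exact-Gibbs sampler returns the posterior of both boundaries — the end
  boundary is the last-appearance estimate — with split R-hat diagnostics.
* **Vole thermometer**: July temperature as the percentage-weighted mean of
  vole species' modern temperature optima (T = Σ oᵢ pᵢ / 100), with the
  standard seven-taxon optimum table and azonal-species exclusion.
* **WA-PLS and MAT transfer functions** for pollen–climate calibration, with
  leave-one-out cross-validation (r², RMSEP, maximum bias), randomization
  t-test component selection, 1000-cycle bootstrap sample-specific errors,
  chord-distance analogue selection with a Monte-Carlo bad-analogue
  threshold, and a random-environment significance test (999 randomizations).
* **Biomization**: plant-functional-type affinity scores (Σ √percent above a
  0.5% threshold), maximum-affinity biome assignment, and the
  arboreal-pollen < 70% override of temperate forest to wooded steppe.
* **Diversity**: Hurlbert rarefaction E(T) and evenness.
* **Synthetic-data generators** with known ground truth for every input, so
  the whole pipeline is testable end to end, plus a config-driven
  `runPipeline()` with a checksummed JSON run manifest.

## Worked example

Estimate a last-appearance date from a synthetic sighting series whose true
extinction time is known, then reconstruct a temperature trajectory from
synthetic pollen data:

```r
library(paleoterm)

## dated records: true extinction 12000 cal BP, recovery window 3000 yr
s <- genSightings(trueExtinction = 12000, window = 3000, n = 20,
                  datingSd = 50, seed = 1)$series

griwm(s, iterations = 10000, seed = 1)
#> GRIWM terminal estimate: 12089 cal BP (11833-12342, alpha 0.05, 10000 iter)

phaseFit(s, iterations = 8000, burnin = 1000, chains = 2, seed = 1)
#> Phase boundaries (16000 draws):
#>   start: 14926 cal BP (95%: 14781-15391)
#>   end:   12231 cal BP (95%: 11761-12369)

## pollen-climate calibration on the synthetic benchmark
ts  <- genTrainingSet(seed = 1)          # 40 taxa, 150 samples, 300 grains
cv  <- looCrossvalidate(ts$counts, ts$climate, maxComponents = 3)
cv@stats$rmsep
#> [1] 0.4962610 0.4403177 0.4141362

traj <- seq(8, 22, length.out = 30)      # known downcore trajectory, deg C
fos  <- genFossilSequence(traj, ts$truth, seed = 2)
fit  <- waplsPredict(waplsFit(ts$counts, ts$climate, 2), fos$counts, 2)
sqrt(mean((fit$estimate - traj)^2))      # recovery error, deg C
#> [1] 0.2910557

## vole thermometer
reconstructTJuly(c("Microtus arvalis" = 50, "Dicrostonyx" = 50))
#> [1] 14.25
```

The GRIWM terminal date sits below (younger than) the youngest record, as an
extrapolated terminal date should, and its interval brackets the true
extinction time of 12,000 cal BP, as does the phase model's end boundary;
the WA-PLS reconstruction recovers the known trajectory to ~0.29 °C under
the benchmark's multinomial counting noise; and the vole thermometer returns
the optimum-weighted mean of the two species (21 and 7.5 °C at 50% each).

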