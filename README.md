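# kip2traffic

Modeling and quantification of kinesin **Kip2** traffic on yeast astral
microtubules.

In budding yeast, Kip2 decorates astral microtubules uniformly along the
shaft with a single plus-end peak, independent of microtubule length —
unlike classical lattice-landing kinesins (Kip3), whose density grows
towards the plus end with lattice length (the antenna pattern). This
package implements the transport model that explains the difference —
a totally asymmetric exclusion process with Langmuir kinetics and a
dedicated **minus-end loading site** at the spindle-pole-body-anchored
end — together with the statistical machinery to estimate its rate
constants from binned fluorescence line-scan profiles, and the
microscopy quantification statistics that accompany such experiments.

The model, for a lattice of N sites (8 nm each, minus end first):

* minus-end loading: rate `r_in = k_in * c_free` onto site 1 if free,
* lattice landing: rate `r_on = k_on * c_free` per free site,
* stepping at `k_step` towards the plus end under hard-core exclusion,
* lattice detachment at `k_off` (sites 1..N−1),
* plus-end detachment at the dedicated rate `k_out`,
* a finite cytoplasmic reservoir:
  `c_free = c_total − bound / (volume · N_A)`.

A flat shaft profile arises **only** when all recruitment is at the
minus end and lattice detachment is zero — the analytic result at the
heart of the model, encoded in `classifyFlatProfile()`.

## What's in the package

| Area | Functions |
|---|---|
| Lattice model | `solveMeanfieldSteadyState`, `solveMasterEquation` (exact, N ≤ 12), `simulateGillespie`, `simulateGrowingLattice`, `timeAveragedOccupancy`, `classifyFlatProfile` |
| Fluorescence forward model | `renderProfile`, `predictBinnedProfiles` |
| Inference | `negLogLikelihood`, `fitMaximumLikelihood`, `sampleLikelihood`, `jointFitStrains`, `summarizeSamples`, `compareParameters` |
| Microscopy quantification | `alignLineScan`, `binProfiles`, `qqNormalize`, `plusEndRegression`, `asymmetryIndex`, `relativeFluorescence`, `speckleSpeed`, `microtubuleLength3d`, `summarizeDynamics` |
| Synthetic data | `truthConfig` (presets `wt`, `bfa1bub2`, `S63A`), `generateProfileDataset`, `generateSpbDataset`, `generateSpeckleTracks`, `generateDynamicsDataset`, `applyDayEffect` |
| Orchestration | `runPipeline` (`generate`, `quantify`, `fit`, `sample`, `compare`, `reproduce`), plus a thin CLI wrapper in `inst/scripts/kip2traffic-cli.R` |

The methods vignette (`vignettes/motor-traffic-methods.Rmd`) documents
the model assumptions, numerical choices and generator design.

## Worked example

Exact small-system check — two lattice sites with unit loading,
stepping and exit rates have hand-solvable stationary occupancies:

```r
library(kip2traffic)
kin <- MotorKinetics(k_in = 1, k_on = 0, k_off = 0, k_step = 1,
                     k_out = 1, c_total = 1)
occupancy(solveMasterEquation(kin, LatticeSpec(2), free_concentration = 1))
#> [1] 0.6 0.4
```

Generate a wild-type synthetic profile dataset and sample the
likelihood (about a minute on one CPU):

```r
truth <- truthConfig("wt", seed = 1)          # k_in / k_on = 500
ds <- generateProfileDataset(truth)
smp <- sampleLikelihood(ds$bins, n_draws = 2000, seed = 11)
d <- parameterDraws(smp)
median(d[, "k_in"]) / median(d[, "k_on"])
#> [1] 497.3546
compareParameters(smp, "k_in > k_on")$p_value
#> [1] 5e-04
```

The ratio of median rate constants recovers the 500-fold dominance of
minus-end loading over per-site lattice landing encoded in the preset
truth (the p-value is the fraction of likelihood draws violating
`k_in > k_on`, floored at 1/n when none do). Cross-strain joint fits
work the same way:

```r
mut <- generateProfileDataset(truthConfig("bfa1bub2", seed = 1))$bins
j <- jointFitStrains(list(wt = ds$bins, mut = mut), n_draws = 2000,
                     seed = 21)
compareParameters(j, "k_in_mut < k_in_wt",
                  conditioning = "c_total >= 35",
                  fold = "k_in_wt / k_in_mut", seed = 5)$fold_difference
#> [1] 10.1835
```

recovering the 12-fold reduction of the minus-end loading rate constant
in the GAP-complex deletion strain.

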