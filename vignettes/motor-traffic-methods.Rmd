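---
title: "Minus-end-loading motor traffic: model, inference, and quantification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minus-end-loading motor traffic: model, inference, and quantification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kip2traffic)
```

This vignette is the package's own account of its science: the transport
model and its assumptions, the numerical choices behind each solver, the
likelihood machinery, the quantification conventions, and what the
synthetic-data generator does and does not emulate.

## The transport model

The kinesin Kip2 decorates yeast astral microtubules in a distinctive
way: a flat, above-zero concentration along the whole shaft with a single
peak at the growing plus end, independent of microtubule length. A
classical lattice-landing kinesin (such as Kip3) instead accumulates
linearly towards the plus end, because a longer lattice offers more
landing sites — the antenna picture. The package models both behaviors
within one exclusion process on a discrete lattice of `n_sites` sites of
8 nm (one tubulin dimer; a single protofilament track, with protofilament
multiplicity absorbed into the fluorescence scale):

* a free motor loads onto the **minus-end site** (site 1, anchored at the
  spindle pole body) at rate $r_\mathrm{in} = k_\mathrm{in}\,c_\mathrm{free}$
  if that site is empty;
* a free motor lands on **any** empty site at
  $r_\mathrm{on} = k_\mathrm{on}\,c_\mathrm{free}$ per site (site 1
  included — it is a lattice site too; the loading-only alternative is
  available via `minus_end_lattice_binding = FALSE`, and at wild-type-like
  parameters the two conventions differ by far less than the profile
  uncertainties, which a regression test pins down);
* a bound motor steps towards the plus end at $k_\mathrm{step}$ when the
  next site is empty (hard-core exclusion), detaches from the lattice at
  $k_\mathrm{off}$ (sites 1..N−1), and detaches from the plus-end site at
  the dedicated rate $k_\mathrm{out}$;
* the cytoplasmic pool is finite: with a closed reservoir of volume $V$
  (default 40 fL, a haploid-yeast order of magnitude) holding
  $c_\mathrm{total} V N_A$ motor copies,
  $c_\mathrm{free} = c_\mathrm{total} - \mathrm{bound}/(V N_A)$.

Units: rate constants that multiply a concentration
($k_\mathrm{in}$, $k_\mathrm{on}$) are in nM$^{-1}$s$^{-1}$; all other
rates in s$^{-1}$; concentrations in nM.

The flat-profile result that motivates the model is analytic: a uniform
shaft occupancy is a steady state only when there are no motors on the
lattice at all, when the motors cannot step (Langmuir equilibrium
everywhere), or when **all** recruitment happens at the minus end with no
lattice detachment ($k_\mathrm{on} = 0$, $k_\mathrm{off} = 0$).
`classifyFlatProfile()` encodes this trichotomy. In the minus-end-only
regime the interior density is $r_\mathrm{in}/k_\mathrm{step}$ on the
low-density branch; flux conservation
($J = r_\mathrm{in}(1-\rho_1) = k_\mathrm{step}\rho_i(1-\rho_{i+1}) =
k_\mathrm{out}\rho_N$) fixes the plus-end site at $J/k_\mathrm{out}$ and
produces a geometric boundary layer of a few sites next to it; tests
assert uniformity to $10^{-6}$ on the interior away from that layer, with
the boundary values frozen from an independent fixed-point iteration.

## Solvers

Three routes to the steady state cross-validate each other:

1. **Master equation** (`solveMasterEquation`): the exact stationary
   distribution of the $2^N$-state Markov chain, for $N \le 12$, solved
   as a sparse linear system. This is the ground truth for small
   lattices; the no-entry case is defined to return the empty absorbing
   configuration.
2. **Mean field** (`solveMeanfieldSteadyState`): the fixed point of the
   site-wise rate equations with the usual factorization of pair
   occupancies. The solver is pseudo-transient continuation: implicit
   Euler steps on $\dot\rho = F(\rho)$ with a tridiagonal Jacobian
   (Thomas algorithm, O(N) per step) and a growing pseudo-timestep, so it
   behaves like a damped relaxation far from the fixed point and like
   Newton near it. Steps are accepted unless the residual grows more than
   threefold — residual fronts travel through the lattice, so the
   max-norm is not monotone along the physical relaxation path. All
   balance residuals are driven below $10^{-10}$; densities are clamped
   to $[0,1]$; initialization is a deterministic uniform low-density
   guess (0.1). The closed-reservoir free concentration is solved by a
   damped conservation fixed point with a bisection fallback (the excess
   function is monotone), warm-starting the inner solve.
3. **Gillespie simulation** (`simulateGillespie`,
   `simulateGrowingLattice`): exact stochastic simulation with integer
   copy-number bookkeeping in closed mode (binding decrements the free
   pool; `bound + free` is conserved exactly). The growing variant adds
   lattice growth as one more reaction channel (Poisson site addition;
   2.92 sites/s corresponds to the measured 1.4 µm/min growth speed), and
   reduces event-for-event to the static simulator at zero growth rate.
   Randomness comes from R's RNG, so a seed fixes the entire event
   sequence. The simulator covers a single filament; multi-filament
   shared pools are a mean-field feature only.

Tests require Gillespie time averages to match exact master-equation
marginals within three Monte-Carlo standard errors (30 batch means) for
$N \le 6$, and the mean field to track the exact marginals within 0.05
in the supremum norm at $N = 4$ — mean-field error is real but small at
these densities.

## From occupancy to fluorescence

`renderProfile()` maps occupancy to a predicted line scan: every bound
motor contributes a unit-mass Gaussian of width `psf_sigma` (default
135 nm, a diffraction-limited sigma for GFP at high numerical aperture)
integrated over pixels of 133.35 nm (half the 266.7 nm two-pixel length
bin), then scaled by `scale` (a.u. per motor) and offset by
`background`. Blur conserves integrated mass exactly, which the tests
assert across sigmas; a window that would truncate the lattice is
refused rather than silently clipped. `predictBinnedProfiles()` renders
one profile per microtubule-length bin at the bin midpoint rounded to
whole sites — the same convention the synthetic generator uses, so
fitting synthetic data involves no discretization mismatch (with real
data this is an approximation: the within-bin length distribution is
unknown).

## Likelihood, optimization, sampling

The fit target is a binned mean ± SEM profile table. The likelihood is
per-pixel Gaussian: negLL $= \frac12\sum ((\mathrm{mean} -
\mathrm{prediction})/\mathrm{SEM})^2$ over all bins and positions.
Parameters are sampled in log10 space over box ranges spanning several
decades (`defaultRanges()`). Two parameters are **fixed** by default:
`k_step` at 13.125 s$^{-1}$ — the directly measured speckle speed of
6.3 µm/min over 8 nm sites — because the profile shape constrains ratios
of rates to $k_\mathrm{step}$ far better than absolute values, and
`k_off` at zero, the analytic requirement for a flat shaft. Letting
`k_off` float creates a near-degeneracy: over these lattice lengths a
small detachment rate tilts the profile down almost linearly, exactly
what a smaller landing rate also does, so $k_\mathrm{on}$ (and with it
the in/on ratio) becomes bimodal and only weakly identified. Both
parameters can be sampled by passing a different `fixed` vector.

The likelihood surface is multimodal (a jammed lattice can mimic a
profile at distant parameters) and only piecewise smooth across jam
onsets. `fitMaximumLikelihood()` therefore screens globally before
polishing locally: a broad uniform scan over the kinetic dimensions with
the two linear nuisances (scale, background) profiled out in closed form
(variable projection), a second scan round resampled around the elite
points, then Nelder–Mead followed by L-BFGS-B from each retained start,
and finally a line search along the two weakly constrained product
directions ($c_\mathrm{total}$ or scale against both binding rate
constants), where gradient methods stall.

`sampleLikelihood()` draws from $\exp(-\mathrm{negLL})$ truncated to the
box with a seeded adaptive random-walk Metropolis sampler: proposal
covariance adapted from the chain history during burn-in (frozen
afterwards), global step size tuned to ~28% acceptance, plus occasional
symmetric moves along the product directions above. Four chains start
from a jittered maximum-likelihood point; the split-chain Rhat statistic
is reported per parameter and the result is flagged when any exceeds
1.05 — weakly identified directions (notably $k_\mathrm{off}$, whose
posterior piles against its lower bound when the truth is zero) mix
slowly, and an honest flag is preferable to hiding it. Ratio summaries
(the quantities the analysis reports) are insensitive to these slow
directions, which the recovery tests demonstrate.

`jointFitStrains()` ties parameters across strains. The default shares
everything except `k_in` and `k_on`: stepping, detachment and the
optical nuisances are properties of the motor and the microscope, and
the total concentration is the motor's expression level, which the
regulatory mutants do not touch. Sharing `c_total` also matters
statistically: left per-strain, its posterior is pinned by reservoir
depletion in the high-occupancy strain but nearly flat in the
low-occupancy one, so conditioning on `c_total >= 35` nM truncates the
two strains asymmetrically and biases the cross-strain fold of median
rate constants severalfold — a distortion we measured on synthetic data
before fixing the default. Cross-strain comparisons
(`compareParameters()`) restrict each strain's draws to the conditioning
expression, pair them by index after a seeded permutation, and report
the one-sided violation fraction (floored at $1/n$) plus the ratio of
conditional medians.

## Quantification conventions

The microscopy statistics follow fixed conventions, chosen once:

* **Peak detection** (`alignLineScan`): global maximum after a 3-pixel
  moving average; ties break towards the scan start (the SPB-proximal
  end); a channel whose smoothed maximum does not exceed median + 3 MAD
  is rejected with a reason code. Origin at the SPB-marker (mCherry)
  peak; profile length is the peak-to-peak distance.
* **Binning** (`binProfiles`): half-open length bins of 266.7 nm; each
  profile truncated at its own plus-end peak plus 3 pixels before
  per-position mean/SEM aggregation; single-profile bins are flagged
  degenerate rather than dropped.
* **Inter-day normalization** (`qqNormalize`): 199 quantiles (0.5% to
  99.5% in 0.5% steps), linear interpolation between order statistics
  (R type 7), ordinary least squares of reference on source quantiles.
* **Plus-end regression** (`plusEndRegression`): per-bin peak = maximum
  of the bin mean within ±2 pixels of the bin-midpoint plus-end
  position; weights $1/\mathrm{SEM}^2$; zero SEMs fall back to
  unweighted with a warning.
* **Asymmetry index**: $(FI_b - FI_m)/(FI_b + FI_m)$, undefined (and
  excluded) only when both sides are zero.
* **3D dynamics** (`microtubuleLength3d`, `summarizeDynamics`): 3D
  Euclidean plus-end–SPB distance; frames with spindles over 2 µm
  excluded; lengths at or below 5 pixels (666.7 nm) flagged
  undetectable; missing plus-end coordinates mean no visible microtubule
  (length 0); recording window 85.6 s = 80 × 1.07 s (a lone "85.7 s" in
  the source description is treated as a rounding slip); phases shorter
  than 2 frames are skipped.
* **Sample summaries** (`summarizeSamples`): quantiles use the averaged
  order-statistic convention (type 2), so the quartiles of 1..100 are
  25.5 and 75.5 and the IQR is exactly 50.

## The synthetic-data generator

`truthConfig()` defines the study conditions; generators are pure
functions of (config, seed) with per-module substreams, and every
generator emits ground-truth sidecars so recovery tests never re-derive
truth from data. Defaults anchor to the measured quantities: speckle
speed 6.3 ± 2.1 µm/min, growth speed 1.4 ± 1.1 µm/min, 94% correct SPB
orientation, a correct-orientation bud:mother intensity ratio with
median 17/3 (asymmetry index 0.7) and an inverted-orientation median of
2/3 (index −0.2), lognormal cell-to-cell spread (log-sd 0.5) and 20%
multiplicative measurement noise per side. Cohort speeds use
zero-truncated normals whose realized mean and SD equal the printed
values (naively truncating N(1.4, 1.1) at zero would inflate the
realized mean to ~1.62 µm/min). Six 266.7 nm length bins from 800.1 to
2400.3 nm with 100 cells per bin; pixel noise has a 100 a.u. additive
floor plus a 12% intensity-proportional component (photon-like), so
profile SEMs are a few percent of the signal everywhere — bright
structures are not unphysically precise.

Absolute kinetic rates are the package's own choices, since the source
analysis reports ratios and bounds rather than absolute values:
$k_\mathrm{in} = 0.009$ nM$^{-1}$s$^{-1}$ (shaft occupancy ≈ 0.03),
$k_\mathrm{on} = k_\mathrm{in}/500$, $k_\mathrm{off} = 0$ (the
flat-profile regime), $k_\mathrm{step} = 13.125$ s$^{-1}$,
$c_\mathrm{total} = 35$ nM, and $k_\mathrm{out} = 0.6$ s$^{-1}$ — about
twice $r_\mathrm{in} \approx 0.32$ s$^{-1}$, i.e. of the same
magnitude. The pair was chosen for morphology: the rendered plus-end
peak stands a pixel's worth of contrast above the shaft only when the
per-site tip-to-shaft density ratio $k_\mathrm{step}/k_\mathrm{out}$
exceeds the ~17 lattice sites a 133.35 nm pixel integrates, while the
plus end must still clear the wild-type input flux at every bin length
(no queue). The wild type sits in that window; rendered wild-type scans
then have their global GFP maximum at the plus end, as real scans do,
which the alignment path relies on. The
presets change only what the cross-strain comparisons report as changed:
the GAP-complex deletion divides $k_\mathrm{in}$ by 12; the
landing-site phosphomutant multiplies $k_\mathrm{on}$ by 6 **and**
scales $k_\mathrm{in}$ by 0.48 so that its within-strain
$k_\mathrm{in}/k_\mathrm{on}$ is 40. The three reported numbers (500-fold
wild-type ratio, 6-fold on-rate increase, ~40-fold residual dominance)
are mutually inconsistent with an unchanged in-rate (500/6 ≈ 83), so the
preset honors all three by carrying the implied mild in-rate shift —
comfortably inside the wide in-rate uncertainty, consistent with it
being reported as not significantly changed.

A deliberate consequence of these ratios: at the longest bins the
landing mutant's input flux exceeds what a plus end of the same
magnitude as the wild-type in-rate can clear, so its lattice develops an
extended high-occupancy region growing back from the plus end. This is
the exclusion-process expression of the mutant's antenna-like, strongly
plus-end-accumulating phenotype, and the closed reservoir self-limits it
through depletion of the free pool.

What the generator does **not** emulate: photophysics (bleaching,
blinking, camera noise statistics beyond i.i.d. Gaussian pixel noise),
pixel-level image formation in 2D/3D, microtubule pivoting out of the
scan line, catastrophe/rescue coupling between length and motor traffic,
or a realistic within-bin length distribution (profiles are rendered at
bin midpoints; raw line scans draw lengths uniformly within bins).
Passing tests therefore demonstrate the correctness and calibration of
the machinery under the stated statistical structure, not robustness to
every feature of real microscopy data.

## Problem sizes

The test suite and the acceptance script run at desk scale: 2,000
retained likelihood draws per fit over 4 chains (6,000 burn-in
iterations for single fits, 12,000 for joint fits), 100 cells per length
bin, 30,000–40,000 s stochastic trajectories for the small-lattice
oracle comparisons, and cohort sizes matching the quantification inputs
(192 speckle tracks, 1,407 cells, 120–250 growth phases). The reference
analysis used 20,000 likelihood draws; `n_draws` scales accordingly when
more precision is wanted.

## Known limitations

* Mean-field occupancies deviate from exact marginals by up to a few
  percent at intermediate densities; fits inherit this as a (matched)
  approximation on both the generation and inference side when the
  generator uses the mean-field forward model.
* The sampler's split-Rhat flag is conservative: weakly identified
  directions (a zero-truth detachment rate, the concentration–scale
  product ridge) mix slowly, and runs that are adequate for ratio
  summaries may still be flagged.
* The growing-lattice control is qualitative (flat shaft preserved, by
  ensemble slope test); no quantitative growing-lattice likelihood is
  provided.
* With an open (clamped) reservoir and per-strain concentrations, the
  cross-strain fold of median rate constants is not identifiable from
  profile shape alone; the shared-concentration default exists precisely
  to keep that quantity meaningful.
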