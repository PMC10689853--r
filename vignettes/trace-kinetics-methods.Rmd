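---
title: "Models and methods for single-molecule trace kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-molecule trace kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracekin)
```

## The measurement this package models

Surface-tethered membrane receptors carrying a single environment-sensitive
fluorophore report their conformation through their fluorescence emission
level under TIRF illumination. A camera integrates the emission over
100 ms frames, producing one intensity trajectory per molecule that
switches among a small number of levels — an inactive state (state 1), an
intermediate (state 2) and an active-like state (state 3) — until the
fluorophore photobleaches in a single step. The analysis task is to turn a
collection of such noisy trajectories into population and kinetic
summaries: what fraction of time the receptor spends in each state, how
fast it exchanges between adjacent states, and whether activation proceeds
sequentially through the intermediate.

`tracekin` implements that full chain: simulation of realistic
trajectories from a continuous-time Markov model, trace selection and
normalization, hidden-Markov idealization, transition-density-plot (TDP)
state assignment, multipeak Gaussian population histograms, and dwell-time
kinetics.

## The kinetic model

A `kinetic_model()` is a continuous-time Markov chain over substates, each
mapped to a coarse state with a normalized emission level (nominally 1.0,
2.0, 3.0 — one normalized unit apart, matching levels separated by roughly
200 a.u. on the raw camera scale when typical noise is ±30–40 a.u.).
Optional *kinetic substates* share one emission level but exit at
different rates; they are invisible to the emission record and surface
only as bi-exponential dwell-time distributions. Photobleaching is an
absorbing dark state entered at a uniform rate from every substate, so
bleach times are exponential and independent of the conformational state;
`generator_matrix()` exposes the full rate matrix with the bleached state
appended.

Because bleaching is state-independent, `simulate_hidden_path()` draws the
bleach time once and runs an exact (Gillespie-style) simulation of the
conformational chain up to it. `render_trace()` then integrates the hidden
path over each frame: the noiseless frame value is the
occupancy-time-weighted mean of the emission levels inside the frame, so a
transition crossing a frame boundary produces an intermediate intensity —
the behavior that makes fast transits through the intermediate state
occasionally look like direct 1↔3 events downstream, as in real data.
I.i.d. Gaussian noise (sd 0.15 normalized units by default) is added per
frame.

### Reference configurations

The shipped `reference_model()` configurations encode rate constants fixed
by algebra from target observables rather than chosen freely: the
stationary distribution of each chain equals the fractional state
populations the analysis should recover, and reciprocal state-1 exit rates
set the mean occupancy times.

| name | states | headline truth |
|---|---|---|
| `apo_wt` | 2 | populations 63/37%, state-1 mean dwell 2.9 s |
| `neca_wt` | 3 | populations 49/37/14% |
| `neca_wt_minigs` | 3 | populations 42/37/21%, state-1 dwell 1.8 s |
| `keq24` | 2 | k(1→2)/k(2→1) = 2.4 |
| `cam` | 3 | state-1 exit 1/1.5 s⁻¹ |
| `substates` | 2 | state-1 split into exits 1.0/0.2 s⁻¹ (50/50 entry) |

Three-state chains are strictly sequential (no direct 1↔3 rates): direct
transitions observed downstream are therefore a fidelity measure of the
idealization, not a property of the generator. One deliberate consequence
of the published population/kinetics pairs is that they cannot all be
reproduced by a single memoryless chain (the equilibrium ratio implied by
the state areas differs from the ratio of fitted rate constants when
hidden substates are present), so occupancy-matching (`neca_wt`) and
ratio-matching (`keq24`) are separate configurations rather than one
reconciled model.

Datasets (`simulate_dataset()`) mix in `static_fraction` (default 0.55)
transition-free traces — the static, single-step-bleaching contaminants
seen in real fields of view, so that roughly 40–50% of trajectories are
dynamic. Bleach lifetime defaults to 30 s with traces capped at 120 s
plus 5 s of post-bleach baseline.

## Selection and normalization

`detect_photobleach()` estimates the frame noise from robust
frame-to-frame differences, takes the terminal sustained level as the
baseline, and reports the first frame after which the running median
stays below baseline + 3 sd for the remainder. Two guards matter in
practice: a trace whose pre-drop record spends appreciable time at the
"baseline" has not bleached (its baseline is an emission state, e.g. a
trace ending in state 1 without bleaching), and a sustained intermediate
level in the post-drop record flags a multi-step (multi-fluorophore)
trace. Both are rejected, as is anything with fewer than 20 pre-bleach
frames; every rejection is logged with a reason code.

Intensities are normalized by the molecule's lowest-intensity state. The
estimate used is the lowest emission mean of the per-trace HMM fit —
the HMM is scale-free, so it is fitted on raw intensities first and the
normalization applied afterwards. This mirrors normalizing to the lowest
state without manual inspection.

## HMM idealization

`fit_hmm()` is maximum-likelihood Baum–Welch EM with Gaussian emissions,
run per trace from 5 seeded restarts (quantile-initialized means with
jitter; sticky 0.9 self-transition start; noise sd initialized from the
frame-difference estimate). States whose fitted means are closer than
0.3 of the lowest fitted mean are merged and states below 1% stationary
occupancy are pruned, then the model is refit — so a two-state trace fed
with `k_max = 3` comes back with two states, and a static one with one.
The emission sd is floored at 1e-4 so noiseless test traces stay
numerically well-behaved; the log-likelihood is asserted non-decreasing
across EM iterations.

`viterbi_path()` decodes the globally optimal state sequence.
`extract_dwells()` applies a minimum-dwell filter (default 2 frames =
200 ms): runs shorter than the minimum are absorbed into their longer
flanking run, suppressing single-frame noise blips. The first and last
dwell of every trace did not both start and end under observation, so
they are censored and excluded from every dwell statistic. Transition
events are defined as the exits of completed dwells, which makes the
bookkeeping exact: per trace, completed dwells and transition events are
equal in number.

Two known, quantifiable consequences of the 2-frame filter are worth
stating openly because they shape what "recovery" means:

* **Occupancy truncation.** Completed dwells are at least 0.2 s, so the
  arithmetic mean dwell of an exponential state with rate *k* estimates
  roughly `0.2 + 1/k` rather than `1/k` (memorylessness), inflating mean
  occupancy times by ~0.15–0.2 s. For slow states (2.9 s) this is within
  a few percent and partially offset by bleach censoring; for fast states
  (1.5 s) it approaches +10%.
* **Skip-event creation.** A genuine fast transit through the
  intermediate state that is decoded as fewer than 2 frames is merged
  into a flank, converting (1→2, 2→3) into a single apparent 1→3 event.
  With intermediate-state exit rates near 0.7–0.8 s⁻¹ this floor is
  about 2–3% of transitions even for a perfectly sequential generator;
  direct-transition fractions below 1% are only reachable with slower
  intermediates or no minimum-dwell merging.

## TDP state assignment

`build_tdp()` lays a separable Gaussian kernel (bandwidth 0.08 normalized
units, about half the emission sd — fixed rather than data-driven for
reproducibility) over the (initial, final) fitted levels of all
transition events on a fixed grid over [0.5, 3.5]². Events within 0.3 of
the diagonal are excluded by construction; self-transitions cannot exist
after idealization, so this is a guard, not a filter. Peak centers pool
the x- and y-coordinates of all density maxima — every symmetric peak
pair contributes through both marginals, making the centers invariant to
mirroring — and are clustered by intensity gaps (levels separated by
less than 0.5 units are one state). Boundaries between adjacent states
are midpoints of their centers: the symmetric, assumption-free choice,
since nothing in the procedure justifies an asymmetric split. A level
exactly on a boundary is assigned to the lower state, deterministically.

## Population histograms

All pre-bleach frames of dynamic traces are pooled (across molecules,
without per-molecule weighting) into a histogram with 0.05-unit bins.
Per-bin standard errors are multinomial, `sqrt(N p (1-p))` on the count
scale; frames within a molecule are autocorrelated, so these errors are
a lower bound — acceptable here because they only serve as fit weights.
`fit_multipeak()` performs bounded weighted least squares of

y(x) = y₀ + Σᵢ Aᵢ · exp(−((x − μᵢ)/σᵢ)²)

with centers initialized at the TDP values and free within ±0.15, widths
bounded in [0.05, 0.5] to prevent peak-swallowing, amplitudes
non-negative, and zero-SE bins given the median weight. Note the peak
form lacks the ½ factor of a normal density, so σᵢ = √2 × the Gaussian
sd and the analytic area is Aᵢσᵢ√π. Fractional areas are
areaᵢ/Σareaⱼ with first-order (delta-method) uncertainties from the fit
covariance.

## Dwell-time kinetics

Completed dwells are partitioned by transition class (i→j) for rate fits
and pooled per state for mean occupancy. Histogram bin widths follow the
Freedman–Diaconis rule `2·IQR/n^(1/3)` with linear-interpolation
quartiles (the common statistical default, fixed for bit-reproducible
widths), falling back to `range/√n` when the IQR vanishes. Both decay
models, `A·e^(−kx)` and `A₁·e^(−k₁x) + A₂·e^(−k₂x)`, are fitted to the
binned counts by weighted least squares with Poisson errors
`sqrt(max(count, 1))`. The bi-exponential is selected only when its
reduced χ² beats the mono fit by more than 10% and is non-degenerate
(rate constants differing by more than 5%, both amplitude percentages
above 2%); ties fall to mono. The 10% threshold and degeneracy guards
are this package's decisions — a bare "compare reduced χ²" rule without
them selects the 4-parameter model on pure mono data far too often.

Amplitude percentages normalize the **fitted amplitudes** (a₁+a₂ = 100%).
Because a count histogram of an exponential mixture has component
amplitudes proportional to (component count × rate), this convention
means the amplitude-weighted rate `1/k̄ = a₁/k₁ + a₂/k₂` equals the
count-weighted arithmetic mean of the component rates — the intended
"average rate weighted by the observed number of transitions". Rates per
class are the chosen model's k̄; for a state with several exits this
conflates the exit-rate split, which is reproduced deliberately as part
of the procedure rather than corrected. Equilibrium ratios
`k_eq(i,j) = k_{i→j}/k_{j→i}` carry first-order propagated standard
deviations, and reciprocal pairs multiply to 1 by construction.

Mean occupancy is the arithmetic mean of completed dwells per state with
SEM = SD/√n. No censoring-bias correction is applied beyond dropping
first/last dwells; bleaching shortens completed dwells by roughly a
factor k/(k + k_bleach), which partially offsets the truncation
inflation described above.

## What the simulator does and does not emulate

Emulated: Markovian state switching with exact frame integration,
Gaussian frame noise, state-independent single-step photobleaching,
static-trace contamination, hidden kinetic substates, strictly
sequential three-state topology. Not emulated: camera (EMCCD) noise
statistics, background drift, fluorophore blinking and other
photophysics, intensity ramps, multi-fluorophore overlaps, or day-to-day
heterogeneity between molecules. Passing recovery tests therefore shows
the analysis is correct and well-calibrated for the idealized generative
process it assumes — not that real traces satisfy those assumptions.

## Problem sizes and reproducibility

Recovery checks run at the scale of one experimental condition: 300
molecules per dataset (roughly 130 dynamic after selection, giving
500–2000 analyzed transitions depending on the kinetics), with
full-pipeline checks at a fixed shipped seed and the acceptance script
reporting per-condition medians over 10 replicate seeds. All randomness
descends from explicit integer seeds: dataset seeds spawn per-trace
seeds, and the HMM restart jitter is seeded per molecule, so every
pipeline run is bit-reproducible.

## Known limitations

* State count is capped at 3 coarse states; no skewed or non-Gaussian
  emission peaks.
* The dwell analysis assumes exponential (or two-component exponential)
  classes; no hierarchical or global fitting across conditions.
* Bayesian/variational alternatives for state-number selection are out
  of scope; the occupancy-pruned EM with TDP consensus is deliberately
  close to established practice for this kind of data.
* The minimum-dwell filter's truncation and skip-event effects discussed
  above are properties of the procedure itself and are left visible
  rather than corrected, to stay faithful to how such data are analyzed.
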