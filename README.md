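# tracekin

Single-molecule fluorescence trace idealization and conformational
kinetics for membrane receptors.

## What problem this solves

In single-molecule TIRF experiments, a receptor carrying one
environment-sensitive fluorophore produces an intensity trajectory that
switches among a few discrete emission levels — inactive (state 1),
intermediate (state 2) and active-like (state 3) conformations — until
the dye photobleaches in a single step. Turning hundreds of such noisy
trajectories into quantitative statements ("the intermediate state gained
7 percentage points of occupancy", "the 1→2 rate constant doubled") takes
a multi-stage analysis that is easy to get subtly wrong. `tracekin`
packages that analysis, end to end and reproducibly, for anyone working
with switching single-channel intensity traces: receptor biophysicists
comparing ligands, mutants or G-protein mimetics, and method developers
who need a simulator with exact ground truth.

The pipeline is:

1. **Simulation** (optional) — continuous-time Markov chains over 2–3
   conformational states (optionally with hidden kinetic substates that
   share an emission level), exact Gillespie paths, frame integration at
   100 ms, Gaussian noise, single-step photobleaching, and a realistic
   fraction of static contaminant traces.
2. **Selection & normalization** — single-step photobleach detection,
   rejection of multi-step and too-short traces (with a reasoned
   selection log), normalization to the lowest-intensity state.
3. **Idealization** — per-trace maximum-likelihood Gaussian HMM
   (Baum–Welch EM, multiple restarts, occupancy-based pruning) and
   Viterbi decoding.
4. **State assignment** — 2-D transition density plots (TDPs) of
   (initial, final) intensities; peak centers define consensus states and
   midpoint cutoffs.
5. **Populations** — pooled intensity histograms fitted with
   `y(x) = y₀ + Σ Aᵢ·exp(−((x−μᵢ)/σᵢ)²)`, centers seeded from the TDP;
   fractional state areas are `Aᵢσᵢ√π / Σⱼ Aⱼσⱼ√π`.
6. **Kinetics** — per-transition-class dwell histograms (Freedman–Diaconis
   bins), mono vs bi-exponential fits selected by reduced χ²,
   amplitude-weighted rates `1/k̄ = a₁/k₁ + a₂/k₂`, equilibrium
   rate-constant ratios `k_eq(i,j) = k_{i→j}/k_{j→i}` with propagated
   uncertainty, and mean occupancy times with SEM.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate one apo-like condition (300 molecules, two states with 63/37%
occupancy and a 2.9 s state-1 dwell by construction) and analyze it:

```r
library(tracekin)
report <- run_pipeline(reference_config("apo_wt", n_traces = 300, seed = 11))
report
#> <tk_report> apo_wt (seed 11, config 2e106cca)
#>   traces: 300 total, 275 accepted, 122 dynamic
#>   state centers: 1.01, 1.98
#>   fractional areas: 62.3%, 37.7%  (red chi-sq 4.74)
#>   k_eq: (1,2) 0.66 +/- 0.05
#>   mean occupancy (s): state 1: 3.05 +/- 0.11; state 2: 1.94 +/- 0.07
```

Reading this: of 300 trajectories, 275 showed clean single-step
photobleaching and 122 of those were dynamic (the rest are the static
contaminants the simulation deliberately includes). The TDP located the
two emission levels at 1.01 and 1.98 normalized units; the two-Gaussian
histogram fit assigns 62.3% of the occupancy to state 1 — recovering the
generating 63% — and the dwell analysis recovers a mean state-1 occupancy
of 3.1 s and an equilibrium ratio k(1→2)/k(2→1) of 0.66 (truth
0.345/0.587 ≈ 0.59; completed-dwell censoring biases ratios slightly
toward 1).

Individual stages are exported too:

```r
ds  <- simulate_dataset(reference_config("neca_wt", n_traces = 50, seed = 1))
sel <- select_traces(ds$traces)
id  <- idealize_traces(sel, seed = 1)
tidy(fit_hmm(sel[sel$molecule_id == "mol0002", ], seed = 1))
```

`tidy(report)` returns every headline number as a long tibble;
`write_report(report, "out/")` writes the JSON report plus TSV
intermediates; `autoplot()` works on TDPs, histogram fits and dwell fits.
A thin CLI covering simulate/analyze/compare lives in
`inst/cli/tracekin.R`.

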