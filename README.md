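# clockgate

Tools for studying how the cell-intrinsic circadian clock gates the
commitment of preadipocytes to differentiate into fat cells.

Adipogenesis takes days, but its irreversible step is fast: commitment is
the moment a cell's PPARG level crosses a threshold at which positive
feedback locks it permanently high, a low-to-high switch that completes in
about 4 hours. Because the switch is fast relative to the ~26-h circadian
clock, the clock can restrict it to a phase window — commitments occur
almost exclusively in the rising half of the Rev-Erbα reporter cycle
(phases π to 2π, peaks ≡ 0/2π, troughs ≡ π), producing daily bursts of
differentiation. The package is aimed at people analyzing dual-reporter
single-cell imaging of this process and at people modeling it.

It provides:

* **A trace pipeline** — 6-h moving-average smoothing, ±4-h
  windowed-regression slopes, prominence-based peak/trough detection,
  H2B-halving division calls (45–55% rule), a control-calibrated fate
  cutoff (< 3% of control cells above it), a ROC threshold scan whose
  optimal point is nearest the (0, 1) corner, first-crossing commitment
  times, piecewise-linear reporter phase maps, Gaussian-mixture fits of
  commitment times, one-term Fourier fits of commitment phases,
  phase-folded slope curves with bootstrap CIs, and a permutation cosinor
  rhythmicity test.
* **A mechanistic model** — seven species (PPARG mRNA/protein/activated
  protein, fast CEBPA-like feedback mRNA/protein, slow FABP4-like feedback
  mRNA/protein) with the published rate constants, circadian forcing of
  the fast branch, static lognormal cell-to-cell noise, vectorized
  ensemble simulation, endpoint-bimodality fate scoring, and the
  architecture variants (low noise, fast-only, slow-only, clock-on-slow,
  no-clock).
* **A synthetic dual-reporter generator** with complete ground truth
  (fates, commitment times and phases, anchor times, divisions), so the
  whole pipeline is testable end to end without any imaging data.

## Worked example

Analyze a synthetic rosiglitazone-stimulated population of 1,000 cells:

```r
library(clockgate)

cfg <- run_config(generator_config(n_cells = 1000, condition = "rosi",
                                   seed = 7))
res <- run_pipeline(cfg)
print(res)
#> <cg_result_bundle> 1000 cells, cutoff 1.08, AUC 1.000, 503 commitments
#>   (475 with phase; excluded: 0 no-anchor, 28 outside map)
res$gmm
#> <cg_gmm> k = 3 components
#>   weight  mean    sd
#> 1  0.451 24.19  4.38
#> 2  0.297 49.91  4.59
#> 3  0.251 77.14 10.50
res$fourier
#> <cg_fourier> peak phase 4.634 rad (1.47 pi), R^2 = 0.853
```

Reading this: the fate cutoff calibrated on unstimulated controls is
1.08 a.u.; predicting each cell's terminal fate from whether its smoothed
PPARG trace ever exceeds a threshold achieves AUC 1.000, and the optimal
threshold yields 503 commitment times. Their distribution splits into
three Gaussian components spaced ~26 h apart — daily commitment bursts —
and the commitment-phase density peaks at phase 1.47π, inside the rising
(π, 2π) half of the reporter cycle.

The same daily bursts emerge from the mechanistic model:

```r
p <- model_params()
ens <- simulate_ensemble(p, 2000, seed = 11)
print(ens)
#> <cg_ensemble> 2000 cells (full), 83.8% differentiated, cutoff 2.45
fit_commitment_time_gmm(ens$commit_time[!is.na(ens$commit_time)] / 60)
#> <cg_gmm> k = 3 components
#>   weight  mean    sd
#> 1  0.531 17.75  2.32
#> 2  0.291 44.33  1.92
#> 3  0.178 80.52 14.58
ensemble_rhythmicity(ens)$rhythmic
#> [1] TRUE
```

Commitment components again sit ~26 h apart (the forcing period), and the
ensemble-mean PPARG synthesis rate is rhythmic at that period. Applying
`apply_variant()` before simulating shows the four requirements for
bursting: reducing noise to 3% collapses the bursts into one wave, making
both feedbacks fast confines commitment to the first cycle, and slowing
both feedbacks or moving the clock onto the slow branch abolishes
circadian PPARG expression.

A thin command-line front end over the same functions ships in
`inst/cli/clockgate.R` (`generate`, `simulate`, `analyze` subcommands).

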