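# clockloops

Which negative feedback loops make the mammalian circadian clock tick —
and does the answer differ between organs?  The core clock is a web of
transcriptional feedbacks in which several loops could each, in
principle, generate the ~24-h rhythm: the *Per2* and *Cry1*
auto-inhibitions, the *Bmal1*/*Rev-erb-α* loop, and the repressilator
(the serial inhibition chain *Per2* ⊣ *Rev-erb-α* ⊣ *Cry1* ⊣ *Per2*).
`clockloops` is for computational chronobiologists who want to fit a
compact, data-driven clock model to tissue expression profiles and then
*ask the fitted model* which loops its rhythm actually requires.

The package implements, in one pipeline:

- a **five-gene delay-differential-equation model** (*Bmal1*, *Dbp*,
  *Per2*, *Cry1*, *Rev-erb-α*; 7 activations + 10 inhibitions via E-box,
  D-box and RRE elements; 34 kinetic parameters)

  dx_g/dt = ∏ₑ f_e(x_s(t − τ_s)) − d_g·x_g,

  with Hill-type activation folds (1 + a(y/K)ⁿ)/(1 + (y/K)ⁿ) and
  inhibition folds 1/(1 + (ry)ⁿ), integrated by a fixed-step RK4 method
  of steps (Rcpp core);
- **feature scoring**: fits are judged on period, relative peak phases and
  fold changes against tolerance units chosen to match experimental
  uncertainty; a score below 10 ⇔ root-mean-square deviation below one
  tolerance;
- **vector field optimization (VFO)**: gradient-matching initialization
  that derives starting parameters from the data's time derivatives
  without a single integration, then seeds
- **particle swarm optimization** over the 34-dimensional bounded
  parameter space (Latin hypercube init, ring neighborhood, optional
  contraction restarts);
- **clamping analysis**: freezing genes at their mean or regulatory terms
  at their cycle-averaged value to identify *essential* loops (every
  single-edge clamp kills the rhythm) and minimal *rhythm-generating
  oscillators* (loop sets sufficient when everything else is clamped),
  with dependent/independent synergy classification;
- **ensemble statistics** over many fits: loop-frequency tables by
  tissue, Venn-style oscillator composition, PCA/LDA projections of the
  parameter ensemble, exact rank-sum tests, circular phase means;
- a **synthetic-data generator** with 10 tissue presets (SCN = small
  amplitudes + early *Cry1*; liver = large *Rev-erb-α* amplitude + late
  *Cry1*) and verified ground-truth fixtures for loop-recovery testing.

## Worked example

```r
library(clockloops)

default_topology()
#> Clock network topology: 5 genes, 17 regulations ( 7 activations, 10 inhibitions )

# a ground-truth model driven by the Bmal1/Rev-erb-α loop, and its profile
fx <- ground_truth_fixture("Bmal1_RevErbA", noise = 0)
extract_features(simulate_clock(fx$params))
#> Clock features: period 24.18 h (reference Bmal1)
#>             Bmal1   Dbp  Per2  Cry1 RevErbA
#> phase_h      0.00 5.464 5.514 4.374   5.565
#> fold_change  3.38 1.285 1.294 1.349   2.235

# dissect the model: which loops does the rhythm require?
loop_report(fx$params)
#> Loop dissection report
#>   essential families: Bmal1_RevErbA
#>   minimal oscillators: Bmal1_RevErbA

# fit the model back from the sampled profile and score it
fit <- fit_profile(fx$profile, config = swarm_config(24, 100), seed = 1,
                   duration = 360, step = 0.1, transient = 240)
fit$score$total
#> [1] 0.9415903
```

The feature table reads: the free-running period is 24.18 h, *Rev-erb-α*
peaks 5.6 h after *Bmal1* (half a cycle before the antiphase trough), and
fold changes are modest.  The dissection says that clamping either edge
of the *Bmal1*/*Rev-erb-α* loop abolishes rhythms, while that loop alone —
every other regulation clamped to its cycle average — keeps oscillating:
it is both essential and sufficient.  The refit of the sampled profile
reaches a score of 0.94: all ten scored features agree with the data
within a third of a tolerance unit RMS.  Dissecting the *refit* rather
than the generator can legitimately report additional essential loops —
distinct loop constellations reproduce the same profile, which is exactly
why the ensemble statistics exist.

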