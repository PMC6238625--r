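---
title: "Dissecting rhythm-generating feedback loops in a five-gene clock model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting rhythm-generating feedback loops in a five-gene clock model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The mammalian core circadian clock is reduced here to five representative
genes — the activators *Bmal1* and *Dbp* and the inhibitors *Per2*, *Cry1*
and *Rev-erb-α* — connected by 17 transcriptional regulations acting through
three promoter element classes (E-boxes, D-boxes, RREs): 7 activations and
10 inhibitions.  Protein synthesis, complex formation and nuclear transport
are not modelled explicitly; each regulator acts on its targets after an
explicit delay.  The dynamics of each mean-normalized transcript level
$x_g$ are

$$\frac{dx_g}{dt} \;=\; \prod_{e \,\in\, \mathrm{in}(g)} f_e\!\big(x_{s(e)}(t - \tau_{s(e)})\big) \;-\; d_g\, x_g ,$$

with activation factors $f_e(y) = \dfrac{1 + a_e (y/K_e)^{n_e}}{1 + (y/K_e)^{n_e}}$
(range $[1, a_e]$) and inhibition factors $f_e(y) = \dfrac{1}{1 + (r_e y)^{n_e}}$
(range $(0,1]$).  The Hill exponents $n_e$ stand for the number of
regulator binding sites; we default to $n_e = 3$ for every edge and expose
them in the serializable edge table, since site-specific counts can be
substituted without code changes.  One delay per regulator gene, shared by
all of its outgoing edges, together with 14 activation parameters, 10
inhibition strengths and 5 degradation rates, gives the 34-parameter
vector the whole package manipulates (`parameter_names()` documents the
flattening order).  There is no separate basal-rate parameter: the basal
state of every factor is 1, and mean-normalized data absorb absolute
scale.

Parameter bounds encode biology rather than convenience: delays up to
12 h (the Bmal1 delay up to 6 h, since BMAL1 protein acts within a
quarter cycle of its mRNA peak), degradation rates between 0.05 and
1 h⁻¹ (mRNA half-lives of roughly 0.7–14 h), and activation thresholds /
inhibition strengths spanning the working range around the normalized
mean level of 1.

## Integration of the delayed system

`simulate_clock()` integrates the delay system with a fixed-step explicit
4th-order scheme (default step 0.05 h) using the method of steps: states
and derivatives are stored on the step grid and delayed lookups are served
by cubic Hermite interpolation; pre-history is constant at the normalized
mean.  A fixed step keeps clamping comparisons deterministic — identical
trajectories in and outside the dissection loop — which adaptive steppers
do not guarantee.  Zero delays are handled exactly (the stage state is
used directly), and step-halving moves fitted-limit-cycle peak times by
less than 0.01 h, the self-convergence check in the test suite.

## Features and scoring

Fits are scored on limit-cycle *features*, not pointwise residuals: the
free-running period $T$, peak phases of each gene relative to Bmal1, and
peak-to-trough fold changes.  Simulated features come from local-maximum
detection with quadratic refinement after discarding a 480-h transient
(720-h simulations by default).  Data features come from least-squares
harmonic regression with a 24-h fundamental plus second harmonic — the
data are entrained, so the data period is pinned at 24 h while the model's
period is free.  The score is

$$S = \Big(\frac{T - 24}{\sigma_T}\Big)^2
  + \sum_{g \ne \mathrm{Bmal1}} \Big(\frac{\mathrm{circ}(\varphi_g^{sim}, \varphi_g^{dat})}{\sigma_\varphi}\Big)^2
  + \sum_g \Big(\frac{\log_2 FC_g^{sim} - \log_2 FC_g^{dat}}{\sigma_{FC}}\Big)^2,$$

ten quadratic terms with tolerances $\sigma_T = 0.5$ h, $\sigma_\varphi = 1$ h,
$\sigma_{FC} = 0.5$ log₂ units, calibrated so that day-to-day experimental
variability lands near the goodness threshold.  A fit is "good" when
$S < 10$ strictly — equivalently, when the root-mean-square deviation is
below one tolerance unit.  Non-rhythmic or failed simulations earn a flat
penalty of 1000; we deliberately do not shape the penalty, accepting a
plateau in the search landscape in exchange for a score whose magnitude is
interpretable.  Phases enter through the shorter circular arc, so a fit
23 h late is 1 h early.

Two caveats the tests make explicit: harmonic regression attenuates sharp,
pulse-like waveforms, so even a model scored against its own sampled
output retains a small residual score (0.2–2.9 across the shipped
fixtures); and when a fitted curve's trough approaches zero the fitted
fold change becomes very large and noise-sensitive, which inflates scores
on noisy profiles of high-amplitude genes.

## Parameter estimation

**Gradient matching ("vector field optimization").**  Before any
integration, `run_vfo()` estimates initial parameters directly from the
data's vector field: the two sampled days are averaged onto one 24-h
cycle, periodic central differences estimate $\dot{x}_g$ at the 12 grid
points, and the squared mismatch between those derivatives and the model
right-hand side (delayed levels read from a periodic cubic interpolant, so
the objective is smooth in the delays) is minimized by bounded L-BFGS-B
from random starts, with an analytic gradient.  The procedure performs
zero simulations — a property asserted in the test suite via an
integration counter.  Central differences at 2-h spacing attenuate the
fundamental by $\sin(\omega h)/\omega h \approx 0.955$; we accept this
bias in an initializer.

**Swarm optimization.**  `run_pso()` is standard inertia-weighted particle
swarm optimization: Latin hypercube initialization, ring neighborhood of
5, cognitive and social weights 1.494, inertia decreasing 0.9 → 0.4,
velocities clamped to 20% of each range, positions clipped at the bounds
with the clipped velocity component zeroed.  The constants are
conventional choices; results are reproducible from (profile, config,
seed).

**Seeding and refinement.**  `fit_profile()` composes the pipeline: the
VFO optimum initializes one particle exactly, and a fraction ρ = 0.25 of
the swarm has its kinetic parameters resampled within ±25% of the VFO
values (delays stay Latin-hypercube) — realizing both "initialize one
particle" and "pre-emphasize kinetics" without collapsing swarm diversity.
After the main run, optional *zoom stages* (default 3) restart a smaller
swarm inside a box contracted geometrically (factor 0.3 per stage) around
the incumbent best, which seeds each stage so the best score never
worsens.  The good-score basins of this landscape are narrow — the period
term alone confines them to delay combinations matching 24 h within about
±1 h — and at desk-scale budgets the contraction stages are what carry the
swarm from qualitatively right basins (scores 20–50) to good fits
(scores < 10).  At full scale (40 × 500 swarms) the plain swarm performs
this refinement itself.

The VFO-benefit comparison in the tests deliberately disables zoom stages
in both arms — restarts rescue poor initializations and would mask
exactly the initialization effect being measured — and runs on
model-generated fixture profiles rather than harmonic ones: gradient
matching can only supply useful seeds when the data's vector field is
representable by the model class, which holds for model-sampled data but
not necessarily for pure cosines.  With matched plain-swarm budgets
(16 particles × 60 iterations) over 20 noisy fixture profiles, the seeded
arm's median final score is consistently lower across seed sets; the
one-sided rank-sum comparison at α = 0.05 is met at the suite's fixed
seed set, though with an effect this size significance is near the
boundary.

## Clamping and loop dissection

`loop_report()` dissects a fitted model by clamping.  A gene clamp freezes
a transcript at its limit-cycle mean (the in-silico analogue of
constitutive expression); a regulation clamp replaces one edge's fold
factor by its time-average over one period of the unclamped limit cycle.
We average the *factor* rather than evaluating the factor at the average
expression — the two differ for nonlinear factors — because the factor
average is what the production term actually contributes over a cycle;
the alternative is available as an option.

A negative feedback loop is **essential** when clamping each of its edges,
one at a time, abolishes sustained rhythmicity.  All 17 single-edge clamps
are simulated once and cached; essentiality of every simple cycle in the
four-family catalog (Per2 and Cry1 auto-inhibitions with their Dbp
extensions, the Bmal1/Rev-erb-α loop, and the repressilator
Per2 ⊣ Rev-erb-α ⊣ Cry1 ⊣ Per2) is then a table lookup.  A set of loops is
**sufficient** when rhythms persist with every regulation outside the set
clamped; minimal sufficient sets are the *rhythm-generating oscillators*.
We test all 15 non-empty family subsets exhaustively rather than a
targeted sequence — 32 short simulations per fit, affordable at this
model size and strictly more complete.  Synergy of a multi-loop
oscillator is *independent* when at least two member loops are each
sufficient alone (mutual compensation) and *dependent* otherwise (shared
feedback).

Rhythmicity itself is decided on the post-transient trajectory: some gene
must show relative amplitude above 1%, with the last cycle's amplitude at
least 0.95 of the previous one (sustained, not damped).  We probe *any*
gene rather than only the reference gene: under clamping, genes
downstream of a clamped edge can be flat while the oscillator lives
elsewhere — with a Bmal1-only criterion, a sufficiency clamp that freezes
Bmal1 would mislabel a running repressilator as arrhythmic.  A specific
gene can still be requested.

## Synthetic data

The generator replaces the external expression atlas with profiles whose
statistical structure matches what the analysis assumes: 24 samples at
2-h spacing over 48 h, mean-normalized, multiplicative log-normal noise
(default sd 0.1 on the log scale, so day-1/day-2 differences resemble the
experimental uncertainty the scoring tolerances encode).  Ten tissue
presets encode the qualitative contrasts the analysis exploits — the SCN
with the smallest amplitudes and earliest Cry1 peak, liver/adrenal/kidney
with large Rev-erb-α amplitudes and late Cry1 — with numeric values that
are generator choices, not measurements.  Harmonic profiles
(`generate_harmonic_profile()`) are cosines with amplitude
$(FC-1)/(FC+1)$; they emulate smooth entrained expression but not
waveform asymmetry, sampling artifacts, or gene-gene noise correlation of
real data, so passing recovery tests demonstrates correctness of the
machinery, not performance on arbitrary transcriptomes.

Model-sampled profiles (`generate_model_profile()`) anchor their 48-h
window at a late reference peak, making phases identifiable without an
external zeitgeber convention.  Four hand-tuned ground-truth fixtures ship
with verified loop structure (repressilator-, Bmal1/Rev-erb-α-, Per2- and
Cry1-auto-inhibition-driven; periods 23.7–24.2 h), plus two synergy
fixtures (a dependent repressilator + Bmal1/Rev-erb-α pair and an
independent Per2 + Cry1 pair).  A model in which both self-inhibitions are
independently supercritical has *no* essential loop — each single-edge
clamp leaves the other loop running — which is why the self-inhibition
fixtures are shipped per gene rather than combined.

## Problem sizes and numerical choices

Default analyses simulate 720 h, discard 480 h, and read features from
the final cycles at step 0.05 h.  The heavier test-suite batteries use a
reduced span (360 h, 240-h transient, step 0.1 h) and reduced swarm
budgets; these sizes are stated in the tests themselves.  Fixture
recovery from noisy profiles uses a 40 × 200 main swarm with four zoom
stages; the VFO comparison uses 16 × 60 plain swarms over 20
model-generated fixture profiles.
Ties in the median-score split go to the lower half; Latin hypercube
sampling comes from the `lhs` package; the within-class scatter in the
discriminant projection carries a ridge of 10⁻⁶ because 34 dimensions can
exceed per-tissue fit counts.

## Known limitations

- Protein dynamics are collapsed into transcriptional delays; mechanisms
  that depend on protein-specific regulation (phosphorylation switches,
  complex stoichiometry) are outside the model class.
- Desk-scale optimization recovers *a* good fit, not the global optimum;
  as in the ensemble analyses, conclusions should be drawn from many fits,
  not one.
- A noisy profile's fitted fold changes can exceed any model-attainable
  value when troughs approach zero; such profiles may have no sub-threshold
  fit at all.
- Loop identifiability is genuinely partial: distinct loop mechanisms can
  reproduce the same profile within tolerance, which is the scientific
  point of the ensemble view — single fits should not be over-interpreted,
  and recovery tests on fitted (rather than ground-truth) parameters can
  legitimately report a different essential loop than the generator used.
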