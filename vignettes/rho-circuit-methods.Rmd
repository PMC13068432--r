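---
title: "Modelling Rho signalling flux under pulsed optogenetic GEF recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Rho signalling flux under pulsed optogenetic GEF recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question and the model

Rho GTPases cycle between an active, GTP-loaded state and an inactive
state. Even when a cell's Rho activity looks steady, individual molecules
are continuously activated by GEFs and deactivated by GAPs — a signalling
flux whose regulation is invisible in steady-state images. A way to probe
the flux is to nudge the system: recruit a GEF domain (the DH/PH domain of
LARG, via an iLID optogenetic dimeriser) to the plasma membrane with a
short light pulse, and watch a Rho biosensor (rGBD) relax back to
baseline. The shape of that transient — how fast activity rises, how high
it peaks, how fast it decays — constrains the underlying GEF/GAP kinetics.

`rhoflux` implements the deterministic circuit used to interpret such
pulse experiments. Three species evolve from zero initial activity:

* **LARG\*** — recruited (active) GEF. A linear model driven by the light
  input $f_{\mathrm{signal}}(t)$:
  $\mathrm{d}L/\mathrm{d}t = k_{on} f_{\mathrm{signal}}(t) - k_{off} L$.
* **GAP\*** — active GAP. In the wild-type (WT) circuit it is activated by
  Rho\* through saturable (Michaelis–Menten) kinetics — a negative
  feedback loop — and decays with first-order kinetics:
  $\mathrm{d}G/\mathrm{d}t = v_{on}^{GAP} R/(K_m^{GAP}+R) - k_{off}^{GAP} G$.
  The knockout (KO) variant replaces the feedback with a constitutive
  activation constant, $\mathrm{d}G/\mathrm{d}t = k_{on}^{GAP} - k_{off}^{GAP} G$;
  the Michaelis constant is structurally absent rather than set to zero,
  which avoids a 0/0 singularity at $R = 0$.
* **Rho\*** — active Rho, activated by LARG\* and deactivated by GAP\*,
  both saturable:
  $\mathrm{d}R/\mathrm{d}t = V_{on}^{Rho} L/(K_{m,on}^{Rho}+L) -
  V_{off}^{Rho}\, G\, R/(K_{m,off}^{Rho}+R)$.

Assumptions inherited from the experimental regime: the perturbation is
weak, so inactive pools are effectively constant (they never appear as
states); initial conditions are exactly zero; time is in seconds and all
rate constants are per second. On the deactivation denominator we use the
dedicated constant $K_{m,off}^{Rho}$ — the parameter table distinguishes
it from the activation constant, and a shared constant would make the
table redundant.

**Observation map.** Measured traces are expressed as fold change to a
pre-stimulus baseline, so their baseline is 1, while the model's baseline
activity is 0. The minimal consistent map is
$\mathrm{obs}(t) = 1 + R(t)$, implemented in `to_observation()`; fitting
therefore compares $1 + R$ with the fold-change data directly.

**Stimulus.** The effective GEF-input window of a single pulse is not a
measured quantity; the default protocol is a boxcar of amplitude 1
lasting 30 s from $t = 150$ s on a 600 s horizon with 1 s sampling and a
0–150 s baseline window. The 30 s window reproduces a clearly resolved
rise phase with the published recruitment kinetics
($k_{on} = 0.0123462$, $k_{off} = 0.0700499\ \mathrm{s^{-1}}$, implying a
dissociation half-life $\ln 2/k_{off} \approx 9.9$ s against a measured
10.8 s). An exponentially decaying input shape is available as an
alternative. Everything is configurable through `stimulus_protocol()`.

## Numerical integration

GAP relaxes on a $1/k_{off}^{GAP}$ timescale (10–20 ms for the published
parameter sets) against a 600 s horizon — a stiff problem. The right-hand
side is compiled C called through `deSolve::lsoda` (stiff-capable via
automatic switching), with defaults `rtol = 1e-8`, `atol = 1e-10`.
Integration is split at the light on/off breakpoints and the input is
frozen to its within-segment value, so the integrator never samples the
discontinuity when it oversteps an output time; this keeps the
pre-stimulus solution exactly zero. After solving, values in
$(-100\,\mathrm{atol}, 0)$ are clamped to zero; anything more negative
raises an error. Inside the fitter tolerances are tightened to
`rtol = 1e-10`, `atol = 1e-12` because basin discrimination (below) needs
sums of squares resolved to ~1e-11.

## Two-stage fitting

Following the two-stage design, `fit_larg_kinetics()` first estimates the
recruitment constants from a recruitment trace; `fit_rho_circuit()` then
freezes the GEF profile and estimates the circuit parameters (7 for WT,
6 for KO) by bounded least squares on the fold-change trace. The loss is
the unweighted sum of squared residuals over all frames. Default bounds
are $[10^{-6}, 100]$ for every parameter, mirroring the magnitude span of
the published estimates; bounds are an explicit, reported part of every
fit because non-identifiable estimates can track them.

Optimisation is Levenberg–Marquardt (`minpack.lm::nls.lm`) on
$\log_{10}$-transformed parameters. A quasi-Newton optimiser with
finite-difference gradients was the first candidate but could not recover
the well-constrained parameters on noiseless round trips: the loss
surface has long, nearly flat ridges on which line-search methods stall
far from the optimum, while a trust-region least-squares method exploits
the residual structure and converges reliably. Quasi-Newton
(`optim(method = "L-BFGS-B")`) remains available and is the natural lens
for the bound-sensitivity diagnostics, whose subject is precisely how a
bounded optimiser behaves on flat ridges.

**Staged multistart.** The circuit is practically non-identifiable in
three directions, which defeats naive random multistart. The fitter
therefore exploits the model's timescale structure. Because GAP
equilibrates in milliseconds, substituting its quasi-steady state (QSS)
yields a reduced model with 4 (KO) or 5 (WT) parameters — the
well-constrained content of the data: $V_{on}^{Rho}$, $K_{m,on}^{Rho}$,
$K_m^{GAP}$ (WT only), a lumped deactivation strength
$C = v_{on}^{GAP} V_{off}^{Rho} / k_{off}^{GAP}$ and $K_{m,off}^{Rho}$.
Stage one runs random-start LM fits of the QSS model; stage two expands
the best reduced candidates into full-model starts (splitting $C$ across
the three lumped constants at sampled GAP turnover rates) and polishes
them with LM, alongside purely random full-model starts. The lowest loss
wins. All starts flow from one seed and are recorded in the result.

**An exact exchange symmetry and its resolution.** In the QSS limit the
WT deactivation flux is
$\propto R^2 / \big((K_m^{GAP}+R)(K_{m,off}^{Rho}+R)\big)$ — symmetric
under swapping $K_m^{GAP} \leftrightarrow K_{m,off}^{Rho}$. The full
model breaks the symmetry only through the milliseconds-scale GAP lag, a
~1e-11 effect in the loss on these problem sizes. Two consequences are
built into the fitter. First, stage two always polishes both assignments
of each reduced candidate, and on noiseless data the true assignment's
strictly deeper basin wins. Second, because data can never distinguish
the assignments beyond that floor, the fitter canonicalises the labelling
to $K_m^{GAP} \le K_{m,off}^{Rho}$ (the feedback saturates at low Rho\*,
the biochemical reading of the loop), accepting the relabelled polish
whenever it costs no more than 0.1% of the loss plus an absolute floor of
1e-9 — the order of the integration noise. Loss differences below that
floor are not treated as evidence.

**Term-deletion (KO-limit) test.** An estimate that runs down a loss-flat
tail toward its lower bound (the feedback constant $K_m^{GAP}$ on
feedback-free data; $V_{on}^{Rho}$ on a null response) is pinned at the
bound and the remaining parameters re-polished; the pinned fit is kept
when it costs nothing. This makes "converged to the bound" a
deterministic outcome instead of an optimiser stall a few percent above
it, and is how `compare_variants()` detects loss of negative feedback:
the reduced model is preferred when the full fit collapses $K_m^{GAP}$
onto its lower bound and matches the reduced fit's loss within 1%.

## Identifiability diagnostics

`profile_likelihood()` fixes one parameter on a log-spaced grid (default
21 points, 0.1–10× the estimate) and re-optimises the rest at each point,
from both a walking warm start and the reference estimates (warm chains
alone can wander onto a worse ridge position). Classification compares
the profile with a threshold: chi-square based
($\mathrm{best} + \sigma^2 \chi^2_{1,0.95}$) when a noise level is known,
otherwise the heuristic $1.05 \times \mathrm{best} + 10^{-9}$ — the floor
again guards against reading integration noise as curvature when the best
loss is essentially zero. Crossing on both sides means identifiable; one
side, practically non-identifiable in the open direction; neither, flat.

`bound_sensitivity_scan()` re-fits with a sequence of upper bounds on one
parameter. Each refit polishes from the reference estimates, from the
same start with the scanned parameter placed at the bound, and from fresh
random starts; near-ties (0.1% relative or the 1e-9 floor) are resolved
toward the at-bound candidate. The rationale: for a ridge parameter the
near-optimal set genuinely extends to the bound — exactly upper-side
profile flatness — and a bounded quasi-Newton fit lands there in
practice. A parameter whose estimate sits within 5% of the imposed bound
for two consecutive bounds is flagged as bound-tracking. On synthetic WT
data this reproduces the published grouping: the GAP turnover and
deactivation constants ($k_{off}^{GAP}$, $V_{off}^{Rho}$,
$K_{m,off}^{Rho}$) track their bounds at unchanged loss, while
$K_m^{GAP}$, $V_{on}^{Rho}$ and $K_{m,on}^{Rho}$ are bound-insensitive.

Structural identifiability (differential-algebra) analysis is out of
scope; the practical diagnostics above are the package's lens.

## Synthetic trace ensembles

`generate_roi_ensemble()` emulates pooled single-ROI recordings around a
shared response: trace$_i$ = $s_i (\mathrm{obs}(t) - 1) + 1 +
\varepsilon_i(t)$ with a log-normal per-ROI amplitude $s_i$
(`roi_scale_sd`, default 0.3 — expression-level heterogeneity) and
Gaussian frame noise (`additive_sd`, default 0.05 fold-change units).
Default ensemble size is 2000 ROIs, the order of the pooled counts in the
motivating experiment. `aggregate_ensemble()` normalises each trace to
its own baseline mean, drops traces with non-positive baselines, and
summarises by the per-timepoint median with a percentile bootstrap band
(default 99%, 1000 resamples of whole traces, seeded; computed in C).
The generator does not model photobleaching drift, frame registration
artifacts, or spatial correlation between ROIs — passing tests therefore
demonstrate correctness of the estimators under this noise model, not
robustness to every artifact of real imaging data.

## Pulse-response statistics

`observed_rates()` summarises a fold-change transient by the mean
derivative over the 10–90% windows: with baseline $b$ (mean over the
baseline window) and peak excess $A$, crossing times of $b + 0.1A$ and
$b + 0.9A$ are linearly interpolated (first upward crossings before the
peak, first downward after), and each rate is the secant slope between
its two crossings — identical to the mean instantaneous derivative over
the window for a continuous trace. No smoothing is applied by default. A
peak must exceed the baseline by twice the baseline SD (any positive
excess on noiseless traces); missing crossings raise errors naming the
crossing. Rates are reported in fold-change per second, consistent with
second-based model time. `decay_half_life()` fits a single exponential
with fixed asymptote to a decay segment and reports $\ln 2 / k$.

## The ROI-targeting image pipeline

The imaging module reproduces the targeting logic on synthetic
two-channel scenes with known ground truth. `synthesize_cell_image()`
renders an elliptical cell (cytosol level over background) in the
biosensor channel and adds elongated, tangentially oriented Gaussian
spots in a peripheral band in the paxillin channel, plus per-frame
Gaussian noise; FA centres are placed at least 20 px apart so the
rendered adhesions are resolvable discrete structures, as adhesions in a
spread fibroblast are. Then `segment_cell()` (Otsu threshold, largest
component, hole filling — a classical replacement for a trained pixel
classifier whose weights are not portable), `detect_focal_adhesions()`
(within-cell mean + $k$ SD threshold, default $k = 2$; component area in
[10, 500] px²; centroid within 15 px of the cell edge),
`select_stimulation_rois()` (one disk ROI per FA centroid, default
radius 3 px, paired with the nearest valid non-FA site in the same
edge-distance band, outside the dilated FA components) and
`extract_roi_traces()` (per-frame disk means). Pixel coordinates are
0-based (row, column); stacks read and write as 16-bit multipage TIFF.
The synthetic scenes do not emulate FA turnover, uneven illumination or
cell movement; detection accuracy measured on them is an upper bound on
real-data performance.

## Problem sizes and reproducibility

The shipped analyses and tests use the default 601-frame grid; ensemble
statistics use 100–2000 ROIs with 200–1000 bootstrap resamples; scans
and profiles use 3 bounds and 7–21 grid points. Fits complete in seconds
to tens of seconds on one core. Every stochastic step takes an explicit
integer seed, and the pipeline driver (`run_pipeline()`) writes a
manifest with config and output checksums so a rerun with the same
configuration is bit-identical.

## Known limitations

* Point estimates of $k_{off}^{GAP}$, $V_{off}^{Rho}$ and
  $K_{m,off}^{Rho}$ are not meaningful on single-condition pulse data;
  only their lumped combination is constrained. The package reports them
  with at-bound flags and diagnostics rather than suppressing them.
* The canonical $K_m^{GAP} \le K_{m,off}^{Rho}$ labelling is a
  convention; data of this design cannot distinguish the swapped
  assignment beyond the integration-noise floor.
* The observation map assumes the biosensor responds linearly to Rho\*
  with unit baseline; saturating readouts would need a different map.
* No spatial modelling: diffusion, membrane geometry and RhoGDI cycling
  are outside the model's scope, as are multi-pulse protocols.
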