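---
title: "A bistable model of spindle-checkpoint adaptation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable model of spindle-checkpoint adaptation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the model

The spindle assembly checkpoint (SAC) arrests budding-yeast cells in
mitosis while kinetochores are unattached or lack tension. The arrest is
enforced by the mitotic checkpoint complex (MCC), which sequesters Cdc20
and inhibits the anaphase-promoting complex APC/C^Cdc20^. The arrest is
leaky: over hours, cells *adapt* (slip) and enter anaphase with
unattached kinetochores, risking chromosome missegregation.

`sacsim` implements a mass-action model of this network with eight
molecular species — free Cdc20 (`C`), free APC/C (`A`), APC/C^Cdc20^
(`AC`), active and inactive Mad pools (`Mada`, `Madi`), the checkpoint
kinase Mps1, free MCC (`MC`) and the inhibited complex APC/C^MCC^
(`ACMC`) — plus the number of unattached kinetochores `nUK` and, in the
stochastic version, two-state ("bursting") promoters for Cdc20 and Mps1.
Two feedback structures matter:

* Mps1 activates the Mad pool in proportion to the saturating
  kinetochore signal `s(nUK) = k' nUK / (Jn + nUK)`, and APC/C^Cdc20^
  degrades Mps1. This mutual antagonism is a positive feedback loop:
  once APC/C^Cdc20^ rises, Mps1 falls and the checkpoint collapses, and
  vice versa.
* The MCC assembles from active Mad and Cdc20, binds APC/C^Cdc20^, and
  the resulting APC/C^MCC^ is turned over, degrading one of its two
  Cdc20 moieties per event.

The deterministic system is bistable over a window of `nUK`: a
checkpoint-ON state (low `AC`, high Mps1) coexists with a checkpoint-OFF
state (high `AC`, low Mps1). The left knee of this window — the
saddle-node bifurcation where the ON state is created or destroyed — is
the minimal signal that can sustain an arrest; `locateSaddleNode()`
finds it by bisection on the existence of the ON fixed point.
Adaptation is the noise-driven escape from the ON basin at fixed
`nUK > nUK*`, and checkpoint satisfaction is the deterministic loss of
the ON state when the last kinetochore attaches.

```{r}
library(sacsim)
findSteadyStates(checkpointParams("nM"), nUK = 10)
locateSaddleNode(checkpointParams("nM"))
```

## Conserved quantities

APC/C (`A + AC + ACMC`, 40 nM = 100 molecules) and the Mad pool
(`Mada + Madi + MC + ACMC`, 70 nM = 175 molecules) are conserved.
APC/C^MCC^ carries **two** Cdc20 moieties (one APC/C-bound, one inside
the MCC), so the Cdc20 bookkeeping is `C + MC + AC + 2·ACMC`; with this
convention the reference checkpoint-ON state sums to the tabulated 40 nM
total, and only synthesis and the degradation channels change it. Both
engines conserve the APC and Mad moieties structurally — the
deterministic derivative is the stoichiometry matrix times the rate
vector, and the stochastic engine applies integer stoichiometry — so
conservation holds to integrator drift (`< 1e-6` relative over 10^4
minutes) and integer-exactly in the SSA.

## Parameter provenance and the two unit columns

The model's constants come tabulated in two columns, deterministic (nM)
and stochastic (molecules per nucleus), related by the nuclear-volume
bookkeeping 40 nM = 100 molecules (2.5 molecules per nM, about 4.15 fL).
While reconstructing the rate laws we found that the tabulated nM column
is not internally consistent: at the tabulated ON state the APC/C^MCC^
balance is off by a factor of about four (formation 3.7 nM/min against
a turnover of 17 nM/min), and integrating it yields a single nonsensical
steady state. Every tabulated nM bimolecular constant equals the molecule
column value divided by 2.5, whereas a volume change *multiplies*
bimolecular constants by 2.5. The molecule column, by contrast, balances
the tabulated states to within their two-digit rounding and is bistable.

`sacsim` therefore treats the molecule column as authoritative.
`checkpointParams("nM")` returns its exact volume conversion
(concentration-like constants divided by 2.5, bimolecular constants
multiplied by 2.5, synthesis divided by 2.5), so the two unit systems
are literally the same model and the bifurcation structure is identical
in both. The as-tabulated nM column is retained for reference in
`paramTable()` but never used by the engines.

## Two ambiguous rate laws and how they were discriminated

The source reaction table flattens two expressions beyond unambiguous
recovery:

* **Mad inactivation**, tabulated as `kinact·Mada·J+Mada`. Candidates
  (`kinact·Mada·(J+Mada)`, `kinact·Mada²/(J+Mada)`, and bimolecular
  forms with AC, C or Mps1 as the second substrate) were scored by two
  independent requirements: the tabulated ON/OFF states must be near-fixed
  points (smallest residual against the tabulated fluxes), and the system
  must be bistable at ten unattached kinetochores with both tabulated
  states on their branches — the premise the whole analysis rests on.
  Only `kinact·Mada²/(J+Mada)` satisfies both (residual 8.3
  molecules/min against a maximal flux of 64; the ON fixed point lands
  at C = 13.0 molecules against the tabulated 13). Under this law
  `kinact` acts as a first-order constant and is not volume-converted.
* **Routing of Mad released by MCC turnover** (`ACMC -> A + C + M`,
  `MC -> M`, `ACMC -> A + M`). Routing the released Mad to the *active*
  pool destroys bistability at `nUK = 10` for every candidate
  inactivation law — the OFF state collapses back to ON — so the
  released Mad re-enters the *inactive* pool and must be re-activated
  through the kinetochore signal. All 2³ per-reaction routing variants
  were checked; the choice shifts the saddle by under 0.1 kinetochores.

## Accuracy of the saddle-node reproduction

With the tabulated constants the wild-type saddle lands at 1.08 unattached
kinetochores, the reduced-association mutant (association rate at 65%,
dissociation rate held fixed so the binding weakens) at 0.39, and the
25% Mad-overexpression mutant at 0.65, against the reference positions of
0.9, 0.3 and 0.4. A sensitivity scan explains the gap: ±20% on `kact`,
`k'` or `ksynX` moves the wild-type saddle across [0.6, >3], so
two-significant-digit constants cannot pin the saddle to ±0.1. The
ordering and monotone shifts across the mutant factor ladders
(88/79/69% association; 105/115/125% Mad) reproduce robustly, and both
interventions widen the distance between the ON and the unstable state
(`checkpointStrength()`), the quantity that suppresses adaptation. The
holding of dissociation fixed (rather than the dissociation constant)
for the APC-A mutant follows from the observed saddle shift: scaling
both rates together leaves the equilibrium unchanged and produces no
shift at all.

## Numerical choices

* Integration: `deSolve::lsoda`/`bdf`, `rtol = atol = 1e-10` for
  trajectories (conservation drift < 1e-6 over 10^4 min), `1e-8` for
  the long settling runs that seed fixed points.
* Fixed points: integrate-then-polish. Long integrations from the
  tabulated ON and OFF states seed a damped Newton iteration in reduced
  coordinates (A and Madi eliminated through the conserved totals; the
  full Jacobian is singular along the moiety directions), to a residual
  below 1e-8 of the characteristic flux. The unstable middle state is
  found by edge tracking: bisect the ON-OFF segment on basin
  membership, flow the bracket along the separatrix toward the saddle,
  re-bisect, and polish. Stability is read off the reduced Jacobian
  spectrum.
* Saddle-node location: bisection on the existence of the ON fixed
  point, bracket 0.01 kinetochores, reported to one decimal. `nUK` is a
  continuous bifurcation parameter here; fractional values mean
  sub-kinetochore signal strength.
* SSA: direct method (exact), no tau-leaping — copy numbers are of
  order 10². Propensities are recomputed per event; the only
  time-dependent propensity (the Mps1-overexpression window) is handled
  by re-drawing at window boundaries, which preserves exactness for
  piecewise-constant rates. The core is compiled (Rcpp) and draws from
  R's RNG, so `set.seed()` reproduces runs bit-identically; ensemble
  run *i* uses `seed0 + i - 1`.
* First passage: the anaphase threshold is 80 molecules of
  APC/C^Cdc20^ (32 nM), tested on `AC` alone after every reaction
  event. Event times are continuous, so crossing and attachment order
  is always well defined.

## Protocols

* **Arrest**: `nUK` fixed (default 10), horizon 700 min, start at the
  tabulated checkpoint-ON state, promoters ON. Adaptation = threshold
  crossing with `nUK > 0`; no crossing by the horizon = arrested.
* **Washout**: first-order attachment (`katt = 0.03`/min, the value
  calibrated against the measured disappearance of Mad2 from
  kinetochores) from t = 0, initial `nUK = 10` (the arrest
  simulations' value; the washout count is not separately constrained),
  horizon 960 min. Crossing after the last attachment = checkpoint
  satisfaction ("exited").
* **Pulse**: from the checkpoint-OFF state at an anaphase
  lack-of-tension signal (default `nUK`-equivalent 10; the reference
  experiments do not state the value, only that tension is absent, so
  any level inside the bistable window reproduces the behavior), Mps1
  synthesis x3 for 60 min. The trajectory switches into the ON basin
  and stays there after the pulse — hysteresis, the model's signature
  of bistability.

The ensemble size defaults to 100 runs, the one size the study states
for its scatter statistics; simulated horizons mirror the experimental
durations. The arrest first-passage ensemble in `scripts/acceptance.R`
extends the horizon to 4000 min so that every trajectory crosses and
the reported maximum is uncensored.

## Single-cell trace rules

The analysis module mirrors the single-cell image-analysis recipe:

* **Mad2 localization index**: maximum over the segmented cell of the
  image filtered with the fixed 3x3 Laplacian-of-Gaussian kernel
  (replicated-edge padding keeps a uniform image at the kernel-sum
  response). A cell counts as localized when the raw index strictly
  exceeds 110% of its own maximal index over the first 20 minutes (G1).
* **Kinetochore signal**: the 5x5-pixel sum around the detected peak on
  the non-deconvolved average projection (deconvolution does not scale
  linearly with total signal); border-clipped windows are renormalized
  by covered area and flagged.
* **Clb2 degradation onset**: Savitzky-Golay smoothing (window 7
  frames, order 2 — the filter is specified, its parameters are not),
  then "starts decreasing and falls" operationalized as a sustained
  drop below 90% of the plateau (the median of the smoothed signal near
  its post-budding maximum) for 2 consecutive frames, with the onset
  reported as the last frame at which the *raw* signal was still at
  plateau level. The raw-signal refinement corrects the 1-2 frame early
  bias that a least-squares smoother's overshoot introduces at a sharp
  falling edge; on noise-free rise-plateau-fall traces the detector is
  frame-exact, and at 2% noise it stays within one 10-min frame in over
  95% of cells.
* **Degradation rate**: log-linear least squares over 4 frames from the
  onset, sign-flipped so decay is positive — the simplest faithful
  reading of an exponential fit. Cells with rate below 0.01/min, or
  degrading less than 50% of the onset-level Clb2 within 90 minutes,
  are "partially degrading"; cells whose signal never falls are
  "arrested".
* **Adaptation call**: among cells that fully degrade Clb2, adapted if
  Mad2 is localized at the degradation-onset frame, exited otherwise.
  Threshold comparisons are strict at boundaries, and the calibration
  uses raw (unsmoothed) index values.
* **Missegregation predictor**: with per-chromosome missegregation
  probability p and n independent chromosomes, the probability of at
  least one missegregation is `1 - (1-p)^n`
  (`missegregationProbability()`).

## The synthetic-data generator

`makeCohort()` emulates what the time-lapse assay records, not the
microscope: 10-min frames, a Clb2 rise after budding to a plateau, an
arrest length drawn as delay + exponential (default 100 min + mean
150 min, the shifted-exponential structure of measured arrest
distributions), an exponential Clb2 fall (0.05/min for full degraders;
0.005/min — below the 0.01 cutoff — for partial ones; none for
arrested), and a Mad2 index that returns to its G1 baseline 30 min
*before* the Clb2 fall in exiting cells and 30 min *after* it in
adapting ones. Noise is additive Gaussian at 2% of the plateau.
Ground-truth labels ride along, so classification accuracy is
measurable: 100% at zero noise by construction, and at least 95% at the
default noise level. What the generator deliberately does not emulate —
segmentation errors, photobleaching, focus drift, cell-to-cell plateau
variability — bounds what passing tests can say about real microscopy:
they validate the decision rules, not the upstream imaging pipeline.

`modelToObservables()` bridges the two worlds: it maps an SSA
trajectory to a synthetic trace (Clb2 plateau until the threshold
crossing, then exponential decay; Mad2 index a saturating function of
the current `nUK`, at baseline when all kinetochores are attached), so
the trace classifier can be validated end-to-end against the
simulation's own outcome labels.

## Known limitations

* The tabulated deterministic column is unusable as tabulated; all nM
  results flow from the molecule column through the volume conversion.
* Saddle positions inherit the tabulated parameters' two-digit precision
  (see above); the wild-type saddle reproduces to ~0.2 kinetochores,
  not ±0.1, and the Mad-overexpression shift is weaker than reported.
* Tension and attachment are one signal; there is no kinetochore
  geometry, re-attachment or error correction.
* The washout adapted fraction is a few percentage points above the
  measured 60.8% — consistent with the slightly right-shifted saddle,
  which weakens the checkpoint's hold near full attachment.
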