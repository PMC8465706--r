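---
title: "Methods: compartmental biokinetics of radioiodinated CLR1404"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental biokinetics of radioiodinated CLR1404}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrkinetics)
```

## The model class and its assumptions

The package models whole-body kinetics of ^124I/^131I-CLR1404 as a
linear, time-invariant compartmental system: each compartment is a
kinetically homogeneous pool exchanging material at first-order rates
k [h⁻¹], and every pool additionally loses activity by radioactive
decay at λ = ln2/T½. In matrix form `dy/dt = M y`, where the diagonal
of `M` collects outgoing rates plus λ and columns sum to exactly −λ:
material leaves the body model only by decay (sink compartments, such
as bladder contents or the spleen pool, simply have no outgoing
edges). The assumptions this buys and their limits:

- *Linearity* — no saturable binding or transporters; reasonable for
  tracer and therapy activities of a phospholipid ether analog, and a
  prerequisite for the closed-form machinery below.
- *Time-invariance* — constant rates over the 0–505 h window; tumor
  growth or physiological change over three weeks is ignored.
- *Well-mixed blood* — organ measurements are modelled as dry-tissue
  pools plus a fraction f_s of the common blood pool
  (`A_s = Σ y_i + f_s y_blood`), so organ VOIs are assumed to sample
  vascular content proportionally.

Because the system is linear with constant coefficients we solve it
exactly by the matrix exponential, `y(t) = e^{Mt} y0`, rather than a
generic ODE stepper, and the cumulated activity (the dosimetric
quantity, in %·h of injected activity) is the closed form
`∫ y dt = −M⁻¹ y0` for any strictly stable `M`. Both are implemented
over an eigendecomposition; if the eigenvector matrix is ill-conditioned
(numerically defective systems), the code falls back to a
scaling-and-squaring series evaluation. A quadrature cross-check of the
closed form is part of the test suite (1e−6 relative on random stable
systems).

## Units, parameters and defaults

| Quantity | Unit | Default | Why |
|---|---|---|---|
| time | h | — | matches acquisition protocols |
| activity | % of injected | bolus = 100% in blood at t = 0 | normalizes subjects |
| rates k | h⁻¹ | fit bounds [1e−8, 1e2] | spans the published values by ≥2 decades each way |
| λ(^131I) | h⁻¹ | ln2/(8.0252 d) | standard nuclide data; configurable (`decay_constant()`), ^124I = 4.176 d |
| blood fractions f_s | fraction | ±30% window around reference | the constraint used when the model was built |
| σ | % activity | 5% of the value; 10% for tumor SPECT; floor 1e−6 | the study's uncertainty model; the floor keeps inverse-variance weights finite at zero activity |

One printed inconsistency is worth knowing: the published best-fit
kidney blood fraction (2.7%) lies *outside* the ±30% window around its
own reference value (2.0% → [1.4, 2.6]%). The window is therefore a
plain argument (`fit_constraints(bf_window = ...)`), and
generate-and-recover experiments should center the window on the
generating truth (`ref_blood_fractions = truth$blood_fractions`),
otherwise the optimum is clipped at the window edge by construction.

## Model construction: decoupling, fitting, selection, pruning

**Forcing function.** `fit_forcing_function()` fits the blood series to
a biexponential with the amplitude sum pinned to the injected 100%
(parameterized as `c·p`, `c·(1−p)` with p ∈ [0, 1]), by weighted
Levenberg–Marquardt. Fitted on decay-included data, the two rates
absorb physical decay.

**Subsystems.** During decoupling the blood state is replaced by two
frozen exponential states (`u1`, `u2`) whose sum is the forcing input;
tissue states keep an explicit −λ term so the decoupled stage is
consistent with the full model on decay-included data. Although the
simplest subsystem equation can be written without decay, fitting
decay-included data without λ would bias the tissue rates, so λ is
always included (a decay-corrected mode exists on the data side).
Candidate structures per organ are the four variants (one compartment,
bidirectional or sink; fast/slow with four rates or slow-sink); for
excretion, the kidney-path scheme with single-edge removals and a
urinary-path scheme with/without return. The urinary-path candidates
retain the kidney fast/slow subsystem off the excretion path so every
excretion candidate is fitted to the same kidneys + bladder data and
AICc values are comparable — comparability across different N is
checked and warned about in `select_structure()`.

**Optimizer.** The annealer uses geometric cooling (factor 0.95),
Gaussian proposals in log-space for rates (linear for fractions),
reflection at the box bounds, restart-from-best at each temperature
level, and an initial temperature set from the interquartile spread of
the objective over a small random probe. Every fit is deterministic
given its seed. Because every objective here is a weighted sum of
squares, each fit ends with a Levenberg–Marquardt refinement
(`minpack.lm::nls.lm`) run from both the annealing incumbent and the
start point; the second start matters when the initial guess is already
good (the pipeline seeds the full fit with the decoupling estimates,
which is also how the model was originally built). A short annealing
schedule plus LM reaches machine-level WRSS on noise-free data; the
annealing stage earns its keep on multimodal cold starts.

**AICc.** `aicc()` reads the logarithm as natural (standard AIC
convention; the base is an argument). The goodness-of-fit reported with
every fit is WRSS/(N−K) with K = free rates + free blood fractions.

**Sobol screening.** The estimator pair is Saltelli sampling with
Jansen estimators for S_i and S_T,i — a low-variance standard choice;
the scalar output defaults to the WRSS against the reference dataset.
Perturbations are zero-mean normal with 10% relative SD, truncated at
zero (at 10% RSD truncation is vanishingly rare but rates must stay
non-negative). Parameters whose total-order index is indistinguishable
from zero (`ST − se < threshold`, default 0.01) are reported as
prunable; pruning an edge and refitting is how the spleen return path
is removed in the original construction. Whether fractions are
perturbed along with rates is up to the caller: the design takes any
named base vector.

**Monte Carlo uncertainty.** Each run resamples every point from
Normal(A, σ) truncated at zero and refits; run r uses seeds
`seed + r` (data) and `seed + 100003 + r` (annealer), so the full table
is bit-reproducible from the master seed. Failed runs are logged and
excluded rather than fatal. The reference protocol is 100 runs; the
test suite uses 3–6.

## Simplified dosimetric estimators

- **SM** — the full structure with slow pools removed everywhere except
  remaining tissues and tumor, refitted as a joint model.
- **BE1/BE2** — per-organ biexponential fits (all points / a four-point
  subset, default [2, 24, 120, 505] h; `best_biexp_subset()` searches
  all subsets exhaustively and scores them on the full series). Rates
  are deliberately left unconstrained: a rising series (bladder-like)
  fits a non-positive rate, and the integral is then reported as
  undefined rather than extrapolated.
- **E t\*** — single-point monoexponential: pure physical decay through
  one measurement. The shipped convention back-extrapolates to t = 0
  with decay only and integrates 0→∞ (`Ã = A* e^{λt*}/λ`), the only
  reading consistent with decay-included data; integrating from t*
  instead is available via `from = "t_star"`.

`compare_cumulated()` tabulates 100·(Ã_simpl − Ã)/Ã per organ, with
undefined entries kept as NA.

## The synthetic data generator

`generate_dataset()` emulates the *statistical structure* of the data
the model was built from, not the data themselves (the original series
were digitized from earlier publications and are not deposited):
PET-like sampling at [2, 5, 24, 48, 72, 120] h and SPECT-like sampling
at [170, 330, 505] h per organ — exact acquisition times are not
published, so these defaults are a plausible reading of the stated
ranges and are fully configurable — plus denser early blood sampling
and a urine (bladder-content) series; multiplicative truncated-normal
noise (lognormal optional) at 5% relative SD, 10% for tumor SPECT;
decay-included activities from a 100% bolus. The xenograft generator
produces 1–4 tumor lines sharing organ kinetics with line-specific
tumor parameters, expressed in %/g through the murine phantom masses
and with no blood/urine series. What it does **not** emulate: PET/SPECT
calibration mismatch beyond the tumor scale factor, reconstruction
artifacts, inter-patient variability, or tumor volume change. Passing
generate-and-recover tests therefore demonstrates correctness of the
estimation machinery under the stated noise model — not that real
clinical data would identify the same structure.

## Numerical choices

- Eigen-solve of `e^{Mt}` vectorized over times; series fallback for
  near-defective matrices (conditioning threshold 1e−13 on the
  eigenvector matrix).
- Predictions are evaluated exactly at observation times — no
  interpolation anywhere in the objective.
- Cumulated activities demand strict stability (all Re(eig) < −1e−14);
  λ = 0 in a closed system raises a divergence error rather than
  returning garbage.
- Structure selection tie-breaks: smaller K, then lexicographic tag —
  deterministic rankings under exact ties.
- The SPECT→PET tumor rescale fits the exponential on log-activities by
  weighted least squares (positivity and stability; the original
  description says only that an exponential was fitted).

## Problem sizes in the shipped tests

The test suite runs the full 17-compartment recovery once (noise-free,
annealing from twice the true rates), the model-recovery study at 50
seeds on a single-organ subsystem, Sobol checks at M = 2000 on analytic
models and M = 256 on the WRSS surface, and Monte Carlo uncertainty at
6 runs across three noise levels on a three-compartment model. These
sizes are the package's choice of a desk-scale demonstration; the
exported functions default to the reference protocol (100 MC runs,
M = 5×10⁴ Sobol samples) when run standalone.

## Known limitations

- The printed parameter table is given to about two significant
  figures; forward computations from it reproduce the published
  cumulated activities to within a few percent, not exactly, and one
  derived quantity (the heart wall's blood-fraction share of Ã) lands
  at ~16% where ~21% is quoted — the share scales with 1/k for the
  heart's fast washout rate, whose printed value carries a 25%
  uncertainty.
- Cold-start full-model fits (30 parameters) are not reliable at desk
  scale; the intended workflow seeds them from decoupling, as the
  pipeline does.
- No structural-identifiability analysis is performed; the package
  asserts numerical recoverability on synthetic data only.
- Absorbed dose (S-value) conversion is out of scope; outputs stop at
  cumulated activities.
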