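---
title: "Perfusion-derived outlet boundary conditions for coronary FFR: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion-derived outlet boundary conditions for coronary FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpffr)
```

This vignette is the package's own account of its science: the model it
implements, the assumptions behind it, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## 1. The physiological model

Fractional flow reserve is the ratio of mean post-stenotic pressure to mean
aortic pressure under maximal hyperemia; FFR ≤ 0.80 defines a
hemodynamically significant lesion. Computing it non-invasively requires
three ingredients: an inlet pressure, a flow model of the epicardial tree,
and — the part this package is about — outlet boundary conditions that say
how much blood each branch actually delivers.

**Inlet.** The mean aortic pressure is estimated from brachial cuff
pressures as `MAP = 0.4 (SBP − DBP) + DBP` (`mean_aortic_pressure()`). The
0.4 weighting is the standard clinical form; MAP is always a convex
combination of the two cuff readings.

**Outlets.** Dynamic CT perfusion measures hyperemic myocardial blood flow
per voxel. Assigning every LV-myocardium voxel to its nearest coronary
outlet (unweighted Euclidean distance between the voxel center and the
outlet's terminal centerline point — `assign_territories()`) partitions the
myocardium into perfusion territories. The flow a territory receives is the
perfusion integral `Q_i = Σ Vol_n · MBF_n` (`outlet_flow()`), and the
microvascular bed downstream of outlet *i* is collapsed to the single
resistance that would carry that flow under the full arteriovenous
gradient, `R_i = (MAP − P_v)/Q_i` (`outlet_resistance()`), with venous
pressure fixed at 5 mmHg. The model's central physiological assumption is
that the perfusion map and the FFR measurement describe the *same*
hyperemic state, so the measured flow deficit already encodes the lesion's
effect.

**K1 correction.** Volume-perfusion-CT software underestimates hyperemic
MBF because first-pass tracer extraction is incomplete; the reported value
behaves like the transfer constant K1. The Renkin–Crone relation
`K1 = (1 − a e^{−b/MBF}) MBF` with `a = 0.904`, `b = 1.203` mL·min⁻¹·g⁻¹
links the two. It is strictly increasing (derivative bounded below by
`1 − a = 0.096`), so `mbf_from_k1()` inverts it by bracketed root-finding
on `[K1, K1/0.096]`. Per-gram/per-mL conversion uses a tissue density of
1.05 g·mL⁻¹ and happens only at this boundary; the flow integral consumes
per-mL values. Because the synthetic generator emits true MBF maps, the
pipeline applies no correction by default; `map_kind = "k1"` switches the
inversion on for K1-like inputs, and `map_mbf_to_k1()` produces such inputs
for round-trip checks.

## 2. The reduced-order solver

The reference workflow solves 3D Navier–Stokes on a segmented lumen; this
package deliberately replaces that stage with a 0D/1D nonlinear resistor
network, preserving the boundary conditions — which are the model's actual
substance — while making every experiment run on a desk. This is the
package's central modelling reduction and is visible in the API
(`build_vessel_graph()`, `solve_network()`), not hidden behind it.

Each segment carries `ΔP(Q) = a Q + b Q |Q|`:

* `a` is Poiseuille resistance `8μ/π ∫ ds / r(s)⁴` through the local radius
  profile — a linear taper, overridden by a constant throat radius
  `(1 − severity/100) · r_ref` across the stenosis extent (top-hat
  narrowing). The integral has a closed form on each piece, so `a` is exact
  for any discretization.
* `b` is the empirical expansion loss `(K_t ρ/2)(1/A_throat − 1/A_ref)²`
  with `K_t = 1.52`, charged where flow exits the throat. Only stenotic
  segments have `b > 0`.

Blood is Newtonian with μ = 0.0035 Pa·s and ρ = 1050 kg·m⁻³; walls are
rigid; flow is steady. Clinical units (mmHg, mL/min) are used throughout
the boundary-condition layer; SI conversion happens once inside the
coefficient computation.

`solve_network()` pins the inlet at MAP, closes each outlet through its
`R_i` to `P_v`, and drives the nodal mass-conservation residual to zero by
damped Newton iteration on nodal pressures. Numerical specifics, each of
which was a real choice:

* **Jacobian.** The weighted network Laplacian with linearized edge
  conductances `1/(a + 2b|Q|)` — symmetric positive definite after
  grounding the inlet, so direct dense solves are safe at these sizes
  (tens to a few hundred nodes).
* **Damping.** Under-relaxation 0.7 on early steps guards against
  overshoot from the quadratic loss; full steps are restored once the
  residual is within 10³ of tolerance so the endgame is quadratic. Steps
  that increase the residual are halved (at most ~13 times).
* **Tolerance.** The user-facing tolerance is 10⁻⁸ mmHg; it is converted
  to a flow-imbalance tolerance through the total outlet conductance. On
  finely subdivided networks the nodal imbalance bottoms out at the
  floating-point floor slightly above that threshold; the solver accepts a
  stalled iterate only if the imbalance is below 10⁻⁹ of the flows being
  balanced, which keeps the advertised mass-conservation property intact.
* **Lossless edges.** Edges with `a = b = 0` would make the Jacobian
  singular at machine precision, so they are contracted (union-find): both
  endpoints share one pressure unknown, and their flows are recovered
  afterwards from downstream demand. This makes the zero-loss limit
  (`FFR ≡ 1`, all pressures = MAP) exact rather than approximate.
* **Discretization.** Segments may be subdivided at a regular arc-length
  step (1 mm for the ground-truth solve), always split at stenosis
  boundaries. Because coefficients are integrated in closed form,
  refinement changes where pressures are tabulated, not their values; the
  refinement-stability test documents this.
* **Flow direction** is root-to-leaves; retrograde flow is not modelled.

**Readout.** `ffr_at()` evaluates `P/MAP` at a point 20 mm distal to the
stenosis exit along the vessel's root-to-outlet path — the invasive
pressure-wire convention. The offset is a parameter; if the vessel ends
sooner, the most distal point is used and flagged. For vessels with serial
lesions the most distal lesion anchors the readout, as a wire pull-back
would capture both.

## 3. The synthetic cohort: what it emulates

`simulate_cohort()` generates the study conditions the evaluation needs:

* **Trees** (`generate_tree()`): a left-main/LAD/LCX skeleton with two
  diagonals and an obtuse marginal, wrapped around the LV; radii satisfy
  Murray's law `r_p³ = Σ r_c³` exactly at every bifurcation (root caliber
  2 mm, log-normally jittered per patient); lengths and node positions are
  jittered. Per patient, one or (with probability 10/93) two evaluable
  vessels receive a primary stenosis, placed proximal/middle/distal with
  probabilities 0.57/0.37/0.06; a second mild serial lesion appears with
  probability 0.25. The LAD carries ~82% of lesions. These frequencies are
  the observed clinical mix for this kind of cohort.
* **LV mask**: a half spherical shell (inner 25 mm, outer 35 mm, ~57 mL),
  LAD/LCX side only — right-coronary myocardium is deliberately absent,
  matching the method's exclusion of the thin right-ventricular wall. Voxel
  spacing defaults to the CT protocol's 0.625 × 0.625 × 1.25 mm.
* **Hemodynamics**: SBP ~ N(128, 14), DBP ~ N(77, 9) mmHg; remote
  hyperemic MBF ~ N(1.5, 0.2) mL·min⁻¹·mL⁻¹ per patient. The MBF magnitude
  is a synthetic choice (volume-perfusion CT underreads PET-scale values);
  no claim is made that it reproduces any particular scanner's scale, and
  the model is scale-invariant in the sense that doubling all MBF halves
  all resistances.
* **Ischemia coupling**: a territory's MBF is
  `mbf_normal_mean · g(FFR)` with `g(F) = 1` above 0.80 and `F/0.8` below —
  the simplest monotone coupling consistent with ischemia reducing
  hyperemic flow (`ffr_flow_coupling()`).
* **Noise**: per-voxel MBF noise (SD 0.15 mL·min⁻¹·mL⁻¹, truncated at 0)
  and invasive-wire measurement noise (SD 0.04 FFR units, representing
  wire drift plus biological state variability; it yields
  limits of agreement near ±0.09 and Pearson r near 0.9, the magnitudes
  clinical repeatability studies report).

**Ground truth as a fixed point.** The generative model must be
self-consistent: the map the analysis stage sees has to imply the same
outlet resistances that produced the ground-truth FFR, otherwise
"parameter recovery" is ill-posed no matter how good the solver is. The
generator therefore solves, per patient, the fixed point

    R_i = (MAP − P_v) / (V_i · m · g_i),   g_i = g(P_i / MAP),

iterating (damped by 0.5, to 10⁻¹¹) between outlet resistances and outlet
pressure ratios. Ground-truth invasive FFR is read from the fine
(1 mm-subdivided) solve of that state; the map is filled with
`m · g_i` per territory. On a noise-free cohort the analysis pipeline then
recovers invasive FFR to machine precision — the recovery test measures the
pipeline's internal consistency, voxelization included, not a hidden
re-use of the answer: territories, flows and resistances are recomputed
from the voxel map alone.

**Prevalence by construction.** Stenosis severity is not drawn directly.
Each evaluable vessel draws a target invasive FFR from band weights
matching the intended prevalence (46% positive; positives split 22:25
between ≤ 0.70 and 0.70–0.80, negatives 44:12 between 0.80–0.90 and
> 0.90), and the primary severity is found by monotone root-finding of the
solved FFR in severity, clamped to the QCA inclusion window [30, 90]%.
Clamping means extreme targets land at the window edge with a slightly
different realized FFR — prevalence is preserved because a 30% lesion is
never ischemic and a 90% lesion always is at these flows.

**What it does not emulate.** Scanner noise and beam hardening, motion,
partial-volume effects, segmentation error in the tree, microvascular
disease (the coupling g is the only ischemia mechanism), collateral flow,
and right-coronary territories. Passing tests on this cohort therefore
demonstrate the pipeline's correctness and internal consistency, not its
clinical accuracy on real images.

## 4. The evaluation module

All analyses are per-vessel at the 0.80/0.80 thresholds (a value exactly at
0.80 is positive); per-patient worst-vessel aggregation
(`aggregate_per_patient()`) is provided but secondary.

* **Confidence intervals** are Clopper–Pearson exact binomial
  (`stats::binom.test`) for all five confusion metrics. Published tables of
  this kind match exact intervals for sensitivity/specificity/accuracy;
  predictive values are sometimes reported with logit-based intervals
  instead, which will differ slightly from the exact ones here at the same
  counts.
* **ROC/AUC** uses the Mann–Whitney statistic with half credit for ties
  via pROC, oriented so that *lower* index values indicate disease —
  essential for FFR-like scores, and fixed explicitly rather than
  auto-detected. DeLong structural-component variance and the paired
  DeLong test come from the same machinery; identical score vectors return
  z = 0, p = 1 directly, since the variance of the difference is legitimately
  zero there.
* **McNemar** defaults to the exact two-sided binomial below 25 discordant
  pairs and the continuity-corrected χ² above — the branching the common
  clinical statistics packages apply. Both branches are conservative: the
  discordant count is discrete, so the true type-I error at α = 0.05 sits
  near 0.02–0.03 for realistic designs. Where calibration matters more
  than convention, `midp = TRUE` gives the mid-p exact test, whose level
  is close to nominal; a property test demonstrates both behaviours.
* **Gray zone**: vessels with invasive FFR in [0.75, 0.80] are flagged in
  `vessel_records()`, since classification there is least certain.
* **Stratification** schemes: QCA bands (30–49, 50–69, ≥ 70%), calcium
  class (Agatston < 400 / ≥ 400), vessel (LAD/LCX), lesion location, and
  invasive-FFR bands (≤ 0.70, 0.70–0.80, 0.80–0.90, > 0.90). Partitions
  are checked to be exhaustive; pooled counts equal summed per-stratum
  counts by construction.

## 5. Problem sizes and reproducibility

The test suite and the acceptance script size their simulations for
desk-scale runs as the package's own study conditions: pipeline-level tests
use a reduced LV (12–18 mm shell at 1.25 × 1.25 × 2.5 mm spacing, ~8 mL)
where voxel resolution is not the property under test; full-resolution
grids (~117,000 masked voxels) are used for the map statistics and the
recovery analysis. Parameter recovery runs 50 noise-free patients; the
type-I-error calibrations run 500 permutation replicates at n = 60; the
DeLong-vs-bootstrap variance check uses 1,000 resamples at n = 100.

All randomness flows from one integer seed through a multiplicative
congruential splitter (`derive_seed()`): per patient, per stage, no shared
streams, no global state. Identical config + seed reproduce byte-identical
trees, maps, CSVs and manifest hashes; `run_pipeline()` writes MD5
checksums of its text outputs and `verify_manifest()` re-checks them, so a
tampered or truncated stage output is caught.

## 6. Known limitations

* The reduced-order solver shares loss-model assumptions (top-hat throat,
  single empirical `K_t`) across all lesions; real lesions have eccentric,
  irregular lumens whose losses a 3D solve would resolve.
* The severity-to-FFR relationship is steeper than clinical experience at
  mild severities (a 50% lesion is nearly lossless at these flows); the
  severity calibration absorbs this for cohort construction, but QCA
  distributions in synthetic cohorts skew high relative to clinical ones.
* Territory assignment uses outlet points, not whole centerlines; for
  long parallel vessels a centerline-distance Voronoi would shift boundary
  voxels. Outlets are the entities that receive flow, which is why the
  point version was chosen.
* Fixed venous pressure (5 mmHg) and a single cuff-pressure pair per
  patient; no autoregulation, no rest-state model, no coronary flow
  reserve.
* The combination of multiple index tests (`combine_tests()`, logical
  any/all rules) is provided as a configurable utility but no claim is
  made that it reproduces any published combined-test column, whose
  combination rule is not public.
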