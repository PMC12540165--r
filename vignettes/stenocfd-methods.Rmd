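---
title: "Methods: desk-scale CFD assessment of intracranial stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale CFD assessment of intracranial stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracranial atherosclerotic stenosis (ICAS) is graded morphologically —
percent diameter stenosis (DS%), percent area stenosis (AS%), reference
diameters, minimal lumen diameter (MLD), lesion length — but its
*functional* severity is better captured by hemodynamic quantities derived
from computational fluid dynamics: the translesional pressure ratio
(PR = P_distal / P_proximal, the cerebrovascular analogue of coronary FFR),
the wall shear stress ratio (WSSR = mean throat WSS / mean proximal
reference WSS), and the luminal area exposed to WSS above 3.0 Pa. Clinical
pipelines build these from segmented DSA or CTA lumens with inlet flows
measured by the TIMI frame-count method (on DSA, at 6 frames/s) or by
transcranial Doppler (for CTA), plus a hybrid "CMD" model that drives the
CTA geometry with the DSA-derived flow. `stenocfd` implements this whole
chain at desk scale, driven by a synthetic lesion cohort, so that the
modality-agreement analysis (Bland-Altman, ICC) can be exercised and tested
end to end without patient images.

## Geometry model

Patient lumens are replaced by axisymmetric surfaces of revolution. This is
the one structural simplification everything else builds on: it preserves
every quantity the pipeline defines (area-averaged pressures along the
axis, WSS along the wall, luminal areas) while admitting analytic oracles
(Hagen-Poiseuille, lubrication theory) that pin down solver accuracy.
Bifurcations and eccentric plaque are deliberately out of scope; side
branches are not modelled, and the Murray cube-law split
(`murray_outlet_split`, fraction_i = d_i^3 / sum d_j^3) is exposed as a
standalone flow-allocation computation.

Lesions are smooth cosine (Young–Tsai style) constrictions

R(x) = R_base(x) − δ·(1 + cos(2π(x − x_c)/L_s))/2

inside the lesion window, with R_base tapering linearly from the proximal
to the distal reference radius across the window and constant outside it,
and δ solved (by `uniroot`) so the minimum diameter equals the requested
MLD. The shape is a modelling choice — clinical reports do not state lesion
shape — and it makes the threshold-based lesion-length measurement exactly
de-biasable (below). Straight parent segments of 10 proximal diameters are
retained on both sides so that measurement planes sit in developed flow;
the entrance length at the cohort's Reynolds numbers (~0.05·Re·D, up to
~20 mm) fits inside this extension.

Inter-modality segmentation differences (DSA resolution ~0.37 mm vs CTA
~0.49 mm) are emulated by `perturb_modality`: seeded Gaussian radial noise,
optionally smoothed by a moving average over a window of k samples, which
attenuates the per-sample SD by 1/sqrt(k) (returned as the `attenuation`
attribute). The magnitude of real segmentation error is not published;
the defaults (SD 0.05 mm, 1 mm smoothing window) are order-of-magnitude
choices exposed in the configuration, not measured values.

## Morphometry

`measure_morphology` computes the six anatomical parameters from a radius
profile. DS% uses the proximal-reference (WASID-style) convention,
DS% = (1 − MLD/D_prox)·100, with the distal reference reported separately;
AS% is the circular-lumen square of the same ratio. Lesion edges are
detected where the diameter recovers to within `lesion_threshold` (default
5%) of the local plateau on each side of the MLD — plateau-relative
detection is robust to tapered parent vessels, where a single global base
line is not. Reference diameters are means over a window (default 2
proximal diameters) just outside the detected edges.

A smooth constriction crosses any finite threshold strictly inside its true
extent, so the raw threshold extent systematically underestimates the
generating lesion length (by ~18% at the default threshold for a typical
lesion). The reported `stenosis_length` is therefore the window length of a
least-squares fit of the cosine lesion model (linear base taper across the
window minus a cosine bump, plateaus outside) to the profile around the
detected constriction — exact for the package's generator, and a stated
model-based convention for arbitrary profiles. The raw crossing extent is
also returned (`threshold_extent`).

## Flow model and solver

Blood is an incompressible Newtonian fluid (ρ = 1060 kg/m³,
μ = 0.0035 Pa·s) in steady laminar flow through a rigid, no-slip lumen —
pulsatility, wall compliance and collateral flow are outside the model.
The solver (`solve_steady`) is a finite-volume SIMPLE scheme written for
this package: colocated body-fitted structured grid over the (x, r)
half-plane with all face areas and cell volumes carrying the axisymmetric
r-weighting, Rhie–Chow mass fluxes, first-order upwind convection
implicitly with a deferred second-order-upwind correction (active after the
first 50 outer iterations; convergence is only declared with it active),
over-relaxed diffusion with explicit non-orthogonal correction, and
weighted least-squares gradients. Boundary conditions: uniform plug
velocity inlet matching the case flow rate, symmetry axis (zero-area faces,
natural), no-slip wall, and a zero-gauge-pressure outlet with zero-gradient
velocity rescaled every outer iteration for exact global mass conservation.
The pressure-correction equation is solved by Jacobi-preconditioned
conjugate gradients; under-relaxation defaults are 0.7 (momentum) and 0.3
(pressure). The laminar model is refused at inlet Reynolds numbers ≥ 2000.

Residuals are L1 imbalance norms normalized by their value at outer
iteration 10 (the norm is a documented package convention — "normalized
residuals" alone does not fix one); convergence requires continuity and
both momentum residuals below 1e-5. Station-wise mass fluxes are reported
from the corrected face-flux field, which satisfies per-cell continuity to
linear-solver accuracy, so conservation holds to well below 1e-6 relative
on every converged case. The solver is deterministic: identical inputs
give bit-identical fields.

Meshes (`build_mesh`) start at 120×10 cells (axial×radial) at level 0 and
scale by 1.5× per level in each direction; radial lines follow the
spline-interpolated radius profile and are clustered toward the wall by a
smooth tanh map (near-wall spacing below half the uniform spacing),
standing in for near-wall prism layers. Wall shear stress is extracted with
a one-sided second-order difference along the wall normal. On a straight
tube the observed convergence order of the developed-region pressure drop
across levels 0–3 is ≈ 2, and level-1 solutions are within 2% of the
Hagen–Poiseuille pressure drop and WSS; on gentle stenoses at creeping flow
the total drop matches the lubrication integral ∫8μQ/(πR⁴)dx within 5%.

Mesh independence is assessed as in practice: `mesh_independence_study`
monitors PR across refinement levels and accepts the first level whose PR
changes by less than 2% (relative) against the next finer level. On the
representative 62% DS model the change between successive levels is well
below 1%.

## Hemodynamic metrics

Gauge CFD pressures only fix pressure *differences*; PR needs positive
absolute pressures. The field is shifted so the inlet-station mean equals a
configurable physiological reference (default 13332 Pa = 100 mmHg) — a
package decision, stated prominently because the ratio depends on it. The
synthetic cohort generator keeps drawn flows inside the envelope where the
translesional drop stays below ~60% of this reference (resampling the
velocity draw, with a cap), mirroring the physiological fact that flow
through a severe stenosis is limited by the available perfusion pressure.

Plane placement (all configurable, `default_planes`): proximal plane one
proximal diameter upstream of the lesion window with the one-diameter-wide
proximal reference window centred there; distal plane three diameters
downstream (past reattachment at desk-scale Reynolds numbers); throat
window the central third of the lesion window. The high-WSS area integrates
2πR(s)·[WSS > 3 Pa] over the whole wall by default (a window argument
restricts it); with plug inlets the entrance region and the re-developing
jet downstream of the throat both contribute, so desk-scale areas are not
comparable in magnitude to patient 3D values — only their modality
agreement and severity trends are meaningful here.

## Agreement statistics

The battery mirrors standard modality-comparison practice: a Shapiro–Wilk
gate (alpha 0.05, configurable) routes paired comparisons to a paired t or
a Wilcoxon signed-rank test (zeros dropped, exact enumeration for small
untied samples, normal approximation with continuity correction otherwise);
Kruskal–Wallis compares the three territories; Bland–Altman reports bias
± 1.96·SD limits of agreement; and ICC(2,1) — single-measure,
absolute-agreement, two-way random effects — quantifies agreement, with the
F-based McGraw–Wong confidence interval. Single- rather than
average-measures ICC is the deliberate choice: each modality contributes
one measurement per lesion. Shapiro–Wilk, t, Wilcoxon and Kruskal–Wallis
call the standard R implementations; ICC and Bland–Altman are implemented
here and verified against brute-force ANOVA sums and sign-flip enumeration
in the test suite. Summaries are formatted mean (SD) for normal samples and
median [Q1, Q3] otherwise.

## The synthetic cohort

`cohort_config` defines the study conditions. Defaults: 40 lesions split
31/6/3 across MCA/ICA/VA; per-territory proximal and distal reference
diameters anchored to published ICAS cohort morphology (MCA 2.19 ± 0.48 mm
proximal, ICA 3.26 ± 0.87, VA 3.95 ± 0.89; distal 2.00 ± 0.55, 2.78 ± 0.74,
3.46 ± 0.49); DS% 58.95 ± 19.84 truncated to 10–85% (the generator's stated
validity envelope for the steady laminar solver); lesion length
4.28 ± 2.18 mm truncated to 1.5–12 mm. Inlet mean velocities (MCA 34 ± 15,
ICA 28 ± 10, VA 11 ± 4 cm/s) were derived once from the published
per-territory flow rates and proximal diameters (v = Q/A) so the synthetic
flows land in the reported ranges. The distal diameter draw is additionally
bounded to 0.55–1.10 of the proximal draw — independent draws occasionally
produce anatomically impossible tapers. Severity, lesion length and
velocity are drawn jointly: a lesion is accepted only if some velocity in
its truncation range keeps the estimated translesional drop (lubrication
integral plus a Borda–Carnot expansion loss, with headroom for the
configured noise) below ~60% of the perfusion reference. All truncations
resample with a cap of 100 attempts.

Per case, the true lumen is perturbed independently per modality, the DSA
inlet comes from a TIMI frame count computed from the (noise-perturbed)
true velocity and a contrast path length of 80% of the vessel span, the CTA
inlet from a TCD velocity with independent noise of the same CV (default
0.10 — measurement-error magnitudes are not published; these are exposed
guesses), and the CMD case reuses the CTA geometry and outlet with the DSA
flow. With all noise at zero the three cases coincide, and the pipeline
reproduces the perfect-agreement limits (ICC = 1, zero bias, degenerate
p = 1) — a structural identity the tests assert.

What the generator does *not* emulate: real segmentation artefacts
(calcium blooming, partial-volume effects are not Gaussian radial noise),
bifurcation flow, pulsatility, collateral supply, and any correlation
between severity and measured velocity beyond the perfusion-pressure
envelope. Passing tests therefore validate the pipeline's internal
consistency and its numerics, not clinical accuracy on patient images.

## Problem sizes and runtimes

The test suite and the acceptance script run everything at desk scale: the
representative lesion study uses refinement levels 0–3 (up to ~405×34
cells), cohort runs use level 1 (~180×15 cells) with 2–10 cases, and the
statistical Monte-Carlo checks use 10^4 replicates. A full
`sample_cohort`/`run_cohort` pass over the default 40-lesion cohort at
level 1 takes on the order of a few minutes on one core; identical
(geometry, flow) pairs — e.g. every zero-noise modality triple — are
memoised, which is exact because the solver is deterministic.

## Known limitations

Axisymmetry excludes every secondary-flow phenomenon; plug inlets create an
entrance singularity at the inlet wall corner (the measurement conventions
keep planes away from it); the steady model cannot represent pulsatile WSS
metrics; WSSR is a ratio of means and inherits the sensitivity of its
denominator to the proximal window placement; and the high-WSS area's
whole-wall convention makes its absolute magnitude convention-dependent.
PR depends explicitly on the absolute-pressure reference; comparisons
across packages must match that convention.
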