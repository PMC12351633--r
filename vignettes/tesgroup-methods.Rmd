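---
title: "Methods: group-level tES dose optimization in tesgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level tES dose optimization in tesgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesgroup)
```

## The planning problem

Transcranial electrical stimulation injects weak currents (a few mA)
through scalp electrodes; its physiological effect is governed by the
induced electric field in the cortex, and in particular by the component
along the cortical surface normal, En. We follow the standard excitability
convention: node normals point outward from the surface and positive En
means the field points *into* the cortex, the direction that depolarizes
pyramidal somas. Dose planning chooses electrode positions and currents so
that the induced En matches a target map — a desired En level on a target
region and zero elsewhere.

A precomputed lead-field matrix `K` makes the physics linear: each column
holds the cortical En (V/m) for +1 mA at one electrode with a fixed
reference (Cz) returning −1 mA. Any montage is a current vector `I` (mA,
reference excluded; the reference current is implicitly −ΣI) and induces
`K I`.

## Fitness: NERNI, its group form, and ⟨En⟩

With per-node weights `w` and target `t`:

$$\mathrm{NERNI}(I) \;=\;
\frac{\lVert w \odot t\rVert^2 - \lVert w\odot(KI) - w\odot t\rVert^2}
     {\lVert w \odot t\rVert^2}$$

This is 1 exactly when the induced field equals the target on every
positively weighted node, 0 at `I = 0` ("relative to no intervention"),
and unbounded below. It is a concave quadratic in `I`, which the optimizer
exploits. Weights sit inside the squared norm, so the default 10 (target)
vs 2 (off-target) weighting acts with an effective 25× ratio; this is
deliberate — with uniform weights the much larger off-target area would
dominate and montages would underdose the target. The group objective is
the arithmetic mean of per-subject NERNIs; since each subject contributes
a quadratic form, the group objective collapses to a single
`electrodes × electrodes` quadratic computed once per cohort, after which
every candidate subset is evaluated at negligible cost.

A montage with an excellent NERNI could in principle score well mostly by
avoiding off-target field, so the area-weighted mean En over the target
region (node areas from the one-third triangle rule) is reported
alongside as an intensity check. Across protocols, NERNI versus ⟨En⟩
follows an inverted-U: too little field underdoses, too much spreads
off-target; `nerni_vs_mean_en_fit()` quantifies this with an OLS quadratic.

## The inner current solve

For a fixed electrode subset the problem is: maximize the (group) NERNI
subject to

* |I_e| ≤ 2 mA for every electrode, the implicit reference included;
* total injected (anodal) current ≤ 4 mA, summed over all positive
  currents including the reference when it is anodal;
* balance: the reference returns −ΣI by construction.

The anodal-sum constraint is piecewise linear (it involves positive
parts). We solve the concave QP exactly in two stages: a split-variable
formulation (`I = p − m`, `p, m ≥ 0`, plus a slack bounding the positive
reference current) with a ridge of relative size 1e−9 linearizes the
constraint exactly and identifies the optimal sign orthant; an exact
dual active-set QP restricted to that orthant's closure — which contains
the global optimum — then delivers the solution to solver precision. Unit
tests verify agreement with exhaustive 0.001-mA grid search to better
than 1e−4 in NERNI.

Two accounting rules resolve ambiguities about the implicit reference: it
is bounded and budgeted like any physical electrode (safety limits are
physical), and it counts toward the 8-electrode cap whenever its current
exceeds `current_tolerance` (1e−6 mA). Consequently, when a candidate
subset already uses the full cap, the solve adds the equality ΣI = 0 so
the reference stays inactive; smaller subsets leave the reference free.
Both limits are configuration fields, not constants.

## The outer subset search

A genetic algorithm searches electrode subsets: binary masks over the
candidate labels repaired to exactly `min(max_electrodes, n_candidates)`
active genes; tournament selection (size 3), uniform crossover (p = 0.5),
per-gene mutation (p = 2/n_candidates), elitism of one, and termination
when the best objective improves by less than 1e−6 for five consecutive
generations. Inner solves are memoized by subset, and ties between
equal-objective subsets break toward the lexicographically smallest label
set, so a fixed seed reproduces results exactly. The production default
population is 3000; desk-scale studies and the test suite use 50–200,
which exhaust small search spaces (the suite verifies the GA attains the
exhaustive C(20,3) optimum in ≥95% of seeded runs).

### How close is 8 electrodes to unlimited?

On the synthetic cohort, the 8-electrode GA objective reaches roughly
97–99% of the unconstrained-cardinality solve on all 39 candidate
positions (the acceptance script reports the per-cohort minimum). We
verified with intensive searches (population 2000, longer stall patience,
multiple seeds) that this is a property of the constrained *optimum*, not
of the search: in this head model the cap itself costs ~1–3%. The
concentric-sphere model with point electrodes produces smoother, more
broadly useful lead-fields than real-head FEM with 1-cm gel pads, so the
unlimited solution profitably spreads current over more positions and an
8-electrode montage concedes more. An alternative accounting (7 candidates
plus an active reference) scores clearly worse (about 96.7% of the
unlimited objective, versus 98.4% for the balanced 8-subset optimum, in
the probe cohort), so the balanced-8 search space is not the limiting
choice. On
realistic head models the published experience is a tighter (~99%)
calibration; users transferring this check to other forward models should
measure rather than assume the ratio.

## The synthetic cohort

The generator stands in for an MRI-derived cohort with a classical
4-shell concentric-sphere conductor:

| shell | outer radius (mm) | conductivity (S/m) |
|-------|------------------:|-------------------:|
| brain (GM+WM merged) | 78 | 0.40 |
| CSF   | 80 | 1.79 |
| skull | 86 | 0.008 |
| scalp | 92 | 0.33 |

Conductivities are the standard head-modelling values; the brain shell
uses the gray-matter value because the forward solve merges GM and WM
(a 5-layer series buys little accuracy for this purpose), while the
tissue-volume features keep distinct GM/WM labels via a WM core of 60 mm
in the feature mesh. The forward solution is the classical Legendre
series for a surface point source in an N-layer sphere, evaluated as the
radial potential derivative at the cortical sphere (the brain shell's
outer surface) and superposed for the electrode/reference pair. The
series is truncated at degree 200 with an estimated relative tail below
1e−8; the layer recursion uses a closed-form well-scaled update so that
high degrees do not overflow. Correctness checks: exact agreement with
the homogeneous-sphere closed form, zero net flux of En through the
closed cortical surface (no enclosed sources), rotational equivariance,
and sign/superposition/reciprocity identities.

Electrodes are 39 idealized 10-10 positions (standard arc construction on
the sphere, spherical interpolation for intermediate rows) with Cz the
fixed reference. The target is a circular cortical patch of angular
radius 0.35 rad centred under F3 — a left-prefrontal stand-in — with
target En 0.25 V/m, weight 10, and weight 2 elsewhere. The patch is a
deliberate geometric simplification; no anatomical equivalence to a real
cortical target is claimed.

Inter-subject variability multiplies every shell radius by an independent
mean-one lognormal factor whose relative standard deviation is
`radius_jitter` (default 0.02, a realistic few-percent head-size spread
that keeps shell crossings — which are resampled — infrequent given the
2-mm brain–CSF gap). Setting `conductivity_jitter > 0` instead (or in
addition) perturbs tissue conductivities the same way, which reproduces a
database-augmentation design: repeated models of a subject that differ
only in their lead-field, never in geometry.

What the generator does *not* emulate: gyrification and sulcal normals,
electrode pads and gel, skull inhomogeneity/anisotropy, ventricles, and
irregular target shapes. Tests passing on this cohort validate the
algorithms and their contracts — not field accuracy on real heads.

## Anatomical features and regressions

Three MRI-free scalp measurements are computed as geodesic chains on the
triangulated scalp: axial perimeter (Nz→LPA→Iz→RPA), sagittal perimeter
(Nz→Cz→Iz) and coronal distance (LPA→Cz→RPA). Geodesics run Dijkstra on a
Steiner-augmented surface graph (5 extra points per mesh edge, all points
sharing a triangle connected), which benchmarks within 0.5% of
great-circle arcs on spheres at the default density — the accuracy
contract; scaling the coordinates scales every distance exactly. Tissue
volumes integrate |det|/6 over a labelled tetrahedral shell mesh.
Normalized variants divide each distance by the sum of the three and each
volume by the total volume.

Outcome-on-anatomy regressions use feature *differences* (template minus
evaluated subject, antisymmetric by construction). Order 1 is the linear
design; order 2 adds, for every feature pair, the full quintuple
(f1, f2, f1·f2, f1², f2²) — the complete degree-2 expansion. Because
expanded designs are collinear, an optional PCA path z-scores the
features (mixed units: mm vs mm³) and regresses on leading principal
components, either a fixed count or the count minimizing leave-one-out
cross-validated prediction error. Reported significance is the overall
F-test of the model. Leave-one-subject-out prediction removes all rows of
one subject, refits, predicts, and reports prediction R² defined as
1 − SS_res/SS_tot over held-out predictions (negative when prediction is
worse than the mean; by construction it cannot systematically beat the
in-sample R², which the suite checks distributionally). When responses
are aggregated, the default is one row per template subject: the mean
outcome its montage produces in the others against its mean feature
differences.

## Transfer evaluation and statistics

Four protocol kinds are compared: personalized (optimized on and
evaluated in the same subject), group-LOO (for every subject, the group
objective optimized on the remaining cohort and evaluated on the held-out
subject, each run an independent search), template (optimized on a
designated unjittered base head excluded from the cohort — the synthetic
stand-in for standard template heads), and non-personalized individual
(one cohort member's personalized montage evaluated in everyone else).
Paired comparisons honour the repeated-measures design: pairwise paired
t-tests with Bonferroni correction over the number of pairs (degenerate
zero-variance differences are mapped to t = 0, p = 1 for identical
conditions); the nonparametric track is Kruskal–Wallis followed by Dunn's
post-hoc z-tests from joint mid-ranks with the standard tie correction
and Bonferroni adjustment. On the synthetic cohort the suite asserts the
qualitative ordering — personalized ≥ group-LOO per subject, and mean
group-LOO above every template/individual-derived protocol — not any
cohort-specific value, which would require the real head models. Note the
synthetic template is the *population-mean* head, so it transfers better
than a demographically mismatched real template would; the margin between
group-LOO and template is accordingly small here.

## Numerical choices and degenerate inputs

* Surfaces reject zero-area triangles (< 1e−12 mm²) at construction;
  triangle windings are made globally consistent by breadth-first
  propagation (non-orientable surfaces are an error) and flipped outward.
* Node normals are the area-weighted average of incident triangle
  normals. On irregular vertex fans this classical rule is first-order
  accurate: on an icosphere the worst-node deviation from radial is about
  1.2e−2 rad at subdivision 3 and halves per level — adequate for En
  projection, and tested as a convergence property rather than a fixed
  small tolerance.
* Node areas use the one-third triangle rule, so they sum exactly to the
  surface area.
* The QP adds a relative 1e−10 ridge only if the objective is numerically
  semidefinite (e.g. near-duplicate lead-field columns); solutions are
  validated against the constraint suite before being returned.
* Currents below 1e−6 mA count as inactive but are not rounded away, so
  balance identities hold to solver precision.
* Seeds: every stochastic component (cohort draws, GA) consumes an
  explicit integer seed, and generators save/restore the caller's RNG
  state.

## Problem sizes in the test suite

The suite runs the study conditions at desk scale, chosen as the
package's own defaults for development hardware: cortical meshes at
icosphere subdivision 2 (162 nodes) for optimizer-heavy checks and 3
(642 nodes) where geometric or field accuracy is asserted; cohorts of
4–20 subjects; GA populations of 40–200 (personalized runs in the
ordering check use 200 with longer stall patience so that per-subject
dominance reflects the optimum rather than search noise). The acceptance
script uses the default subdivision-3 cohort with population 100.

## Known limitations

* The spherical cohort validates algorithms, not field magnitudes on real
  anatomy; absolute En values are model-specific.
* The 8-electrode-cap-vs-unlimited ratio is model-dependent (see above).
* Dunn's test uses the large-sample normal approximation; very small
  cohorts should rely on the paired track.
* Per-subject significance of protocol differences requires
  within-subject replication (conductivity-jitter repeats), available via
  the generator but not part of the default pipeline.
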