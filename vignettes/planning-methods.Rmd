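---
title: "Automated robust IMPT and transmission-beam planning: models and methods"
author: "protonMCO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated robust IMPT and transmission-beam planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Intensity-modulated proton therapy (IMPT) shapes dose by optimizing the
weights of thousands of scanned pencil-beam spots. Each spot deposits most
of its energy at the end of its range — the Bragg peak — giving a sharp
*distal* fall-off, but its *lateral* penumbra widens with depth, with lower
energies, and especially behind range shifters. In nasopharyngeal
geometries the primary target abuts the brainstem, so the lateral penumbra
is exactly what limits the achievable trade-off between target coverage
and serial-organ sparing, and clinical plans sometimes concede coverage to
respect brainstem or optic-pathway constraints.

A transmission beam (TB) is a pencil beam of the highest deliverable
energy (244 MeV here) whose Bragg peak lies *beyond* the patient: tissue
sees only the low-gradient proximal plateau. TBs forgo the distal edge but
keep a markedly sharper lateral penumbra (no range shifter, small relative
depth), so mixing a minority of TB spots into an IMPT plan can steepen
lateral gradients precisely at target/serial-organ interfaces — at the cost
of some extra integral dose downstream of the target.

`protonMCO` implements this planning-and-evaluation loop end to end at
desk scale: a seeded synthetic phantom stands in for clinical CT data
(which cannot be shipped), an analytic pencil-beam model produces
per-scenario dose-influence matrices, a lexicographic ("wish-list")
multi-criteria optimizer with minimax robustness and sparsity-induced spot
selection generates paired IMPT and IMPT+TB plans, and the evaluation
layer computes DVH, robustness, conformity and NTCP metrics with paired
signed-rank comparisons.

## Synthetic phantom

`generatePhantom()` composes the anatomy procedurally from ellipsoids and
tubes with seeded jitter; no image realism is attempted. The geometry
reproduces the planning *topology* that drives the method: a primary
target (`ctv7000`, volume drawn within the population range 27.3–408.7
cm^3) whose posterior surface abuts the brainstem (a configurable
`ctv_oar_gap`, 0 mm by default), bilateral elective targets (`ctv5425`,
256.6–565.3 cm^3) split into left/right lobes, serial organs (brainstem,
spinal cord, optic nerves and chiasm), parallel organs (parotids, oral
cavity, superior pharyngeal constrictor), brain, mandible and a dental
avoidance volume. Relative stopping power is uniform 1.0 inside the body
by default; optional bone and air inserts exercise range heterogeneity.

Derived structures follow clinical convention: `body_minus_ctvs` and
`brain_minus_ctv7000` by set subtraction; brainstem and cord "surface"
shells as a 3 mm outward dilation (at least one voxel thick on coarse
grids; core/surface shell definitions vary between clinics, so the shell
thickness is a configuration knob, not a claim); a `ctv_ring` high-dose
envelope (targets dilated by 2.5 voxels) used for hot-spot and per-beam-cap
control; and `ctv7000_opt`/`ctv5425_opt`, the coverage-optimization
volumes excluding the serial organs and their shells. That exclusion is
the standard planning concession: voxels inside the brainstem shell can
never receive full prescription under the hard constraints, and optimizing
coverage over them only distorts the objective. Evaluation always reports
coverage of the *full* CTVs, so the concession remains visible.

Resolution presets: `mini` (12 mm, the package's demonstration and test
scale), `desk` (8 mm, default), `fine` (4 mm) and `clinical` (2 mm), all
on a ~264 mm cube. Everything downstream scales with the preset; the
shipped tests and the acceptance script run the 12 mm scale so a full
two-variant planning study completes in minutes on one CPU. Structures of
sub-voxel calibre (optic nerves, cord) keep a partial-volume floor on
their radius so they exist at every preset.

## Dose model

The engine is a deliberately small analytic pencil-beam model — clinical
planning systems use Monte Carlo dose engines and commissioned beam
models, which are out of scope here; what matters are the shape and
ordering properties the planning argument rests on.

* **Range–energy**: Bragg–Kleeman, $R = \alpha E^{p}$ with water defaults
  $\alpha = 0.0022\ \mathrm{cm\,MeV}^{-p}$, $p = 1.77$; a range shifter
  subtracts its water-equivalent thickness. 244 MeV gives $R \approx 36.9$
  cm, far beyond any head-and-neck path, so every transmission spot's peak
  is outside the body.
* **Depth dose**: a flat proximal plateau (35 % of the peak Gaussian
  amplitude, sigmoidally cut at the range) plus a Gaussian Bragg peak of
  width `bragg_width_mm` (12 mm default), identically zero beyond
  $R + 3\sigma_B$. Inside the patient a transmission spot therefore sits
  on the plateau, non-increasing with depth to within 2 %.
* **Lateral spread**: a single Gaussian with
  $\sigma(z)^2 = \sigma_0^2 + \sigma_{sh}^2 + (c\, z\, z/R)^2$
  ($\sigma_0 = 10$ mm, $\sigma_{sh} = 4$ mm per 3 cm shifter, $c = 0.045$).
  The three terms encode the penumbra ordering the method exploits: a
  shifter widens the beam at every depth, and a 244 MeV spot (large $R$)
  grows more slowly than any spot whose peak lies at the depth of
  interest. Deposition is truncated at 3 lateral sigma for sparsity.
* **Scenarios**: each setup/range scenario is recomputed exactly — the ray
  is traced through the shifted geometry and the stopping-power map scaled
  by the range factor — rather than shifting dose post hoc.
* **RBE**: constant 1.1 dose weighting; no LET modelling.

The widths are desk-scale choices: with 8–12 mm voxels and spot grids of
~2 sigma pitch, coverage is attainable and the matrices stay tractable.
They are not a commissioned beam model, and absolute penumbra widths
should not be read clinically; the *orderings* (TB < shifted IMPT at every
depth 0–15 cm) are the tested claims.

## Beams, spots, candidates

The six-field arrangement uses gantry angles 50/100/160/200/260/310
degrees with a 3 cm range shifter on beams 2–5 and a 47.0 Gy(RBE) cap on
any voxel's dose from a single beam. The planner is coplanar: the small
couch rotations clinical setups sometimes add to oblique beams are
omitted, as every property exercised here is two-dimensional in the
gantry plane.
Below the parotids the elective volume splits into a left lobe (beams 1–3
only) and a right lobe (beams 4–6 only) to avoid irradiating through the
contralateral neck; the map is configurable per structure.

Spot placement covers each beam's-eye-view projection of its assigned
targets (plus a 5 mm margin) with a lateral grid, and each intersecting
ray with energy layers spanning the target's water-equivalent depth
interval; energies are inverted from the Bragg–Kleeman relation so peaks
land on their layers after the shifter. Spots whose entrance path (the ray
segment proximal to the peak) crosses an avoidance volume are removed.
Transmission candidates are then created by duplicating the selected IMPT
spots at 244 MeV without a shifter; duplicates sharing a (beam, lateral
position) collapse to one TB candidate per ray, which avoids exactly
collinear influence columns. Spot and layer spacings default to 18 mm /
2.2 cm WET at the desk preset (engineering choices) and should stay near
twice the lateral sigma so the spot lattice can produce a flat dose.

## Scenario sets

Robust optimization uses the standard 21-scenario set: {nominal + 6
cardinal 3 mm shifts} x {range factors 0.97, 1.00, 1.03}. Robustness
evaluation uses 28 scenarios: {6 cardinal + 8 body-diagonal shifts, all
normalized to 3 mm} x {0.97, 1.03} — the clinical systems' exact
enumerations are not public, so these constructions reproduce the printed
cardinalities and magnitudes and are recorded in run metadata. Voxel-wise
minimum and maximum dose surfaces are element-wise extrema over a scenario
set; they bracket the nominal dose whenever the nominal scenario is a
member (as in the 21-set), which is one of the invariants the test suite
checks.

## Lexicographic wish-list optimization

Every stage is a sparse linear program over non-negative spot weights
$w$. Constraint and objective library:

* `max_dose` — per-voxel upper bounds, or minimized via an auxiliary bound
  variable $t$ with rows $d_v^{(s)} \le t$ (worst case over scenarios when
  robust);
* `mean_dose` — structure mean, analogous;
* `mean_underdose` — the coverage objective: deficit variables
  $u_v \ge G - d_v^{(s)}$ across all robust scenarios give
  $u_v \ge G - \min_s d_v^{(s)}$, i.e. voxel-wise-minimum semantics
  consistent with how robust coverage is evaluated; the stage minimizes
  the structure mean of $u$. This one-sided linear deficit is the
  package's surrogate for the proprietary coverage functionals of
  clinical lexicographic optimizers; it keeps every stage an LP.

The solver minimizes priorities in order. After stage $k$ attains value
$a_k$, the objective is frozen at $a_k \times$ `slack` (1.03 default, plus
a 1e-4 absolute floor so zero-valued objectives stay feasible); an
objective flagged `sufficient` that beats its goal is frozen at the goal
instead, leaving the surplus to lower priorities. Hard constraints — here
the serial-organ maxima in all 21 scenarios, the 110 % hot-spot cap and
the 47 Gy per-beam cap on the target ring — hold at every stage and are
never relaxed; an unsolvable stage raises an error naming it. Because all
constraints are upper bounds on a non-negative linear dose, $w = 0$ is
always feasible and stage-1 feasibility is guaranteed.

The default nasopharynx wish-list orders: robust primary coverage (goal
65.8 Gy on `ctv7000_opt`), robust elective coverage (51.0 Gy), hot-spot
control (sufficient at 74.9 Gy = 107 %), brainstem core+surface worst-case
maximum, optic-pathway worst-case maximum, parotid mean, oral-cavity/
constrictor mean, and the `body_minus_ctvs` dose bath. It is a labelled
stand-in written for the synthetic phantom — the verbatim clinical
wish-list is not public — and ships as an editable YAML
(`inst/extdata/wishlists/npc_default.yaml`).

**Sparsity-induced spot selection (SISS).** With every objective frozen,
an iteratively reweighted L1 norm of the weights is minimized (two
reweighting passes, weights $1/(w + \varepsilon)$, a deterministic
smallest-index tie-break so exact duplicates resolve reproducibly), spots
below `prune_rel` (1e-3) of the maximum weight are removed, and the whole
lexicographic sequence is re-solved on the surviving candidates. The
transmission fraction of the final active set is the quantity compared
against the cohort's reported TB contribution. If the re-solve fails the
pruned spots are restored and the dense plan returned, with the event
logged.

**Monotone benefit and the slack cascade.** Enlarging the candidate set
(adding TBs) can only improve a stage *given the same earlier budgets* —
the IMPT solution extended with zero TB weights remains feasible. In the
plain two-chain comparison, however, a variant that does better on an
early priority is frozen *tighter* there, so a later priority can end
worse; the dose-bath stage shows this with TBs, whose shoot-through
plateau genuinely costs integral dose — the trade-off clinical studies of
combined IMPT+TB planning also report. The test suite therefore checks the superset property
under fixed budgets (via `solveLexicographic(freeze_bounds =)`) for every
priority, and the plain chain comparison on the coverage and serial-organ
priorities where the TB benefit is the method's point.

**Numerical choices.** LPs are solved with HiGHS (interior point with
crossover, deterministic under fixed settings) through a bundled Python
helper, since the R stack offers no LP solver; an independent dense
simplex is the oracle in the tests. Feasibility residuals of the returned
plans are typically below 1e-8 Gy; tests allow 1e-5. Solver determinism
plus the single global seed make whole runs bit-reproducible, which
`runPipeline()` verifies by manifest checksums.

## Evaluation

DVH statistics use the inclusive "receives at least d" convention on the
linearly interpolated cumulative DVH of sorted voxel doses; D$x$% with
$x\%$ of the volume below one voxel, and absolute-volume metrics
(D0.03cm^3) below one voxel, extrapolate to the hottest voxel. Conformity
is Paddick's index at the 95 % isodose of each target's own prescription
(70.00 or 54.25 Gy). Targets are scored nominally and on the voxel-wise
minimum; serial organs on the voxel-wise maximum; parallel organs by
nominal mean dose; the dose bath by V2Gy/V5Gy/Dmean of `body_minus_ctvs`;
and the per-beam maximum dose is verified body-wide against the 47 Gy cap.
NTCP models are logistic functions of (possibly square-root-transformed)
structure mean doses. The shipped xerostomia and dysphagia coefficients
are synthetic, protocol-style placeholders — the national indication
protocol's appendix is not in the public text — and are meant to be
replaced via `readNtcpModels()`.

Paired plan comparison uses the two-sided Wilcoxon signed-rank test with
zero differences dropped, the exact null for up to 25 untied pairs and the
tie-corrected normal approximation otherwise (conventions differ between
systems; ours are declared). No multiple-testing correction is applied, as
is usual in planning comparisons of this kind.
`clinicalSurrogateWishList()` provides a deliberately detuned baseline arm
— it stops optimizing once coverage and hot-spot goals are met, mimicking
manual planning practice — for three-arm cohort demonstrations; it is a
labelled surrogate, not a replication of manual plans.

## What the synthetic setting does and does not show

Passing tests demonstrate the machinery: scenario construction, the
influence model's orderings, lexicographic optimality against an
independent formulation, constraint feasibility across all scenarios,
SISS behaviour, metric definitions, and end-to-end determinism. They do
not reproduce cohort medians: those depend on 21 real anatomies, a
commissioned beam model and Monte Carlo dose, none of which are available
or in scope. Quantities with a qualitative anchor — the transmission spot
fraction (a ~15 % minority here, against the ~14 %, range 10–17 %, that
clinical studies of this strategy report),
additional serial-organ sparing from TBs, and the slight dose-bath
increase — land in plausible agreement at the demonstration scale.

Known limitations: the analytic beam has no nuclear halo and a single
Gaussian lateral profile; voxels of 8–12 mm exaggerate interface effects
(the brainstem-shell concession region is one voxel thick); energy-layer
and spot spacings are coarse relative to clinical practice; NTCP
coefficients are placeholders; and delivery-time, LET and DICOM-RT
concerns are out of scope by design.

## Problem sizes used

`scripts/acceptance.R` runs the 12 mm `mini` preset with a 24 mm / 3.2 cm
spot grid (~600 candidate spots, stage LPs of roughly 20,000 rows and one
to two million nonzeros; a full two-variant study in several minutes on
one CPU). The test suite uses the same preset with a slightly coarser
26 mm / 3.4 cm grid for its cached planning run, and an 18 mm voxel /
36 mm spot grid for the repeated end-to-end determinism runs. The `desk`
(8 mm) preset with default spacing is the recommended interactive scale;
`fine` and `clinical` presets exist for users with more patience.
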