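---
title: "Predicting aromatic hydroxylation regioselectivity from arenium-intermediate geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aromatic hydroxylation regioselectivity from arenium-intermediate geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenium)
```

## The model

Diiron monooxygenases hydroxylate aromatic rings through an electrophilic
attack of the activated, iron-bound oxygen on a ring carbon, passing
through a cationic sigma complex — the *arenium intermediate*. Which ring
carbon is attacked decides the product (ortho-, meta- or para-phenol;
4- versus 5-hydroxy isomer of a fused bicycle), so regioselectivity can be
framed as a question about intermediates: which of the candidate arenium
species can adopt, inside the active site, the same arrangement relative
to the diiron cluster that the enzyme's productive reference reaction
uses?

The package operationalizes "same arrangement" with two geometric
predictors, computed after superposing the pose's active-site frame onto
the reference frame:

* `d_cn_c4` — distance (Å) from the pose's oxygen-accepting carbon
  (`C_N`) to the reference complex's accepting carbon (`C4_REF`);
* `delta_theta` — deviation (°) of the torsion θ = Fe2–O–Cn–Cm from the
  reference value θ_ref = 103.6°, where `C_M` is the ring neighbour of
  `C_N` on the side nearer the closest substituent. Angles are wrapped to
  (−180°, 180°]; the sign convention is the standard one (cis = 0°,
  matching `bio3d::torsion.xyz` numerically).

Displacements below about 0.2 Å with Δθ between −10° and +5° characterize
high-turnover reactions. Observed productive poses sit at d ≤ 0.25 Å
while every unproductive one sits at d ≥ 0.42 Å, so the default
classifier cuts at `d_max = 0.30` Å — an interpolation between the two
populations, flagged here because the boundary between 0.25 and 0.42 is
not itself observed. Three classes are produced:

| label | rule | reading |
|---|---|---|
| `efficient` | d ≤ 0.30 Å and Δθ ∈ [−10°, +5°] | product formed at useful rates |
| `poor` | d ≤ 0.30 Å, Δθ outside | slow conversion |
| `inactive` | d > 0.30 Å | no appreciable product |

The middle class is needed because two experimentally distinct behaviours
— slow conversion versus near-total inactivity — both exist at acceptable
distances but different torsions. `d ≤ 0.20` Å additionally raises a
`high_kcat` flag. The non-covalent binding energy (`ncbe`, the
Lennard-Jones + Coulomb sum over intermediate–protein pairs only, with no
restraint term) is reported alongside but deliberately excluded from
classification: the most negative ncBE among candidate poses is not the
productive one in the data this method was built against.

## Docking

`mc_search()` performs seeded Monte Carlo energy minimization:
perturb-then-minimize cycles with Metropolis acceptance between cycles,
geometric cooling (kT₀ = 0.596 kcal/mol, the 300 K equivalent, ×0.95 per
cycle), Gaussian rigid-body kicks (0.4 Å translation, 20° rotation SD),
and Nelder-Mead local descent over the intermediate's six rigid-body
degrees of freedom interleaved with accept-if-lower rigid rotamer jumps
(60° increments) for mobile side chains. The transferred oxygen is held
at coordination distance from Fe2 (2.0 Å target) by a harmonic restraint.
All randomness flows from one seeded generator; the seed is recorded in
every pose and the global RNG stream is left untouched.

The force field is intentionally small: 6-12 Lennard-Jones with
Lorentz-Berthelot combining, Coulomb with a distance-dependent dielectric
ε(r) = ε₀·r (ε₀ = 1) or a constant dielectric, 10 Å cutoff, harmonic
restraints. It is a desk-scale stand-in, not a calibrated potential —
which is why measured pose-parameter tables enter the prediction pipeline
as *fixtures* (`predict_products(fixture = ...)`) rather than as energies
to be re-derived, and why the package's accuracy claims are all
property-based (oracle equivalence, invariances, constructive fixtures)
rather than claims about absolute energetics. Iron centers are fixed
point charges (+0.6 e) with small, soft LJ spheres (σ = 1.2 Å) so that
bare LJ does not forbid the 2 Å Fe–O coordination the restraint enforces;
there is no ligand-field term.

## Intermediate enumeration and geometry

Substrates are described topologically — a six-membered aromatic ring,
substituents at numbered positions with a bulk radius, optionally a ring
fused at two adjacent positions. One arenium intermediate exists per
symmetry-unique unsubstituted carbon; uniqueness is decided by the
subgroup of the hexagon's rotations and reflections that preserves the
substitution pattern. (A mirror-only treatment was considered and
rejected: it cannot merge the six equivalent positions of benzene into
one.) The builder pyramidalizes the accepting carbon by lifting it
h = b/√8 out of plane (b = 1.40 Å aromatic bond), which makes its two
ring bonds subtend exactly the tetrahedral angle, then completes the sp³
frame with the oxygen (C–O 1.43 Å) and hydrogen. Substituents are single
bulk pseudo-atoms; stereochemistry beyond one canonical pyramidalization,
and the exact internal coordinates of any historical model, are out of
scope — the builder is parameterized precisely because no deposited
geometry exists to copy.

## Assay analytics

**%DPPH reduced** is `[1 − A(t_end)/A(0)]·100` with radical concentration
from Beer–Lambert (ε₅₁₅ = 12 mM⁻¹cm⁻¹ in methanol, 1 cm path); the ratio
makes the result invariant to joint rescaling of absorbance and ε.

**EC50** is fitted with a Hill model `%red = 100·rⁿ/(EC50ⁿ + rⁿ)` (floor
0, ceiling 100, n bounded in [0.5, 6]) by Levenberg–Marquardt least
squares. The Hill form is the standard saturating curve and reduces to
the simple binding isotherm at n = 1; when no observed response reaches
50% the result is flagged as an extrapolation instead of being reported
silently.

**TEC50** fits `A(t) = A_f + (A₀ − A_f)·exp(−t/τ)` and reports the first
time the remaining excess absorbance is within 1% (configurable) of the
fitted plateau — analytically τ·ln(100) — snapped to the trace's sampling
resolution. A trace whose exponential fit is no better than a straight
line, or which rises, is a plateau error. "Stable absorbance" has no
unique operationalization; the 1%-of-drop criterion is this package's.

**AE = 1/(EC50·TEC50)**. `antioxidant_result()` computes AE per replicate
and averages, and also reports the mean-of-inputs convention
1/(mean EC50 · mean TEC50): published tables are not always explicit
about which was used, and the two differ measurably (for EC50 = 0.40,
TEC50 = 19.0 the mean-of-inputs value is 0.1316 while the corresponding
published figure is 0.140 ± 0.006 — consistent only with per-replicate
averaging).

**Formation rates** are ordinary least-squares slopes over the initial
linear window. The default window grows while the next point is predicted
by the current fit within 3 residual SDs (scaled for multiplicative
noise, requiring two consecutive outliers so single noisy points do not
truncate) and the extended fit keeps R² ≥ 0.98. The prediction test is
what stops the window at the changepoint: an R² threshold alone barely
moves for the first few post-linear points and would overrun. **Yield**
at time t is 100·Σ products/substrate; the **distribution** is each
product's share of the product pool (sums to exactly 100) — with
`rate_distribution()` as the alternative estimator from rate ratios,
since the two differ when curves leave linearity at different times.

## Synthetic generators

`simulate_dpph()` integrates irreversible second-order scavenging
d[D]/dt = −k[D][A], d[A]/dt = −(k/σ)[D][A] (σ = stoichiometric factor,
radicals quenched per antioxidant molecule) with fixed-step RK4 at
0.1 min, giving the analytic endpoint %red → 100·min(1, σr). Defaults
emulate the assay conditions: 100 µM radical, ε₅₁₅ = 12, σ = 2,
k = 0.005 µM⁻¹min⁻¹ (plateaus on the tens-of-minutes scale the TEC50
values occupy), 1% multiplicative noise, and six doses bracketing the
expected half-reduction ratio 0.5/σ at 0.3–1.4× — a piloted titration,
as an experimentalist would run. The fixed step bounds usable rate
constants (k·[D]₀·dt ≪ 1); the fast-kinetics regime is exercised at
k = 0.2, not at a literal k → ∞.

`simulate_timecourse()` accumulates each product linearly to
`linear_until` (120 min default) then relaxes exponentially (τ = 20 min)
to a plateau, conserving mass exactly in the noiseless output.
`make_toy_site()` builds a diiron pocket with pseudo-residues on an 8 Å
sphere and optional bulky blockers parked where a docked substituent at a
given ring position would sit (both mirror-image ring layouts are
blocked, since the oxygen sits off-plane and the two ring traversals are
mirror images). `make_pose_with_geometry()` constructs poses scoring
exactly (d, Δθ) by internal-coordinate placement: the accepting carbon is
offset perpendicular to the O–C4 bond and its neighbour placed so the
torsion is θ_ref + Δθ. A rigid rotation about the Fe2–O axis, by
contrast, provably *cannot* change θ (the axis passes through both Fe2
and O, so all three torsion bond vectors transform identically) — that
invariance is tested rather than used for construction.

What the generators do not emulate: real electron densities or
force-field physics in the pocket, chromatogram waveforms, multi-step
oxidation kinetics (a two-pool sigmoidal variant was considered and left
out as the underlying chemistry is only qualitatively proposed), or
inter-day assay drift. Passing recovery tests therefore demonstrates the
estimators are correct on data satisfying their assumptions — not that
those assumptions hold for any particular wet-lab trace.

## Numerical choices and scale

Problem sizes were chosen for a laptop-class machine: toy sites of 2–14
atoms, intermediates of 8–13, Monte Carlo budgets of tens of trials,
exhaustive-grid cross-checks at 0.2 Å on a one-atom probe (the grid
comparison uses a constant dielectric of 4 and a −0.2 e probe so the well
curvature stays below what a 0.2 Å lattice can resolve to 0.1 kcal/mol).
Superposition is Kabsch via SVD with the reflection branch explicitly
forbidden; degenerate (collinear, <3-point) selections are errors.
Coordinates are Å throughout; angles are degrees at every API boundary.
PDB I/O is fixed-column with 3-decimal coordinates; role tags and
non-bonded parameters travel in a sidecar YAML because the PDB format has
no slot for them; alternate locations and insertion codes are rejected
rather than silently dropped.

## Known limitations

The active-site model is an input, not a constant — no specific crystal
structure is bundled, and the toy generator's pocket is a stand-in. The
classifier thresholds interpolate between observed populations (d_max
especially); ncBE values from the simplified force field are not
comparable to values from any other potential; and the docking search is
a local-basin sampler whose global behaviour is only validated on toy
landscapes. Second hydroxylations (catechol formation from a first-pass
phenol) are not modelled.
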