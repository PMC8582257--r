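---
title: "Methods: corrected equilibrium structures and semi-experimental refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corrected equilibrium structures and semi-experimental refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolego)
```

## The problem

Equilibrium geometries (r~e~) of semi-rigid molecules are the reference
quantities of rotational spectroscopy: the ground-state rotational constants
$B_\alpha^0$ ($\alpha = a, b, c$) measured by microwave spectroscopy are,
after removal of vibrational contributions, inversely proportional to the
principal moments of inertia of the equilibrium structure. Two practical
obstacles stand between a measured spectrum and an accurate r~e~ structure:

1. a full semi-experimental (SE) determination needs rotational constants for
   enough isotopologues to determine every internal coordinate, which is
   rarely available for molecules beyond ~10 atoms;
2. affordable DFT optimizations carry small but systematic errors in bond
   lengths and valence angles.

This package implements the correction-and-refinement toolchain around those
obstacles: class-wise linear-regression corrections of optimized parameters
(LRA), transfer of SE-minus-optimized offsets from template fragments (TMA),
forward computation of rotational constants for arbitrary isotopologues, and
weighted nonlinear least-squares refinement against SE constants with
predicate observations. Electronic-structure computation is out of scope
throughout: optimized geometries and vibrational contributions
$\Delta B_\alpha^{vib}$ are inputs, never computed.

## Geometry model

A structure is an ordered list of atoms with internal-coordinate placements:
one distance for the second atom, distance + angle for the third, and
distance + angle + torsion from the fourth atom on — 3N − 6 coordinates for N
explicitly placed atoms. Cartesian construction uses the standard local-frame
(NeRF-style) step in a canonical frame: first atom at the origin, second
along +z, third in the xz-plane.

Three extensions are needed to encode published parameter tables faithfully:

* **Improper torsions.** Published placement torsions sometimes run over
  atoms that are not a bonded chain (e.g. a dihedral whose two middle atoms
  are the angle and distance references in reversed order). The placed atom
  may sit at either end of the stored 4-tuple; reversal preserves the signed
  dihedral. When the dihedral's axis coincides with the placement axis the
  constraint is linear in the placement torsion and solved in closed form;
  the fully generic case falls back to a bracketed 1-D root search on the
  placement circle.
* **Torsion sign convention.** Signed dihedrals follow the standard
  right-hand rule (cis = 0); no convention is stated with the published
  tables, so self-consistency of build-then-measure is the contract, and the
  bundled fixtures encode signs as published. All fixtures rebuild and
  re-measure to < 1e−8.
* **Mirror completion.** C~s~ molecules publish only symmetry-unique
  parameters. Reflection steps (a plane through three placed atoms plus a
  source → new-label map) may appear anywhere in the placement sequence, so
  later placements can reference generated atoms.
* **Linear placements.** An exactly linear nitrile angle (180°) makes the
  dependent torsion meaningless; such placements omit the torsion and the
  parameter count is reduced accordingly.

Rotational constants come from the eigenvalues of the inertia tensor in the
center-of-mass frame, $B_\alpha = K / I_\alpha$ with
$K = h / (8\pi^2)$ expressed in MHz amu Å² and computed from the SI-exact
Planck constant and the CODATA-2018 atomic mass constant
(`rotational_constant_K()`, ≈ 505379.01 MHz amu Å²). Isotope masses are a
bundled AME2020-derived table; the most abundant isotope is the default and
per-atom mass-number overrides define isotopologues. Linear tops report `A`
as undefined rather than infinite. The inertia defect
$\Delta = I_c - I_a - I_b$ serves as the planarity diagnostic; exactly planar
reference structures rebuild to $|\Delta| < 10^{-6}$ amu Å².

## Correction models

**LRA.** For each bond/angle class (unordered element pair for bonds; vertex
element plus unordered end pair for angles, so C–O–H and H–C–N remain
distinct classes) and each model chemistry, a linear model of the deviation
from SE reference values gives slope A and intercept B, and the corrected
value is

$$r_{corr} = r_{opt} + (A\,r_{opt} + B).$$

The defining equation is sometimes written with a subtracted correction; the
*additive* convention above is the one that reproduces every published
corrected column we can check (C–S 1.8201 → 1.8146, O–H 0.9808 → 0.9819,
C–N 1.3615 → 1.3583, C–C 1.4064 → 1.4038, C–O 1.3624 → 1.3644, C–O–H
104.96 → 105.11), so it is what `apply_lra_value()` implements; the report
objects record the convention string. Torsions are never LRA-corrected
(no published parameterization exists), and lookups never fall back across
element classes: unparameterized coordinates (e.g. S–H) stay at their input
value and are flagged, matching the published treatment. The bundled
registry carries the two published model-chemistry tags (`"revDSD"` for the
double-hybrid, `"PW6B95"` for the hybrid); further classes can be supplied
through the same registry schema. `fit_lra_parameters()` refits A and B from
(r~opt~, r~SE~) pairs by OLS of the deviation on r~opt~ (optionally with the
intercept pinned to zero) and reports standard OLS 95% confidence intervals —
the published statistics do not state an interval construction, so the
textbook one is used.

**TMA.** A template molecule with a known SE structure donates its
SE-minus-optimized offset: $r_{corr} = r_{opt} + (r_e^{SE}(TM) -
r_{opt}(TM))$, exact arithmetic with no fitted quantity. Template choice is
explicit user input (a mapping of target parameter → template parameter);
the package deliberately does not attempt substructure matching. The
pipeline entry point `run_nanolego()` partitions a structure's parameters
into fragment sets corrected by TMA and leftovers corrected by LRA, and
emits a per-parameter provenance report.

Predicted ground-state constants are $B^0 = B^e + \Delta B^{vib}$ with the
vibrational contributions supplied per axis, and agreement with experiment is
scored as the mean absolute percentage deviation over the three axes
(`mad_percent()`, two decimals, experimental value in the denominator — the
convention validated by reproducing the published guanine scores 0.53/0.09
from published numbers alone).

## Semi-experimental refinement

`se_constant()` implements $B^{SE} = B^0 - \Delta B^{vib}$. `fit_structure()`
minimizes

$$\sum_i w_i\,(I_i^{SE} - I_i^{calc})^2 \;+\; \sum_p
\left(\frac{p_{pred} - p}{\sigma_p}\right)^2$$

over the free internal coordinates, with residuals in inertia-moment space
(amu Å²) by default — constants space (MHz) is an option — because published
fit qualities are quoted in amu Å². Weights default to $1/\sigma^2$ from the
SE-constant uncertainties (propagated to moments) and to unity when no
uncertainty is given. Axes can be omitted per isotopologue (fits using only
B and C are common), and `down_weight()` scales one isotopologue's weights
down by factor² — the documented device for suspect isotopologue data.
Predicate observations — theoretical parameter values with an assigned
σ — enter as ordinary residual rows (the mixed-regression model); in the
σ → 0 limit they pin parameters exactly, and fixing a parameter is
numerically equivalent to a vanishing-σ predicate (verified to 1e−6 in the
tests).

The optimizer is a damped Gauss–Newton (Levenberg) iteration with a
forward-difference Jacobian (relative step 1e−6, absolute floors 1e−6 Å and
1e−5°), taking steps from a QR factorization of the whitened stacked system
(numerically stable even at predicate weights of 10²⁰), with convergence when
the relative objective decrease falls below 1e−12 or the step norm below
1e−10. Parameter standard deviations come from
$\hat\sigma^2 (J^T J)^{-1}$ with predicates counted as observations in the
degrees of freedom. A rank-deficient Jacobian at the start aborts with an
"unidentifiable parameters" error — the documented failure mode when, for
example, ring angles are strongly correlated — rather than returning a
silently ill-determined result. Staged protocols (release bond lengths
first, then angles, …) are expressed as sequences of `fit_spec()` objects,
not as an engine mode. The exact weighting behind published parameter
uncertainties is not documented anywhere we can check, so reported standard
deviations are validated statistically (3σ coverage ≥ 95% on synthetic
replicates; linear scaling with injected noise) rather than against printed
uncertainty digits.

## Bundled reference data and its quirks

Thirteen molecules are shipped as JSON fixtures with per-level parameter
columns, uncertainties, vibrational contributions and experimental
constants. Choices a user should know about:

* Published tables list only symmetry-unique or chemically independent
  values. Unlisted torsions of planar rings and substituents are completed
  as exact 0/180 by cis/trans topology, explicitly in the fixture data (never
  by a code heuristic). Guanine completes 6 of its 13 torsions this way; its
  amino hydrogens are genuinely pyramidal and keep published torsions.
* The C~s~ nitrile case study is heavy-atom planar (sp² ring apex): the
  mirror plane is the molecular plane and generates the four out-of-plane
  methylene hydrogens. Its ring carbons are placed in-plane symmetrically
  about the exocyclic double-bond axis from the published apex-to-ring and
  ring-closure distances; the implied apex angle agrees with the published
  one within its printed rounding. The unpublished nitrile angle is
  completed as exactly linear. With these choices the rebuilt double-hybrid
  column reproduces the published constants score (0.47) exactly.
* Values judged misprinted (a 1.7272 Å C–C bond where ~1.43 is plausible; a
  ring angle one degree out of line with every other column and with the
  published constants) are stored as printed with a `misprint` flag carrying
  the plausible value; tests avoid flagged columns.
* The cysteine corrected-column constants row is not reproducible from the
  published corrected geometry itself (rebuilding gives a score of ~0.19 vs
  the published 0.34, while all four bare columns of the same tables
  reproduce to ±0.01). The likely cause is a different vibrational treatment
  for the corrected row (the source discusses a reduced-dimensionality
  treatment of the large-amplitude S–H torsion). The fixture stores the
  published number; the package reports what it computes.
* One aromatic C–H bond length (8-hydroxyquinoline) is absent from the
  published table although its angle is given; it is completed with a
  typical aromatic value (1.081 Å) and flagged.
* Hydroxyl/oxime conformations not fixed by the published parameters
  (in-plane orientation choices) are encoded as explicit 0/180 choices with
  per-fixture notes.

## Synthetic data

`synth_molecule()` draws tree-connected structures with bonds 0.9–1.9 Å,
angles 90–150°, uniform torsions, heavy interior atoms (C/N/O/S) and
optional terminal hydrogens — the regime of semi-rigid molecules the methods
address. `synth_study()` emulates the SE data model: random single/double
substitutions (H→D, ¹²C→¹³C, ¹⁴N→¹⁵N, ¹⁶O→¹⁸O), Gaussian noise of chosen σ
on the constants, and per-axis vibrational contributions drawn between 0.1
and 1 percent of each constant (negative, as ground-state constants lie
below equilibrium ones for semi-rigid species) and stored so the SE relation
inverts exactly. Both are bit-reproducible per seed and restore the global
RNG state.

What passing synthetic tests do and do not show: they validate the
estimator's numerical contract (exact-data recovery, predicate limits,
coverage of reported uncertainties under the assumed noise model) on
idealized rigid molecules with uncorrelated Gaussian errors. Real SE data
have correlated vibrational-correction errors, axis-dependent quality and
large-amplitude-motion biases; none of that is emulated, which is why the
bundled real-molecule fixtures carry the comparisons to published values.
Problem sizes in the test suite (molecules of 5–9 atoms, 5–8 isotopologues,
200 replicates for coverage) were chosen as the smallest sizes at which the
statistical checks are sharp.

## Numerical choices

* Round-trip tolerance 1e−8 (build → measure); rigid-motion invariance of
  constants to 1e−9 relative; planarity threshold 1e−6 amu Å².
* Finite-difference steps as above; damping factor ×10 up / ÷3 down with
  λ ∈ [1e−12, 1e12].
* Degenerate inputs: coincident atoms, collinear angle references, torsions
  over collinear triples, non-positive bonds, out-of-range angles and
  duplicate labels are hard errors, not warnings.
* Display rounding follows the published style: 4 decimals for Å, 2 for
  degrees, 3 for MHz, 2 for MAD%.

## Limitations

No electronic structure, no vibrational perturbation theory, no Eckart-frame
averaging, no substitution-structure (Kraitchman) analysis, no automatic
fragment discovery, and no treatment of large-amplitude motions beyond
accepting externally supplied vibrational contributions. Registry coverage
is limited to the published parameter classes; anything else is left
uncorrected by design rather than extrapolated.
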