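# nanolego

Accurate equilibrium structures of semi-rigid molecules from corrected
quantum-chemical geometries and semi-experimental rotational constants.

## The problem

The equilibrium structure r<sub>e</sub> of a molecule — the geometry at the
minimum of the Born–Oppenheimer potential — is the quantity that electronic
structure theory predicts and that different experiments can be compared
against. It is not directly observable: rotational spectroscopy measures
ground-state constants B<sub>0</sub> that include vibrational contributions,
and affordable density-functional optimizations carry systematic errors of
several thousandths of an Ångström in bond lengths.

This package implements a "molecular LEGO" workflow that combines three
ingredients:

1. **Geometry engine.** Structures are defined in internal coordinates
   (bonds, valence angles, dihedrals — including improper dihedrals where a
   placed atom is the first atom of the 4-tuple) plus optional
   mirror-symmetry steps, and converted to Cartesian coordinates in a
   canonical frame. From the Cartesians and an isotopic mass assignment the
   principal moments of inertia I<sub>a</sub> ≤ I<sub>b</sub> ≤ I<sub>c</sub>
   and rotational constants are computed as

   B<sub>α</sub> = h / (8π² I<sub>α</sub>), expressed in MHz with I in amu Å².

2. **Geometry corrections.** Optimized bond lengths and valence angles are
   moved toward their semi-experimental values by one of two schemes:

   - **Linear regression (LRA):** for each parameter class (bonds keyed by
     the unordered element pair, angles by the vertex element plus the
     unordered end pair) and model chemistry, a linear model of the deviation
     against the optimized value gives

     r<sub>corr</sub> = r<sub>opt</sub> + (A·r<sub>opt</sub> + B).

     The bundled registry carries the published (A, B) for the
     rev-DSDPBEP86/jun-cc-pVTZ and PW6B95/SNSD model chemistries. Torsions
     are never corrected; classes without a registry entry are left
     untouched.

   - **Template transfer (TMA):** for a parameter with a counterpart in a
     small template molecule whose semi-experimental structure is known,

     r<sub>corr</sub> = r<sub>opt</sub> + (r<sub>se</sub>(template) −
     r<sub>opt</sub>(template)),

     using an explicit target → template mapping, with optional fallback to
     LRA for unmapped parameters.

3. **Semi-experimental refinement.** Experimental ground-state constants are
   converted to semi-experimental equilibrium constants,
   B<sub>e</sub><sup>SE</sup> = B<sub>0</sub> − ΔB<sub>vib</sub>, using
   computed vibrational contributions, and selected internal coordinates are
   refined by damped Gauss–Newton weighted least squares over all
   isotopologues at once. Parameters may be fixed, or constrained softly by
   *predicate* observations (prior value with an uncertainty) that enter the
   residual vector alongside the spectroscopic data — a mixed regression.

The end-to-end check of a structure is the mean absolute percentage
deviation of predicted ground-state constants from experiment:

MAD% = mean( 100 · |B<sub>calc</sub> − B<sub>exp</sub>| / B<sub>exp</sub> ),
rounded to two decimals.

## Worked example

Rebuild the cysteine geometry from its optimized double-hybrid
internal-coordinate column, apply the regression corrections, and compare the
predicted ground-state constants with experiment:

```r
library(nanolego)

fx <- load_fixture("cysteine")
sd <- fixture_structure(fx, "revDSD")

rotational_constants(build_cartesian(sd))
#> <rotational_constants> (MHz)
#>   A = 3074.641  B = 1610.396  C = 1331.982
#>   Ia = 164.370080  Ib = 313.822851  Ic = 379.418932 amu A^2

res <- correct_structure_lra(sd, lra_registry(), "revDSD")
head(as.data.frame(res$report[res$report$method != "none",
                              c("id", "kind", "original", "corrected")]), 5)
#>     id kind original corrected
#> 1 S1C2 bond   1.8201 1.8145784
#> 2 C2C3 bond   1.5289 1.5260868
#> 3 C3C4 bond   1.5375 1.5346710
#> 4 C4O5 bond   1.3361 1.3321318
#> 5 O5H6 bond   0.9808 0.9818926

pred <- ground_state_prediction(res$structure, fx$dvib, fx$experimental)
pred
#> # A tibble: 3 × 6
#>   axis  equilibrium_MHz dvib_MHz ground_state_MHz experimental_MHz percent_dev
#>   <chr>           <dbl>    <dbl>            <dbl>            <dbl>       <dbl>
#> 1 a               3090.   -29.3             3061.            3071.     -0.353
#> 2 b               1618.   -11.1             1607.            1607.      0.0200
#> 3 c               1338.    -9.11            1329.            1332.     -0.214

mad_percent(pred$ground_state_MHz, pred$experimental_MHz)
#> [1] 0.2
```

Other entry points: `fit_structure()` / `fit_spec()` for semi-experimental
refinement (with `tidy()`, `glance()` and `autoplot()` methods),
`correct_structure_tma()` for template transfer, `run_nanolego()` for the
full pipeline, `synth_molecule()` / `synth_study()` for synthetic validation
data, `read_zmat()` / `read_xyz()` / `read_study()` for file I/O, and a
command-line interface at `inst/cli/nanolego` (also callable in-process via
`cli()`).

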