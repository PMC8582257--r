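Package: nanolego
Title: Accurate Equilibrium Molecular Structures from Corrected Geometries and Rotational Constants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving accurate equilibrium structures of semi-rigid
    molecules. Builds Cartesian geometries from internal-coordinate (Z-matrix
    style) definitions with mirror-symmetry completion, computes principal
    moments of inertia and rotational constants for arbitrary isotopologues,
    corrects optimized bond lengths and valence angles by per-parameter-class
    linear regressions (LRA) or by transfer from template fragments with known
    semi-experimental values (TMA), and refines structural parameters against
    semi-experimental rotational constants by weighted nonlinear least squares
    with predicate observations (mixed regression). Ships machine-readable
    reference geometries for a set of case-study molecules, a synthetic
    molecule and study generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
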