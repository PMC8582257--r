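#' Per-atom masses for an isotopologue
#'
#' Non-overridden atoms receive the most-abundant-isotope mass of their
#' element; overrides select a specific mass number per atom label.
#'
#' @param sd_or_geom A `structure_def` or `cartesian_geom`.
#' @param overrides Named integer vector, atom label -> mass number, e.g.
#'   `c(H9 = 2, C3 = 13)`. Empty for the parent species.
#' @return Named numeric vector of masses (amu) in atom order.
#' @export
#' @examples
#' # isotopologue_masses(sd, c(H9 = 2))
isotopologue_masses <- function(sd_or_geom, overrides = integer()) {
  atoms <- sd_or_geom$atoms
  m <- vapply(atoms$element, function(el) isotope_mass(el), 0)
  names(m) <- atoms$label
  if (length(overrides)) {
    bad <- setdiff(names(overrides), atoms$label)
    if (length(bad)) {
      stop("override for unknown atom label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (l in names(overrides)) {
      el <- atoms$element[match(l, atoms$label)]
      m[[l]] <- isotope_mass(el, overrides[[l]])
    }
  }
  m
}

#' Rotational constants and principal moments of inertia
#'
#' Shifts the geometry to its center of mass, diagonalizes the inertia tensor
#' and converts the principal moments \eqn{I_a \le I_b \le I_c} (amu
#' \eqn{\AA^2}) to rotational constants \eqn{A \ge B \ge C} (MHz) through
#' \eqn{B_\alpha = K / I_\alpha}. For linear molecules \eqn{I_a \approx 0};
#' `A` is then reported as `NA` with `degenerate = TRUE` rather than as an
#' infinity.
#'
#' @param geom A `cartesian_geom`.
#' @param masses Named numeric vector of per-atom masses (amu); defaults to
#'   the parent species.
#' @return A `rotational_constants` object: list with `A`, `B`, `C` (MHz),
#'   `Ia`, `Ib`, `Ic` (amu A^2) and `degenerate`.
#' @export
rotational_constants <- function(geom, masses = isotopologue_masses(geom)) {
  xyz <- geom$xyz
  if (nrow(xyz) < 2) stop("need at least two atoms", call. = FALSE)
  m <- masses[rownames(xyz)]
  if (anyNA(m) || any(m <= 0)) stop("invalid masses", call. = FALSE)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  if (max(abs(r)) < 1e-10) stop("all atoms coincident", call. = FALSE)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),      -sum(m * x * z),
    -sum(m * x * y),      sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),      sum(m * (x^2 + y^2))
  ), 3, 3)
  mom <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  K <- rotational_constant_K()
  degenerate <- mom[1] < 1e-8 * mom[3]
  structure(
    list(
      A = if (degenerate) NA_real_ else K / mom[1],
      B = K / mom[2],
      C = K / mom[3],
      Ia = mom[1], Ib = mom[2], Ic = mom[3],
      degenerate = degenerate
    ),
    class = "rotational_constants"
  )
}

#' Inertia defect
#'
#' \eqn{\Delta = I_c - I_a - I_b}; zero for a rigid planar equilibrium
#' geometry, negative for out-of-plane mass distribution.
#'
#' @param rc A `rotational_constants` object.
#' @return Inertia defect in amu \eqn{\AA^2}.
#' @export
inertia_defect <- function(rc) {
  if (isTRUE(rc$degenerate)) {
    stop("inertia defect undefined for a linear top", call. = FALSE)
  }
  rc$Ic - rc$Ia - rc$Ib
}

#' @export
print.rotational_constants <- function(x, ...) {
  cat("<rotational_constants> (MHz)\n")
  cat(sprintf("  A = %s  B = %.3f  C = %.3f\n",
              if (is.na(x$A)) "linear (undefined)" else sprintf("%.3f", x$A),
              x$B, x$C))
  cat(sprintf("  Ia = %.6f  Ib = %.6f  Ic = %.6f amu A^2\n",
              x$Ia, x$Ib, x$Ic))
  invisible(x)
}

#' @method as_tibble rotational_constants
#' @export
as_tibble.rotational_constants <- function(x, ...) {
  tibble::tibble(
    axis = c("a", "b", "c"),
    constant_MHz = c(x$A, x$B, x$C),
    moment_amuA2 = c(x$Ia, x$Ib, x$Ic)
  )
}
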