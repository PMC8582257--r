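#' Build Cartesian coordinates from a structure definition
#'
#' Converts the internal-coordinate placements of a [structure_def()] into a
#' Cartesian geometry in the canonical frame: first atom at the origin, second
#' along +z, third in the xz-plane. Mirror-symmetry steps are applied at the
#' position they occupy in the step sequence, so later placements may
#' reference generated atoms.
#'
#' @param sd A `structure_def`.
#' @return A `cartesian_geom`: list with `atoms` (tibble `label`, `element`)
#'   and `xyz` (N x 3 matrix, Angstrom, rows named by label).
#' @export
#' @examples
#' sd <- structure_def(
#'   tibble::tibble(label = c("O1", "H2"), element = c("O", "H")),
#'   list(place_step("O1", "O"),
#'        place_step("H2", "H", dist = list("O1", 0.96)))
#' )
#' build_cartesian(sd)$xyz
build_cartesian <- function(sd) {
  pos <- list()
  for (st in sd$steps) {
    if (st$type == "place") {
      pos[[st$label]] <- .place_one(pos, st)
    } else {
      plane <- lapply(st$plane, function(l) pos[[l]])
      for (s in names(st$map)) {
        pos[[st$map[[s]]]] <- reflect_point(pos[[s]], plane[[1]], plane[[2]],
                                            plane[[3]])
      }
    }
  }
  xyz <- do.call(rbind, pos[sd$atoms$label])
  rownames(xyz) <- sd$atoms$label
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(atoms = sd$atoms[, c("label", "element")], xyz = xyz),
    class = "cartesian_geom"
  )
}

.place_one <- function(pos, st) {
  n <- length(pos)
  if (n == 0) return(c(0, 0, 0))
  P <- pos[[st$dist[[1]]]]
  d <- st$dist[[2]]
  if (n == 1) return(P + c(0, 0, d))
  theta <- st$ang[[2]]
  Q <- pos[[st$ang[[1]]]]
  if (n == 2) {
    # third atom: in the xz-plane, x >= 0
    u <- vunit(Q - P)
    w <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
    if (vnorm(w) < 1e-12) w <- c(1, 0, 0)
    w <- vunit(w)
    th <- theta * .deg2rad
    return(P + d * (cos(th) * u + sin(th) * w))
  }
  if (abs(theta - 180) < 1e-9) {
    # degenerate linear placement: torsion undefined
    return(P + d * vunit(P - Q))
  }
  tat <- st$tors[[1]]
  phi <- st$tors[[2]]
  if (tat[4] == st$label) tat <- rev(tat)  # sign-preserving normalization
  if (identical(tat[2], st$dist[[1]]) && identical(tat[3], st$ang[[1]])) {
    # standard placement: dihedral about the P-Q axis with reference tat[4]
    return(place_nerf(pos[[tat[4]]], Q, P, d, theta, phi))
  }
  .place_generic(pos, P, Q, d, theta, tat, phi)
}

# Improper placement: X constrained by |X-P| = d, angle(X,P,Q) = theta and a
# dihedral over an arbitrary previously-placed 4-tuple (X first). X lies on a
# circle about the P-Q axis parameterized by the standard torsion tau; when
# the dihedral's middle pair is collinear with P-Q the map tau -> dihedral is
# linear, otherwise a bracketed root search resolves it.
.place_generic <- function(pos, P, Q, d, theta, tat, phi) {
  ref <- NULL
  for (cand in setdiff(names(pos), c())) {
    v <- pos[[cand]]
    if (vnorm(vcross(vunit(Q - P), v - P)) > 1e-8) {
      ref <- v
      break
    }
  }
  if (is.null(ref)) stop("no non-collinear torsion reference available")
  Xof <- function(tau) place_nerf(ref, Q, P, d, theta, tau)
  f <- function(tau) {
    wrap_deg(dihedral_points(Xof(tau), pos[[tat[2]]], pos[[tat[3]]],
                             pos[[tat[4]]]) - phi)
  }
  d0 <- f(0)
  d90 <- f(90)
  slope <- wrap_deg(d90 - d0) / 90
  if (abs(abs(slope) - 1) < 1e-6) {
    tau <- wrap_deg(-d0 / slope)
    if (abs(f(tau)) < 1e-9) return(Xof(tau))
  }
  # generic fallback: scan for a sign change and refine
  taus <- seq(-180, 180, by = 2)
  vals <- vapply(taus, f, 0)
  for (i in seq_len(length(taus) - 1)) {
    if (is.finite(vals[i]) && is.finite(vals[i + 1]) &&
        vals[i] * vals[i + 1] <= 0 && abs(vals[i] - vals[i + 1]) < 180) {
      r <- stats::uniroot(f, c(taus[i], taus[i + 1]), tol = 1e-12)
      return(Xof(r$root))
    }
  }
  stop("could not satisfy improper torsion constraint", call. = FALSE)
}

#' Measure one internal coordinate on a Cartesian geometry
#'
#' @param geom A `cartesian_geom`.
#' @param kind `"bond"`, `"angle"` or `"torsion"`.
#' @param atoms Character vector of 2-4 atom labels.
#' @return Distance in Angstrom or angle/torsion in degrees.
#' @export
measure_internal <- function(geom, kind, atoms) {
  p <- lapply(atoms, function(l) {
    i <- match(l, rownames(geom$xyz))
    if (is.na(i)) stop("unknown atom label: ", l, call. = FALSE)
    geom$xyz[i, ]
  })
  switch(kind,
    bond = vnorm(p[[2]] - p[[1]]),
    angle = angle_points(p[[1]], p[[2]], p[[3]]),
    torsion = dihedral_points(p[[1]], p[[2]], p[[3]], p[[4]]),
    stop("unknown coordinate kind: ", kind)
  )
}

#' Measure every parameter of a structure definition on a geometry
#'
#' Degenerate torsions (placement angle of 180 degrees) are skipped by
#' construction: they never enter the parameter table.
#'
#' @param sd A `structure_def`.
#' @param geom A `cartesian_geom`, by default built from `sd`.
#' @return The parameter tibble with an extra `measured` column.
#' @export
measure_structure <- function(sd, geom = build_cartesian(sd)) {
  p <- sd$params
  p$measured <- purrr::map2_dbl(p$kind, p$atoms,
                                function(k, a) measure_internal(geom, k, a))
  p
}

#' Complete a geometry by mirror reflection
#'
#' Adds the reflections of the source atoms through the plane spanned by three
#' placed atoms; element (and therefore default mass) is copied from the
#' source.
#'
#' @param geom A `cartesian_geom`.
#' @param plane Three atom labels spanning the mirror plane.
#' @param map Named character vector `c(source = "new_label", ...)`.
#' @return The augmented `cartesian_geom`.
#' @export
complete_by_symmetry <- function(geom, plane, map) {
  idx <- match(plane, rownames(geom$xyz))
  if (anyNA(idx)) stop("unknown plane atom label", call. = FALSE)
  p1 <- geom$xyz[idx[1], ]; p2 <- geom$xyz[idx[2], ]; p3 <- geom$xyz[idx[3], ]
  for (s in names(map)) {
    i <- match(s, rownames(geom$xyz))
    if (is.na(i)) stop("unknown source atom label: ", s, call. = FALSE)
    if (map[[s]] %in% rownames(geom$xyz)) {
      stop("generated label already exists: ", map[[s]], call. = FALSE)
    }
    newxyz <- reflect_point(geom$xyz[i, ], p1, p2, p3)
    geom$xyz <- rbind(geom$xyz, matrix(newxyz, 1, 3,
                                       dimnames = list(map[[s]], NULL)))
    geom$atoms <- dplyr::bind_rows(
      geom$atoms,
      tibble::tibble(label = map[[s]], element = geom$atoms$element[i])
    )
  }
  colnames(geom$xyz) <- c("x", "y", "z")
  geom
}

#' @export
print.cartesian_geom <- function(x, ...) {
  cat("<cartesian_geom> ", nrow(x$xyz), " atoms\n", sep = "")
  print(utils::head(cbind(element = x$atoms$element,
                          as.data.frame(round(x$xyz, 6))), 10))
  if (nrow(x$xyz) > 10) cat("...\n")
  invisible(x)
}

#' @method as_tibble cartesian_geom
#' @export
as_tibble.cartesian_geom <- function(x, ...) {
  tibble::tibble(
    label = x$atoms$label, element = x$atoms$element,
    x = x$xyz[, 1], y = x$xyz[, 2], z = x$xyz[, 3]
  )
}
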