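#' Internal-coordinate structure definitions
#'
#' A `structure_def` couples an ordered atom list with the internal-coordinate
#' parameters (bonds in Angstrom, valence angles and torsions in degrees) that
#' place each atom, plus optional mirror-symmetry directives that generate
#' further atoms by reflection. The placement coordinates form the molecule's
#' parameter set: for N explicitly placed atoms there are 3N - 6 of them
#' (N >= 3), and rebuilding Cartesians then re-measuring reproduces each value.
#'
#' @details
#' The object is a list with elements:
#' \describe{
#'   \item{atoms}{tibble with `label`, `element`, `generated` (logical).}
#'   \item{params}{tibble with `id`, `kind` (`"bond"`, `"angle"`,
#'     `"torsion"`), `atoms` (list column of label vectors) and `value`.}
#'   \item{steps}{ordered list of placement / reflection steps.}
#' }
#' Torsion parameters may be "improper": the placed atom must sit at the first
#' or last position of the 4-tuple, but the two middle atoms need not be the
#' distance/angle references, and the dihedral is evaluated on the atoms in
#' stored order.
#'
#' @param atoms Data frame with columns `label` and `element`.
#' @param steps List of steps created by [place_step()] / [reflect_step()].
#' @param values Optional named numeric vector overriding parameter values
#'   by id.
#' @return A `structure_def` object.
#' @export
structure_def <- function(atoms, steps, values = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("label", "element") %in% names(atoms)))
  if (anyDuplicated(atoms$label)) {
    stop("atom labels must be unique", call. = FALSE)
  }
  known <- .isotope_masses[atoms$element]
  if (any(vapply(known, is.null, logical(1)))) {
    bad <- atoms$element[vapply(known, is.null, logical(1))]
    stop("unrecognized element symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sd <- structure(
    list(atoms = dplyr::mutate(atoms, generated = FALSE), steps = steps),
    class = "structure_def"
  )
  sd <- .index_structure(sd)
  if (!is.null(values)) {
    sd <- set_param_values(sd, values)
  }
  validate_structure(sd)
  sd
}

#' @rdname structure_def
#' @param label,element Atom being placed.
#' @param dist Length-2: reference label and distance value, e.g.
#'   `list("C1", 1.52)`.
#' @param ang For the third atom onward: `list(ref_label, value)`; the angle
#'   vertex is the distance reference.
#' @param tors For the fourth atom onward: `list(atoms, value)` where `atoms`
#'   is the 4-label tuple (placed atom first or last); or `NULL` when the
#'   placement angle is 180 degrees (degenerate linear placement).
#' @param ids Optional named character overriding the auto-generated parameter
#'   ids (`dist`, `ang`, `tors`).
#' @export
place_step <- function(label, element, dist = NULL, ang = NULL, tors = NULL,
                       ids = NULL) {
  structure(
    list(type = "place", label = label, element = element,
         dist = dist, ang = ang, tors = tors, ids = ids),
    class = "nanolego_step"
  )
}

#' @rdname structure_def
#' @param plane Three atom labels defining the mirror plane.
#' @param map Named character vector, `c(source = "new_label", ...)`.
#' @param elements Optional named character giving elements for generated
#'   atoms; defaults to the source atom's element.
#' @export
reflect_step <- function(plane, map, elements = NULL) {
  structure(
    list(type = "reflect", plane = plane, map = map, elements = elements),
    class = "nanolego_step"
  )
}

# Build the params table and atom table from the steps.
.index_structure <- function(sd) {
  params <- list()
  atoms <- list()
  placed <- character()
  add_param <- function(id, kind, atom_labels, value) {
    params[[length(params) + 1]] <<- tibble::tibble(
      id = id, kind = kind, atoms = list(atom_labels), value = value
    )
  }
  for (st in sd$steps) {
    if (st$type == "place") {
      n_placed <- length(placed)
      if (n_placed >= 1) {
        if (is.null(st$dist)) stop("missing distance placement for ", st$label)
        ref <- st$dist[[1]]
        if (!ref %in% placed) {
          stop("unresolvable reference '", ref, "' placing ", st$label,
               call. = FALSE)
        }
        id <- st$ids[["dist"]] %||% paste0(ref, st$label)
        add_param(id, "bond", c(ref, st$label), st$dist[[2]])
      }
      if (n_placed >= 2) {
        if (is.null(st$ang)) stop("missing angle placement for ", st$label)
        ref2 <- st$ang[[1]]
        if (!ref2 %in% placed) {
          stop("unresolvable reference '", ref2, "' placing ", st$label,
               call. = FALSE)
        }
        id <- st$ids[["ang"]] %||% paste0(ref2, st$dist[[1]], st$label)
        add_param(id, "angle", c(ref2, st$dist[[1]], st$label), st$ang[[2]])
      }
      if (n_placed >= 3) {
        if (is.null(st$tors)) {
          if (!isTRUE(abs(st$ang[[2]] - 180) < 1e-9)) {
            stop("missing torsion placement for ", st$label, call. = FALSE)
          }
        } else {
          tat <- st$tors[[1]]
          if (length(tat) != 4) stop("torsion needs 4 atom labels")
          if (tat[1] != st$label && tat[4] != st$label) {
            stop("placed atom must be first or last in torsion tuple placing ",
                 st$label, call. = FALSE)
          }
          others <- setdiff(tat, st$label)
          if (!all(others %in% placed)) {
            stop("unresolvable reference(s) '",
                 paste(setdiff(others, placed), collapse = ","),
                 "' placing ", st$label, call. = FALSE)
          }
          id <- st$ids[["tors"]] %||% paste0(tat, collapse = "")
          add_param(id, "torsion", tat, st$tors[[2]])
        }
      }
      placed <- c(placed, st$label)
      atoms[[length(atoms) + 1]] <- tibble::tibble(
        label = st$label, element = st$element, generated = FALSE
      )
    } else if (st$type == "reflect") {
      if (!all(st$plane %in% placed)) {
        stop("symmetry plane references unplaced atom(s)", call. = FALSE)
      }
      srcs <- names(st$map)
      if (!all(srcs %in% placed)) {
        stop("symmetry source references unplaced atom(s)", call. = FALSE)
      }
      elmap <- stats::setNames(
        vapply(atoms, function(a) a$element, ""),
        vapply(atoms, function(a) a$label, "")
      )
      for (s in srcs) {
        newl <- st$map[[s]]
        if (newl %in% placed) stop("duplicate generated label ", newl)
        el <- st$elements[[newl]] %||% unname(elmap[[s]])
        placed <- c(placed, newl)
        atoms[[length(atoms) + 1]] <- tibble::tibble(
          label = newl, element = el, generated = TRUE
        )
      }
    } else {
      stop("unknown step type: ", st$type)
    }
  }
  sd$atoms <- dplyr::bind_rows(atoms)
  sd$params <- dplyr::bind_rows(params)
  if (anyDuplicated(sd$params$id)) {
    stop("duplicate parameter ids: ",
         paste(sd$params$id[duplicated(sd$params$id)], collapse = ", "),
         call. = FALSE)
  }
  sd
}

#' @export
validate_structure <- function(sd) {
  p <- sd$params
  bad <- p$kind == "bond" & p$value <= 0
  if (any(bad)) stop("non-positive bond length: ", p$id[bad][1], call. = FALSE)
  bad <- p$kind == "angle" & (p$value <= 0 | p$value > 180)
  if (any(bad)) stop("angle out of (0, 180]: ", p$id[bad][1], call. = FALSE)
  bad <- p$kind == "torsion" & (p$value <= -180 | p$value > 180)
  if (any(bad)) stop("torsion out of (-180, 180]: ", p$id[bad][1], call. = FALSE)
  n_explicit <- sum(!sd$atoms$generated)
  # linear (180 degree) placements have a degenerate, omitted torsion
  place_steps <- Filter(function(s) s$type == "place", sd$steps)
  n_degen <- sum(vapply(seq_along(place_steps), function(i) {
    st <- place_steps[[i]]
    i >= 4 && is.null(st$tors) && !is.null(st$ang) &&
      abs(st$ang[[2]] - 180) < 1e-9
  }, TRUE))
  if (n_explicit >= 3 && nrow(p) != 3 * n_explicit - 6 - n_degen) {
    stop("expected ", 3 * n_explicit - 6 - n_degen,
         " placement coordinates, found ", nrow(p), call. = FALSE)
  }
  invisible(sd)
}

#' Parameters of a structure definition
#'
#' @param sd A `structure_def`.
#' @return Tibble with `id`, `kind`, `atoms`, `value`.
#' @export
param_table <- function(sd) sd$params

#' Update parameter values by id
#'
#' @param sd A `structure_def`.
#' @param values Named numeric vector, names are parameter ids.
#' @return The updated `structure_def`.
#' @export
set_param_values <- function(sd, values) {
  idx <- match(names(values), sd$params$id)
  if (anyNA(idx)) {
    stop("unknown parameter id(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sd$params$value[idx] <- unname(values)
  # keep the step records in sync so rebuilds see the new values
  sd$steps <- .push_values_to_steps(sd$steps, sd$params)
  sd
}

.push_values_to_steps <- function(steps, params) {
  val <- stats::setNames(params$value, params$id)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st$type != "place") next
    if (!is.null(st$dist)) {
      id <- st$ids[["dist"]] %||% paste0(st$dist[[1]], st$label)
      st$dist[[2]] <- val[[id]]
    }
    if (!is.null(st$ang)) {
      id <- st$ids[["ang"]] %||% paste0(st$ang[[1]], st$dist[[1]], st$label)
      st$ang[[2]] <- val[[id]]
    }
    if (!is.null(st$tors)) {
      id <- st$ids[["tors"]] %||% paste0(st$tors[[1]], collapse = "")
      st$tors[[2]] <- val[[id]]
    }
    steps[[i]] <- st
  }
  steps
}

#' @export
print.structure_def <- function(x, ...) {
  n_gen <- sum(x$atoms$generated)
  cat("<structure_def> ", nrow(x$atoms), " atoms (",
      n_gen, " symmetry-generated), ", nrow(x$params), " parameters\n",
      sep = "")
  counts <- table(x$params$kind)
  cat("  ", paste(names(counts), counts, sep = ": ", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
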