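# File formats: XYZ, the Z-matrix text dialect, JSON structure schema and
# study files. Units are fixed package-wide (Angstrom, degrees, MHz, amu).

#' Read and write XYZ files
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records in
#' Angstrom. Writing uses 10 significant digits so a round trip is lossless
#' at 1e-9. Atom labels are generated as element + position on read.
#'
#' @param path File path.
#' @param geom A `cartesian_geom`.
#' @param comment Comment line for the second record.
#' @return `read_xyz()` returns a `cartesian_geom`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 2]
  if (length(lines) < 1) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ count line", call. = FALSE)
  if (length(lines) < n + 2) stop("XYZ file truncated: expected ", n,
                                  " records", call. = FALSE)
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(vapply(rec, length, 0L) < 4)
  if (length(bad)) stop("malformed XYZ record on line ", bad[1] + 2,
                        call. = FALSE)
  element <- vapply(rec, `[[`, "", 1)
  xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinates in XYZ file", call. = FALSE)
  labels <- paste0(element, seq_len(n))
  rownames(xyz) <- labels
  colnames(xyz) <- c("x", "y", "z")
  structure(list(atoms = tibble::tibble(label = labels, element = element),
                 xyz = xyz),
            class = "cartesian_geom")
}

#' @rdname read_xyz
#' @export
write_xyz <- function(geom, path, comment = "") {
  lines <- c(
    as.character(nrow(geom$xyz)),
    comment,
    sprintf("%-3s %18.10f %18.10f %18.10f", geom$atoms$element,
            geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the Z-matrix text dialect
#'
#' One atom per line: `label element [ref1 dist [ref2 angle [ref3 torsion]]]`.
#' `ref3` is normally a single label (torsion tuple `label ref1 ref2 ref3`);
#' an improper torsion over an arbitrary previously placed triple is written
#' `a:b:c`, meaning the dihedral of (`label`, a, b, c). A linear placement
#' (angle 180) omits the torsion. Trailing directives
#' `SYMMETRY plane=a,b,c map=src:new,...` reflect atoms through the plane of
#' three placed atoms at that point of the sequence. Comment lines start
#' with `#`.
#'
#' @param path File path.
#' @param sd A [structure_def()].
#' @return `read_zmat()` returns a [structure_def()].
#' @export
read_zmat <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  steps <- list()
  atoms <- list()
  seen <- character()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (startsWith(ln, "SYMMETRY")) {
      plane_m <- regmatches(ln, regexec("plane=([^ ]+)", ln))[[1]][2]
      map_m <- regmatches(ln, regexec("map=([^ ]+)", ln))[[1]][2]
      if (is.na(plane_m) || is.na(map_m)) {
        stop("malformed SYMMETRY directive on line ", k, call. = FALSE)
      }
      plane <- strsplit(plane_m, ",")[[1]]
      pairs <- strsplit(strsplit(map_m, ",")[[1]], ":")
      map <- stats::setNames(vapply(pairs, `[[`, "", 2),
                             vapply(pairs, `[[`, "", 1))
      if (!all(c(plane, names(map)) %in% seen)) {
        stop("SYMMETRY references unplaced atom on line ", k, call. = FALSE)
      }
      steps[[length(steps) + 1]] <- reflect_step(plane, map)
      seen <- c(seen, unname(map))
      for (i in seq_along(map)) {
        src <- names(map)[i]
        el <- vapply(atoms, function(a) a$element, "")[
          vapply(atoms, function(a) a$label, "") == src]
        atoms[[length(atoms) + 1]] <- list(label = unname(map[i]),
                                           element = el)
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    label <- tok[1]
    element <- tok[2]
    if (label %in% seen) stop("duplicate atom label '", label, "' on line ",
                              k, call. = FALSE)
    dist <- ang <- tors <- NULL
    if (length(tok) >= 4) {
      if (!tok[3] %in% seen) {
        stop("forward reference '", tok[3], "' on line ", k, call. = FALSE)
      }
      dist <- list(tok[3], as.numeric(tok[4]))
    }
    if (length(tok) >= 6) {
      if (!tok[5] %in% seen) {
        stop("forward reference '", tok[5], "' on line ", k, call. = FALSE)
      }
      ang <- list(tok[5], as.numeric(tok[6]))
    }
    if (length(tok) >= 8) {
      refs <- strsplit(tok[7], ":")[[1]]
      tuple <- if (length(refs) == 1) {
        c(label, dist[[1]], ang[[1]], refs)
      } else if (length(refs) == 3) {
        c(label, refs)
      } else {
        stop("malformed torsion reference on line ", k, call. = FALSE)
      }
      if (!all(setdiff(tuple, label) %in% seen)) {
        stop("forward reference in torsion on line ", k, call. = FALSE)
      }
      tors <- list(tuple, as.numeric(tok[8]))
    }
    steps[[length(steps) + 1]] <- place_step(label, element, dist = dist,
                                             ang = ang, tors = tors)
    atoms[[length(atoms) + 1]] <- list(label = label, element = element)
    seen <- c(seen, label)
  }
  structure_def(
    tibble::tibble(label = vapply(atoms, `[[`, "", "label"),
                   element = vapply(atoms, `[[`, "", "element")),
    steps
  )
}

#' @rdname read_zmat
#' @export
write_zmat <- function(sd, path) {
  fmt <- function(x) sprintf("%.15g", x)
  lines <- character()
  for (st in sd$steps) {
    if (st$type == "reflect") {
      lines <- c(lines, paste0(
        "SYMMETRY plane=", paste(st$plane, collapse = ","),
        " map=", paste(paste0(names(st$map), ":", unname(st$map)),
                       collapse = ",")
      ))
      next
    }
    parts <- c(st$label, st$element)
    if (!is.null(st$dist)) parts <- c(parts, st$dist[[1]], fmt(st$dist[[2]]))
    if (!is.null(st$ang)) parts <- c(parts, st$ang[[1]], fmt(st$ang[[2]]))
    if (!is.null(st$tors)) {
      tuple <- st$tors[[1]]
      if (tuple[4] == st$label) tuple <- rev(tuple)
      ref <- if (identical(tuple[2], st$dist[[1]]) &&
                   identical(tuple[3], st$ang[[1]])) {
        tuple[4]
      } else {
        paste(tuple[2:4], collapse = ":")
      }
      parts <- c(parts, ref, fmt(st$tors[[2]]))
    }
    lines <- c(lines, paste(parts, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the JSON structure schema
#'
#' Mirrors the internal representation: ordered atoms and placement steps.
#'
#' @param path File path.
#' @param sd A [structure_def()].
#' @return `read_structure_json()` returns a [structure_def()].
#' @export
read_structure_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  steps <- lapply(raw$steps, function(st) {
    if (!is.null(st$reflect)) {
      reflect_step(unlist(st$reflect$plane), unlist(st$reflect$map))
    } else {
      place_step(
        st$atom, st$element,
        dist = if (is.null(st$dist)) NULL else list(st$dist[[1]],
                                                    as.numeric(st$dist[[2]])),
        ang = if (is.null(st$ang)) NULL else list(st$ang[[1]],
                                                  as.numeric(st$ang[[2]])),
        tors = if (is.null(st$tors)) NULL else list(unlist(st$tors$atoms),
                                                    as.numeric(st$tors$value))
      )
    }
  })
  atoms <- tibble::tibble(
    label = vapply(raw$atoms, function(a) a[[1]], ""),
    element = vapply(raw$atoms, function(a) a[[2]], "")
  )
  structure_def(atoms, steps)
}

#' @rdname read_structure_json
#' @export
write_structure_json <- function(sd, path) {
  steps <- lapply(sd$steps, function(st) {
    if (st$type == "reflect") {
      list(reflect = list(plane = st$plane, map = as.list(st$map)))
    } else {
      out <- list(atom = st$label, element = st$element)
      if (!is.null(st$dist)) out$dist <- list(st$dist[[1]], st$dist[[2]])
      if (!is.null(st$ang)) out$ang <- list(st$ang[[1]], st$ang[[2]])
      if (!is.null(st$tors)) {
        out$tors <- list(atoms = st$tors[[1]], value = st$tors[[2]])
      }
      out
    }
  })
  explicit <- sd$atoms[!sd$atoms$generated, ]
  atoms <- purrr::map2(explicit$label, explicit$element, function(l, e)
    list(l, e))
  jsonlite::write_json(list(atoms = atoms, steps = steps), path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a rotational study file
#'
#' JSON with fields `structure` (a path to a Z-matrix/JSON structure, or an
#' inline structure object), `isotopologues` (named records of atom-label ->
#' mass-number overrides), `observations` (records with `iso`, `axis`, `B0`,
#' `sigma`, `dvib`), optional `predicates` (records with `param`, `value`,
#' `sigma`), `free` (parameter ids) and `options`.
#'
#' @param path Study file path.
#' @return A [fit_spec()].
#' @export
read_study <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sd <- if (is.character(raw$structure)) {
    p <- raw$structure
    if (!file.exists(p)) {
      p <- file.path(dirname(path), raw$structure)
    }
    if (grepl("\\.json$", p)) read_structure_json(p) else read_zmat(p)
  } else {
    stop("study 'structure' must be a file path", call. = FALSE)
  }
  isos <- lapply(raw$isotopologues, function(ov)
    stats::setNames(as.integer(unlist(ov)), names(ov)))
  obs <- dplyr::bind_rows(lapply(raw$observations, function(o) {
    se <- se_constant(as.numeric(o$B0), as.numeric(o$dvib),
                      if (is.null(o$sigma)) 0 else as.numeric(o$sigma))
    tibble::tibble(iso = o$iso, axis = o$axis, B_se = se$B_se,
                   sigma = se$sigma,
                   weight = if (is.null(o$weight)) 1 else as.numeric(o$weight))
  }))
  preds <- if (is.null(raw$predicates)) NULL else {
    dplyr::bind_rows(lapply(raw$predicates, function(p)
      tibble::tibble(param = p$param, value = as.numeric(p$value),
                     sigma = as.numeric(p$sigma))))
  }
  opts <- raw$options %||% list()
  fit_spec(
    sd, free = unlist(raw$free), observations = obs, isotopologues = isos,
    predicates = preds,
    residual_space = opts$residual_space %||% "moments",
    max_iter = opts$max_iter %||% 100,
    ftol = opts$ftol %||% 1e-12, xtol = opts$xtol %||% 1e-10
  )
}
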