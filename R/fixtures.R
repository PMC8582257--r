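#' Bundled case-study geometries
#'
#' The package ships machine-readable equilibrium structures for a set of
#' case-study molecules: per-level internal-coordinate columns (semi-
#' experimental where published, optimized, regression- and template-
#' corrected), parameter uncertainties, vibrational contributions to the
#' rotational constants, experimental ground-state constants, and completion /
#' misprint flags. `load_fixture()` returns one molecule; `fixture_ids()`
#' lists what is available.
#'
#' @param id Molecule identifier (see [fixture_ids()]).
#' @return A `case_fixture` object.
#' @export
#' @examples
#' fx <- load_fixture("cysteine")
#' fixture_levels(fx)
load_fixture <- function(id) {
  files <- .fixture_files()
  if (!id %in% names(files)) {
    stop("unknown fixture id: '", id, "'. Available: ",
         paste(names(files), collapse = ", "), call. = FALSE)
  }
  raw <- jsonlite::fromJSON(files[[id]], simplifyVector = FALSE)
  atoms <- tibble::tibble(
    label = vapply(raw$atoms, function(a) a[[1]], ""),
    element = vapply(raw$atoms, function(a) a[[2]], "")
  )
  params <- tibble::tibble(
    id = vapply(raw$params, function(p) p$id, ""),
    kind = vapply(raw$params, function(p) p$kind, ""),
    atoms = lapply(raw$params, function(p) unlist(p$atoms)),
    values = lapply(raw$params, function(p)
      vapply(p$values, as.numeric, 0)),
    sigma = lapply(raw$params, function(p)
      if (is.null(p$sigma)) NULL else vapply(p$sigma, as.numeric, 0)),
    completed = vapply(raw$params, function(p) isTRUE(p$completed), TRUE),
    predicate = vapply(raw$params, function(p) isTRUE(p$predicate), TRUE),
    fixed = lapply(raw$params, function(p) unlist(p$fixed)),
    uncorrected_levels = lapply(raw$params,
                                function(p) unlist(p$uncorrected_levels)),
    misprint = lapply(raw$params, function(p) p$misprint)
  )
  num3 <- function(x) if (is.null(x)) NULL else vapply(x, as.numeric, 0)
  structure(
    list(
      id = raw$id, name = raw$name, description = raw$description,
      levels = unlist(raw$levels), atoms = atoms, params = params,
      placements = raw$placements,
      dvib = num3(raw$dvib), experimental = num3(raw$experimental),
      constants_printed = lapply(raw$constants_printed, function(x)
        vapply(x, as.numeric, 0)),
      mad_printed = num3(raw$mad_printed),
      planar = isTRUE(raw$planar), notes = unlist(raw$notes)
    ),
    class = "case_fixture"
  )
}

.fixture_files <- function() {
  dir <- system.file("extdata", package = "nanolego")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  ids <- vapply(files, function(f) jsonlite::fromJSON(f)$id, "")
  stats::setNames(files, ids)
}

#' @rdname load_fixture
#' @export
fixture_ids <- function() sort(names(.fixture_files()))

#' @rdname load_fixture
#' @param fx A `case_fixture`.
#' @export
fixture_levels <- function(fx) fx$levels

#' Parameter value at a level, with fallback
#'
#' Corrected-level columns publish no torsions (and keep unparameterized
#' entries at the parent value); lookups therefore fall back from e.g.
#' `"revDSD-LRA"` to `"revDSD"`, and `"all"` matches any level.
#'
#' @param fx A `case_fixture`.
#' @param id Parameter id.
#' @param level Level tag.
#' @return Numeric value.
#' @export
param_value <- function(fx, id, level) {
  i <- match(id, fx$params$id)
  if (is.na(i)) stop("unknown parameter id: ", id, call. = FALSE)
  .value_at(fx$params$values[[i]], level)
}

.value_at <- function(values, level) {
  if (level %in% names(values)) return(unname(values[[level]]))
  if ("all" %in% names(values)) return(unname(values[["all"]]))
  base <- sub("-(LRA|TMA|NL)$", "", level)
  if (base != level && base %in% names(values)) {
    return(unname(values[[base]]))
  }
  NA_real_
}

#' Realize a fixture column as a buildable structure definition
#'
#' @param fx A `case_fixture`.
#' @param level Level tag, one of `fixture_levels(fx)`.
#' @return A [structure_def()] whose parameter ids match the fixture's.
#' @export
#' @examples
#' fx <- load_fixture("cysteine")
#' sd <- fixture_structure(fx, "PW6B95")
#' rotational_constants(build_cartesian(sd))
fixture_structure <- function(fx, level) {
  if (!level %in% fx$levels) {
    stop("unknown level '", level, "' for fixture ", fx$id, call. = FALSE)
  }
  elem <- stats::setNames(fx$atoms$element, fx$atoms$label)
  pidx <- stats::setNames(seq_len(nrow(fx$params)), fx$params$id)
  pval <- function(id) {
    v <- param_value(fx, id, level)
    if (is.na(v)) {
      stop("parameter ", id, " has no value at level ", level, call. = FALSE)
    }
    v
  }
  steps <- list()
  for (pl in fx$placements) {
    if (!is.null(pl$reflect)) {
      steps[[length(steps) + 1]] <- reflect_step(
        plane = unlist(pl$reflect$plane),
        map = unlist(pl$reflect$map)
      )
      next
    }
    atom <- pl$atom
    dist <- ang <- tors <- NULL
    ids <- character()
    if (!is.null(pl$dist)) {
      p <- fx$params[pidx[[pl$dist]], ]
      ref <- setdiff(p$atoms[[1]], atom)
      dist <- list(ref, pval(pl$dist))
      ids["dist"] <- pl$dist
    } else if (!is.null(pl$dist_from)) {
      # bond value shared with another parameter (symmetric ring closure)
      dist <- list(pl$dist_ref, pval(pl$dist_from))
      ids["dist"] <- paste0(pl$dist_ref, atom)
    }
    drv <- pl$derive
    if (is.null(drv)) {
      if (!is.null(pl$ang)) {
        p <- fx$params[pidx[[pl$ang]], ]
        a <- p$atoms[[1]]
        if (a[3] == atom) a <- rev(a)
        stopifnot(a[1] == atom, a[2] == dist[[1]])
        ang <- list(a[3], pval(pl$ang))
        ids["ang"] <- pl$ang
      }
      if (!is.null(pl$tors)) {
        p <- fx$params[pidx[[pl$tors]], ]
        tors <- list(p$atoms[[1]], pval(pl$tors))
        ids["tors"] <- pl$tors
      }
    } else if (drv == "ring_closure") {
      # in-plane symmetric ring placement: the apex half-angle comes from the
      # published closure distance, giving an angle within printed rounding of
      # the published one (which slightly over-determines the triangle)
      a <- unlist(pl$ang_atoms)
      if (a[3] == atom) a <- rev(a)
      d <- dist[[2]]
      y <- pval(pl$closure) / 2
      alpha <- 180 - asin(min(1, y / d)) * .rad2deg
      ang <- list(a[3], alpha)
      ids["ang"] <- paste0(rev(a), collapse = "")
      tuple <- unlist(pl$tors_tuple)
      tors <- list(tuple, pl$tors_value)
      ids["tors"] <- paste0(tuple, collapse = "")
    } else {
      stop("unknown placement derivation: ", drv)
    }
    steps[[length(steps) + 1]] <- place_step(
      atom, elem[[atom]], dist = dist, ang = ang, tors = tors, ids = ids
    )
  }
  structure_def(fx$atoms[, c("label", "element")], steps)
}

#' @export
print.case_fixture <- function(x, ...) {
  cat("<case_fixture> ", x$id, " (", x$name, ")\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms, ", nrow(x$params), " parameters, levels: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  if (!is.null(x$experimental)) {
    cat("  experimental constants (MHz): ",
        paste(sprintf("%.3f", x$experimental), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Generate a random semi-rigid molecule
#'
#' Draws a tree-connected structure with chemically plausible ranges: bonds
#' 0.9-1.9 Angstrom, valence angles 90-150 degrees, torsions uniform on
#' (-180, 180]. Interior atoms are heavy (C/N/O/S); terminal atoms may be
#' hydrogen. Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param n_atoms Number of atoms (>= 2).
#' @return A [structure_def()].
#' @export
#' @examples
#' sd <- synth_molecule(1, 6)
#' measure_structure(sd)
synth_molecule <- function(seed, n_atoms) {
  stopifnot(n_atoms >= 2)
  pick <- function(x) x[sample.int(length(x), 1L)]
  .with_seed(seed, {
    parent <- c(NA_integer_, 1L,
                if (n_atoms > 2) vapply(3:n_atoms,
                                        function(i) pick(seq_len(i - 1L)),
                                        1L))
    has_child <- seq_len(n_atoms) %in% parent
    heavy <- c("C", "C", "N", "O", "S")
    element <- vapply(seq_len(n_atoms), function(i) {
      if (has_child[i] || i <= 2) pick(heavy)
      else if (stats::runif(1) < 0.4) "H" else pick(heavy)
    }, "")
    labs <- paste0(element, seq_len(n_atoms))
    steps <- list(place_step(labs[1], element[1]))
    # positions tracked during generation so angle/torsion references are
    # guaranteed geometrically valid (distinct, non-collinear); insertion
    # order matches atom order, so integer indexing works alongside labels
    pos <- stats::setNames(list(c(0, 0, 0)), labs[1])
    for (i in seq_len(n_atoms)[-1]) {
      p <- parent[i]
      dist <- list(labs[p], stats::runif(1, 0.9, 1.9))
      ang <- tors <- NULL
      if (i >= 3) {
        q <- pick(setdiff(seq_len(i - 1), p))
        ang <- list(labs[q], stats::runif(1, 90, 150))
        if (i >= 4) {
          axis <- pos[[q]] - pos[[p]]
          cand <- setdiff(seq_len(i - 1), c(p, q))
          ok <- cand[vapply(cand, function(r) {
            vnorm(vcross(axis, pos[[r]] - pos[[p]])) /
              max(vnorm(axis), 1e-12) > 1e-3
          }, TRUE)]
          if (length(ok) == 0) ok <- cand  # fall back; engine will validate
          r <- pick(ok)
          tors <- list(c(labs[i], labs[p], labs[q], labs[r]),
                       stats::runif(1, -180, 180))
        }
      }
      st <- place_step(labs[i], element[i], dist = dist, ang = ang,
                       tors = tors)
      steps[[i]] <- st
      pos[[labs[i]]] <- .place_one(pos, st)
    }
    structure_def(tibble::tibble(label = labs, element = element), steps)
  })
}

#' Generate a synthetic rotational study
#'
#' Emulates the data model of a semi-experimental refinement: a set of
#' isotopologues (random single/double substitutions H->D, 12C->13C,
#' 14N->15N, 16O->18O, 32S->34S), exact equilibrium constants from the true geometry,
#' additive Gaussian noise of width `noise_sigma` on the semi-experimental
#' constants, and per-axis vibrational contributions drawn between 0.1 and 1
#' percent of each constant (negative sign) and stored so that removing them
#' from the ground-state constants recovers the noisy semi-experimental
#' values exactly.
#'
#' @param sd True [structure_def()].
#' @param n_iso Number of isotopologues (>= 1); the parent species is always
#'   included first.
#' @param noise_sigma Gaussian noise on the constants, MHz.
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `structure`, `isotopologues`
#'   (named list of override vectors), and `observations` (tibble with `iso`,
#'   `axis`, `B0`, `sigma`, `dvib`, `B_exact`).
#' @export
synth_study <- function(sd, n_iso, noise_sigma = 0.05, seed = 1) {
  stopifnot(n_iso >= 1)
  geom <- build_cartesian(sd)
  subst <- c(H = 2L, C = 13L, N = 15L, O = 18L, S = 34L)
  eligible <- sd$atoms$label[sd$atoms$element %in% names(subst)]
  m <- length(eligible)
  # distinct single + double substitution patterns available
  capacity <- m + m * (m - 1L) %/% 2L
  if (n_iso - 1L > capacity) {
    stop("cannot draw ", n_iso - 1L, " distinct isotopologues: only ",
         capacity, " substitution patterns exist for ", m,
         " substitutable atoms", call. = FALSE)
  }
  .with_seed(seed, {
    isos <- list(parent = stats::setNames(integer(), character()))
    while (length(isos) < n_iso) {
      k <- sample(1:2, 1)
      at <- sample(eligible, min(k, length(eligible)))
      ov <- stats::setNames(
        subst[sd$atoms$element[match(at, sd$atoms$label)]], at
      )
      key <- paste(sort(paste0(names(ov), ov)), collapse = "_")
      if (!key %in% names(isos)) isos[[key]] <- ov
    }
    obs <- purrr::imap(isos, function(ov, nm) {
      rc <- rotational_constants(geom, isotopologue_masses(sd, ov))
      B <- c(a = rc$A, b = rc$B, c = rc$C)
      dvib <- -stats::runif(3, 0.001, 0.01) * B
      Bse <- B + stats::rnorm(3, 0, noise_sigma)
      out <- tibble::tibble(
        iso = nm, axis = c("a", "b", "c"),
        B0 = unname(Bse + dvib), sigma = noise_sigma,
        dvib = unname(dvib), B_exact = unname(B)
      )
      out[!is.na(out$B0), ]
    })
    structure(
      list(structure = sd, isotopologues = isos,
           observations = dplyr::bind_rows(obs),
           noise_sigma = noise_sigma, seed = seed),
      class = "synthetic_study"
    )
  })
}

# evaluate expr under a local RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
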