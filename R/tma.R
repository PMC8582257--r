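# Template-molecule correction (TMA): transfer the semi-experimental minus
# optimized offset of a template fragment's parameter onto the matching
# parameter of the target, r_corr = r_opt + (r_se(TM) - r_opt(TM)).

#' Apply one template correction
#'
#' @param r_opt_target Optimized value of the target parameter.
#' @param r_opt_template Value of the template parameter optimized at the
#'   same level of theory.
#' @param r_se_template Semi-experimental value of the template parameter.
#' @return Corrected target value (exact arithmetic).
#' @export
#' @examples
#' apply_tma_value(1.500, 1.520, 1.510)  # 1.490
apply_tma_value <- function(r_opt_target, r_opt_template, r_se_template) {
  r_opt_target + (r_se_template - r_opt_template)
}

#' Build a template library
#'
#' A template library is a tibble with one row per (template molecule,
#' parameter, level): columns `template_id`, `param_id`, `kind`, `level_tag`,
#' `r_opt`, `r_se`. `as_template_library()` derives one from a bundled
#' [load_fixture()] molecule whose columns include a semi-experimental level.
#'
#' @param fx A `case_fixture` with an `"SE"` level.
#' @param level_tags Optimized levels to expose (default both bundled tags).
#' @return Template library tibble.
#' @export
#' @examples
#' lib <- as_template_library(load_fixture("phenol"))
#' head(lib)
as_template_library <- function(fx, level_tags = c("revDSD", "PW6B95")) {
  if (!"SE" %in% fx$levels) {
    stop("fixture ", fx$id, " has no semi-experimental column", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(fx$params))) {
    p <- fx$params[i, ]
    if (p$kind == "torsion") next
    se <- .value_at(p$values[[1]], "SE")
    if (is.na(se)) next
    for (lt in level_tags) {
      ro <- .value_at(p$values[[1]], lt)
      if (is.na(ro)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        template_id = fx$id, param_id = p$id, kind = p$kind,
        level_tag = lt, r_opt = ro, r_se = se
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Look up a template parameter
#'
#' @param library Template library tibble.
#' @param template_id,param_id,level_tag Row selector.
#' @return One-row tibble; error if absent (a mapped template parameter must
#'   exist at the requested level).
#' @export
lookup_template <- function(library, template_id, param_id, level_tag) {
  hit <- library[library$template_id == template_id &
                   library$param_id == param_id &
                   library$level_tag == level_tag, ]
  if (nrow(hit) == 0) {
    stop("template parameter ", template_id, ":", param_id,
         " not available at level ", level_tag, call. = FALSE)
  }
  hit[1, ]
}

#' Correct a structure by template transfer with LRA fallback
#'
#' Parameters listed in `mapping` are corrected by TMA from their template;
#' unmapped bonds and angles are corrected by LRA when a registry entry
#' exists; everything else (including all torsions) is left unchanged and
#' flagged.
#'
#' @param sd A [structure_def()].
#' @param mapping Tibble with columns `target` (parameter id in `sd`),
#'   `template_id`, `template_param`; may be empty.
#' @param library Template library tibble (see [as_template_library()]).
#' @param level_tag Model-chemistry tag of the target geometry.
#' @param lra_fallback Registry tibble for unmapped parameters, or `NULL` to
#'   leave them unchanged.
#' @return List with `structure` and `report` (as in
#'   [correct_structure_lra()], with `method` of `"TMA"`, `"LRA"` or
#'   `"none"` and the template or class used).
#' @export
correct_structure_tma <- function(sd, mapping, library, level_tag,
                                  lra_fallback = NULL) {
  mapping <- tibble::as_tibble(mapping)
  if (nrow(mapping) > 0) {
    stopifnot(all(c("target", "template_id", "template_param") %in%
                    names(mapping)))
    bad <- setdiff(mapping$target, sd$params$id)
    if (length(bad)) {
      stop("mapping targets not in structure: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(mapping$target)) {
      stop("overlapping assignment: one template parameter per target",
           call. = FALSE)
    }
  }
  elem <- stats::setNames(sd$atoms$element, sd$atoms$label)
  rows <- purrr::pmap(sd$params, function(id, kind, atoms, value) {
    base <- tibble::tibble(id = id, kind = kind, class = NA_character_,
                           original = value, corrected = value,
                           method = "none", template = NA_character_,
                           note = NA_character_)
    if (kind == "torsion") {
      base$note <- "torsion: never corrected"
      return(base)
    }
    m <- if (nrow(mapping)) mapping[mapping$target == id, ] else mapping
    if (nrow(m) == 1) {
      tm <- lookup_template(library, m$template_id, m$template_param,
                            level_tag)
      if (tm$kind != kind) {
        stop("kind mismatch mapping ", id, " to ", m$template_param,
             call. = FALSE)
      }
      base$corrected <- apply_tma_value(value, tm$r_opt, tm$r_se)
      base$method <- "TMA"
      base$template <- paste0(m$template_id, ":", m$template_param)
      return(base)
    }
    if (!is.null(lra_fallback)) {
      els <- unname(elem[atoms])
      entry <- lookup_lra(lra_fallback, kind, els, level_tag)
      if (!is.null(entry)) {
        base$corrected <- apply_lra_value(value, entry)
        base$method <- "LRA"
        base$class <- entry$class
        return(base)
      }
    }
    base$note <- "no parameterization: uncorrected value"
    base
  })
  report <- dplyr::bind_rows(rows)
  corrected <- stats::setNames(report$corrected, report$id)
  list(structure = set_param_values(sd, corrected), report = report)
}

#' Read / write template mappings and libraries
#'
#' JSON records with the tibble's columns.
#'
#' @param path File path.
#' @param x Mapping or library tibble.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @export
read_template_mapping <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' @rdname read_template_mapping
#' @export
write_template_mapping <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname read_template_mapping
#' @export
read_template_library <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' @rdname read_template_mapping
#' @export
write_template_library <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}
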