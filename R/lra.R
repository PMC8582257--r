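# Linear-regression correction (LRA) of optimized bond lengths and valence
# angles: r_corrected = r_opt + (A * r_opt + B), with (A, B) parameterized per
# bond/angle class and model chemistry against a semi-experimental reference
# set. The bundled registry carries the published parameter classes for the
# rev-DSDPBEP86/jun-cc-pV(T+d)Z ("revDSD") and PW6B95/jul-cc-pV(D+d)Z
# ("PW6B95") levels, together with the published deviation statistics (MD,
# MAD, largest negative/positive error) of the bare and corrected functionals.

.lra_rows <- function() {
  # class, kind, vertex, ends, level, n, A, B, fixed ("B","AB",""),
  # bare: md neg pos mad ; corrected: md neg pos mad
  L <- list(
    list("CC",  "bond", NA, c("C","C"), "revDSD", 115, -0.00184, 0, "B",
         c(0.0026, -0.0046, 0.0081, 0.0028), c(-0.00002, -0.0072, 0.0056, 0.0013)),
    list("CC",  "bond", NA, c("C","C"), "PW6B95", 115, 0.00014, 0, "B",
         c(-0.0001, -0.0064, 0.0072, 0.0018), c(-0.00006, -0.0062, 0.0073, 0.0018)),
    list("CH",  "bond", NA, c("C","H"), "revDSD", 162, -0.00239, 0, "B",
         c(0.0026, -0.0018, 0.0054, 0.0026), c(-5e-06, -0.0044, 0.0028, 0.00059)),
    list("CH",  "bond", NA, c("C","H"), "PW6B95", 162, -0.00586, 0, "B",
         c(0.0064, NA, 0.0095, 0.0064), c(-4e-06, -0.0042, 0.0030, 0.00084)),
    list("CO",  "bond", NA, c("C","O"), "revDSD", 48, -0.00297, 0, "B",
         c(0.0038, NA, 0.0058, 0.0038), c(4e-05, -0.0031, 0.0022, 0.00070)),
    list("CO",  "bond", NA, c("C","O"), "PW6B95", 48, 0.01708, -0.0212, "",
         c(-0.00050, -0.0070, 0.0034, 0.0020), c(3e-05, -0.0039, 0.0029, 0.0013)),
    list("CN",  "bond", NA, c("C","N"), "revDSD", 39, -0.00234, 0, "B",
         c(0.0031, -0.00027, 0.0069, 0.0032), c(3e-05, -0.0034, 0.0038, 0.0013)),
    list("CN",  "bond", NA, c("C","N"), "PW6B95", 39, 0.01705, -0.02079, "",
         c(-0.0017, -0.0082, 0.0039, 0.0026), c(0.00013, -0.0056, 0.0056, 0.0019)),
    list("CS",  "bond", NA, c("C","S"), "revDSD", 18, -0.01222, 0.01672, "",
         c(0.0042, NA, 0.0088, 0.0041), c(2e-06, -0.0030, 0.0033, 0.0012)),
    list("CS",  "bond", NA, c("C","S"), "PW6B95", 18, -0.01296, 0.02188, "",
         c(0.00020, -0.0050, 0.0071, 0.0019), c(7e-06, -0.0041, 0.0060, 0.0017)),
    list("CF",  "bond", NA, c("C","F"), "revDSD", 8, -0.00307, 0, "B",
         c(0.0041, NA, 0.0052, 0.0041), c(1e-06, -0.0012, 0.0011, 0.00067)),
    list("CF",  "bond", NA, c("C","F"), "PW6B95", 8, -0.00598, 0, "B",
         c(0.0081, NA, 0.0093, 0.0081), c(-8e-06, -0.0017, 0.0013, 0.00091)),
    list("CCl", "bond", NA, c("C","Cl"), "revDSD", 7, -0.0043, 0, "B",
         c(0.0075, NA, 0.0091, 0.0075), c(-1e-05, -0.0028, 0.0015, 0.0010)),
    list("CCl", "bond", NA, c("C","Cl"), "PW6B95", 7, -0.0014, 0, "B",
         c(0.0024, NA, 0.0037, 0.0024), c(-7e-06, -0.0023, 0.0012, 0.00075)),
    list("NH",  "bond", NA, c("N","H"), "revDSD", 14, -0.00216, 0, "B",
         c(0.0022, -0.0020, 0.0048, 0.0025), c(4e-06, -0.0042, 0.0026, 0.0011)),
    list("NH",  "bond", NA, c("N","H"), "PW6B95", 14, -0.00331, 0, "B",
         c(0.0034, NA, 0.0067, 0.0034), c(-8e-06, -0.0031, 0.0032, 0.0011)),
    list("OH",  "bond", NA, c("O","H"), "revDSD", 9, 0.24674, -0.24091, "",
         c(0.0033, NA, 0.0040, 0.0033), c(3e-06, -0.00094, 0.00054, 0.00038)),
    list("OH",  "bond", NA, c("O","H"), "PW6B95", 9, 0.17529, -0.17005, "",
         c(0.0015, NA, 0.0025, 0.0015), c(-8e-06, -0.00098, 0.00069, 0.00030)),
    list("CCH", "angle", "C", c("C","H"), "revDSD", 159, -0.00001, 0, "B",
         c(0.001, -1.21, 1.48, 0.16), c(-6e-05, -1.22, 1.48, 0.16)),
    list("CCH", "angle", "C", c("C","H"), "PW6B95", 159, -0.00027, 0, "B",
         c(0.032, -1.21, 1.51, 0.18), c(-8e-04, -1.24, 1.48, 0.18)),
    list("HCH", "angle", "C", c("H","H"), "revDSD", 54, 0.01695, -1.77589, "",
         c(-0.15, -0.58, 0.33, 0.17), c(4e-04, -0.39, 0.37, 0.09)),
    list("HCH", "angle", "C", c("H","H"), "PW6B95", 54, 0.02077, -2.01637, "",
         c(-0.33, -0.90, 0.35, 0.38), c(-2e-04, -0.64, 0.70, 0.22)),
    list("OCO", "angle", "C", c("O","O"), "revDSD", 7, -0.06709, 8.1676, "",
         c(0.12, -0.03, 0.25, 0.13), c(-4e-04, -0.05, 0.08, 0.03)),
    list("OCO", "angle", "C", c("O","O"), "PW6B95", 7, 0.00063, 0, "B",
         c(-0.08, -0.30, 0.11, 0.13), c(-9e-05, -0.22, 0.19, 0.10)),
    list("HCN", "angle", "C", c("H","N"), "revDSD", 31, -0.00003, 0, "B",
         c(0.005, -0.62, 0.33, 0.16), c(-9e-04, -0.63, 0.33, 0.16)),
    list("HCN", "angle", "C", c("H","N"), "PW6B95", 31, -0.0014, 0, "B",
         c(0.17, -0.39, 0.59, 0.22), c(-2e-04, -0.57, 0.42, 0.15)),
    list("COH", "angle", "O", c("C","H"), "revDSD", 8, 0, 0, "AB",
         c(-0.011, -0.20, 0.12, 0.09), c(NA, NA, NA, NA)),
    list("COH", "angle", "O", c("C","H"), "PW6B95", 8, -0.16466, 17.43968, "",
         c(0.31, -0.08, 0.66, 0.34), c(-4e-04, -0.15, 0.23, 0.09))
  )
  dplyr::bind_rows(lapply(L, function(x) {
    tibble::tibble(
      class = x[[1]], kind = x[[2]], vertex = x[[3]],
      end1 = sort(x[[4]])[1], end2 = sort(x[[4]])[2],
      level_tag = x[[5]], n = x[[6]], A = x[[7]], B = x[[8]],
      fixed_zero = x[[9]],
      bare_md = x[[10]][1], bare_neg = x[[10]][2], bare_pos = x[[10]][3],
      bare_mad = x[[10]][4],
      md = x[[11]][1], neg = x[[11]][2], pos = x[[11]][3], mad = x[[11]][4]
    )
  }))
}

#' Bundled LRA parameter registry
#'
#' @return Tibble with one row per (parameter class, level), columns
#'   `class`, `kind`, `vertex`, `end1`, `end2`, `level_tag`, `n`, `A`, `B`,
#'   `fixed_zero` (which of A/B were constrained to zero in the published
#'   fit), and deviation statistics of the bare (`bare_*`) and corrected
#'   functionals (MD, largest negative/positive error, MAD; Angstrom for
#'   bonds, degrees for angles).
#' @export
#' @examples
#' dplyr::filter(lra_registry(), class == "CS")
lra_registry <- function() .lra_rows()

#' Canonical LRA key
#'
#' Bonds use the unordered element pair; angles the vertex element plus the
#' unordered pair of end elements (so C-O-H and H-C-N parameterizations stay
#' distinct by vertex).
#'
#' @param kind `"bond"` or `"angle"`.
#' @param elements Elements of the coordinate's atoms in order (2 for a bond,
#'   3 for an angle with the vertex in the middle).
#' @return Canonical key string.
#' @export
lra_key <- function(kind, elements) {
  if (kind == "bond") {
    paste(sort(elements), collapse = "|")
  } else if (kind == "angle") {
    ends <- sort(elements[c(1, 3)])
    paste(ends[1], elements[2], ends[2], sep = "|")
  } else {
    stop("no LRA key for kind ", kind, call. = FALSE)
  }
}

#' Look up an LRA entry
#'
#' Exact canonical-key match; a missing class returns `NULL` (never a
#' fallback across element classes).
#'
#' @param registry Registry tibble as from [lra_registry()].
#' @param kind `"bond"` or `"angle"`.
#' @param elements Element vector (see [lra_key()]).
#' @param level_tag Model-chemistry tag (`"revDSD"` or `"PW6B95"` for the
#'   bundled registry).
#' @return One-row tibble or `NULL` if absent.
#' @export
#' @examples
#' lookup_lra(lra_registry(), "bond", c("S", "C"), "revDSD")$A  # -0.01222
lookup_lra <- function(registry, kind, elements, level_tag) {
  key <- lra_key(kind, elements)
  keys <- vapply(seq_len(nrow(registry)), function(i) {
    if (registry$kind[i] == "bond") {
      paste(sort(c(registry$end1[i], registry$end2[i])), collapse = "|")
    } else {
      paste(registry$end1[i], registry$vertex[i], registry$end2[i], sep = "|")
    }
  }, "")
  hit <- which(keys == key & registry$kind == kind &
                 registry$level_tag == level_tag)
  if (length(hit) == 0) return(NULL)
  registry[hit[1], ]
}

#' Apply one LRA correction
#'
#' Returns \code{r + (A r + B)}. The correction is added: this is the
#' convention that reproduces the published corrected structures (see the
#' methods vignette for the sign-convention discussion).
#'
#' @param r_opt Optimized value (Angstrom or degrees).
#' @param entry One-row registry tibble (or any list with `A` and `B`).
#' @return Corrected value.
#' @export
#' @examples
#' apply_lra_value(1.8201, list(A = -0.01222, B = 0.01672))  # 1.8146
apply_lra_value <- function(r_opt, entry) {
  r_opt + (entry$A * r_opt + entry$B)
}

#' Correct a structure's bonds and angles by LRA
#'
#' Every bond and valence angle whose element class has a registry entry at
#' `level_tag` is corrected by \code{r + (A r + B)}; torsions are never
#' corrected; parameters without an entry are left unchanged and flagged.
#'
#' @param sd A [structure_def()].
#' @param registry Registry tibble; defaults to the bundled one.
#' @param level_tag Model-chemistry tag of the input geometry.
#' @return List with `structure` (corrected [structure_def()]) and `report`
#'   (tibble: `id`, `kind`, `class`, `original`, `corrected`, `method`,
#'   `note`).
#' @export
correct_structure_lra <- function(sd, registry = lra_registry(), level_tag) {
  elem <- stats::setNames(sd$atoms$element, sd$atoms$label)
  rows <- purrr::pmap(sd$params, function(id, kind, atoms, value) {
    if (kind == "torsion") {
      return(tibble::tibble(id = id, kind = kind, class = NA_character_,
                            original = value, corrected = value,
                            method = "none", note = "torsion: never corrected"))
    }
    els <- unname(elem[atoms])
    entry <- lookup_lra(registry, kind, els, level_tag)
    if (is.null(entry)) {
      return(tibble::tibble(id = id, kind = kind,
                            class = paste(els, collapse = ""),
                            original = value, corrected = value,
                            method = "none",
                            note = "no parameterization: uncorrected value"))
    }
    tibble::tibble(id = id, kind = kind, class = entry$class,
                   original = value,
                   corrected = apply_lra_value(value, entry),
                   method = "LRA", note = NA_character_)
  })
  report <- dplyr::bind_rows(rows)
  corrected <- report$corrected
  names(corrected) <- report$id
  list(structure = set_param_values(sd, corrected), report = report)
}

#' Fit LRA parameters from (optimized, semi-experimental) pairs
#'
#' Ordinary least squares of the deviation \code{r_se - r_opt} on
#' \code{r_opt}; with `fix_intercept`, B is constrained to 0. Residual
#' statistics are those of the corrected values against the reference.
#'
#' @param pairs Data frame with columns `r_opt` and `r_se`.
#' @param fix_intercept Constrain the intercept to zero.
#' @param conf_level Confidence level for the parameter intervals.
#' @return An `lra_fit`: list with `A`, `B`, `n`, standard errors,
#'   confidence intervals, residual stats (`md`, `mad`, `neg`, `pos`) and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' p <- data.frame(r_opt = c(1.0, 1.2, 1.4), r_se = c(1.001, 1.2022, 1.4034))
#' fit_lra_parameters(p)$A
fit_lra_parameters <- function(pairs, fix_intercept = FALSE,
                               conf_level = 0.95) {
  stopifnot(all(c("r_opt", "r_se") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < (if (fix_intercept) 1 else 2)) {
    stop("need at least ", if (fix_intercept) 1 else 2, " pairs", call. = FALSE)
  }
  if (!fix_intercept && stats::sd(pairs$r_opt) == 0) {
    stop("degenerate design: all r_opt equal with a free intercept",
         call. = FALSE)
  }
  d <- data.frame(r_opt = pairs$r_opt, delta = pairs$r_se - pairs$r_opt)
  fit <- if (fix_intercept) {
    stats::lm(delta ~ 0 + r_opt, data = d)
  } else {
    stats::lm(delta ~ r_opt, data = d)
  }
  co <- stats::coef(fit)
  A <- unname(co[["r_opt"]])
  B <- if (fix_intercept) 0 else unname(co[["(Intercept)"]])
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- tryCatch(suppressMessages(stats::confint(fit, level = conf_level)),
                 error = function(e) NULL)
  resid <- d$delta - (A * d$r_opt + B)
  structure(
    list(
      A = A, B = B, n = n, fix_intercept = fix_intercept,
      se_A = unname(se[["r_opt"]]),
      se_B = if (fix_intercept) 0 else unname(se[["(Intercept)"]]),
      conf_level = conf_level, conf_int = ci,
      md = mean(resid), mad = mean(abs(resid)),
      neg = min(resid), pos = max(resid),
      pairs = tibble::as_tibble(pairs), lm = fit
    ),
    class = "lra_fit"
  )
}

#' @export
print.lra_fit <- function(x, ...) {
  cat(sprintf("<lra_fit> n = %d: A = %.5f (se %.2g), B = %.5f%s\n",
              x$n, x$A, x$se_A, x$B,
              if (x$fix_intercept) " (fixed)" else sprintf(" (se %.2g)", x$se_B)))
  cat(sprintf("  corrected residuals: MD %.2g, MAD %.2g, range [%.2g, %.2g]\n",
              x$md, x$mad, x$neg, x$pos))
  invisible(x)
}

#' Read / write an LRA registry file
#'
#' JSON (a list of records) or CSV with the registry columns.
#'
#' @param path File path; format chosen by extension.
#' @param registry Registry tibble.
#' @return `read_lra_registry()` returns the registry tibble.
#' @export
read_lra_registry <- function(path) {
  tab <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  tab
}

#' @rdname read_lra_registry
#' @export
write_lra_registry <- function(registry, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(registry, path, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    utils::write.csv(registry, path, row.names = FALSE)
  }
  invisible(path)
}
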