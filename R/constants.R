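# Physical constants (CODATA 2018, SI-exact where applicable) and the bundled
# isotopic mass table.

#' Rotational conversion constant
#'
#' Returns \eqn{K = h / (8 \pi^2)} expressed in MHz amu \eqn{\AA^2}, so that a
#' rotational constant in MHz is \code{K / I} with the principal moment of
#' inertia \code{I} in amu \eqn{\AA^2}. Computed from the SI-exact Planck
#' constant and the 2018 CODATA atomic mass constant, never hard-coded.
#'
#' @return A single numeric, about 505379 MHz amu \eqn{\AA^2}.
#' @export
#' @examples
#' rotational_constant_K()
rotational_constant_K <- function() {
  h <- 6.62607015e-34          # J s, exact
  u <- 1.66053906660e-27       # kg, CODATA 2018
  # I [kg m^2] = I [amu A^2] * u * 1e-20 ; B [Hz] = h / (8 pi^2 I)
  h / (8 * pi^2 * u * 1e-20) / 1e6
}

# Isotopic masses in unified amu (AME2020 evaluation, truncated to ~1e-8 amu)
# and terrestrial most-abundant mass numbers. Elements limited to those the
# package's structural scope covers (H, B, C, N, O, F, P, S, Cl).
.isotope_masses <- list(
  H  = c(`1` = 1.00782503207, `2` = 2.01410177785, `3` = 3.01604928199),
  B  = c(`10` = 10.01293695, `11` = 11.00930536),
  C  = c(`12` = 12.0, `13` = 13.00335483507, `14` = 14.003241988),
  N  = c(`14` = 14.00307400443, `15` = 15.00010889888),
  O  = c(`16` = 15.99491461957, `17` = 16.99913175650, `18` = 17.99915961286),
  F  = c(`19` = 18.99840316273),
  P  = c(`31` = 30.97376199842),
  S  = c(`32` = 31.9720711744, `33` = 32.9714589098, `34` = 33.967867004,
         `36` = 35.96708071),
  Cl = c(`35` = 34.968852682, `37` = 36.965902602)
)

.most_abundant <- c(H = 1L, B = 11L, C = 12L, N = 14L, O = 16L, F = 19L,
                    P = 31L, S = 32L, Cl = 35L)

#' Bundled isotope mass table
#'
#' @return A tibble with columns \code{element}, \code{mass_number},
#'   \code{mass} (amu) and \code{most_abundant} (logical).
#' @export
isotope_masses <- function() {
  rows <- purrr::imap(.isotope_masses, function(m, el) {
    tibble::tibble(
      element = el,
      mass_number = as.integer(names(m)),
      mass = unname(m),
      most_abundant = as.integer(names(m)) == .most_abundant[[el]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Look up the mass of one isotope
#'
#' @param element Chemical symbol (e.g. \code{"C"}).
#' @param mass_number Integer mass number, or \code{NULL} for the
#'   most-abundant isotope.
#' @return Mass in unified amu.
#' @export
#' @examples
#' isotope_mass("C")       # 12
#' isotope_mass("H", 2)    # deuterium
isotope_mass <- function(element, mass_number = NULL) {
  tab <- .isotope_masses[[element]]
  if (is.null(tab)) {
    stop("unknown element: ", element, call. = FALSE)
  }
  if (is.null(mass_number)) {
    mass_number <- .most_abundant[[element]]
  }
  m <- tab[as.character(mass_number)]
  if (is.na(m)) {
    stop("no bundled mass for ", element, "-", mass_number, call. = FALSE)
  }
  unname(m)
}
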