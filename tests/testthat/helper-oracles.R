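# Shared helpers and independent oracles.

# geometry with explicit coordinates, bypassing the builder
make_geom <- function(labels, elements, xyz) {
  rownames(xyz) <- labels
  colnames(xyz) <- c("x", "y", "z")
  structure(list(atoms = tibble::tibble(label = labels, element = elements),
                 xyz = xyz),
            class = "cartesian_geom")
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# closed-form OLS of (r_se - r_opt) on r_opt via normal equations
ols_oracle <- function(r_opt, r_se, fix_intercept = FALSE) {
  d <- r_se - r_opt
  if (fix_intercept) {
    list(A = sum(r_opt * d) / sum(r_opt^2), B = 0)
  } else {
    X <- cbind(1, r_opt)
    beta <- solve(t(X) %*% X, t(X) %*% d)
    list(A = beta[2], B = beta[1])
  }
}

# small rigid test molecule (non-planar, 5 atoms) for refinement tests
refit_molecule <- function() {
  atoms <- tibble::tibble(label = c("C1", "O2", "N3", "H4", "H5"),
                          element = c("C", "O", "N", "H", "H"))
  structure_def(atoms, list(
    place_step("C1", "C"),
    place_step("O2", "O", dist = list("C1", 1.21)),
    place_step("N3", "N", dist = list("C1", 1.36), ang = list("O2", 123.5)),
    place_step("H4", "H", dist = list("N3", 1.01), ang = list("C1", 119.0),
               tors = list(c("H4", "N3", "C1", "O2"), 14.0)),
    place_step("H5", "H", dist = list("C1", 1.10), ang = list("O2", 121.0),
               tors = list(c("H5", "C1", "O2", "N3"), 175.0))
  ))
}

# observations tibble (exact or noisy) for a structure over isotopologues
exact_observations <- function(sd, isos, sigma = 0, noise = 0) {
  obs <- predict_observables(sd, isos)
  obs <- obs[!is.na(obs$B_MHz), ]
  tibble::tibble(iso = obs$iso, axis = obs$axis,
                 B_se = obs$B_MHz + stats::rnorm(nrow(obs), 0, noise),
                 sigma = sigma)
}

five_isotopologues <- function() {
  list(parent = c(),
       d4 = c(H4 = 2L), d5 = c(H5 = 2L),
       c13 = c(C1 = 13L), o18 = c(O2 = 18L), n15 = c(N3 = 15L))
}
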