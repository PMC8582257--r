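# Internal-coordinate engine: construction, measurement, symmetry, inertia.

test_that("canonical frame and closed-form diatomic constants", {
  sd <- structure_def(
    tibble::tibble(label = c("H1", "H2"), element = c("H", "H")),
    list(place_step("H1", "H"), place_step("H2", "H", dist = list("H1", 1.0)))
  )
  g <- build_cartesian(sd)
  expect_equal(unname(g$xyz[1, ]), c(0, 0, 0))
  expect_equal(unname(g$xyz[2, ]), c(0, 0, 1.0))
  rc <- rotational_constants(g)
  mu <- isotope_mass("H") / 2
  expect_true(rc$degenerate)
  expect_true(is.na(rc$A))
  expect_equal(rc$B, rotational_constant_K() / mu, tolerance = 1e-12)
  expect_equal(rc$B, rc$C, tolerance = 1e-12)
})

test_that("angles and torsions measure with the documented conventions", {
  # equilateral triangle, side 1
  tri <- make_geom(c("A", "B", "C"), rep("C", 3),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  for (perm in list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"))) {
    expect_equal(measure_internal(tri, "angle", perm), 60, tolerance = 1e-12)
  }
  # cis planar arrangement: torsion exactly 0
  cis <- make_geom(paste0("A", 1:4), rep("C", 4),
                   rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0), c(1, -1, 0)))
  expect_equal(measure_internal(cis, "torsion", paste0("A", 1:4)), 0,
               tolerance = 1e-12)
  # reversal of the four atoms preserves the signed value
  sd <- synth_molecule(5, 6)
  g <- build_cartesian(sd)
  tors <- sd$params[sd$params$kind == "torsion", ]
  for (a in tors$atoms) {
    expect_equal(measure_internal(g, "torsion", a),
                 measure_internal(g, "torsion", rev(a)), tolerance = 1e-10)
  }
})

test_that("build/measure round trip holds on random tree structures", {
  for (seed in 1:100) {
    sd <- synth_molecule(seed, sample(4:9, 1))
    m <- measure_structure(sd)
    expect_lt(max(abs(m$value - m$measured)), 1e-8)
  }
})

test_that("improper and reversed-axis torsion placements round-trip", {
  # placed atom last in the stored tuple, and a dihedral whose middle pair is
  # the (angle-ref, dist-ref) axis reversed -- both used by bundled fixtures
  sd <- structure_def(
    tibble::tibble(label = paste0("C", 1:5), element = rep("C", 5)),
    list(
      place_step("C1", "C"),
      place_step("C2", "C", dist = list("C1", 1.5)),
      place_step("C3", "C", dist = list("C2", 1.4), ang = list("C1", 112)),
      place_step("C4", "C", dist = list("C3", 1.3), ang = list("C2", 118),
                 tors = list(c("C1", "C2", "C3", "C4"), -55.5)),
      # dihedral about the (ang-ref -> dist-ref) axis, like O5C4C3O7
      place_step("C5", "C", dist = list("C3", 1.2), ang = list("C4", 105),
                 tors = list(c("C2", "C4", "C3", "C5"), -170.25))
    )
  )
  m <- measure_structure(sd)
  expect_lt(max(abs(m$value - m$measured)), 1e-8)
})

test_that("rotational constants are invariant under rigid motions", {
  set.seed(42)
  sd <- synth_molecule(7, 8)
  g <- build_cartesian(sd)
  rc0 <- rotational_constants(g)
  for (i in 1:10) {
    g2 <- g
    g2$xyz <- g$xyz %*% random_rotation() +
      matrix(rep(stats::rnorm(3, 0, 10), each = nrow(g$xyz)), ncol = 3)
    rc <- rotational_constants(g2)
    expect_equal(rc$A, rc0$A, tolerance = 1e-9)
    expect_equal(rc$B, rc0$B, tolerance = 1e-9)
    expect_equal(rc$C, rc0$C, tolerance = 1e-9)
  }
})

test_that("constant-moment product equals K on every axis", {
  K <- rotational_constant_K()
  for (seed in c(3, 11, 19)) {
    rc <- rotational_constants(build_cartesian(synth_molecule(seed, 7)))
    expect_equal(rc$A * rc$Ia, K, tolerance = 1e-12)
    expect_equal(rc$B * rc$Ib, K, tolerance = 1e-12)
    expect_equal(rc$C * rc$Ic, K, tolerance = 1e-12)
  }
})

test_that("heavier single-atom substitution never decreases any moment", {
  set.seed(5)
  for (seed in 1:20) {
    sd <- synth_molecule(seed, 6)
    g <- build_cartesian(sd)
    m0 <- isotopologue_masses(sd)
    rc0 <- rotational_constants(g, m0)
    lab <- sample(sd$atoms$label, 1)
    m1 <- m0
    m1[[lab]] <- m1[[lab]] + stats::runif(1, 0.5, 2)
    rc1 <- rotational_constants(g, m1)
    expect_gte(rc1$Ia - rc0$Ia, -1e-10)
    expect_gte(rc1$Ib - rc0$Ib, -1e-10)
    expect_gte(rc1$Ic - rc0$Ic, -1e-10)
  }
})

test_that("mirror completion reflects through the atom-defined plane", {
  g <- make_geom(c("P1", "P2", "P3", "X"), c("C", "C", "C", "H"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 1, 0)))
  g2 <- complete_by_symmetry(g, c("P1", "P2", "P3"), c(X = "Y"))
  expect_equal(unname(g2$xyz["Y", ]), c(1, -1, 0), tolerance = 1e-12)
  expect_equal(g2$atoms$element[g2$atoms$label == "Y"], "H")
  # a source lying in the plane is its own image
  g3 <- complete_by_symmetry(g, c("P1", "P2", "P3"), c(P2 = "Q"))
  expect_lt(max(abs(g3$xyz["Q", ] - g3$xyz["P2", ])), 1e-12)
  # collinear plane is rejected
  gbad <- make_geom(c("A", "B", "C"), rep("C", 3),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(complete_by_symmetry(gbad, c("A", "B", "C"), c(A = "Z")),
               "collinear")
})

test_that("isotopologue masses: defaults, locality, table lookups", {
  sd <- refit_molecule()
  m <- isotopologue_masses(sd)
  expect_equal(unname(m["C1"]), 12.0)
  expect_equal(unname(m["O2"]), isotope_mass("O", 16))
  m2 <- isotopologue_masses(sd, c(H4 = 2L))
  expect_equal(m2[names(m2) != "H4"], m[names(m) != "H4"])
  expect_equal(unname(m2["H4"]), isotope_mass("H", 2))
  # published atomic-mass-evaluation spot values
  expect_equal(isotope_mass("C", 13), 13.00335483507, tolerance = 1e-10)
  expect_equal(isotope_mass("O", 18), 17.99915961286, tolerance = 1e-10)
  expect_error(isotopologue_masses(sd, c(Zz9 = 2L)), "unknown atom label")
  expect_error(isotope_mass("C", 11), "no bundled mass")
})

test_that("inertia defect: planar zero, pyramidal negative", {
  # planar: any geometry with all z = 0
  set.seed(8)
  xy <- cbind(matrix(stats::rnorm(10), 5), 0)
  g <- make_geom(paste0("C", 1:5), rep("C", 5), xy)
  expect_lt(abs(inertia_defect(rotational_constants(g))), 1e-8)
  # tetrahedral methane-like: negative defect
  t <- 1.09 / sqrt(3)
  gm <- make_geom(c("C1", "H1", "H2", "H3", "H4"), c("C", rep("H", 4)),
                  rbind(c(0, 0, 0), c(t, t, t), c(t, -t, -t),
                        c(-t, t, -t), c(-t, -t, t)))
  expect_lt(inertia_defect(rotational_constants(gm)), 0)
})

test_that("structure validation rejects malformed definitions", {
  atoms <- tibble::tibble(label = c("C1", "C2"), element = c("C", "C"))
  expect_error(structure_def(atoms, list(
    place_step("C1", "C"), place_step("C2", "C", dist = list("C1", -1))
  )), "non-positive bond")
  expect_error(structure_def(
    tibble::tibble(label = c("C1", "C1"), element = c("C", "C")),
    list(place_step("C1", "C"), place_step("C1", "C", dist = list("C1", 1)))
  ), "unique")
  expect_error(structure_def(
    tibble::tibble(label = "X1", element = "Xx"), list(place_step("X1", "Xx"))
  ), "unrecognized element")
  expect_error(structure_def(atoms, list(
    place_step("C1", "C"), place_step("C2", "C", dist = list("C9", 1.0))
  )), "unresolvable reference")
})
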