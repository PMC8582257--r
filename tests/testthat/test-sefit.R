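# Semi-experimental constants and weighted nonlinear refinement.

test_that("semi-experimental constants subtract vibrational contributions", {
  expect_equal(se_constant(1000.0, 0)$B_se, 1000.0)
  # ground-state minus (negative) vibrational contribution
  expect_equal(se_constant(3071.437, -29.267)$B_se, 3100.704)
  # exact inverse
  b0 <- c(5000.1, 1234.5)
  dv <- c(-12.3, 4.5)
  expect_identical(se_constant(b0, dv)$B_se + dv, b0)
  expect_error(se_constant(c(1, 2), 0), "length")
})

test_that("forward model agrees with direct computation and mass ordering", {
  sd <- refit_molecule()
  pred <- predict_observables(sd, list(parent = c()))
  rc <- rotational_constants(build_cartesian(sd))
  expect_equal(pred$B_MHz, c(rc$A, rc$B, rc$C), tolerance = 1e-12)
  expect_equal(pred$I_amuA2, c(rc$Ia, rc$Ib, rc$Ic), tolerance = 1e-12)
  # deuteration lowers each constant or leaves it unchanged
  pd <- predict_observables(sd, list(parent = c(), d = c(H4 = 2L)))
  par <- pd[pd$iso == "parent", ]
  deu <- pd[pd$iso == "d", ]
  expect_true(all(deu$B_MHz <= par$B_MHz + 1e-10))
  # brute-force oracle: constants from an explicitly mass-weighted rebuild
  ov <- c(H4 = 2L, O2 = 18L)
  rc2 <- rotational_constants(build_cartesian(sd),
                              isotopologue_masses(sd, ov))
  p2 <- predict_observables(sd, list(x = ov))
  expect_equal(p2$B_MHz, c(rc2$A, rc2$B, rc2$C), tolerance = 1e-12)
})

test_that("zero-noise synthetic data is recovered to machine precision", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  obs <- exact_observations(sd_true, isos)
  free <- c("C1O2", "C1N3", "O2C1N3", "H4N3C1O2")
  truth <- sd_true$params$value[match(free, sd_true$params$id)]
  guess <- truth + c(0.008, -0.006, 0.9, -0.8)
  fs <- fit_spec(set_param_values(sd_true, stats::setNames(guess, free)),
                 free, obs, isos)
  res <- fit_structure(fs)
  expect_true(res$converged)
  expect_lt(max(abs(res$values - truth)), 1e-6)
  expect_lt(res$rms, 1e-10)
  # tidy/glance accessors
  expect_equal(generics::tidy(res)$term, free)
  expect_equal(generics::glance(res)$n_obs, nrow(obs))
})

test_that("a vanishing-sigma predicate pins its parameter", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  set.seed(31)
  obs <- exact_observations(sd_true, isos, sigma = 0.05, noise = 0.05)
  free <- c("C1O2", "C1N3")
  target <- 1.2154321
  fs <- fit_spec(sd_true, free, obs, isos,
                 predicates = tibble::tibble(param = "C1O2", value = target,
                                             sigma = 1e-10))
  res <- fit_structure(fs)
  expect_lt(abs(res$values[["C1O2"]] - target), 1e-8)
})

test_that("fixing a parameter equals an infinite-weight predicate", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  set.seed(32)
  obs <- exact_observations(sd_true, isos, sigma = 0.05, noise = 0.05)
  fixed_val <- sd_true$params$value[sd_true$params$id == "C1N3"]
  res_fixed <- fit_structure(fit_spec(sd_true, c("C1O2", "O2C1N3"), obs, isos))
  res_pred <- fit_structure(fit_spec(
    sd_true, c("C1O2", "O2C1N3", "C1N3"), obs, isos,
    predicates = tibble::tibble(param = "C1N3", value = fixed_val,
                                sigma = 1e-9)
  ))
  expect_lt(abs(res_fixed$values[["C1O2"]] - res_pred$values[["C1O2"]]), 1e-6)
  expect_lt(abs(res_fixed$values[["O2C1N3"]] - res_pred$values[["O2C1N3"]]),
            1e-6)
})

test_that("shrinking a predicate sigma moves the estimate monotonically", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  set.seed(33)
  obs <- exact_observations(sd_true, isos, sigma = 0.05, noise = 0.05)
  target <- 1.225  # away from both truth and the data optimum
  prev <- NULL
  dists <- c()
  for (sig in c(0.05, 0.01, 0.002, 1e-4, 1e-7)) {
    res <- fit_structure(fit_spec(
      sd_true, "C1O2", obs, isos,
      predicates = tibble::tibble(param = "C1O2", value = target, sigma = sig)
    ))
    dists <- c(dists, abs(res$values[["C1O2"]] - target))
  }
  expect_true(all(diff(dists) <= 1e-12))
})

test_that("down-weighting scales contributions and removes in the limit", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  set.seed(34)
  obs <- exact_observations(sd_true, isos, sigma = 0.05, noise = 0.05)
  fs <- fit_spec(sd_true, c("C1O2", "C1N3"), obs, isos)
  # factor 1 is a no-op
  expect_equal(down_weight(fs, "d4", 1)$observations, fs$observations)
  # weight scales by 1/factor^2, so the objective contribution halves when
  # the weight is halved (factor sqrt(2))
  r0 <- nanolego:::.sefit_residuals(fs, fs$structure$params$value[
    match(fs$free, fs$structure$params$id)])
  fs2 <- down_weight(fs, "d4", sqrt(2))
  r2 <- nanolego:::.sefit_residuals(fs2, fs$structure$params$value[
    match(fs$free, fs$structure$params$id)])
  sel <- fs$observations$iso == "d4"
  expect_equal(sum(r2[sel]^2), sum(r0[sel]^2) / 2, tolerance = 1e-10)
  # factor -> infinity reproduces the fit without the isotopologue
  res_dw <- fit_structure(down_weight(fs, "d4", 1e8))
  fs_wo <- fit_spec(sd_true, c("C1O2", "C1N3"),
                    obs[obs$iso != "d4", ], isos[names(isos) != "d4"])
  res_wo <- fit_structure(fs_wo)
  expect_lt(max(abs(res_dw$values - res_wo$values)), 1e-8)
  expect_error(down_weight(fs, "nope", 2), "unknown isotopologue")
})

test_that("reported uncertainties scale linearly with injected noise", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  free <- c("C1O2", "C1N3")
  sd_at <- function(noise, seeds) {
    sds <- sapply(seeds, function(s) {
      set.seed(s)
      obs <- exact_observations(sd_true, isos, sigma = noise, noise = noise)
      fit_structure(fit_spec(sd_true, free, obs, isos))$sd
    })
    rowMeans(sds)
  }
  s1 <- sd_at(0.02, 1:12)
  s2 <- sd_at(0.08, 1:12)
  ratio <- s2 / s1
  expect_true(all(ratio > 2.5 & ratio < 5.5))  # nominal 4, simulation error
})

test_that("the refinement matches an independent Levenberg-Marquardt solver", {
  sd_true <- refit_molecule()
  isos <- five_isotopologues()
  set.seed(35)
  obs <- exact_observations(sd_true, isos, sigma = 0.05, noise = 0.05)
  free <- c("C1O2", "C1N3", "O2C1N3")
  truth <- sd_true$params$value[match(free, sd_true$params$id)]
  guess <- stats::setNames(truth + c(0.006, -0.007, 0.6), free)
  sd0 <- set_param_values(sd_true, guess)
  fs <- fit_spec(sd0, free, obs, isos)
  res <- fit_structure(fs)
  lm_out <- minpack.lm::nls.lm(
    par = guess,
    fn = function(p) nanolego:::.sefit_residuals(fs, p)
  )
  expect_lt(max(abs(res$values - stats::coef(lm_out))), 1e-6)
})

test_that("degenerate systems are reported as unidentifiable", {
  sd_true <- refit_molecule()
  # a single isotopologue cannot determine four parameters
  obs <- exact_observations(sd_true, list(parent = c()))
  expect_error(
    fit_spec(sd_true, c("C1O2", "C1N3", "O2C1N3", "H4N3C1O2", "N3H4"),
             obs, list(parent = c())),
    "under-determined"
  )
  # duplicating one parameter's role via an exactly collinear pair
  obs2 <- exact_observations(sd_true, list(parent = c(), d = c(H4 = 2L)))
  expect_error(
    {
      fs <- fit_spec(sd_true, c("C1O2", "C1O2"), obs2,
                     list(parent = c(), d = c(H4 = 2L)))
      fit_structure(fs)
    },
    "rank-deficient|duplicate"
  )
})
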