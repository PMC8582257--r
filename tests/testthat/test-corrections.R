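# Regression (LRA) and template (TMA) corrections.

test_that("bundled registry matches the published parameterization", {
  reg <- lra_registry()
  expect_equal(nrow(reg), 28)  # 14 classes x 2 levels
  pick <- function(class, level) reg[reg$class == class &
                                       reg$level_tag == level, ]
  e <- pick("CS", "revDSD")
  expect_equal(e$A, -0.01222)
  expect_equal(e$B, 0.01672)
  expect_equal(e$n, 18)
  expect_equal(pick("CC", "revDSD")$A, -0.00184)
  expect_equal(pick("OH", "PW6B95")$B, -0.17005)
  expect_equal(pick("HCH", "revDSD")$B, -1.77589)
  expect_equal(pick("COH", "PW6B95")$A, -0.16466)
  # fixed-to-zero bookkeeping
  expect_equal(pick("COH", "revDSD")$fixed_zero, "AB")
  expect_equal(pick("CH", "revDSD")$fixed_zero, "B")
  # published corrected-MAD statistics
  expect_equal(pick("CH", "revDSD")$mad, 0.00059)
  expect_equal(pick("CS", "revDSD")$bare_mad, 0.0041)
})

test_that("lookup canonicalizes keys and never falls back across classes", {
  reg <- lra_registry()
  e1 <- lookup_lra(reg, "bond", c("S", "C"), "revDSD")
  e2 <- lookup_lra(reg, "bond", c("C", "S"), "revDSD")
  expect_equal(e1$A, e2$A)
  expect_equal(e1$A, -0.01222)
  # angle keys distinguish the vertex: C-O-H is bundled, O-C-H is not
  expect_false(is.null(lookup_lra(reg, "angle", c("C", "O", "H"), "PW6B95")))
  expect_null(lookup_lra(reg, "angle", c("O", "C", "H"), "PW6B95"))
  expect_null(lookup_lra(reg, "angle", c("C", "S", "H"), "revDSD"))
  expect_null(lookup_lra(reg, "bond", c("S", "H"), "revDSD"))
})

test_that("correction arithmetic reproduces published corrected entries", {
  reg <- lra_registry()
  cases <- list(
    list("bond", c("S", "C"), "revDSD", 1.8201, 1.8146, 2e-4),
    list("bond", c("O", "H"), "revDSD", 0.9808, 0.9819, 2e-4),
    list("bond", c("C", "N"), "revDSD", 1.3615, 1.3583, 2e-4),
    list("bond", c("C", "C"), "revDSD", 1.4064, 1.4038, 2e-4),
    list("bond", c("C", "O"), "PW6B95", 1.3624, 1.3644, 2e-4),
    list("angle", c("C", "O", "H"), "PW6B95", 104.96, 105.11, 0.02)
  )
  for (cs in cases) {
    e <- lookup_lra(reg, cs[[1]], cs[[2]], cs[[3]])
    expect_equal(apply_lra_value(cs[[4]], e), cs[[5]], tolerance = cs[[6]])
  }
  # null correction is the identity
  expect_equal(apply_lra_value(1.234, list(A = 0, B = 0)), 1.234)
})

test_that("structure-level LRA corrects parameterized classes only", {
  fx <- load_fixture("cysteine")
  sd <- fixture_structure(fx, "revDSD")
  res <- correct_structure_lra(sd, lra_registry(), "revDSD")
  rep <- res$report
  expect_equal(nrow(rep), nrow(sd$params))
  expect_setequal(rep$id, sd$params$id)
  # every published corrected bond is reproduced within input rounding
  for (id in c("S1C2", "C2C3", "C3C4", "C4O5", "O5H6", "C4O7", "C3N8",
               "N8H10", "N8H11", "C3H12", "C2H13", "C2H14")) {
    expect_equal(rep$corrected[rep$id == id],
                 param_value(fx, id, "revDSD-LRA"), tolerance = 2e-4,
                 label = id)
  }
  # unparameterized S-H stays put and is flagged
  sh <- rep[rep$id == "S1H9", ]
  expect_equal(sh$corrected, sh$original)
  expect_match(sh$note, "no parameterization")
  # torsions are never corrected
  tors <- rep[rep$kind == "torsion", ]
  expect_true(all(tors$corrected == tors$original))
  expect_true(all(tors$method == "none"))
  # idempotence in report form: empty registry changes nothing further
  empty <- lra_registry()[0, ]
  res2 <- correct_structure_lra(res$structure, empty, "revDSD")
  expect_equal(res2$structure$params$value, res$structure$params$value)
  expect_true(all(res2$report$method == "none"))
})

test_that("template transfer is exact arithmetic", {
  expect_equal(apply_tma_value(1.500, 1.520, 1.510), 1.490)
  expect_equal(apply_tma_value(1.500, 1.500, 1.4937), 1.4937)  # self-template
  expect_equal(apply_tma_value(2.0, 1.7, 1.7), 2.0)            # null offset
  # (target - output) + (se - opt) == 0 up to one rounding of the sum
  set.seed(1)
  for (i in 1:50) {
    t0 <- stats::runif(1, 0.9, 1.9)
    to <- stats::runif(1, 0.9, 1.9)
    ts <- to + stats::rnorm(1, 0, 0.01)
    expect_lt(abs((t0 - apply_tma_value(t0, to, ts)) + (ts - to)), 1e-12)
  }
})

test_that("structure-level TMA maps templates and falls back to LRA", {
  sd <- refit_molecule()
  # synthetic template: same parameter classes, known SE values
  lib <- tibble::tibble(
    template_id = "synthetic-template",
    param_id = c("co", "cn"), kind = "bond", level_tag = "revDSD",
    r_opt = c(1.215, 1.372), r_se = c(1.2075, 1.3648)
  )
  mapping <- tibble::tibble(target = c("C1O2", "C1N3"),
                            template_id = "synthetic-template",
                            template_param = c("co", "cn"))
  res <- correct_structure_tma(sd, mapping, lib, "revDSD",
                               lra_fallback = lra_registry())
  rep <- res$report
  expect_equal(rep$corrected[rep$id == "C1O2"], 1.21 + (1.2075 - 1.215))
  expect_equal(rep$method[rep$id == "C1O2"], "TMA")
  # unmapped N-H bond picked up by the regression fallback
  expect_equal(rep$method[rep$id == "N3H4"], "LRA")
  # a target whose fragments copy the template exactly lands on the SE value
  sd2 <- set_param_values(sd, c(C1O2 = 1.215, C1N3 = 1.372))
  res2 <- correct_structure_tma(sd2, mapping, lib, "revDSD")
  expect_equal(res2$report$corrected[res2$report$id == "C1O2"], 1.2075)
  expect_equal(res2$report$corrected[res2$report$id == "C1N3"], 1.3648)
  # empty mapping + registry is exactly the LRA path
  resL <- correct_structure_tma(sd, mapping[0, ], lib, "revDSD",
                                lra_fallback = lra_registry())
  ref <- correct_structure_lra(sd, lra_registry(), "revDSD")
  expect_equal(resL$structure$params$value, ref$structure$params$value)
  # kind mismatch is an error
  badmap <- tibble::tibble(target = "O2C1N3",
                           template_id = "synthetic-template",
                           template_param = "co")
  expect_error(correct_structure_tma(sd, badmap, lib, "revDSD"),
               "kind mismatch")
  # missing template parameter at the level is an error
  badmap2 <- tibble::tibble(target = "C1O2",
                            template_id = "synthetic-template",
                            template_param = "co")
  expect_error(correct_structure_tma(sd, badmap2, lib, "PW6B95"),
               "not available at level")
})

test_that("LRA fitting recovers exact lines and matches the OLS oracle", {
  r <- seq(1.0, 1.6, by = 0.1)
  # exact line r_se = 1.002 r - 0.001  <=>  delta = 0.002 r - 0.001
  f <- fit_lra_parameters(data.frame(r_opt = r, r_se = 1.002 * r - 0.001))
  expect_equal(f$A, 0.002, tolerance = 1e-12)
  expect_equal(f$B, -0.001, tolerance = 1e-12)
  # identity data
  f0 <- fit_lra_parameters(data.frame(r_opt = r, r_se = r))
  expect_equal(f0$A, 0, tolerance = 1e-12)
  expect_equal(f0$B, 0, tolerance = 1e-12)
  expect_equal(f0$mad, 0, tolerance = 1e-12)
  # free-intercept fit has exactly zero mean deviation on its training set
  set.seed(2)
  noisy <- data.frame(r_opt = r, r_se = r + 0.002 * r - 0.001 +
                        stats::rnorm(length(r), 0, 5e-4))
  fn <- fit_lra_parameters(noisy)
  expect_lt(abs(fn$md), 1e-12)
  # closed-form normal-equations oracle
  oracle <- ols_oracle(noisy$r_opt, noisy$r_se)
  expect_equal(fn$A, oracle$A, tolerance = 1e-10)
  expect_equal(fn$B, oracle$B, tolerance = 1e-10)
  o2 <- ols_oracle(noisy$r_opt, noisy$r_se, fix_intercept = TRUE)
  f2 <- fit_lra_parameters(noisy, fix_intercept = TRUE)
  expect_equal(f2$A, o2$A, tolerance = 1e-10)
  expect_identical(f2$B, 0)
  # degenerate design
  expect_error(fit_lra_parameters(data.frame(r_opt = rep(1.5, 5),
                                             r_se = stats::rnorm(5, 1.5))),
               "degenerate")
})

test_that("noisy synthetic pairs recover the generating line within 3 SE", {
  set.seed(123)
  A_true <- 0.0035
  B_true <- -0.004
  r <- stats::runif(100, 1.0, 1.8)
  rse <- r + (A_true * r + B_true) + stats::rnorm(100, 0, 1e-3)
  f <- fit_lra_parameters(data.frame(r_opt = r, r_se = rse))
  expect_lt(abs(f$A - A_true), 3 * f$se_A)
  expect_lt(abs(f$B - B_true), 3 * f$se_B)
  td <- generics::tidy(f)
  expect_equal(td$estimate, c(f$A, f$B))
  expect_equal(generics::glance(f)$n, 100)
})
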