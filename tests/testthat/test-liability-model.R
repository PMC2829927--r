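test_that("threshold/prevalence round-trips and matches quantile oracle", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(1/250), qnorm(1 - 1/250))
  expect_equal(threshold_from_prevalence(0.841345), -1, tolerance = 1e-4)
  for (k in c(1e-6, 1e-3, 1/250, 0.1, 0.5, 0.9, 1 - 1e-6)) {
    t <- threshold_from_prevalence(k)
    expect_equal(pnorm(t, lower.tail = FALSE), k, tolerance = 1e-12)
  }
  expect_error(threshold_from_prevalence(0), "domain")
  expect_error(threshold_from_prevalence(1), "domain")
})

test_that("genotype values are mean-centered additive contributions", {
  expect_equal(genotype_value(0L, 0.3, 0), 0)
  expect_equal(genotype_value(1L, 0.425, 0.083), 0.01245)
  # centering identity under HWE, any (raf, a)
  for (p in c(0.05, 0.425, 0.9)) for (a in c(0, 0.1, 0.5)) {
    expect_equal(sum(hwe_genotype_freqs(p) * genotype_value(0:2, p, a)), 0,
                 tolerance = 1e-14)
  }
  expect_error(genotype_value(3L, 0.4, 0.1), "domain")
  expect_true(is.na(genotype_value(NA_integer_, 0.4, 0.1)))
})

test_that("variance explained follows 2p(1-p)a^2 and the packaged table", {
  expect_equal(variance_explained(0.425, 0.083), 0.0034, tolerance = 0.015)
  expect_equal(variance_explained(0.018, 0.504), 0.0090, tolerance = 0.01)
  expect_equal(variance_explained(0.3, 0), 0)
  expect_equal(variance_explained(0, 0.5), 0)
  tab <- read_variant_table(crohns30_path())
  ve <- variance_explained(tab$raf, tab$a)
  # printed column was computed from unrounded a values; matching "at
  # printed precision, allowing +/-1 in the last printed digit" means the
  # recomputed value rounds to within one unit of the 4th decimal
  expect_true(all(abs(round(ve, 4) - tab$ve) <= 1.000001e-4))
  expect_equal(sum(ve), 0.064, tolerance = 0.001 / 0.064)
})

test_that("GRR <-> additive value mapping inverts and hits known pairs", {
  k <- 1/250
  expect_equal(grr_from_additive_value(0, 0.425, k), 1)
  expect_equal(grr_from_additive_value(0.01, 0.425, k), 1.03, tolerance = 5e-3)
  expect_equal(grr_from_additive_value(0.05, 0.425, k), 1.16, tolerance = 5e-3)
  expect_equal(additive_value_from_grr(1, 0.3, k), 0)
  expect_equal(additive_value_from_grr(1.16, 0.425, k), 0.05,
               tolerance = 0.02)
  # monotone in a, and round trip over a wide range
  a_grid <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  g <- grr_from_additive_value(a_grid, 0.425, k)
  expect_true(all(diff(g) > 0))
  expect_equal(additive_value_from_grr(g, 0.425, k), a_grid,
               tolerance = 1e-8)
  # protective alleles calibrate too
  expect_lt(additive_value_from_grr(0.8, 0.3, k), 0)
})

test_that("variance components validate and expose the sibling correlation", {
  vc <- variance_components(0.7, 0.2, 0.1)
  expect_equal(vc$rho_sib, 0.55)
  expect_error(variance_components(0.7, 0.2, 0.2), "sum to 1")
  expect_error(variance_components(-0.1, 1.0, 0.1), "non-negative")
  expect_error(variance_components(0, 1, 0), "correlation")  # rho_sib = 1
})

test_that("disease model assembles, calibrates missing a, and validates", {
  m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
                     data.frame(raf = 0.425, grr = 1.25))
  expect_s3_class(m, "disease_model")
  expect_equal(m$rho_sib, 0.55)
  # calibrated a should reproduce its grr through the forward map
  expect_equal(grr_from_additive_value(m$variants$a, 0.425, 1/250), 1.25,
               tolerance = 1e-8)
  expect_error(disease_model(1/250, variance_components(),
                             data.frame(grr = 1.2)), "raf")
  expect_error(disease_model(1/250, variance_components(),
                             data.frame(raf = 0.4)), "'a' or 'grr'")
})

test_that("sibling recurrence risk matches the quadrature oracle and is monotone in rho", {
  k <- 1/250
  m <- disease_model(k, variance_components(0.7, 0.2, 0.1))
  rr <- sibling_recurrence_risk(m)
  t <- threshold_from_prevalence(k)
  pb <- oracle_orthant(t, t, 0.55)
  expect_equal(rr$K_S, pb / k, tolerance = 1e-10)
  expect_equal(rr$lambda_S, pb / k^2, tolerance = 1e-10)
  expect_equal(rr$lambda_S, rr$K_S / k, tolerance = 1e-12)
  # independence limit: rho = 0 gives K_S = k exactly
  m0 <- disease_model(k, variance_components(0, 0, 1))
  expect_equal(sibling_recurrence_risk(m0)$K_S, k, tolerance = 1e-12)
  # strictly increasing in rho on a grid (vary shared environment)
  ks <- vapply(seq(0, 0.8, by = 0.1), function(ce)
    sibling_recurrence_risk(
      disease_model(k, variance_components(0, ce, 1 - ce)))$K_S, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("genotype-mixture recurrence matches its enumeration oracle", {
  sl <- single_locus_model()
  res <- sibling_recurrence_risk(sl)
  mix <- sibling_recurrence_risk(sl, include_variants = TRUE)
  # oracle value: mix over the exact sibpair table at the example locus
  J <- oracle_locus_joint(0.425, 0.083, 1/250, 0.55)
  pb <- sum(J[, , 1, 1])
  pds <- sum(J[, , , 1])
  expect_equal(mix$K_S, pb / pds, tolerance = 1e-9)
  # under total-variance standardization a locus's 0.5 genotype correlation
  # displaces residual correlation 0.55, so the genotype-aware value sits
  # marginally BELOW the residual-only reporting value
  expect_lt(mix$K_S, res$K_S)
  expect_lt(abs(mix$K_S - res$K_S), 1e-3)
  # with rho_sib < 0.5 the displacement goes the other way
  lo <- disease_model(1/250, variance_components(0.4, 0, 0.6),
                      data.frame(raf = 0.425, a = 0.083))
  expect_gt(sibling_recurrence_risk(lo, include_variants = TRUE)$K_S,
            sibling_recurrence_risk(lo)$K_S)
})
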