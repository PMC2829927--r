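sl_model <- function() single_locus_model()

test_that("joint disease distribution is a coherent 2x2 table", {
  m <- sl_model()
  for (gi in 0:2) for (gs in 0:2) {
    tab <- joint_disease_distribution(gi, gs, m)
    expect_equal(sum(tab), 1, tolerance = 1e-10)
    expect_true(all(tab >= 0))
    # margins equal the scaled univariate tails
    mu_i <- genotype_value(gi, 0.425, 0.083)
    mu_s <- genotype_value(gs, 0.425, 0.083)
    s <- m$residual_scale
    expect_equal(sum(tab["D", ]),
                 pnorm((m$threshold - mu_i) / s, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(sum(tab[, "D"]),
                 pnorm((m$threshold - mu_s) / s, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # null effects + rho 0: independent products of k and 1-k
  m0 <- disease_model(1/250, variance_components(0, 0, 1),
                      data.frame(raf = 0.425, a = 0))
  tab <- joint_disease_distribution(1, 1, m0)
  k <- 1/250
  expect_equal(as.vector(tab), c(k * k, k * (1 - k), (1 - k) * k,
                                 (1 - k)^2), tolerance = 1e-12)
  expect_error(joint_disease_distribution(c(1, 2), 1, m), "input")
})

test_that("high-risk genotypes raise the conditional sibling risk", {
  m <- sl_model()
  tab <- joint_disease_distribution(2, 2, m)
  ks_resid <- sibling_recurrence_risk(m)$K_S
  expect_gt(tab["D", "D"] / sum(tab[, "D"]), ks_resid)
})

test_that("per-locus likelihood ratios behave and match the brute-force oracle", {
  m <- sl_model()
  v <- m$variants[1, ]
  # uninformative locus
  null_v <- data.frame(id = "z", raf = 0.425, a = 0)
  expect_equal(locus_likelihood_ratio(2, variant = null_v, model = m)$lr, 1)
  expect_equal(locus_likelihood_ratio(NA, variant = v, model = m)$log_lr, 0)
  # G_I-only ratio increasing in gi
  lr_g <- vapply(0:2, function(g)
    locus_likelihood_ratio(g, variant = v, model = m)$lr, numeric(1))
  expect_true(all(diff(lr_g) > 0))
  # full-model ratio strictly decreasing in the sibling's copy count
  for (gi in 0:2) {
    lr_full <- vapply(0:2, function(gs)
      locus_likelihood_ratio(gi, gs, TRUE, v, m)$lr, numeric(1))
    expect_true(all(diff(lr_full) < 0))
  }
  expect_error(locus_likelihood_ratio(1, gs = 2, ds = NULL, v, m), "input")
})

test_that("single-locus posteriors equal brute-force Bayes at machine precision", {
  k <- 1/250
  for (spec in list(c(0.425, 0.083), c(0.1, 0.3))) {
    m <- disease_model(k, variance_components(0.7, 0.2, 0.1),
                       data.frame(raf = spec[1], a = spec[2]))
    for (gi in 0:2) {
      rep_g <- predict(m, gi = gi)
      expect_equal(unname(rep_g$risks["g"]),
                   oracle_posterior(gi, NULL, NULL, spec[1], spec[2], k,
                                    0.55, "g"), tolerance = 1e-12)
      for (ds in c(TRUE, FALSE)) {
        rep2 <- predict(m, gi = gi, ds = ds)
        expect_equal(unname(rep2$risks["g_ds"]),
                     oracle_posterior(gi, NULL, ds, spec[1], spec[2], k,
                                      0.55, "g_ds"), tolerance = 1e-12)
        for (gs in 0:2) {
          rep3 <- predict(m, gi = gi, gs = gs, ds = ds)
          expect_equal(unname(rep3$risks["g_gs_ds"]),
                       oracle_posterior(gi, gs, ds, spec[1], spec[2], k,
                                        0.55, "g_gs_ds"), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the five reported risks hit the packaged single-locus example", {
  m <- sl_model()
  expect_equal(unname(predict(m, gi = 0)$risks["unconditional"]), 1/250)
  risk_g <- vapply(0:2, function(g)
    unname(predict(m, gi = g)$risks["g"]), numeric(1))
  expect_equal(risk_g, c(0.0031932, 0.0040953, 0.0052190), tolerance = 1e-4)
  full <- outer(0:2, 0:2, Vectorize(function(gi, gs)
    unname(predict(m, gi = gi, gs = gs, ds = TRUE)$risks["g_gs_ds"])))
  expect_equal(range(full), c(0.089563, 0.146375), tolerance = 1e-4)
  # minimum at (index low-risk homozygote, sibling high-risk homozygote)
  expect_equal(which.min(full), which(outer(0:2, 0:2,
    function(i, s) i == 0 & s == 2)))
  g_ds <- vapply(0:2, function(g)
    unname(predict(m, gi = g, ds = TRUE)$risks["g_ds"]), numeric(1))
  expect_equal(g_ds, c(0.101803, 0.115402, 0.130248), tolerance = 1e-4)
  expect_equal(unname(predict(m, gi = NA_integer_, ds = TRUE)$risks["ds"]),
               0.1144487, tolerance = 1e-6)
})

test_that("risk is monotone: up in own copies, down in the affected sib's", {
  m <- sl_model()
  risk_g <- vapply(0:2, function(g)
    unname(predict(m, gi = g)$risks["g"]), numeric(1))
  expect_true(all(diff(risk_g) > 0))
  for (gi in 0:2) {
    r <- vapply(0:2, function(gs)
      unname(predict(m, gi = gi, gs = gs, ds = TRUE)$risks["g_gs_ds"]),
      numeric(1))
    expect_true(all(diff(r) < 0))
  }
})

test_that("zero residual familiality makes sibling data uninformative", {
  # with rho_sib = 0 the measured variants carry the entire familial
  # covariance: conditional on the index genotype, the sibling's genotype
  # and phenotype add nothing. Exact under the exact-Bayes (realized)
  # prior; the nominal-prior reporting approximation preserves the
  # collapse g_ds == g_gs_ds exactly and g to ~(realized - nominal
  # prevalence)/nominal relative (about 1.5% here).
  m <- disease_model(1/250, variance_components(0, 0, 1),
                     data.frame(raf = 0.425, a = 0.083))
  for (gi in 0:2) {
    r <- predict(m, gi = gi, gs = 1, ds = TRUE, prior = "realized")$risks
    expect_equal(unname(r["g_ds"]), unname(r["g"]), tolerance = 1e-10)
    expect_equal(unname(r["g_gs_ds"]), unname(r["g"]), tolerance = 1e-10)
    rn <- predict(m, gi = gi, gs = 1, ds = TRUE)$risks
    expect_equal(unname(rn["g_gs_ds"]), unname(rn["g_ds"]),
                 tolerance = 1e-12)
    expect_equal(unname(rn["g_ds"]), unname(rn["g"]), tolerance = 0.02)
    expect_equal(unname(rn["ds"]), 1/250, tolerance = 1e-12)
  }
})

test_that("all-null variants collapse every risk to its baseline", {
  m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
                     data.frame(raf = c(0.2, 0.6), a = c(0, 0)))
  r <- predict(m, gi = c(2, 2), gs = c(0, 0), ds = TRUE)$risks
  ks <- sibling_recurrence_risk(m)$K_S
  expect_equal(unname(r["g"]), 1/250, tolerance = 1e-12)
  expect_equal(unname(r["ds"]), ks, tolerance = 1e-12)
  expect_equal(unname(r["g_ds"]), ks, tolerance = 1e-12)
  expect_equal(unname(r["g_gs_ds"]), ks, tolerance = 1e-12)
})

test_that("realized-prior risks satisfy the laws of total probability", {
  m <- sl_model()
  v <- m$variants[1, ]
  hwe <- hwe_genotype_freqs(v$raf)
  risk_g <- vapply(0:2, function(g)
    unname(predict(m, gi = g, prior = "realized")$risks["g"]), numeric(1))
  kv <- sum(hwe * risk_g)
  # averaging over HWE recovers the realized prevalence
  mu <- genotype_value(0:2, v$raf, v$a)
  kv_direct <- sum(hwe * pnorm((m$threshold - mu) / m$residual_scale,
                               lower.tail = FALSE))
  expect_equal(kv, kv_direct, tolerance = 1e-6)
  # averaging the full family risk over P(G_I, G_S | D_S) recovers K_S
  cond <- sibpair_freqs_given_sib_affected(v, m)
  full <- outer(0:2, 0:2, Vectorize(function(gi, gs)
    unname(predict(m, gi = gi, gs = gs, ds = TRUE,
                   prior = "realized")$risks["g_gs_ds"])))
  ks_mix <- sibling_recurrence_risk(m, include_variants = TRUE)$K_S
  expect_equal(sum(cond$probs * full), ks_mix, tolerance = 1e-6)
})

test_that("multilocus combination multiplies per-locus ratios and skips missing", {
  m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
                     data.frame(raf = c(0.425, 0.2), a = c(0.083, 0.15)))
  rep <- predict(m, gi = c(2, NA))
  one <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
                       data.frame(raf = 0.425, a = 0.083))
  # second locus missing: log-LR contribution must be zero
  expect_equal(rep$loci$log_lr_g[2], 0)
  # the combined posterior is not identical to the single-locus package
  # model (per-locus residuals differ), but the log LRs add
  rep2 <- predict(m, gi = c(2, 1))
  expect_equal(sum(rep2$loci$log_lr_g),
               rep2$loci$log_lr_g[1] + rep2$loci$log_lr_g[2])
  expect_error(predict(m, gi = c(1, 1, 1)), "input")
  expect_error(predict(m, gi = c(1, 1), gs = c(1, 1)), "phenotype")
})

test_that("delta metric is a mean absolute difference", {
  expect_equal(delta_metric(c(0.1, 0.2), c(0.2, 0.1)), 0.1)
  expect_equal(delta_metric(c(0.3, 0.3), c(0.3, 0.3)), 0)
  x <- runif(10); y <- runif(10)
  expect_equal(delta_metric(x, y), delta_metric(y, x))
  expect_error(delta_metric(c(0.1), c(0.1, 0.2)), "input")
})

test_that("report serialization round-trips through JSON and TSV", {
  m <- sl_model()
  rep <- predict(m, gi = 2, gs = 0, ds = TRUE)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(jp, tp)))
  write_risk_report(rep, json_path = jp, tsv_path = tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$risks$g_gs_ds, unname(rep$risks["g_gs_ds"]),
               tolerance = 1e-12)
  tsv <- read.delim(tp)
  expect_equal(tsv$g_gs_ds, signif(unname(rep$risks["g_gs_ds"]), 4))
})
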