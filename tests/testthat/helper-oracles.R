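# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of the Gauss-Legendre orthant,
# direct enumeration instead of the sibpair/likelihood machinery.

# P(Z1 >= h1, Z2 >= h2) by adaptive quadrature of the conditioning integral
oracle_orthant <- function(h1, h2, rho) {
  if (rho == 0) return(pnorm(-h1) * pnorm(-h2))
  f <- function(z) dnorm(z) *
    pnorm((h2 - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
  integrate(f, h1, Inf, rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# sibpair genotype table by brute force over all ordered parental allele
# pairs and all 4 transmission patterns per sibling
oracle_sibpair <- function(p) {
  probs <- matrix(0, 3, 3)
  for (m1 in 0:1) for (m2 in 0:1) for (f1 in 0:1) for (f2 in 0:1) {
    w <- prod(ifelse(c(m1, m2, f1, f2) == 1, p, 1 - p))
    for (a1 in 1:2) for (b1 in 1:2) for (a2 in 1:2) for (b2 in 1:2) {
      g1 <- c(m1, m2)[a1] + c(f1, f2)[b1]
      g2 <- c(m1, m2)[a2] + c(f1, f2)[b2]
      probs[g1 + 1, g2 + 1] <- probs[g1 + 1, g2 + 1] + w / 16
    }
  }
  probs
}

# IBD-mixture form of the same table
oracle_sibpair_ibd <- function(p) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  ibd1 <- matrix(0, 3, 3)
  for (s in 0:1) for (x in 0:1) for (y in 0:1) {
    pr <- prod(ifelse(c(s, x, y) == 1, p, 1 - p))
    ibd1[s + x + 1, s + y + 1] <- ibd1[s + x + 1, s + y + 1] + pr
  }
  0.25 * outer(hwe, hwe) + 0.5 * ibd1 + 0.25 * diag(hwe)
}

# Full single-locus joint P(G_I, G_S, D_I, D_S) under the model's variance
# convention (total liability variance 1, residual 1 - ve), built from the
# quadrature orthant. Cells indexed [gi+1, gs+1, di, ds], 1 = affected.
oracle_locus_joint <- function(raf, a, k, rho) {
  t <- qnorm(k, lower.tail = FALSE)
  ve <- 2 * raf * (1 - raf) * a^2
  s <- sqrt(1 - ve)
  mu <- (0:2 - 2 * raf) * a
  sib <- oracle_sibpair(raf)
  J <- array(0, c(3, 3, 2, 2))
  for (i in 1:3) for (j in 1:3) {
    pb <- oracle_orthant((t - mu[i]) / s, (t - mu[j]) / s, rho)
    pi_ <- pnorm((t - mu[i]) / s, lower.tail = FALSE)
    ps_ <- pnorm((t - mu[j]) / s, lower.tail = FALSE)
    J[i, j, 1, 1] <- sib[i, j] * pb
    J[i, j, 1, 2] <- sib[i, j] * (pi_ - pb)
    J[i, j, 2, 1] <- sib[i, j] * (ps_ - pb)
    J[i, j, 2, 2] <- sib[i, j] * (1 - pi_ - ps_ + pb)
  }
  J
}

# Brute-force Bayes posterior under the nominal-prior measure: posterior
# odds = odds(k) * P(data | D_I) / P(data | !D_I), with the family factor
# entering once and the genotype factor conditional on D_S -- computed
# directly from the oracle joint, independently of the engine's tables.
oracle_posterior <- function(gi, gs, ds, raf, a, k, rho,
                             conditioning = c("g", "ds", "g_ds", "g_gs_ds")) {
  conditioning <- match.arg(conditioning)
  J <- oracle_locus_joint(raf, a, k, rho)
  t <- qnorm(k, lower.tail = FALSE)
  pb <- oracle_orthant(t, t, rho)
  l_fam <- if (isTRUE(ds)) (pb / k) / ((k - pb) / (1 - k))
           else (1 - pb / k) / (1 - (k - pb) / (1 - k))
  dsi <- if (isTRUE(ds)) 1 else 2
  lr <- switch(conditioning,
    g = {
      kv <- sum(J[gi + 1, , 1, ]) / sum(J[gi + 1, , , ]) # not used; direct form below
      tail_g <- sum(J[gi + 1, , 1, ]) / sum(J[gi + 1, , , ])
      ktot <- sum(J[, , 1, ])
      (sum(J[gi + 1, , 1, ]) / ktot) / (sum(J[gi + 1, , 2, ]) / (1 - ktot))
    },
    ds = l_fam,
    g_ds = l_fam * (sum(J[gi + 1, , 1, dsi]) / sum(J[, , 1, dsi])) /
      (sum(J[gi + 1, , 2, dsi]) / sum(J[, , 2, dsi])),
    g_gs_ds = l_fam * (J[gi + 1, gs + 1, 1, dsi] / sum(J[, , 1, dsi])) /
      (J[gi + 1, gs + 1, 2, dsi] / sum(J[, , 2, dsi])))
  k * lr / (k * lr + 1 - k)
}

crohns30_path <- function() {
  system.file("extdata", "crohns30.tsv", package = "sibrisk",
              mustWork = TRUE)
}
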