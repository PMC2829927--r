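#' Hardy--Weinberg genotype frequencies
#'
#' @param raf risk-allele frequency \eqn{p}.
#' @return numeric vector \eqn{((1-p)^2, 2p(1-p), p^2)} of frequencies for
#'   0, 1, 2 risk-allele copies.
#' @export
hwe_genotype_freqs <- function(raf) {
  if (any(raf < 0 | raf > 1))
    stop("sibrisk_domain_error: raf must lie in [0, 1]", call. = FALSE)
  c(`0` = (1 - raf)^2, `1` = 2 * raf * (1 - raf), `2` = raf^2)
}

#' Joint sibpair genotype distribution at one locus
#'
#' Exact 3x3 joint probability table of risk-allele copy counts for two full
#' siblings under random mating and Hardy--Weinberg equilibrium, obtained by
#' summing over all parental mating types (parents drawn from HWE) and
#' Mendelian transmissions; the two siblings' genotypes are conditionally
#' independent given the parents.
#'
#' @param raf risk-allele frequency.
#' @return an object of class \code{sibpair_table}: a list with \code{probs}
#'   (3x3 matrix, rows = index copies 0..2, columns = sibling copies 0..2)
#'   and \code{raf}. The table is symmetric and both marginals equal
#'   \code{\link{hwe_genotype_freqs}(raf)}.
#' @export
sibpair_joint_freqs <- function(raf) {
  if (length(raf) != 1 || raf < 0 || raf > 1)
    stop("sibrisk_domain_error: raf must be a single value in [0, 1]",
         call. = FALSE)
  p <- raf
  probs <- matrix(0, 3, 3, dimnames = list(index = 0:2, sib = 0:2))
  # parental genotypes: allele pairs (ordered), each allele Bernoulli(p)
  for (m1 in 0:1) for (m2 in 0:1) for (f1 in 0:1) for (f2 in 0:1) {
    w_par <- p^(m1 + m2 + f1 + f2) * (1 - p)^(4 - m1 - m2 - f1 - f2)
    # each sib independently inherits one maternal and one paternal allele
    kid <- numeric(3)
    for (tm in 1:2) for (tf in 1:2) {
      g <- (if (tm == 1) m1 else m2) + (if (tf == 1) f1 else f2)
      kid[g + 1] <- kid[g + 1] + 0.25
    }
    probs <- probs + w_par * outer(kid, kid)
  }
  structure(list(probs = probs, raf = raf), class = "sibpair_table")
}

#' @export
print.sibpair_table <- function(x, ...) {
  cat(sprintf("Sibpair genotype table (raf = %.4g)\n", x$raf))
  print(round(x$probs, 6))
  invisible(x)
}

#' Sibpair genotype distribution given an affected sibling
#'
#' Conditional distribution \eqn{P(G_I, G_S \mid D_S)} of the sibpair
#' genotypes at one locus given the sibling's disease state, computed as
#' \eqn{P(D_S \mid G_S) P(G_I, G_S)} renormalized. Because the index's
#' residual liability integrates out, \eqn{P(D_S \mid G_S)} is the exact
#' univariate normal tail beyond \eqn{t - (g_S - 2p)a} (unit residual
#' variance).
#'
#' With \code{at_least_one = TRUE} the conditioning event is instead "at
#' least one of the two siblings is affected" (the reporting variant used
#' for the single-locus illustration), which requires the bivariate residual
#' orthant and yields a symmetric table.
#'
#' @param variant one-row data frame or list with \code{raf} and \code{a}.
#' @param model a \code{\link{disease_model}} supplying the threshold and
#'   residual sibling correlation.
#' @param affected logical; condition on the sibling being affected
#'   (\code{TRUE}, default) or unaffected.
#' @param at_least_one logical; condition on "at least one sibling affected"
#'   instead of the designated sibling.
#' @return a \code{sibpair_table} whose \code{probs} hold the conditional
#'   distribution (no longer symmetric unless \code{at_least_one}).
#' @export
sibpair_freqs_given_sib_affected <- function(variant, model,
                                             affected = TRUE,
                                             at_least_one = FALSE) {
  stopifnot(inherits(model, "disease_model"))
  v <- as.list(as.data.frame(variant))
  t <- model$threshold
  joint <- sibpair_joint_freqs(v$raf)
  mu <- genotype_value(0:2, v$raf, v$a)
  lr <- locus_residual(model, v$raf, v$a)
  if (!at_least_one) {
    p_ds <- pnorm((t - mu) / lr$s, lower.tail = FALSE) # P(D_S=1 | G_S)
    if (!affected) p_ds <- 1 - p_ds
    cond <- sweep(joint$probs, 2, p_ds, `*`)
  } else {
    p_evt <- outer(mu, mu, function(mi, ms) {
      1 - bvn_orthant(-(t - mi) / lr$s, -(t - ms) / lr$s, lr$rho)
    })                                                 # 1 - P(neither)
    # 1 - P(neither): P(neither) = P(-Q_I >= -(t-mu_I), -Q_S >= ...) with
    # the same correlation; expressed via the lower orthant identity
    p_evt <- matrix(p_evt, 3, 3)
    if (!affected) p_evt <- 1 - p_evt
    cond <- joint$probs * p_evt
  }
  tot <- sum(cond)
  if (tot <= 0)
    stop("sibrisk_domain_error: degenerate model, conditioning event has ",
         "probability zero", call. = FALSE)
  structure(list(probs = cond / tot, raf = v$raf), class = "sibpair_table")
}

#' Write a sibpair genotype table as TSV
#'
#' Labeled 3x3 export (rows = index copies, columns = sibling copies), used
#' for the genotype-combination frequency inset of the single-locus
#' illustration.
#'
#' @param table a \code{sibpair_table}.
#' @param path output file path.
#' @export
write_sibpair_table <- function(table, path) {
  stopifnot(inherits(table, "sibpair_table"))
  df <- data.frame(index_copies = 0:2, table$probs, check.names = FALSE)
  names(df)[2:4] <- paste0("sib_", 0:2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
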