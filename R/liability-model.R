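#' Liability threshold from disease prevalence
#'
#' Under the liability-threshold model an individual is affected when an
#' unobserved standard-normal liability exceeds a threshold \eqn{t} chosen so
#' that the upper-tail probability equals the population prevalence \eqn{k}:
#' \eqn{P(Q \ge t) = k}.
#'
#' @param k population prevalence(s), strictly inside (0, 1).
#' @return liability threshold(s) \eqn{t = \Phi^{-1}(1-k)}.
#' @examples
#' threshold_from_prevalence(0.5)     # 0
#' threshold_from_prevalence(1/250)   # 2.652
#' @export
threshold_from_prevalence <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0) || any(k >= 1))
    stop("sibrisk_domain_error: prevalence must lie strictly in (0, 1)",
         call. = FALSE)
  qnorm(k, lower.tail = FALSE)
}

#' Residual variance components of liability
#'
#' Partition of the residual (non-variant) liability variance into an
#' additive polygenic part \eqn{\sigma^2_{poly}}, a family-wide shared
#' environment part \eqn{\sigma^2_c}, and a nonshared individual part
#' \eqn{\sigma^2_e} (which absorbs measurement error). The three components
#' are fractions of the unit residual variance and must sum to 1; measured
#' variants add their variance on top of this unit residual.
#'
#' The residual liability correlation between full siblings is
#' \eqn{\rho = 0.5\,\sigma^2_{poly} + \sigma^2_c}.
#'
#' @param poly,shared_env,nonshared non-negative fractions summing to 1.
#' @return an object of class \code{variance_components} with fields
#'   \code{poly}, \code{shared_env}, \code{nonshared} and \code{rho_sib}.
#' @examples
#' variance_components(0.7, 0.2, 0.1)$rho_sib  # 0.55
#' @export
variance_components <- function(poly = 0.7, shared_env = 0.2,
                                nonshared = 0.1) {
  stopifnot(is.numeric(poly), is.numeric(shared_env), is.numeric(nonshared))
  if (poly < 0 || shared_env < 0 || nonshared < 0)
    stop("sibrisk_domain_error: variance components must be non-negative",
         call. = FALSE)
  if (abs(poly + shared_env + nonshared - 1) > 1e-8)
    stop("sibrisk_domain_error: variance components must sum to 1 ",
         "(residual liability variance is unit-scaled)", call. = FALSE)
  rho <- 0.5 * poly + shared_env
  if (rho >= 1)
    stop("sibrisk_domain_error: residual sibling correlation must be < 1",
         call. = FALSE)
  structure(list(poly = poly, shared_env = shared_env,
                 nonshared = nonshared, rho_sib = rho),
            class = "variance_components")
}

#' Liability variance explained by one biallelic variant
#'
#' Additive variance contributed by a locus with risk-allele frequency
#' \code{raf} and per-allele liability value \code{a}:
#' \eqn{VE = 2p(1-p)a^2}.
#'
#' @param raf risk-allele frequency in [0, 1].
#' @param a additive genetic value (liability units per risk-allele copy).
#' @return variance explained, same length as the inputs.
#' @export
variance_explained <- function(raf, a) {
  if (any(raf < 0 | raf > 1, na.rm = TRUE))
    stop("sibrisk_domain_error: raf must lie in [0, 1]", call. = FALSE)
  2 * raf * (1 - raf) * a^2
}

#' Mean-centered additive genotype value
#'
#' Liability contribution of carrying \code{copies} risk alleles at a locus,
#' centered so its population mean under Hardy--Weinberg equilibrium is zero:
#' \eqn{g \cdot a - 2pa}. Centering keeps the realized prevalence close to
#' the nominal one when variants are added on top of the unit residual
#' (only variance inflation remains).
#'
#' @param copies risk-allele copy count(s) in \{0, 1, 2\}; \code{NA} allowed
#'   (propagated).
#' @param raf risk-allele frequency.
#' @param a additive genetic value.
#' @return centered liability value(s).
#' @export
genotype_value <- function(copies, raf, a) {
  ok <- is.na(copies) | copies %in% c(0L, 1L, 2L)
  if (!all(ok))
    stop("sibrisk_domain_error: copies must be 0, 1, 2 or NA", call. = FALSE)
  (copies - 2 * raf) * a
}

#' Genotypic relative risk implied by an additive liability value
#'
#' Under the centered single-locus liability model with unit residual
#' variance, the risk for genotype \eqn{g} is the normal upper tail beyond
#' \eqn{t - (g - 2p)a}. The genotypic relative risk is operationalized as
#' the heterozygote : reference-homozygote risk ratio
#' \eqn{P(D \mid g{=}1) / P(D \mid g{=}0)}.
#'
#' @param a additive genetic value (liability units).
#' @param raf risk-allele frequency.
#' @param k population prevalence.
#' @return genotypic relative risk (1 when \code{a = 0}).
#' @examples
#' grr_from_additive_value(0.05, 0.425, 1/250)  # ~1.16
#' @export
grr_from_additive_value <- function(a, raf, k) {
  t <- threshold_from_prevalence(k)
  pnorm(t - genotype_value(1L, raf, a), lower.tail = FALSE) /
    pnorm(t - genotype_value(0L, raf, a), lower.tail = FALSE)
}

#' Additive liability value implied by a genotypic relative risk
#'
#' Inverts \code{\link{grr_from_additive_value}} by monotone root-finding
#' (the GRR is strictly increasing in \code{a} for risk-increasing alleles).
#' This is the calibration used to turn an epidemiological (RAF, GRR) pair
#' into the liability-scale effect the model needs.
#'
#' @param grr genotypic relative risk, > 0.
#' @param raf risk-allele frequency.
#' @param k population prevalence.
#' @param interval search bracket for \code{a}, in liability units.
#' @param tol convergence tolerance on the root.
#' @return the additive value \code{a} with
#'   \code{grr_from_additive_value(a, raf, k) == grr} to within \code{tol}.
#' @export
additive_value_from_grr <- function(grr, raf, k, interval = c(0, 5),
                                    tol = 1e-10) {
  if (any(grr <= 0))
    stop("sibrisk_domain_error: grr must be positive", call. = FALSE)
  vapply(seq_along(grr), function(i) {
    g <- grr[i]
    p <- if (length(raf) > 1) raf[i] else raf
    if (g == 1) return(0)
    br <- if (g > 1) interval else -rev(interval)
    f <- function(a) grr_from_additive_value(a, p, k) - g
    flo <- f(br[1]); fhi <- f(br[2])
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
      stop("sibrisk_convergence_error: no root for grr=", g,
           " in bracket [", br[1], ", ", br[2], "]", call. = FALSE)
    uniroot(f, br, tol = tol)$root
  }, numeric(1))
}

#' Assemble a disease model
#'
#' Bundles the prevalence, the residual variance components and a table of
#' known risk variants into the model object used throughout the package.
#' Variants missing the additive value \code{a} are calibrated from their
#' GRR via \code{\link{additive_value_from_grr}}; the variance explained
#' \code{ve} is always (re)computed as \eqn{2p(1-p)a^2}.
#'
#' Total liability variance is standardized to 1: the variants contribute
#' \code{sum(ve)} and the residual has variance \code{1 - sum(ve)},
#' partitioned by the \code{components} fractions. The realized prevalence
#' therefore drifts only slightly above the nominal \code{prevalence} (the
#' genotype-value mixture is not exactly normal).
#'
#' @param prevalence population prevalence \eqn{k}.
#' @param components a \code{\link{variance_components}} object.
#' @param variants optional data frame with columns \code{raf} and at least
#'   one of \code{grr}, \code{a}; an optional \code{id} column labels loci.
#' @return an object of class \code{disease_model} with fields
#'   \code{prevalence}, \code{threshold}, \code{components}, \code{rho_sib},
#'   \code{variants} (a data frame with \code{id}, \code{raf}, \code{grr},
#'   \code{a}, \code{ve}), \code{total_ve} and \code{residual_scale}
#'   (\eqn{\sqrt{1 - \sum ve}}).
#' @examples
#' m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
#'                    data.frame(raf = 0.425, a = 0.083))
#' m$threshold
#' @export
disease_model <- function(prevalence, components = variance_components(),
                          variants = NULL) {
  stopifnot(inherits(components, "variance_components"))
  t <- threshold_from_prevalence(prevalence)
  v <- normalize_variants(variants, prevalence)
  total_ve <- sum(v$ve)
  if (total_ve >= 1)
    stop("sibrisk_domain_error: variants explain >= 100% of liability ",
         "variance", call. = FALSE)
  structure(list(prevalence = prevalence, threshold = t,
                 components = components, rho_sib = components$rho_sib,
                 variants = v, total_ve = total_ve,
                 residual_scale = sqrt(1 - total_ve)),
            class = "disease_model")
}

normalize_variants <- function(variants, k) {
  if (is.null(variants) || nrow(as.data.frame(variants)) == 0)
    return(data.frame(id = character(0), raf = numeric(0),
                      grr = numeric(0), a = numeric(0), ve = numeric(0)))
  v <- as.data.frame(variants)
  if (!"raf" %in% names(v))
    stop("sibrisk_parse_error: variant table needs a 'raf' column",
         call. = FALSE)
  if (!any(c("a", "grr") %in% names(v)))
    stop("sibrisk_parse_error: variant table needs an 'a' or 'grr' column",
         call. = FALSE)
  if (any(v$raf < 0 | v$raf > 1))
    stop("sibrisk_domain_error: raf must lie in [0, 1]", call. = FALSE)
  if (is.null(v$id)) v$id <- paste0("v", seq_len(nrow(v)))
  if (is.null(v$a)) v$a <- NA_real_
  need <- is.na(v$a)
  if (any(need)) {
    if (is.null(v$grr) || anyNA(v$grr[need]))
      stop("sibrisk_parse_error: variants without 'a' must carry 'grr'",
           call. = FALSE)
    v$a[need] <- additive_value_from_grr(v$grr[need], v$raf[need], k)
  }
  if (is.null(v$grr)) v$grr <- NA_real_
  v$ve <- variance_explained(v$raf, v$a)
  v[, c("id", "raf", "grr", "a", "ve")]
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Liability-threshold disease model\n")
  cat(sprintf("  prevalence k = %.6g (threshold t = %.4f)\n",
              x$prevalence, x$threshold))
  cat(sprintf("  residual components: poly = %.3g, shared_env = %.3g, nonshared = %.3g\n",
              x$components$poly, x$components$shared_env,
              x$components$nonshared))
  cat(sprintf("  residual sibling correlation rho = %.4g\n", x$rho_sib))
  cat(sprintf("  %d variant(s), total VE = %.4g\n",
              nrow(x$variants), sum(x$variants$ve)))
  invisible(x)
}

#' Sibling recurrence risk and sibling relative risk
#'
#' Analytic risk of disease for an individual with an affected sibling.
#' With residual sibling correlation \eqn{\rho}, the joint probability that
#' both siblings are affected is the bivariate-normal upper orthant at
#' \eqn{(t, t)} with correlation \eqn{\rho}; the recurrence risk is
#' \eqn{K_S = P(\mathrm{both}) / k} and the sibling relative risk is
#' \eqn{\lambda_S = K_S / k}.
#'
#' By default only the residual correlation is used (the measured variants
#' are ignored), which is the reporting convention here. With
#' \code{include_variants = TRUE} the orthant is averaged over the joint
#' sibpair genotype distribution at every model locus; because each locus'
#' 0.5 genotype correlation displaces residual correlation \eqn{\rho}, the
#' genotype-aware value sits marginally below the residual-only one when
#' \eqn{\rho > 0.5} (and above it otherwise). For more than
#' \code{max_enum_loci} loci the genotype mixture is integrated by
#' mean-splitting the per-locus value sums onto a fine grid.
#'
#' @param model a \code{\link{disease_model}}.
#' @param include_variants logical; mix over measured genotypes as well.
#' @param max_enum_loci exact 9^L enumeration is used up to this many loci.
#' @return list with \code{K_S} (recurrence risk), \code{lambda_S}
#'   (relative risk) and \code{p_both} (joint probability).
#' @examples
#' m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1))
#' sibling_recurrence_risk(m)$K_S  # ~0.11
#' @export
sibling_recurrence_risk <- function(model, include_variants = FALSE,
                                    max_enum_loci = 5) {
  stopifnot(inherits(model, "disease_model"))
  t <- model$threshold
  rho <- model$rho_sib
  k <- model$prevalence
  if (!include_variants || nrow(model$variants) == 0) {
    pb <- bvn_orthant(t, t, rho)
    return(list(K_S = pb / k, lambda_S = pb / k^2, p_both = pb))
  }
  mix <- sibpair_value_mixture(model, max_enum_loci)
  s <- model$residual_scale
  pb <- sum(mix$w * bvn_orthant((t - mix$mu_i) / s, (t - mix$mu_s) / s, rho))
  # marginal sibling prevalence under the same mixture
  ks_marg <- sum(mix$w * pnorm((t - mix$mu_s) / s, lower.tail = FALSE))
  list(K_S = pb / ks_marg, lambda_S = pb / ks_marg^2, p_both = pb)
}

# Joint distribution of the summed genotype values (mu_index, mu_sib) over
# all model loci: exact enumeration for few loci, otherwise a mean-splitting
# discretization onto a fine grid (error second order in the grid step).
sibpair_value_mixture <- function(model, max_enum_loci = 5, step = 2e-3) {
  v <- model$variants
  L <- nrow(v)
  per_locus <- lapply(seq_len(L), function(i) {
    tab <- sibpair_joint_freqs(v$raf[i])
    list(mu = genotype_value(0:2, v$raf[i], v$a[i]), p = tab$probs)
  })
  if (L <= max_enum_loci) {
    grid <- expand.grid(rep(list(1:3), 2 * L))
    w <- rep(1, nrow(grid)); mu_i <- 0; mu_s <- 0
    for (l in seq_len(L)) {
      gi <- grid[[l]]; gs <- grid[[L + l]]
      w <- w * per_locus[[l]]$p[cbind(gi, gs)]
      mu_i <- mu_i + per_locus[[l]]$mu[gi]
      mu_s <- mu_s + per_locus[[l]]$mu[gs]
    }
    return(list(w = w, mu_i = mu_i, mu_s = mu_s))
  }
  rng <- sum(vapply(per_locus, function(x) max(abs(x$mu)), numeric(1)))
  ax <- seq(-(rng + 2 * step), rng + 2 * step, by = step)
  nx <- length(ax)
  dist <- matrix(0, nx, nx)
  i0 <- which.min(abs(ax))
  dist[i0, i0] <- 1
  # new[r+di, c+dc] += wgt * dist[r, c], clipped to the grid
  shift_add <- function(acc, src, di, dc, wgt) {
    r <- max(1, 1 - di):min(nx, nx - di)
    cc <- max(1, 1 - dc):min(nx, nx - dc)
    acc[r + di, cc + dc] <- acc[r + di, cc + dc] + wgt * src[r, cc]
    acc
  }
  for (l in seq_len(L)) {
    acc <- matrix(0, nx, nx)
    mu <- per_locus[[l]]$mu; p <- per_locus[[l]]$p
    for (gi in 1:3) for (gs in 1:3) {
      if (p[gi, gs] == 0) next
      si <- mu[gi] / step; ss <- mu[gs] / step
      fi <- floor(si); fs <- floor(ss)
      wi <- si - fi; ws <- ss - fs
      for (di in 0:1) for (ds in 0:1) {
        wgt <- p[gi, gs] * (if (di == 0) 1 - wi else wi) *
          (if (ds == 0) 1 - ws else ws)
        if (wgt > 0) acc <- shift_add(acc, dist, fi + di, fs + ds, wgt)
      }
    }
    dist <- acc
  }
  keep <- which(dist > 1e-300, arr.ind = TRUE)
  list(w = dist[keep], mu_i = ax[keep[, 1]], mu_s = ax[keep[, 2]])
}
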