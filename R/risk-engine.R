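#' Joint sibling disease-state distribution given genotypes
#'
#' 2x2 probability table over (index disease, sibling disease) for a sibling
#' pair with multilocus genotypes \code{gi}, \code{gs}. The pair's liability
#' means are the summed centered genotype values \eqn{\mu_I, \mu_S}; the
#' residual liabilities are standard bivariate normal with correlation
#' \eqn{\rho}, so each cell is an orthant probability at the shifted
#' thresholds \eqn{(t - \mu_I, t - \mu_S)}.
#'
#' @param gi,gs integer vectors of risk-allele copy counts, one entry per
#'   model variant (\code{NA} = missing, contributes no liability shift).
#' @param model a \code{\link{disease_model}}.
#' @return 2x2 matrix with dimnames \code{index = c("D","U")},
#'   \code{sib = c("D","U")}, summing to 1.
#' @export
joint_disease_distribution <- function(gi, gs, model) {
  stopifnot(inherits(model, "disease_model"))
  v <- model$variants
  if (length(gi) != nrow(v) || length(gs) != nrow(v))
    stop("sibrisk_input_error: genotype vectors must match the model's ",
         nrow(v), " variant(s)", call. = FALSE)
  mu_i <- sum(genotype_value(gi, v$raf, v$a), na.rm = TRUE)
  mu_s <- sum(genotype_value(gs, v$raf, v$a), na.rm = TRUE)
  t <- model$threshold
  rho <- model$rho_sib
  s <- model$residual_scale
  p_both <- bvn_orthant((t - mu_i) / s, (t - mu_s) / s, rho)
  p_i <- pnorm((t - mu_i) / s, lower.tail = FALSE)
  p_s <- pnorm((t - mu_s) / s, lower.tail = FALSE)
  m <- matrix(c(p_both, p_s - p_both, p_i - p_both, 1 - p_i - p_s + p_both),
              2, 2, dimnames = list(index = c("D", "U"), sib = c("D", "U")))
  m
}

# Per-locus probability machinery. For locus v returns everything the
# likelihood ratios need:
#   hwe  : P(G)                       tail : P(D | G) = Phibar(t - mu_g)
#   sib  : P(G_I, G_S)                J    : P(G_I, G_S, D_I, D_S) [3,3,2,2]
# J[, , d_i, d_s] uses index 1 = affected, 2 = unaffected.
# Residual seen by one locus when the other loci are marginalized into it:
# variance 1 - ve_v (total liability variance is 1), sibling correlation
# blending the residual correlation with the 0.5 genotype correlation of
# the marginalized loci; reduces to (1 - ve, rho_sib) for a one-locus model.
locus_residual <- function(model, raf, a) {
  ve_v <- variance_explained(raf, a)
  list(s = sqrt(1 - ve_v),
       rho = (model$rho_sib * (1 - model$total_ve) +
                0.5 * (model$total_ve - ve_v)) / (1 - ve_v))
}

locus_joint <- function(raf, a, model) {
  t <- model$threshold
  res <- locus_residual(model, raf, a)
  s <- res$s
  rho <- res$rho
  mu <- genotype_value(0:2, raf, a)
  hwe <- hwe_genotype_freqs(raf)
  sib <- sibpair_joint_freqs(raf)$probs
  tail <- pnorm((t - mu) / s, lower.tail = FALSE)
  J <- array(0, c(3, 3, 2, 2))
  for (i in 1:3) for (j in 1:3) {
    pb <- bvn_orthant((t - mu[i]) / s, (t - mu[j]) / s, rho)
    pi_ <- tail[i]; ps_ <- tail[j]
    J[i, j, 1, 1] <- sib[i, j] * pb
    J[i, j, 1, 2] <- sib[i, j] * (pi_ - pb)
    J[i, j, 2, 1] <- sib[i, j] * (ps_ - pb)
    J[i, j, 2, 2] <- sib[i, j] * (1 - pi_ - ps_ + pb)
  }
  list(mu = mu, hwe = hwe, sib = sib, tail = tail, J = J,
       kv = sum(hwe * tail))
}

# Per-locus log likelihood-ratio lookup tables for the three genotype-based
# conditioning models. ds is indexed 1 = sibling affected, 2 = unaffected.
#   lg[g+1]            : log P(G_I | D_I) / P(G_I | !D_I)
#   lg_ds[g+1, ds]     : log P(G_I | D_I, D_S) / P(G_I | !D_I, D_S)
#   lg_gs_ds[gi,gs,ds] : log P(G_I, G_S | D_I, D_S) / P(G_I, G_S | !D_I, D_S)
locus_loglr_tables <- function(raf, a, model) {
  lj <- locus_joint(raf, a, model)
  J <- lj$J
  lg <- log(lj$tail / lj$kv) - log((1 - lj$tail) / (1 - lj$kv))
  lg_ds <- matrix(0, 3, 2)
  lg_gs_ds <- array(0, c(3, 3, 2))
  for (ds in 1:2) {
    pDI <- sum(J[, , 1, ds])   # P(D_I, D_S = ds)
    pUI <- sum(J[, , 2, ds])
    gi_marg_D <- rowSums(J[, , 1, ds])
    gi_marg_U <- rowSums(J[, , 2, ds])
    lg_ds[, ds] <- log(gi_marg_D / pDI) - log(gi_marg_U / pUI)
    lg_gs_ds[, , ds] <- log(J[, , 1, ds] / pDI) - log(J[, , 2, ds] / pUI)
  }
  list(lg = lg, lg_ds = lg_ds, lg_gs_ds = lg_gs_ds, kv = lj$kv)
}

# Sibling-phenotype likelihood ratio, entered once per family:
# log P(D_S = ds | D_I) / P(D_S = ds | !D_I), residual-only.
family_loglr <- function(model) {
  k <- model$prevalence
  pb <- bvn_orthant(model$threshold, model$threshold, model$rho_sib)
  l1 <- log(pb / k) - log((k - pb) / (1 - k))
  l0 <- log(1 - pb / k) - log(1 - (k - pb) / (1 - k))
  c(l0, l1)  # index by ds + 1
}

post_from_loglr <- function(log_lm, k) {
  logit <- log(k) - log(1 - k) + log_lm
  plogis(logit)
}

#' Per-locus likelihood ratio for the index's disease state
#'
#' The likelihood ratio \eqn{L_v = P(\mathrm{data} \mid D_I) /
#' P(\mathrm{data} \mid \bar D_I)} at a single locus, where the data are the
#' index genotype alone, or the index genotype together with the sibling's
#' phenotype and (optionally) genotype. For family-conditioned data the
#' ratio is conditional on \eqn{D_S} (the sibling-phenotype factor is
#' carried once per family, not per locus; see \code{\link{predict.disease_model}}).
#'
#' @param gi index copy count (0, 1, 2 or \code{NA}).
#' @param gs sibling copy count or \code{NULL}/\code{NA} when unobserved.
#' @param ds sibling disease state (\code{TRUE}/\code{FALSE}) or \code{NULL};
#'   required whenever \code{gs} is given.
#' @param variant one-row data frame or list with \code{raf} and \code{a}.
#' @param model a \code{\link{disease_model}}.
#' @return list with \code{id}, \code{log_lr} and \code{lr}.
#' @export
locus_likelihood_ratio <- function(gi, gs = NULL, ds = NULL, variant, model) {
  v <- as.list(as.data.frame(variant))
  if (!is.null(gs) && !is.na(gs) && is.null(ds))
    stop("sibrisk_input_error: sibling genotype requires sibling phenotype",
         call. = FALSE)
  if (is.na(gi) || v$a == 0)
    return(list(id = v$id %||% "v1", log_lr = 0, lr = 1))
  tabs <- locus_loglr_tables(v$raf, v$a, model)
  ll <- if (is.null(ds)) {
    tabs$lg[gi + 1]
  } else if (is.null(gs) || is.na(gs)) {
    tabs$lg_ds[gi + 1, if (isTRUE(ds)) 1 else 2]
  } else {
    tabs$lg_gs_ds[gi + 1, gs + 1, if (isTRUE(ds)) 1 else 2]
  }
  list(id = v$id %||% "v1", log_lr = ll, lr = exp(ll))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted disease risk for an index individual
#'
#' Computes the index's posterior disease risk under the five nested
#' conditioning models: no information; own genotype \eqn{P(D_I|G_I)};
#' sibling phenotype \eqn{P(D_I|D_S)}; own genotype plus sibling phenotype
#' \eqn{P(D_I|G_I,D_S)}; and the full family model
#' \eqn{P(D_I|G_I,G_S,D_S)}.
#'
#' Risks follow the likelihood-ratio construction: posterior odds equal
#' prior odds times \eqn{L_M}, with \eqn{\log L_M = \sum_v \log L_v} across
#' independent loci. The sibling-phenotype factor enters once per family;
#' the per-locus ratios of the family models are conditional on \eqn{D_S},
#' which makes the single-locus case exact Bayes under the nominal-prior
#' measure. Missing genotypes contribute \eqn{L_v = 1}. All combination is
#' done on the log-odds scale.
#'
#' With \code{prior = "nominal"} (default, the reporting convention) the
#' prior odds use the nominal prevalence \eqn{k}; with
#' \code{prior = "realized"} they use the model-implied prevalence at each
#' locus, under which averaging \eqn{P(D_I|G_I)} over HWE genotype
#' frequencies recovers the realized prevalence exactly.
#'
#' @param object a \code{\link{disease_model}}.
#' @param gi integer vector of index copy counts, one per model variant.
#' @param gs optional sibling copy counts (requires \code{ds}).
#' @param ds optional sibling disease state (logical scalar).
#' @param prior \code{"nominal"} or \code{"realized"}.
#' @param ... unused.
#' @return an object of class \code{risk_report}: list with \code{risks}
#'   (named numeric: \code{unconditional}, \code{g}, \code{ds}, \code{g_ds},
#'   \code{g_gs_ds}; entries are \code{NA} when the conditioning data are
#'   absent) and \code{loci} (data frame of per-locus log likelihood ratios
#'   per model).
#' @examples
#' m <- disease_model(1/250, variance_components(0.7, 0.2, 0.1),
#'                    data.frame(raf = 0.425, a = 0.083))
#' predict(m, gi = 2, gs = 0, ds = TRUE)
#' @export
predict.disease_model <- function(object, gi, gs = NULL, ds = NULL,
                                  prior = c("nominal", "realized"), ...) {
  model <- object
  prior <- match.arg(prior)
  v <- model$variants
  nv <- nrow(v)
  if (length(gi) != nv)
    stop("sibrisk_input_error: gi must have one entry per model variant",
         call. = FALSE)
  if (!is.null(gs) && is.null(ds))
    stop("sibrisk_input_error: sibling genotype requires sibling phenotype",
         call. = FALSE)
  if (!is.null(gs) && length(gs) != nv)
    stop("sibrisk_input_error: gs must have one entry per model variant",
         call. = FALSE)
  k <- model$prevalence

  tabs <- lapply(seq_len(nv), function(i)
    locus_loglr_tables(v$raf[i], v$a[i], model))
  ll_g <- vapply(seq_len(nv), function(i)
    if (is.na(gi[i])) 0 else tabs[[i]]$lg[gi[i] + 1], numeric(1))
  loci <- data.frame(id = v$id, log_lr_g = ll_g)

  k0 <- k
  if (prior == "realized" && nv > 0) {
    # prior = model-implied prevalence; with one locus this makes every
    # reported risk exact Bayes on the locus joint distribution
    k0 <- realized_prevalence(model)
  }
  risks <- c(unconditional = k0,
             g = post_from_loglr(sum(ll_g), k0),
             ds = NA_real_, g_ds = NA_real_, g_gs_ds = NA_real_)

  if (!is.null(ds)) {
    dsi <- if (isTRUE(ds)) 1 else 2
    if (prior == "nominal" || nv == 0) {
      fam <- family_loglr(model)[if (isTRUE(ds)) 2 else 1]
    } else {
      pb <- sibling_recurrence_risk(model, include_variants = TRUE)$p_both
      fam <- if (isTRUE(ds)) {
        log(pb / k0) - log((k0 - pb) / (1 - k0))
      } else {
        log(1 - pb / k0) - log(1 - (k0 - pb) / (1 - k0))
      }
    }
    ll_g_ds <- vapply(seq_len(nv), function(i)
      if (is.na(gi[i])) 0 else tabs[[i]]$lg_ds[gi[i] + 1, dsi], numeric(1))
    risks["ds"] <- post_from_loglr(fam, k0)
    risks["g_ds"] <- post_from_loglr(fam + sum(ll_g_ds), k0)
    loci$log_lr_g_ds <- ll_g_ds
    if (!is.null(gs)) {
      ll_full <- vapply(seq_len(nv), function(i) {
        if (is.na(gi[i])) return(0)
        if (is.na(gs[i])) return(tabs[[i]]$lg_ds[gi[i] + 1, dsi])
        tabs[[i]]$lg_gs_ds[gi[i] + 1, gs[i] + 1, dsi]
      }, numeric(1))
      risks["g_gs_ds"] <- post_from_loglr(fam + sum(ll_full), k0)
      loci$log_lr_g_gs_ds <- ll_full
    }
  }
  structure(list(risks = risks, loci = loci, prior = prior,
                 prevalence = k), class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Predicted index disease risk\n")
  lab <- c(unconditional = "P(D_I)", g = "P(D_I|G_I)", ds = "P(D_I|D_S)",
           g_ds = "P(D_I|G_I,D_S)", g_gs_ds = "P(D_I|G_I,G_S,D_S)")
  for (nm in names(x$risks)) {
    if (!is.na(x$risks[nm]))
      cat(sprintf("  %-20s %s\n", lab[nm], format(signif(x$risks[nm], 4))))
  }
  invisible(x)
}

# Model-implied index prevalence: E over genotypes of Phibar(t - mu).
realized_prevalence <- function(model) {
  v <- model$variants
  if (nrow(v) == 0) return(model$prevalence)
  mix <- genotype_value_mixture(model)
  sum(mix$w * pnorm((model$threshold - mix$mu) / model$residual_scale,
                    lower.tail = FALSE))
}

# Distribution of the summed centered genotype value for one individual:
# exact sparse convolution across loci (support merged on a 1e-12 grid).
genotype_value_mixture <- function(model) {
  v <- model$variants
  w <- 1; mu <- 0
  for (i in seq_len(nrow(v))) {
    hwe <- hwe_genotype_freqs(v$raf[i])
    val <- genotype_value(0:2, v$raf[i], v$a[i])
    w <- as.vector(outer(w, hwe))
    mu <- as.vector(outer(mu, val, `+`))
    if (length(w) > 20000) {
      key <- round(mu / 1e-9)
      agg <- rowsum(w, key)
      mu <- as.numeric(rownames(agg)) * 1e-9
      w <- as.vector(agg)
    }
  }
  list(w = w, mu = mu)
}

#' Expected absolute change in predicted risk
#'
#' The personal-impact metric \eqn{\delta = \sum_i |P_i - Q_i| / N}
#' comparing pre-test risks \eqn{P} with post-test risks \eqn{Q}.
#'
#' @param pre_risks,post_risks equal-length probability vectors.
#' @return mean absolute difference.
#' @export
delta_metric <- function(pre_risks, post_risks) {
  if (length(pre_risks) != length(post_risks))
    stop("sibrisk_input_error: risk vectors must have equal length",
         call. = FALSE)
  mean(abs(pre_risks - post_risks))
}

#' Score a simulated family dataset under the five models
#'
#' Vectorized scoring of every family in a \code{\link{simulate_families}}
#' dataset: per-locus log likelihood-ratio lookup tables are built once and
#' applied by genotype indexing, then combined across loci on the log scale.
#'
#' @param dataset a \code{family_dataset}.
#' @param model the \code{\link{disease_model}} used for prediction (usually
#'   the generating model).
#' @return data frame with one row per family: \code{risk_g},
#'   \code{risk_ds}, \code{risk_g_ds}, \code{risk_g_gs_ds} (posterior risks
#'   for the index) and \code{affected_index}, \code{affected_sib}.
#' @export
score_families <- function(dataset, model) {
  stopifnot(inherits(dataset, "family_dataset"),
            inherits(model, "disease_model"))
  v <- model$variants
  nv <- nrow(v)
  gi <- dataset$genotypes_index
  gs <- dataset$genotypes_sib
  if (ncol(gi) != nv)
    stop("sibrisk_input_error: dataset loci do not match model variants",
         call. = FALSE)
  n <- nrow(gi)
  dsi <- ifelse(dataset$affected_sib, 1L, 2L)
  ll_g <- numeric(n); ll_g_ds <- numeric(n); ll_full <- numeric(n)
  for (i in seq_len(nv)) {
    tb <- locus_loglr_tables(v$raf[i], v$a[i], model)
    ll_g <- ll_g + tb$lg[gi[, i] + 1L]
    ll_g_ds <- ll_g_ds + tb$lg_ds[cbind(gi[, i] + 1L, dsi)]
    ll_full <- ll_full + tb$lg_gs_ds[cbind(gi[, i] + 1L, gs[, i] + 1L, dsi)]
  }
  fam <- family_loglr(model)
  ll_fam <- fam[ifelse(dataset$affected_sib, 2L, 1L)]
  k <- model$prevalence
  data.frame(
    risk_g = post_from_loglr(ll_g, k),
    risk_ds = post_from_loglr(ll_fam, k),
    risk_g_ds = post_from_loglr(ll_fam + ll_g_ds, k),
    risk_g_gs_ds = post_from_loglr(ll_fam + ll_full, k),
    affected_index = dataset$affected_index,
    affected_sib = dataset$affected_sib
  )
}
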