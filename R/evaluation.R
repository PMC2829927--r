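#' Area under the ROC curve
#'
#' Rank-based (Mann--Whitney) AUC with midrank tie handling: the probability
#' that a randomly chosen case outranks a randomly chosen control, counting
#' ties as one half. Invariant to monotone transformations of the scores.
#' Midranks matter here because single-locus risk predictions take only a
#' handful of distinct values.
#'
#' @param scores numeric predicted risks (higher = more at risk).
#' @param labels binary disease states (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("sibrisk_domain_error: AUC undefined with a single class",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Squared correlation between disease state and predicted risk
#'
#' Point-biserial (Pearson) correlation between the 0/1 disease state and
#' the predicted risk, squared.
#'
#' @inheritParams auc
#' @return \eqn{R^2} in [0, 1].
#' @export
r_squared <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (stats::sd(scores) == 0 || stats::sd(labels) == 0)
    stop("sibrisk_domain_error: R^2 undefined with zero variance",
         call. = FALSE)
  stats::cor(scores, labels)^2
}

#' Nagelkerke pseudo-R-squared of predicted risks
#'
#' Likelihood-based variance-explained measure widely used for genetic risk
#' scores: the Cox--Snell ratio \eqn{1 - (L_0/L_1)^{2/n}} rescaled by its
#' maximum \eqn{1 - L_0^{2/n}}, where \eqn{L_1} is the Bernoulli likelihood
#' of the labels under the predicted risks and \eqn{L_0} under the sample
#' case rate. Unlike the point-biserial \code{\link{r_squared}}, which is
#' bounded near zero for rare outcomes, this measure is comparable across
#' prevalences, and it is the scale on which variance-explained values near
#' 5--10\% are conventionally reported for risk-variant panels.
#'
#' @inheritParams auc
#' @return pseudo-R-squared in [0, 1].
#' @export
r2_nagelkerke <- function(scores, labels) {
  labels <- as.integer(labels)
  if (any(scores <= 0 | scores >= 1))
    stop("sibrisk_domain_error: scores must be probabilities in (0, 1)",
         call. = FALSE)
  n <- length(labels)
  k <- mean(labels)
  if (k == 0 || k == 1)
    stop("sibrisk_domain_error: undefined with a single class", call. = FALSE)
  ll1 <- sum(log(ifelse(labels == 1L, scores, 1 - scores)))
  ll0 <- n * (k * log(k) + (1 - k) * log(1 - k))
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

#' Case enrichment in the top risk quantile
#'
#' Case rate among the \code{ceiling(q * N / 100)} individuals with the
#' highest predicted risk, divided by the population prevalence \code{k}
#' (not the sample case rate; in an ascertained sample the enrichment can
#' therefore greatly exceed 1). Ties at the cutoff are broken by stable
#' score order, then input order.
#'
#' @inheritParams auc
#' @param q top percentage, in (0, 100].
#' @param k population prevalence used as the denominator.
#' @return fold enrichment \eqn{T_q}.
#' @export
enrichment_top_q <- function(scores, labels, q, k) {
  if (q <= 0 || q > 100)
    stop("sibrisk_domain_error: q must lie in (0, 100]", call. = FALSE)
  labels <- as.integer(labels)
  n <- length(scores)
  m <- ceiling(q * n / 100)
  top <- order(-scores)[seq_len(m)]   # order() is stable: input order breaks ties
  mean(labels[top]) / k
}

#' Calibration table of predicted versus observed risk
#'
#' Bins individuals by predicted risk and reports, per bin, the mean
#' predicted risk, the observed case rate and the count. A well-calibrated
#' model has observed rates close to mean predictions relative to binomial
#' error \eqn{\sqrt{p(1-p)/n}}.
#'
#' @inheritParams auc
#' @param breaks bin boundaries covering (0, 1), or a single bin width.
#' @return data frame with columns \code{bin_lo}, \code{bin_hi}, \code{n},
#'   \code{mean_predicted}, \code{observed_rate} (NA for empty bins).
#' @export
calibration_table <- function(scores, labels, breaks = 0.02) {
  labels <- as.integer(labels)
  if (length(breaks) == 1) breaks <- seq(0, 1, by = breaks)
  if (breaks[1] > min(scores) || breaks[length(breaks)] < max(scores))
    stop("sibrisk_domain_error: breaks must cover the score range",
         call. = FALSE)
  bin <- cut(scores, breaks, include.lowest = TRUE)
  n <- as.vector(table(bin))
  mp <- tapply(scores, bin, mean)
  ob <- tapply(labels, bin, mean)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             n = n, mean_predicted = as.vector(mp),
             observed_rate = as.vector(ob), row.names = NULL)
}

#' Full metrics report for one prediction model
#'
#' AUC, squared correlation and top-quantile enrichments for one vector of
#' predicted risks, in the shape of one row of the simulation results table.
#'
#' @inheritParams auc
#' @param k population prevalence for the enrichment denominator.
#' @param quantiles top percentages for the enrichment metrics.
#' @return list of class \code{metrics_report} with \code{auc}, \code{r2},
#'   \code{t_enrich} (named vector), \code{n_cases}, \code{n_total}.
#' @export
metrics_report <- function(scores, labels, k, quantiles = c(1, 5, 10)) {
  labels <- as.integer(labels)
  te <- vapply(quantiles, function(q) enrichment_top_q(scores, labels, q, k),
               numeric(1))
  names(te) <- paste0("T", quantiles)
  structure(list(auc = auc(scores, labels),
                 r2 = r_squared(scores, labels),
                 r2_nagelkerke = r2_nagelkerke(scores, labels),
                 t_enrich = te,
                 n_cases = sum(labels == 1L), n_total = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.3f  R2 %.3f  %s  (%d cases / %d)\n", x$auc, x$r2,
              paste(names(x$t_enrich), sprintf("%.2f", x$t_enrich),
                    collapse = "  "),
              x$n_cases, x$n_total))
  invisible(x)
}

#' Metrics table across prediction models
#'
#' Applies \code{\link{metrics_report}} to each score column and stacks the
#' results into the results-table shape (rows = model, columns = AUC, R2,
#' T1, T5, T10).
#'
#' @param scores data frame of predicted-risk columns (e.g. from
#'   \code{\link{score_families}}).
#' @param labels binary disease states.
#' @param k population prevalence.
#' @param quantiles top percentages.
#' @return data frame, one row per score column.
#' @export
metrics_table <- function(scores, labels, k, quantiles = c(1, 5, 10)) {
  rows <- lapply(names(scores), function(nm) {
    m <- metrics_report(scores[[nm]], labels, k, quantiles)
    data.frame(model = nm, AUC = m$auc, R2 = m$r2,
               R2_nagelkerke = m$r2_nagelkerke,
               t(as.data.frame(m$t_enrich)), row.names = NULL)
  })
  do.call(rbind, rows)
}
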