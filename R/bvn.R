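#' Bivariate normal orthant probability
#'
#' Computes \eqn{P(Z_1 \ge h_1, Z_2 \ge h_2)} for a standard bivariate normal
#' vector with correlation \code{rho}. This is the workhorse of the
#' liability-threshold machinery: joint sibling disease probabilities are
#' upper orthants of the residual liability distribution.
#'
#' Uses Genz's Gauss--Legendre algorithm (the BVND routine underlying
#' TVPACK): a transformed single integral over \code{asin(rho)} for
#' \code{|rho| < 0.925} and a Taylor-corrected expansion near the
#' comonotone limit otherwise. Absolute accuracy is better than 1e-14,
#' well inside the 1e-10 contract.
#'
#' @param h1,h2 numeric vectors of lower limits, in liability (standard
#'   deviation) units. Recycled to a common length.
#' @param rho correlation(s), \code{-1 <= rho <= 1}. The boundary values are
#'   returned as their analytic limits: for \code{rho = 1},
#'   \eqn{\bar\Phi(\max(h_1,h_2))}; for \code{rho = -1},
#'   \eqn{\max(0, 1 - \Phi(h_1) - \Phi(h_2))}.
#' @return numeric vector of probabilities.
#' @examples
#' bvn_orthant(0, 0, 0)    # 0.25
#' bvn_orthant(0, 0, 0.5)  # 1/3
#' @export
bvn_orthant <- function(h1, h2, rho) {
  n <- max(length(h1), length(h2), length(rho))
  h1 <- rep_len(as.numeric(h1), n)
  h2 <- rep_len(as.numeric(h2), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("sibrisk_domain_error: correlation must lie in [-1, 1]",
         call. = FALSE)
  r1 <- rho[1]
  if (n > 1 && all(rho == r1) && abs(r1) < 0.925 && r1 != 0 &&
      all(is.finite(h1)) && all(is.finite(h2)))
    return(bvnu_vec(h1, h2, r1))
  vapply(seq_len(n), function(i) bvnu_scalar(h1[i], h2[i], rho[i]),
         numeric(1))
}

# vectorized Gauss-Legendre path for a single moderate correlation
bvnu_vec <- function(h, k, r) {
  ar <- abs(r)
  if (ar < 0.3)       { w <- .gl6w;  x <- .gl6x }
  else if (ar < 0.75) { w <- .gl12w; x <- .gl12x }
  else                { w <- .gl20w; x <- .gl20x }
  w <- c(w, w); x <- c(1 - x, 1 + x)
  asr <- asin(r) / 2
  sn <- sin(asr * x)
  hk <- h * k
  hs <- (h * h + k * k) / 2
  # outer over quadrature points: n x m
  e <- exp((outer(hk, sn) - hs) / rep(1 - sn * sn, each = length(h)))
  bvn <- drop(e %*% w) * asr / (2 * pi) + pnorm(-h) * pnorm(-k)
  pmin(1, pmax(0, bvn))
}

# Gauss-Legendre abscissae/weights on (0,1) halves, per Genz's BVND
.gl6w <- c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904)
.gl6x <- c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
.gl12w <- c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
            0.2031674267230659, 0.2334925365383547, 0.2491470458134029)
.gl12x <- c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
            0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
.gl20w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
            0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
            0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
            0.1527533871307259)
.gl20x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
            0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
            0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
            0.07652652113349733)

# scalar P(Z1 >= h, Z2 >= k), |r| <= 1
bvnu_scalar <- function(h, k, r) {
  if (is.na(h) || is.na(k)) return(NA_real_)
  if (h == Inf || k == Inf) return(0)
  if (h == -Inf) return(if (k == -Inf) 1 else pnorm(-k))
  if (k == -Inf) return(pnorm(-h))
  if (r == 0) return(pnorm(-h) * pnorm(-k))
  if (r == 1) return(pnorm(-max(h, k)))
  if (r == -1) return(max(0, pnorm(-h) - pnorm(k)))
  ar <- abs(r)
  if (ar < 0.3)       { w <- .gl6w;  x <- .gl6x }
  else if (ar < 0.75) { w <- .gl12w; x <- .gl12x }
  else                { w <- .gl20w; x <- .gl20x }
  w <- c(w, w); x <- c(1 - x, 1 + x)
  tp <- 2 * pi
  hk <- h * k
  if (ar < 0.925) {
    hs <- (h * h + k * k) / 2
    asr <- asin(r) / 2
    sn <- sin(asr * x)
    bvn <- sum(exp((sn * hk - hs) / (1 - sn * sn)) * w)
    bvn <- bvn * asr / tp + pnorm(-h) * pnorm(-k)
  } else {
    if (r < 0) { k <- -k; hk <- -hk }
    bvn <- 0
    as_ <- 1 - r * r
    a <- sqrt(as_)
    bs <- (h - k)^2
    asr <- -(bs / as_ + hk) / 2
    cc <- (4 - hk) / 8
    d <- (12 - hk) / 16
    if (asr > -100)
      bvn <- a * exp(asr) *
        (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
    if (hk > -100) {
      b <- sqrt(bs)
      sp <- sqrt(tp) * pnorm(-b / a)
      bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
    }
    a <- a / 2
    for (i in seq_along(x)) {
      xs <- (a * x[i])^2
      rs <- sqrt(1 - xs)
      asr <- -(bs / xs + hk) / 2
      if (asr > -100) {
        sp <- 1 + cc * xs * (1 + d * xs)
        ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
        bvn <- bvn + a * w[i] * exp(asr) * (ep - sp)
      }
    }
    bvn <- -bvn / tp
    if (r > 0) {
      bvn <- bvn + pnorm(-max(h, k))
    } else {
      bvn <- -bvn + max(0, pnorm(-h) - pnorm(-k))
    }
  }
  min(1, max(0, bvn))
}
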