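#' Log probability mass of the binomial count model
#'
#' Thin, vectorized wrapper around the exact binomial pmf with the limiting
#' conventions at p = 0 and p = 1 (a point mass at 0 or n).
#'
#' @param y Observed germinant count(s), `0 <= y <= n`.
#' @param n Seeds planted.
#' @param p Germination probability in `[0, 1]`.
#' @return Log probability (vectorized).
#' @export
logpmf_binomial <- function(y, n, p) {
  if (any(y < 0 | y > n)) stop("y must satisfy 0 <= y <= n", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  stats::dbinom(y, n, p, log = TRUE)
}

#' Log probability mass of the beta-binomial count model
#'
#' Beta-binomial in mean/precision form: the per-group germination
#' probability is Beta(p*phi, (1-p)*phi), so E(y) = n*p and
#' Var(y) = n*p*(1-p)*(1 + (n-1)/(phi+1)). Small `phi` means strong
#' overdispersion (heterogeneous seed quality within a mean); as
#' `phi -> Inf` the distribution converges to Binomial(n, p).
#'
#' @param y Observed count(s), `0 <= y <= n`.
#' @param n Seeds planted.
#' @param p Mean germination probability, strictly inside (0, 1).
#' @param phi Precision, `> 0`.
#' @return Log probability (vectorized).
#' @export
logpmf_betabinomial <- function(y, n, p, phi) {
  if (any(y < 0 | y > n)) stop("y must satisfy 0 <= y <= n", call. = FALSE)
  if (any(phi <= 0)) stop("phi must be > 0", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  a <- p * phi
  b <- (1 - p) * phi
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

#' Log probability mass of a zero-inflated count model
#'
#' Mixes a structural-zero component (probability `pi`, e.g. a wholly
#' inviable group of seeds) with a base count distribution. Zeros can
#' therefore arise from two processes: the structural component or an
#' ordinary draw of 0 from the base pmf. Computed with log-sum-exp
#' stability at y = 0.
#'
#' @param y Observed count(s).
#' @param n Seeds planted.
#' @param base_logpmf Function `(y, n) -> log pmf` of the base count model
#'   (already bound to its parameters).
#' @param pi Zero-inflation probability in `[0, 1]` (scalar or vector).
#' @return Log probability (vectorized over `y`, `n`, `pi`).
#' @export
logpmf_zero_inflated <- function(y, n, base_logpmf, pi) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
  base <- base_logpmf(y, n)
  k <- pmax(length(y), length(n), length(pi))
  y <- rep_len(y, k); pi <- rep_len(pi, k); base <- rep_len(base, k)
  out <- log1p(-pi) + base
  at0 <- y == 0
  if (any(at0)) {
    # log(pi + (1-pi) * exp(base)) via log-sum-exp
    la <- log(pi[at0])
    lb <- log1p(-pi[at0]) + base[at0]
    m <- pmax(la, lb)
    out[at0] <- ifelse(pi[at0] == 0, lb,
                       ifelse(pi[at0] == 1, 0,
                              m + log(exp(la - m) + exp(lb - m))))
  }
  if (any(pi == 1 & y > 0)) out[pi == 1 & y > 0] <- -Inf
  out
}

# Pointwise log-likelihood for one parameter setting across all groups.
# family is "BIN", "ZIB", "BB" or "ZIBB"; p and pi are per-group vectors.
loglik_family <- function(family, y, n, p, phi = NULL, pi = NULL) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  base <- switch(family,
    BIN  = ,
    ZIB  = stats::dbinom(y, n, p, log = TRUE),
    BB   = ,
    ZIBB = logpmf_betabinomial(y, n, p, phi),
    stop("unknown family: ", family, call. = FALSE)
  )
  if (family %in% c("ZIB", "ZIBB")) {
    out <- log1p(-pi) + base
    at0 <- y == 0
    if (any(at0)) {
      la <- log(pi[at0]); lb <- log1p(-pi[at0]) + base[at0]
      m <- pmax(la, lb)
      out[at0] <- m + log(exp(la - m) + exp(lb - m))
    }
    out
  } else {
    base
  }
}

# Random counts from one of the four families (vectorized over groups).
rcounts_family <- function(family, n, p, phi = NULL, pi = NULL) {
  k <- length(n)
  p <- rep_len(pmin(pmax(p, 1e-12), 1 - 1e-12), k)
  y <- if (family %in% c("BB", "ZIBB")) {
    pg <- stats::rbeta(k, p * phi, (1 - p) * phi)
    # guard against numerically degenerate beta draws
    pg[!is.finite(pg)] <- p[!is.finite(pg)]
    stats::rbinom(k, n, pg)
  } else {
    stats::rbinom(k, n, p)
  }
  if (family %in% c("ZIB", "ZIBB")) {
    z <- stats::rbinom(k, 1, rep_len(pi, k))
    y[z == 1] <- 0L
  }
  y
}
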