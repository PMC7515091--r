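# Exact algebra of exponential polynomials sum_j c_j t^k_j exp(-l_j t).
# This is the closed-form engine behind path-chain probabilities: the
# convolution int_0^t exp(-a(t-s)) f(s) ds maps the family to itself, and
# repeated rates are merged into t^k terms instead of being pushed through
# near-singular divided differences.

.EP_RATE_RTOL <- 1e-12

#' Construct an exponential polynomial
#'
#' @param coef numeric coefficients.
#' @param power non-negative integer powers of `t`.
#' @param rate non-negative decay rates.
#' @return An [ExpPolynomial-class]; terms with equal power and rate
#'   (within a relative `1e-12` on the rate) are merged, zero terms
#'   dropped.
#' @examples
#' f <- expPolynomial(1, 0, 2)   # exp(-2 t)
#' epEval(f, c(0, 1))
#' @export
expPolynomial <- function(coef, power = 0L, rate = 0) {
  n <- max(length(coef), length(power), length(rate))
  ep <- new("ExpPolynomial", coef = rep_len(as.numeric(coef), n),
    power = rep_len(as.integer(power), n), rate = rep_len(as.numeric(rate), n))
  .epNormalize(ep)
}

.epNormalize <- function(ep) {
  keep <- ep@coef != 0
  cf <- ep@coef[keep]; pw <- ep@power[keep]; rt <- ep@rate[keep]
  if (!length(cf))
    return(new("ExpPolynomial", coef = numeric(0), power = integer(0),
      rate = numeric(0)))
  # cluster rates within relative tolerance, then merge identical (k, rate)
  o <- order(rt)
  cf <- cf[o]; pw <- pw[o]; rt <- rt[o]
  cluster <- cumsum(c(TRUE,
    diff(rt) > .EP_RATE_RTOL * pmax(1, rt[-length(rt)])))
  rt <- stats::ave(rt, cluster, FUN = function(v) v[1L])
  key <- paste(pw, cluster)
  first <- !duplicated(key)
  agg <- rowsum(cf, key)
  cf <- unname(agg[match(key[first], rownames(agg)), 1L])
  pw <- pw[first]; rt <- rt[first]
  keep <- cf != 0
  new("ExpPolynomial", coef = cf[keep], power = pw[keep], rate = rt[keep])
}

#' Evaluate, convolve, scale and integrate exponential polynomials
#'
#' `epEval()` evaluates the sum at the given times.  `epConvolve()`
#' returns the exact closed form of
#' \eqn{\beta \int_0^t e^{-a(t-s)} f(s)\,ds}: for a term
#' \eqn{c\,s^k e^{-\lambda s}} with \eqn{\mu = \lambda - a} away from zero
#' the integral is a divided-difference pair of exponentials, while for
#' \eqn{|\mu|} below a relative `1e-12` the degenerate limit
#' \eqn{c\,t^{k+1}/(k+1)\,e^{-at}} is taken, which is what keeps repeated
#' exit rates (a revisited population along a path) numerically exact.
#' `epIntegral()` is the exact antiderivative evaluated on `[0, t]`;
#' `epScale()` multiplies by a constant; `epGateFactor()` multiplies by
#' \eqn{A\,(1 - e^{-a t})}, the elementary factor of the gating cascade.
#'
#' @param ep an [ExpPolynomial-class].
#' @param t numeric vector of times.
#' @param a decay rate of the convolution kernel / gate factor.
#' @param beta multiplicative transition rate.
#' @param s,A scalar factors.
#' @return `epEval`/`epIntegral`: numeric vector over `t`; the others: an
#'   [ExpPolynomial-class].
#' @export
epEval <- function(ep, t) {
  if (!length(ep@coef)) return(numeric(length(t)))
  vapply(t, function(tt)
    sum(ep@coef * tt^ep@power * exp(-ep@rate * tt)), numeric(1))
}

#' @rdname epEval
#' @export
epConvolve <- function(ep, a, beta = 1) {
  cf <- numeric(0); pw <- integer(0); rt <- numeric(0)
  for (i in seq_along(ep@coef)) {
    c0 <- beta * ep@coef[i]
    k <- ep@power[i]
    lam <- ep@rate[i]
    mu <- lam - a
    if (abs(mu) <= .EP_RATE_RTOL * max(1, a, lam)) {
      cf <- c(cf, c0 / (k + 1)); pw <- c(pw, k + 1L); rt <- c(rt, a)
    } else {
      cf <- c(cf, c0 * factorial(k) / mu^(k + 1))
      pw <- c(pw, 0L); rt <- c(rt, a)
      j <- 0:k
      cf <- c(cf, -c0 * (factorial(k) / factorial(j)) / mu^(k + 1 - j))
      pw <- c(pw, as.integer(j)); rt <- c(rt, rep(lam, k + 1))
    }
  }
  .epNormalize(new("ExpPolynomial", coef = cf, power = pw, rate = rt))
}

#' @rdname epEval
#' @export
epIntegral <- function(ep, t) {
  if (!length(ep@coef)) return(numeric(length(t)))
  vapply(t, function(tt) {
    tot <- 0
    for (i in seq_along(ep@coef)) {
      c0 <- ep@coef[i]; k <- ep@power[i]; lam <- ep@rate[i]
      tot <- tot + if (lam <= .EP_RATE_RTOL) {
        c0 * tt^(k + 1) / (k + 1)
      } else {
        j <- 0:k
        c0 * (factorial(k) / lam^(k + 1) -
          exp(-lam * tt) * sum((factorial(k) / factorial(j)) *
            tt^j / lam^(k + 1 - j)))
      }
    }
    tot
  }, numeric(1))
}

#' @rdname epEval
#' @export
epScale <- function(ep, s) {
  new("ExpPolynomial", coef = s * ep@coef, power = ep@power, rate = ep@rate)
}

#' @rdname epEval
#' @export
epGateFactor <- function(ep, A, a) {
  .epNormalize(new("ExpPolynomial",
    coef = c(A * ep@coef, -A * ep@coef),
    power = c(ep@power, ep@power),
    rate = c(ep@rate, ep@rate + a)))
}

setMethod("show", "ExpPolynomial", function(object) {
  if (!length(object@coef)) {
    cat("ExpPolynomial: 0\n")
    return(invisible(NULL))
  }
  terms <- sprintf("%+.6g t^%d e^(-%g t)", object@coef, object@power,
    object@rate)
  cat("ExpPolynomial:", paste(terms, collapse = " "), "\n")
})
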