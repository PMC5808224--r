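#' Lower branch of the Lambert W function
#'
#' Vectorized evaluation of \eqn{W_{-1}(x)} for \eqn{x \in [-1/e, 0)}, the
#' branch with \eqn{W \le -1}.  This branch gives the larger-\eqn{V} (spike
#' threshold) crossing of the membrane-potential nullcline of the aEIF model;
#' see [nullcline_threshold_V()].
#'
#' Computed in log space, writing \eqn{W = -t} with \eqn{t - \ln t =
#' -\ln(-x)}: fixed-point iterations \eqn{t \leftarrow -\ln(-x) + \ln t}
#' followed by Newton polishing, which is immune to underflow of `x` itself;
#' near the branch point \eqn{-1/e} a series in \eqn{\sqrt{2(1 + e x)}} is
#' used.  Accurate to machine precision on the whole branch; `x = -0`
#' (underflow) maps to `-Inf`.
#'
#' @param x numeric vector in `[-1/e, 0]`.
#' @return numeric vector of the same length, values in `[-Inf, -1]`.
#' @export
#' @examples
#' lambert_wm1(-exp(-1))   # exactly -1
#' w <- lambert_wm1(-0.1)
#' w * exp(w)              # recovers -0.1
lambert_wm1 <- function(x) {
  x <- as.numeric(x)
  out <- rep(NA_real_, length(x))
  bad <- is.na(x) | x < -exp(-1) - 1e-12 | x > 0
  # clip tiny overshoot of the branch point from upstream rounding
  x[!bad & x < -exp(-1)] <- -exp(-1)
  zero <- !bad & x == 0
  out[zero] <- -Inf
  near <- !bad & !zero & x < -exp(-1) * 0.995   # close to the branch point
  if (any(near)) {
    p <- -sqrt(pmax(0, 2 * (exp(1) * x[near] + 1)))
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72 - 43 * p^4 / 540
    # polish with Halley (no underflow issues here, w is O(1))
    for (i in 1:5) {
      ew <- exp(w)
      f <- w * ew - x[near]
      w1 <- w + 1
      dw <- f / (ew * w1 - (w + 2) * f / (2 * w1))
      dw[!is.finite(dw)] <- 0              # exactly at the branch point
      w <- w - dw
    }
    out[near] <- pmin(w, -1)
  }
  ok <- !bad & !zero & !near
  if (any(ok)) {
    mu <- -log(-x[ok])                          # t - ln t = mu, mu > 1
    t <- pmax(1.2, mu)
    for (i in 1:60) t <- mu + log(t)            # contraction for t > 1
    for (i in 1:4) t <- t - (t - log(t) - mu) * t / (t - 1)   # Newton polish
    out[ok] <- -t
  }
  if (any(bad & !is.na(x))) out[bad & !is.na(x)] <- NaN
  out
}

# W_{-1}(-e^u) computed directly from u, immune to underflow of e^u for very
# negative u (adaptation far above the nullcline minimum maps there).
lambert_wm1_exp <- function(u) {
  u <- as.numeric(u)
  out <- rep(NA_real_, length(u))
  hi <- !is.na(u) & u > -30          # no underflow risk: go through x
  if (any(hi)) out[hi] <- lambert_wm1(-exp(u[hi]))
  lo <- !is.na(u) & u <= -30
  if (any(lo)) {
    mu <- -u[lo]                      # solve t - ln t = mu, W = -t
    t <- mu
    for (i in 1:40) t <- mu + log(t)
    for (i in 1:4) t <- t - (t - log(t) - mu) * t / (t - 1)
    out[lo] <- -t
  }
  out
}
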