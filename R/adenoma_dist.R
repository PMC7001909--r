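#' Negative-binomial parameters of the adenoma compartment
#'
#' With the transformation rate set to zero the adenoma compartment is a
#' linear birth-death process with immigration and its size at age `t` is
#' negative binomial with dispersion `r = mu1 / b1` and success probability
#' `p(t) = b1 (exp(gamma1 t) - 1) / (b1 exp(gamma1 t) - d1)`.  Optionally the
#' transformation drain can be folded into the death rate
#' (`include_mu2 = TRUE`), giving the exact A marginal of the full process.
#'
#' @param theta a [model_params()] object.
#' @param t age(s) in years.
#' @param include_mu2 if TRUE use effective death rate `d1 + mu2`.
#' @return list with `r` (scalar) and `p` (same length as `t`), plus
#'   `log1mp = log(1 - p)` computed stably.
#' @examples
#' th <- model_params(3.1, 9, 8.8)
#' nb_params(th, 1)  # r = 0.3444, p = 0.9088
#' @export
nb_params <- function(theta, t, include_mu2 = FALSE) {
  if (theta$b1 <= 0) stop("b1 must be positive")
  if (any(t < 0)) stop("age must be non-negative")
  d1 <- theta$d1 + if (include_mu2) theta$mu2 else 0
  g1 <- theta$b1 - d1
  r <- theta$mu1 / theta$b1
  # p = Q/(Q + g1), 1 - p = g1/(Q + g1), Q = b1*expm1(g1 t); g1 -> 0 limit
  # p = b1 t / (1 + b1 t)
  small <- abs(g1 * t) < 1e-10
  Q <- theta$b1 * expm1(g1 * t)
  p <- ifelse(small, theta$b1 * t / (1 + theta$b1 * t), Q / (Q + g1))
  log1mp <- ifelse(small, -log1p(theta$b1 * t), log(g1) - log(Q + g1))
  list(r = r, p = p, log1mp = log1mp)
}

#' Probability mass function of the adenoma compartment size
#'
#' @inheritParams nb_params
#' @param k cell count(s), non-negative integers.
#' @param log return log-probabilities.
#' @return `P(A(t) = k)`, vectorized over `k` (with scalar `t`) or over `t`
#'   (with scalar `k`).
#' @export
adenoma_pmf <- function(theta, t, k, log = FALSE, include_mu2 = FALSE) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integer")
  nb <- nb_params(theta, t, include_mu2)
  out <- dnbinom(k, size = nb$r, prob = exp(nb$log1mp), log = log)
  # t = 0 gives p = 0: point mass at zero (dnbinom handles prob = 1)
  out
}

#' Cumulative distribution of the adenoma compartment size
#'
#' `P(A(t) <= k)`, evaluated through the regularized incomplete beta
#' function: the upper tail `P(A >= k)` equals `I_p(k, r) = pbeta(p, k, r)`.
#'
#' @inheritParams adenoma_pmf
#' @export
adenoma_cdf <- function(theta, t, k, include_mu2 = FALSE) {
  nb <- nb_params(theta, t, include_mu2)
  ifelse(k < 0, 0, pnbinom(pmax(k, 0), size = nb$r, prob = exp(nb$log1mp)))
}

# upper-tail P(A(t) > L) for half-open bins; L = -1 gives 1
nb_tail <- function(nb, L) {
  ifelse(L < 0, 1,
         ifelse(is.infinite(L), 0, pbeta(nb$p, L + 1, nb$r)))
}

#' Binned likelihood of an adenoma observation
#'
#' The probability that the adenoma compartment size falls in the half-open
#' bin `(L, U]` at the observation age:
#' `I_p(L + 1, r) - I_p(U + 1, r)` with `I_p(k, r)` the regularized
#' incomplete beta function (the negative-binomial tail).  A zero-containing
#' bin (`lower = -1`) gives `P(A <= U)`.
#'
#' @param theta a [model_params()] object.
#' @param obs a `crc_obs` data.frame of compartment-A rows, or a list/row
#'   with `age`, `lower`, `upper`.
#' @param include_mu2 see [nb_params()].
#' @return vector of bin probabilities, one per row of `obs`.
#' @export
adenoma_bin_likelihood <- function(theta, obs, include_mu2 = FALSE) {
  if (!is.data.frame(obs)) obs <- as.data.frame(obs)
  if ("compartment" %in% names(obs) && !all(obs$compartment == "A"))
    stop("adenoma_bin_likelihood expects compartment-A observations")
  if (any(obs$lower >= obs$upper)) stop("degenerate bin: lower >= upper")
  out <- numeric(nrow(obs))
  for (tt in unique(obs$age)) {
    idx <- obs$age == tt
    nb <- nb_params(theta, tt, include_mu2)
    out[idx] <- nb_tail(nb, obs$lower[idx]) - nb_tail(nb, obs$upper[idx])
  }
  pmin(pmax(out, 0), 1)
}

#' Mean adenoma compartment size
#'
#' `E[A(t)] = mu1 (exp(gamma1 t) - 1) / gamma1` (limit `mu1 t` at
#' `gamma1 = 0`).
#' @inheritParams nb_params
#' @export
adenoma_mean <- function(theta, t, include_mu2 = FALSE) {
  g1 <- theta$gamma1 - if (include_mu2) theta$mu2 else 0
  ifelse(abs(g1 * t) < 1e-10, theta$mu1 * t, theta$mu1 * expm1(g1 * t) / g1)
}
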