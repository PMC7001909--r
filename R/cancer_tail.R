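# Large-size saddle-point approximation to the carcinoma size distribution
# and the binned compartment-M likelihood built on it.

#' Saddle-point exponent and derivatives
#'
#' `V(s) = -log(1 - s) + log G(s, t) - (N + 1) log s` and its first two
#' derivatives, the exponent of the contour-integral representation of
#' `P(M(t) <= N)`.  Derivatives of `log G` are obtained from companion ODEs
#' for the s-derivatives of the single-ancestor PGF, not finite differences.
#'
#' @param s evaluation point(s) in (0, 1).
#' @param theta a [model_params()] object.
#' @param t age in years.
#' @param N target cell count.
#' @return list with vectors `V`, `V1`, `V2`.
#' @export
V_and_derivatives <- function(s, theta, t, N) {
  if (any(s <= 0 | s >= 1)) stop("s must be inside (0, 1)")
  res <- V_profile_cpp(as_par_vector(theta), as.numeric(s), t, N, 0L, 0,
                       1L, .pgf_rtol, .pgf_atol)
  list(V = res$V, V1 = res$V1, V2 = res$V2)
}

# internal: saddle state for a vector of N at one age; returns log CDF
saddle_log_cdf <- function(theta, t, N, mode = 0L, s0 = 0, tail = 1L) {
  res <- saddle_cdf_cpp(as_par_vector(theta), t, as.numeric(N), mode, s0,
                        tail, .pgf_rtol, .pgf_atol)
  if (any(res$converged == 0))
    warning("saddle-point root search did not fully converge for some N")
  res
}

#' Saddle-point CDF of the carcinoma compartment
#'
#' Large-size approximation
#' `P(M(t) <= N) ~ exp(V(s*)) / sqrt(2 pi V''(s*))`, with `s*` the root of
#' `V'(s) = 0` in (0, 1).  Accurate to well under 1% relative error for
#' `N >= 100`; below `N_min_approx` the computation is routed to the exact
#' contour coefficients of [exact_cdf_small()].
#'
#' @param theta a [model_params()] object.
#' @param t age in years (scalar).
#' @param N cell count(s).
#' @param N_min_approx switch-over size below which the exact contour path
#'   is used (default 100).
#' @param log.p return log-probabilities.
#' @return `P(M(t) <= N)` (clipped to `[0, 1]`), same length as `N`.
#' @examples
#' th <- model_params(3.1, 9, 8.8, 1e-5, 9.2, 8.8)
#' cancer_cdf_approx(th, 50, c(100, 1000))
#' @export
cancer_cdf_approx <- function(theta, t, N, N_min_approx = 100,
                              log.p = FALSE) {
  if (any(N < 0)) stop("N must be non-negative")
  out <- numeric(length(N))
  small <- N < N_min_approx
  if (any(small))
    out[small] <- log(pmax(exact_cdf_small(theta, t, N[small]), 1e-300))
  if (any(!small)) {
    res <- saddle_log_cdf(theta, t, N[!small])
    out[!small] <- pmin(res$log_coef, 0)  # clip approximation overshoot at 1
  }
  if (log.p) out else exp(out)
}

#' Binned likelihood of a carcinoma observation
#'
#' `P(L < M(t) <= U)` as a difference of saddle-point (or exact, for small
#' bounds) CDF values.  A zero-containing bin (`lower = -1`) gives
#' `P(M <= U)`; `upper = Inf` gives the upper tail `1 - P(M <= L)`.
#'
#' @param theta a [model_params()] object.
#' @param obs a `crc_obs` data.frame of compartment-M rows (or any
#'   data.frame with `age`, `lower`, `upper`).
#' @param N_min_approx see [cancer_cdf_approx()].
#' @return vector of bin probabilities, one per row, floored at 0.
#' @export
cancer_bin_likelihood <- function(theta, obs, N_min_approx = 100) {
  if (!is.data.frame(obs)) obs <- as.data.frame(obs)
  if ("compartment" %in% names(obs) && !all(obs$compartment == "M"))
    stop("cancer_bin_likelihood expects compartment-M observations")
  if (any(obs$lower >= obs$upper)) stop("degenerate bin: lower >= upper")
  out <- numeric(nrow(obs))
  for (tt in unique(obs$age)) {
    idx <- which(obs$age == tt)
    lo <- obs$lower[idx]; up <- obs$upper[idx]
    cdf_at <- function(k) {
      v <- numeric(length(k))
      fin <- is.finite(k) & k >= 0
      v[is.infinite(k)] <- 1
      v[k < 0] <- 0
      if (any(fin)) v[fin] <- cancer_cdf_approx(theta, tt, k[fin], N_min_approx)
      v
    }
    out[idx] <- cdf_at(up) - cdf_at(lo)
  }
  pmax(out, 0)
}
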