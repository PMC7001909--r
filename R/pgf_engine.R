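# Probability generating function of the carcinoma compartment.
#
# All PGF work is built on the backward Kolmogorov equation for the
# single-ancestor generating function f(s, u) (one fresh adenoma cell,
# no malignant cells), integrated by an adaptive RK45 in compiled code,
# with the immigration integral log G(s,t) = mu1 * Int_0^t (f(s,u) - 1) du
# carried as additional ODE state.

.pgf_rtol <- 1e-10
.pgf_atol <- 1e-12

pgf_profile <- function(theta, s, ages, mode = c("M", "A"), s0 = 0,
                        order = 2, rtol = .pgf_rtol, atol = .pgf_atol) {
  mode <- match.arg(mode)
  s <- as.complex(s)
  pgf_profile_cpp(as_par_vector(theta), Re(s), Im(s), as.numeric(ages),
                  if (mode == "M") 0L else 1L, s0, as.integer(order),
                  rtol, atol)
}

#' Single-ancestor PGF of the carcinoma compartment
#'
#' `f(s, u) = E[s^M(u)]` for the process started from one adenoma cell at
#' time 0, with the adenoma variable marginalised out.  Solves the backward
#' Kolmogorov equation
#' `df/du = b1 f^2 - (b1 + d1 + mu2) f + d1 + mu2 h(s, u)`,
#' `f(s, 0) = 1`, where `h` is the PGF of a linear birth-death process
#' started from one malignant cell.
#'
#' @param s PGF argument(s) in `[0, 1]`.
#' @param u elapsed time(s) in years (sorted ascending if a vector).
#' @param theta a [model_params()] object.
#' @return matrix of `f` values, `length(u)` rows by `length(s)` columns
#'   (dropped to a vector when either is scalar).
#' @export
single_clone_pgf <- function(s, u, theta) {
  if (any(s < 0 | s > 1)) stop("s must be in [0, 1]")
  if (any(u < 0)) stop("u must be non-negative")
  ord <- order(u)
  res <- pgf_profile(theta, s, u[ord], mode = "M", order = 0)
  f <- Re(res$f)
  f[order(ord), , drop = FALSE][, , drop = TRUE]
}

# 16-point Gauss-Legendre nodes/weights on [-1, 1]
.gl16 <- local({
  x <- c(0.0950125098376374, 0.2816035507792589, 0.4580167776572274,
         0.6178762444026438, 0.7554044083550030, 0.8656312023878318,
         0.9445750230732326, 0.9894009349916499)
  w <- c(0.1894506104550685, 0.1826034150449236, 0.1691565193950025,
         0.1495959888165767, 0.1246289712555339, 0.0951585116824928,
         0.0622535239386479, 0.0271524594117541)
  list(x = c(-rev(x), x), w = c(rev(w), w))
})

#' Log PGF of the carcinoma compartment under immigration
#'
#' `log G(s, t)` where `G(s, t) = E[s^M(t)]` for the full process with
#' adenoma-cell immigration at rate `mu1`.  Computed from the immigration
#' representation `log G = mu1 * Int_0^t (f(s, u) - 1) du` along two routes:
#' `"rk45"` carries the integral as augmented ODE state of the adaptive
#' integrator (default), `"quadrature"` applies composite 16-point
#' Gauss-Legendre quadrature to `f(s, u) - 1`.  The two agree to ~1e-8
#' relative and serve as mutual checks.
#'
#' @param s PGF argument(s) in `[0, 1]`.
#' @param t age in years (scalar).
#' @param theta a [model_params()] object.
#' @param method integration route.
#' @param panels number of quadrature panels for `"quadrature"`.
#' @return `log G(s, t)` (<= 0), same length as `s`.
#' @export
immigration_pgf <- function(s, t, theta, method = c("rk45", "quadrature"),
                            panels = 12) {
  method <- match.arg(method)
  if (any(s < 0 | s > 1)) stop("s must be in [0, 1]")
  if (t < 0) stop("t must be non-negative")
  if (t == 0 || theta$mu1 == 0) return(rep(0, length(s)))
  if (method == "rk45") {
    res <- pgf_profile(theta, s, t, mode = "M", order = 0)
    return(theta$mu1 * Re(res$If)[1, ])
  }
  # composite Gauss-Legendre over u in [0, t]
  edges <- seq(0, t, length.out = panels + 1)
  uu <- unlist(lapply(seq_len(panels), function(i) {
    0.5 * (edges[i] + edges[i + 1]) + 0.5 * diff(edges[i + 0:1]) * .gl16$x
  }))
  ww <- unlist(lapply(seq_len(panels), function(i) {
    0.5 * diff(edges[i + 0:1]) * .gl16$w
  }))
  ord <- order(uu)
  f <- pgf_profile(theta, s, uu[ord], mode = "M", order = 0)$f
  f <- Re(f)[order(ord), , drop = FALSE]
  theta$mu1 * as.numeric(crossprod(ww, f - 1))
}

#' Exact small-size CDF of the carcinoma compartment
#'
#' `P(M(t) <= N)` as the `N`-th Taylor coefficient of `G(s, t) / (1 - s)`,
#' extracted by trapezoidal contour quadrature on a circle of radius `rho`
#' (exact up to quadrature aliasing, which is driven below 1e-8 by the
#' default radius/node choice).  Intended for `N` up to a few thousand;
#' above that use [cancer_cdf_approx()].
#'
#' @param theta a [model_params()] object.
#' @param t age in years (scalar).
#' @param N cell count(s).
#' @param rho contour radius in (0, 1); default `exp(-3 / (N + 1))` keeps
#'   the `rho^-N` roundoff amplification bounded at `e^3`.
#' @param nodes number of quadrature nodes; default `max(64, 6 (N + 1))`.
#' @return `P(M(t) <= N)`, same length as `N`.
#' @export
exact_cdf_small <- function(theta, t, N, rho = NULL, nodes = NULL) {
  if (any(N < 0)) stop("N must be non-negative")
  vapply(N, function(n) {
    n <- floor(n)
    r <- if (is.null(rho)) exp(-3 / (n + 1)) else rho
    m <- if (is.null(nodes)) max(64, 6 * (n + 1)) else nodes
    th <- 2 * pi * (seq_len(m) - 1) / m
    sc <- r * exp(1i * th)
    logG <- complex_logG(theta, sc, t)
    Fv <- exp(logG) / (1 - sc)
    val <- Re(mean(Fv * exp(-1i * n * th))) / r^n
    resid <- abs(mean(Im(Fv * exp(-1i * n * th)))) / r^n
    if (resid > 1e-6)
      stop("contour quadrature did not converge (imaginary residue ", resid, ")")
    min(max(val, 0), 1)
  }, numeric(1))
}

# log G at complex arguments (vectorized); one ODE solve over all nodes
complex_logG <- function(theta, s, t, mode = "M", s0 = 0) {
  res <- pgf_profile(theta, s, t, mode = mode, s0 = s0, order = 0)
  theta$mu1 * res$If[1, ]
}

# All joint coefficients P(A = k, M = 0), k = 0..K-1, via FFT on a circle.
# G_A(x) = G(x, s = 0, t) marks adenoma cells with the malignant compartment
# conditioned empty.
joint_coef_m0 <- function(theta, t, K, rho = exp(-3 / K)) {
  m <- 2^ceiling(log2(max(128, 2 * K)))
  th <- 2 * pi * (seq_len(m) - 1) / m
  x <- rho * exp(1i * th)
  logG <- complex_logG(theta, x, t, mode = "A", s0 = 0)
  co <- Re(stats::fft(exp(logG))) / m
  co[seq_len(K)] / rho^(seq_len(K) - 1)
}
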