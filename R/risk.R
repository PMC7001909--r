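# Conditional probability of synchronous carcinoma given an adenoma finding.
#
# The joint generating function of the adenoma count with the malignant
# compartment conditioned empty, G_A(x) = G(x, s = 0, t), delivers the
# numerator P(A = k, M = 0): exactly by FFT contour extraction for small k,
# and through singularity analysis for large k.  G_A has an algebraic
# branch point of exponent -r (r = mu1/b1, the same exponent as the
# adenoma marginal) at the Riccati blow-up radius x_c > 1/p, so
#   q(k) = P(M = 0 | A = k) ~ B * (p * x_c)^(-k),
# an exact exponential up to O(1/k) corrections.  x_c is located to
# machine precision by bisection on ODE divergence and B is calibrated in
# the FFT-exact region; range sums over q(k) * P(A = k) then reduce to
# negative-binomial tail differences with the tilted success probability
# 1/x_c.  Conditioning on a detected adenoma (k >= 1) makes the resistant
# fraction lambda cancel; it enters only when the range includes A = 0.

# blow-up radius (radius of convergence) of the M-extinct sliced PGF
joint_sing_x <- function(theta, t) {
  pv <- as_par_vector(theta)
  div <- function(x) pgf_diverges_cpp(pv, x, t, 1L, 0, .pgf_rtol, .pgf_atol)
  lo <- 1
  hi <- 1 + 1e-8
  while (!div(hi)) { lo <- hi; hi <- 1 + (hi - 1) * 2
    if (hi > 1e6) stop("no finite radius of convergence found") }
  for (i in 1:100) {
    mid <- 0.5 * (lo + hi)
    if (div(mid)) hi <- mid else lo <- mid
    if (hi - lo < 1e-15 * lo) break
  }
  0.5 * (lo + hi)
}

# calibration of q(k) ~ B exp(-lam_q k): slope from the singularity radius,
# intercept from exact FFT coefficients around k0
q_tail_calibration <- function(theta, t, exact_marginal = FALSE,
                               k0 = 3000, window = 500) {
  xc <- joint_sing_x(theta, t)
  nb <- nb_params(theta, t, include_mu2 = exact_marginal)
  lam_q <- log(nb$p) + log(xc)
  co <- joint_coef_m0(theta, t, k0 + window)
  ks <- (k0 - window):(k0 + window - 1)
  qk <- co[ks + 1] / dnbinom(ks, size = nb$r, prob = exp(nb$log1mp))
  list(B = mean(qk * exp(lam_q * ks)), lam_q = lam_q, xc = xc, nb = nb)
}

#' Probability that no carcinoma is present given the adenoma size
#'
#' `P(M(t) = 0 | A(t) = k)` via Bayes' theorem:
#' the coefficient of `x^k` in `G(x, 0, t)` divided by `P(A(t) = k)`.
#'
#' @param theta a [model_params()] object.
#' @param t age in years (scalar).
#' @param k adenoma cell count(s).
#' @param exact_marginal use the exact adenoma marginal (effective death
#'   rate `d1 + mu2`) in the denominator instead of the closed-form marginal
#'   with the transformation rate set to zero.  The same convention should
#'   be used consistently; the default matches the binned adenoma
#'   likelihood.
#' @param k_switch size above which the saddle-point coefficient replaces
#'   the FFT contour extraction.
#' @return `P(M = 0 | A = k)`, in `[0, 1]`, nonincreasing in `k`.
#' @export
p_no_cancer_given_A <- function(theta, t, k, exact_marginal = FALSE,
                                k_switch = 3500) {
  if (any(k < 0)) stop("k must be non-negative")
  if (theta$mu2 == 0) return(rep(1, length(k)))
  k <- floor(k)
  out <- numeric(length(k))
  small <- k < k_switch
  if (any(small)) {
    co <- joint_coef_m0(theta, t, max(k[small]) + 1)
    num <- log(pmax(co[k[small] + 1], 1e-300))
    den <- adenoma_pmf(theta, t, k[small], log = TRUE,
                       include_mu2 = exact_marginal)
    out[small] <- exp(num - den)
  }
  if (any(!small)) {
    cal <- q_tail_calibration(theta, t, exact_marginal)
    out[!small] <- cal$B * exp(-cal$lam_q * k[!small])
  }
  pmin(out, 1)
}

# P(A in (L, U], M = 0) / P(A in (L, U]): exact FFT coefficients below
# `fft_max`, singularity-analysis tail sums above
joint_ratio_m0 <- function(theta, t, lower, upper, exact_marginal = FALSE,
                           fft_max = 4000) {
  if (theta$mu2 == 0) return(1)
  lower <- max(lower, -1)
  num <- 0
  k_hi <- min(floor(upper), fft_max - 1)
  if (lower + 1 <= k_hi) {               # exact part of the bin
    co <- joint_coef_m0(theta, t, k_hi + 1)
    ks <- (lower + 1):k_hi
    num <- num + sum(co[ks + 1])
  }
  if (is.infinite(upper) || upper >= fft_max) {   # asymptotic tail part
    cal <- q_tail_calibration(theta, t, exact_marginal)
    ptilde <- 1 / cal$xc
    logpref <- log(cal$B) +
      cal$nb$r * (cal$nb$log1mp - (log(cal$xc - 1) - log(cal$xc)))
    tilted_tail <- function(L)      # P(tilted NB > L)
      if (is.infinite(L)) 0 else pbeta(ptilde, L + 1, cal$nb$r)
    Lt <- max(lower, fft_max - 1)
    num <- num + exp(logpref) * (tilted_tail(Lt) - tilted_tail(upper))
  }
  den <- adenoma_cdf(theta, t, upper, include_mu2 = exact_marginal) -
    adenoma_cdf(theta, t, lower, include_mu2 = exact_marginal)
  if (den < 1e-14) stop("conditioning range has negligible probability mass")
  min(max(num / den, 0), 1)
}

#' Probability of synchronous carcinoma given an adenoma size range
#'
#' `P(M(t) > 0 | A(t) in (L, U])`, computed as
#' `1 - sum_k P(A = k, M = 0) / sum_k P(A = k)` over the range.  The
#' resistant fraction `lam` enters only when the range contains 0
#' (`lower = -1`); for a detected adenoma it cancels.
#'
#' @param theta a [model_params()] object.
#' @param age age in years.
#' @param lower,upper half-open cell-count range `(lower, upper]`;
#'   `lower = -1` includes a lesion-free finding, `upper` may be `Inf`.
#' @param lam resistant fraction (used only for zero-containing ranges).
#' @param exact_marginal see [p_no_cancer_given_A()]; ranges above
#'   `fft_max` always use matched saddle-point pairs, which imply the exact
#'   marginal.
#' @param fft_max largest finite upper bound handled by exact FFT
#'   coefficient sums; larger ranges use ratios of identically constructed
#'   saddle-point CDFs so that the approximation error cancels.
#' @return probability in `[0, 1]`.
#' @export
cancer_risk_given_adenoma <- function(theta, age, lower, upper, lam = 0,
                                      exact_marginal = FALSE,
                                      fft_max = 4000) {
  if (lower >= upper) stop("degenerate range: lower >= upper")
  ratio <- joint_ratio_m0(theta, age, lower, upper, exact_marginal, fft_max)
  if (lower < 0 && lam > 0) {
    # resistant individuals all sit at A = 0, M = 0
    pA <- adenoma_cdf(theta, age, upper, include_mu2 = exact_marginal) -
      adenoma_cdf(theta, age, lower, include_mu2 = exact_marginal)
    ratio <- (lam + (1 - lam) * ratio * pA) / (lam + (1 - lam) * pA)
  }
  min(max(1 - ratio, 0), 1)
}

#' Cancer-risk table over ages and reported adenoma size ranges
#'
#' The risk-calculator surface: for each age and reported-mm size range,
#' the probability of synchronous carcinoma given an adenoma in that range.
#' The default ranges are <5 mm (starting at 1 mm), 5 to <10 mm,
#' 10 to <20 mm, and >= 20 mm.
#'
#' @param theta a [model_params()] object.
#' @param lam resistant fraction (has no effect on detected-adenoma rows;
#'   kept for interface symmetry).
#' @param ages vector of ages in years.
#' @param mm_ranges list of `c(low, high)` reported sizes in mm (`high` may
#'   be `Inf`); the lower edge of the smallest bucket defaults to 1 mm.
#' @param cells_per_cm3 size conversion constant.
#' @return data.frame with columns `age`, `mm_low`, `mm_high`,
#'   `probability`.
#' @export
risk_table <- function(theta, lam = 0, ages = 30:70,
                       mm_ranges = list(c(1, 5), c(5, 10), c(10, 20),
                                        c(20, Inf)),
                       cells_per_cm3 = 1e8) {
  rows <- expand.grid(range = seq_along(mm_ranges), age = ages)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    rg <- mm_ranges[[rows$range[i]]]
    lo <- mm_to_cells(rg[1], cells_per_cm3)
    hi <- if (is.infinite(rg[2])) Inf else mm_to_cells(rg[2], cells_per_cm3)
    p <- tryCatch(cancer_risk_given_adenoma(theta, rows$age[i], lo, hi, lam),
                  error = function(e) {
                    if (grepl("negligible", conditionMessage(e)))
                      NA_real_            # conditioning event has no mass
                    else stop(e)
                  })
    data.frame(age = rows$age[i], mm_low = rg[1], mm_high = rg[2],
               probability = p)
  })
  do.call(rbind, out)
}
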