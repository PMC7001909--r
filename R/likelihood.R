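# Composite likelihood over size-binned adenoma and carcinoma observations.
#
# The compartment-A part is closed form (negative-binomial tails).  The
# compartment-M part needs P(M(t) <= N) at many (age, N) pairs per
# parameter value; evaluating a fresh saddle-point root solve for each pair
# is wasteful because the underlying ODE profile depends only on theta.
# m_profile() therefore solves the PGF system once per theta on a fixed
# logit-spaced s-grid, recording log G and its first two s-derivatives at
# every requested age, and the saddle points of all bins are then located
# by vectorized bisection on monotone spline interpolants.  Accuracy of
# this fast path against the direct per-N solver is covered by tests.

.m_sgrid_xi <- seq(-7.5, 30, length.out = 180)

m_profile <- function(theta, ages) {
  ages <- sort(unique(ages))
  s <- plogis(.m_sgrid_xi)
  prof <- pgf_profile(theta, s, ages, mode = "M", order = 4)
  list(ages = ages, xi = .m_sgrid_xi, s = s,
       LG = theta$mu1 * Re(prof$If),    # log G(s, t)        (<= 0)
       LG1 = theta$mu1 * Re(prof$Ig),   # d log G / ds       (>= 0)
       LG2 = theta$mu1 * Re(prof$Iw),   # d^2 log G / ds^2   (>= 0)
       LG3 = theta$mu1 * Re(prof$I3),
       LG4 = theta$mu1 * Re(prof$I4))
}

# log P(M(t) <= N) for vectors age/N (same length) from a profile object
profile_log_cdf <- function(prof, age, N) {
  out <- numeric(length(N))
  for (a in unique(age)) {
    ia <- match(a, prof$ages)
    if (is.na(ia)) stop("age ", a, " missing from profile")
    idx <- which(age == a)
    lg1 <- prof$LG1[ia, ]
    if (max(lg1, na.rm = TRUE) <= 0) { out[idx] <- 0; next }  # mu2 = 0
    # drop grid nodes whose derivative states saturated (fast-growth
    # parameter regimes near s = 1); saddle points never lie there
    bad <- which(!(is.finite(prof$LG4[ia, ]) & prof$LG4[ia, ] < 1e250 &
                     is.finite(lg1)))
    ok <- seq_len(if (length(bad)) min(bad) - 1 else length(prof$xi))
    if (length(ok) < 20) stop("PGF profile unusable: too few valid nodes")
    xi <- prof$xi[ok]
    spLG <- splinefun(xi, log(pmax(-prof$LG[ia, ok], 1e-300)), method = "natural")
    spL1 <- splinefun(xi, log(pmax(lg1[ok], 1e-300)), method = "natural")
    spL2 <- splinefun(xi, log(pmax(prof$LG2[ia, ok], 1e-300)), method = "natural")
    spL3 <- splinefun(xi, log(pmax(prof$LG3[ia, ok], 1e-300)), method = "natural")
    spL4 <- splinefun(xi, log(pmax(prof$LG4[ia, ok], 1e-300)), method = "natural")
    n <- N[idx]
    v1_top <- 1 / (1 - plogis(max(xi))) + exp(spL1(max(xi))) -
      (n + 1) / plogis(max(xi))
    if (any(v1_top < 0))
      stop("bin bound beyond the representable saddle range")
    lo <- rep(xi[1], length(n)); hi <- rep(max(xi), length(n))
    for (it in 1:60) {
      mid <- 0.5 * (lo + hi)
      sm <- plogis(mid)
      v1 <- 1 / (1 - sm) + exp(spL1(mid)) - (n + 1) / sm
      pos <- v1 > 0
      hi[pos] <- mid[pos]; lo[!pos] <- mid[!pos]
    }
    xis <- 0.5 * (lo + hi)
    ss <- plogis(xis)
    om <- 1 - ss
    V <- -log(om) - exp(spLG(xis)) - (n + 1) * log(ss)
    V2 <- 1 / om^2 + exp(spL2(xis)) + (n + 1) / ss^2
    V3 <- 2 / om^3 + exp(spL3(xis)) - 2 * (n + 1) / ss^3
    V4 <- 6 / om^4 + exp(spL4(xis)) + 6 * (n + 1) / ss^4
    corr <- pmin(pmax(1 + V4 / (8 * V2^2) - 5 * V3^2 / (24 * V2^3), 0.2), 2)
    out[idx] <- pmin(V - 0.5 * log(2 * pi * V2) + log(corr), 0)
  }
  out
}

# bin probabilities for compartment-M rows through the profile fast path
m_bin_probs <- function(theta, mobs) {
  prof <- m_profile(theta, mobs$age)
  p_up <- ifelse(is.infinite(mobs$upper), 0, NA_real_)
  atzero <- mobs$upper == 0            # P(M <= 0) = G(0, t), no saddle
  if (any(atzero)) {
    ag <- sort(unique(mobs$age[atzero]))
    g0 <- theta$mu1 * Re(pgf_profile(theta, 0, ag, mode = "M",
                                     order = 0)$If)[, 1]
    p_up[atzero] <- g0[match(mobs$age[atzero], ag)]
  }
  fin <- is.finite(mobs$upper) & !atzero
  if (any(fin))
    p_up[fin] <- profile_log_cdf(prof, mobs$age[fin], mobs$upper[fin])
  p <- numeric(nrow(mobs))
  zero <- mobs$lower < 0
  p[zero] <- exp(p_up[zero])
  pos <- !zero
  if (any(pos)) {
    llo <- profile_log_cdf(prof, mobs$age[pos], mobs$lower[pos])
    pup <- ifelse(is.infinite(mobs$upper[pos]), 1, exp(p_up[pos]))
    p[pos] <- pup - exp(llo)
  }
  pmax(p, 0)
}

#' Resistant-fraction mixture likelihood
#'
#' A proportion `lam` of the population never develops adenoma (and hence
#' carcinoma).  For a zero-containing bin the likelihood becomes
#' `lam + (1 - lam) * L`, otherwise `(1 - lam) * L`, where `L` is the base
#' binned likelihood of the observation.
#'
#' @param theta a [model_params()] object.
#' @param lam resistant fraction in `[0, 1]`.
#' @param obs a `crc_obs` data.frame (both compartments allowed).
#' @param N_min_approx passed to [cancer_bin_likelihood()].
#' @return vector of per-row mixture likelihoods.
#' @export
mixture_likelihood <- function(theta, lam, obs, N_min_approx = 100) {
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  obs <- validate_observations(obs)
  base <- numeric(nrow(obs))
  isA <- obs$compartment == "A"
  if (any(isA)) base[isA] <- adenoma_bin_likelihood(theta, obs[isA, ])
  if (any(!isA)) base[!isA] <- cancer_bin_likelihood(theta, obs[!isA, ],
                                                     N_min_approx)
  ifelse(obs$lower < 0, lam + (1 - lam) * base, (1 - lam) * base)
}

#' Composite log-likelihood of the two-compartment model
#'
#' Sum of the per-observation log binned likelihoods of compartments A and
#' M, each passed through the resistant-fraction mixture, with row weights
#' multiplying the log terms.  Compartment A uses the negative-binomial
#' tails; compartment M the saddle-point CDF (fast profile path).
#'
#' @param fit a [fit_params()] vector (or a [model_params()] object plus
#'   `lam`).
#' @param obs a `crc_obs` data.frame.
#' @param lam resistant fraction used when `fit` carries none.
#' @param control a [crc_control()] list.
#' @return scalar log-likelihood; `-Inf` if any row has zero probability or
#'   the parameters are inadmissible (negative death rates).
#' @export
composite_loglik <- function(fit, obs, lam = NULL, control = crc_control()) {
  if (inherits(fit, "crc_params")) {
    theta <- fit
    if (is.null(lam)) lam <- 0
  } else {
    theta <- try(as_model_params(fit), silent = TRUE)
    if (inherits(theta, "try-error")) return(-Inf)
    if (is.null(lam)) lam <- if (!is.na(fit$lam)) fit$lam else control$lam
    if (is.null(lam)) lam <- 0
  }
  if (lam < 0 || lam > 1) return(-Inf)
  if (nrow(obs) == 0) return(0)
  ll <- 0
  isA <- obs$compartment == "A"
  if (any(isA)) {
    a <- obs[isA, ]
    base <- adenoma_bin_likelihood(theta, a, control$include_mu2)
    p <- ifelse(a$lower < 0, lam + (1 - lam) * base, (1 - lam) * base)
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(a$weight * log(p))
  }
  if (any(!isA)) {
    m <- obs[!isA, ]
    if (!is.finite(theta$b2) || theta$b2 < 0) return(-Inf)
    base <- m_bin_probs(theta, m)
    p <- ifelse(m$lower < 0, lam + (1 - lam) * base, (1 - lam) * base)
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(m$weight * log(p))
  }
  ll
}

#' Prevalence-only log-likelihood (carcinoma yes/no)
#'
#' Discards the size information of compartment-M observations, keeping only
#' whether a carcinoma is present: an M row whose bin excludes zero counts
#' as "cancer", a zero-containing M bin as "no cancer".  The per-age
#' Bernoulli probability is `(1 - lam) * P(M(t) > n0)`, where `n0` is the
#' detection scale implied by the zero-containing bins (0 for exact
#' presence/absence data, giving `(1 - lam) * (1 - G(0, t))`).  Used to
#' demonstrate that (mu2, b2) are not identifiable without sizes.
#'
#' @param detect_cells detection scale `n0`; by default the largest upper
#'   bound among zero-containing M bins (0 if there are none).
#' @inheritParams composite_loglik
#' @export
prevalence_only_loglik <- function(fit, obs, lam = NULL,
                                   control = crc_control(),
                                   detect_cells = NULL) {
  if (inherits(fit, "crc_params")) {
    theta <- fit
    if (is.null(lam)) lam <- 0
  } else {
    theta <- try(as_model_params(fit), silent = TRUE)
    if (inherits(theta, "try-error")) return(-Inf)
    if (is.null(lam)) lam <- if (!is.na(fit$lam)) fit$lam else control$lam
    if (is.null(lam)) lam <- 0
  }
  m <- obs[obs$compartment == "M", , drop = FALSE]
  if (nrow(m) == 0) return(0)
  if (is.null(detect_cells)) {
    z <- m$lower < 0
    detect_cells <- if (any(z)) max(m$upper[z]) else 0
  }
  ages <- sort(unique(m$age))
  if (detect_cells == 0) {
    prof <- pgf_profile(theta, 0, ages, mode = "M", order = 0)
    cdf0 <- theta$mu1 * Re(prof$If)[, 1]      # log G(0, t)
  } else {
    prof <- m_profile(theta, ages)
    cdf0 <- profile_log_cdf(prof, ages, rep(detect_cells, length(ages)))
  }
  p1 <- (1 - lam) * (-expm1(cdf0))  # P(detectable cancer at age t)
  names(p1) <- as.character(ages)
  y <- as.numeric(m$lower >= 0)
  pv <- p1[as.character(m$age)]
  lik <- ifelse(y == 1, pv, 1 - pv)
  if (any(lik <= 0)) return(-Inf)
  sum(m$weight * log(lik))
}
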