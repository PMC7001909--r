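# Parameter inference: search parameterization, priors, Nelder-Mead MLE,
# grid search and adaptive Metropolis MCMC.

#' Inference control settings
#'
#' @param N_min_approx size below which the exact contour CDF replaces the
#'   saddle-point approximation.
#' @param use_priors apply the lognormal priors on `mu1` and `b1`.
#' @param lam default resistant fraction when it is held fixed.
#' @param include_mu2 fold the transformation drain into the adenoma
#'   marginal (effective death rate `d1 + mu2`); default FALSE, matching the
#'   closed-form solution with the transformation rate set to zero.
#' @param prior_mu1,prior_b1 `c(meanlog, sdlog)` of the two lognormal
#'   priors.  The stated central values (3,100 initiations/year; birth rate
#'   9/year) are taken as medians, the stated spreads (1/25, 1/3) as
#'   standard deviations of the natural logarithm.
#' @return list of class `crc_control`.
#' @export
crc_control <- function(N_min_approx = 100, use_priors = FALSE, lam = NULL,
                        include_mu2 = FALSE,
                        prior_mu1 = c(meanlog = log(3100), sdlog = 1 / 25),
                        prior_b1 = c(meanlog = log(9), sdlog = 1 / 3)) {
  structure(list(N_min_approx = N_min_approx, use_priors = use_priors,
                 lam = lam, include_mu2 = include_mu2,
                 prior_mu1 = prior_mu1, prior_b1 = prior_b1),
            class = "crc_control")
}

#' Search parameterization of the model
#'
#' Fits run over `(mu1, ratio = mu1/b1, gamma1, mu2, gamma2)` plus an
#' optional resistant fraction `lam`; the death rates are tied
#' (`d2 = d1`), so `(b2, d2)` are reconstructed from `(gamma2, d1)`.
#' Unused entries (e.g. `mu2`, `gamma2` in an adenoma-only fit) stay `NA`.
#'
#' @param mu1 adenoma initiation rate.
#' @param ratio `mu1 / b1` (the negative-binomial dispersion).
#' @param gamma1 adenoma net growth rate `b1 - d1`.
#' @param mu2 transformation rate (optional).
#' @param gamma2 carcinoma net growth rate `b2 - d2` (optional).
#' @param lam resistant fraction (optional).
#' @return list of class `crc_fit_params`.
#' @export
fit_params <- function(mu1, ratio, gamma1, mu2 = NA, gamma2 = NA, lam = NA) {
  structure(list(mu1 = mu1, ratio = ratio, gamma1 = gamma1, mu2 = mu2,
                 gamma2 = gamma2, lam = lam), class = "crc_fit_params")
}

#' @export
print.crc_fit_params <- function(x, ...) {
  v <- unlist(x[c("mu1", "ratio", "gamma1", "mu2", "gamma2", "lam")])
  print(v[!is.na(v)])
  invisible(x)
}

#' Convert search parameters to model rates
#'
#' @param fit a [fit_params()] object.
#' @return a [model_params()] object with `d2 = d1`.
#' @export
as_model_params <- function(fit) {
  if (inherits(fit, "crc_params")) return(fit)
  b1 <- fit$mu1 / fit$ratio
  d1 <- b1 - fit$gamma1
  if (!is.finite(d1) || d1 < 0)
    stop("inadmissible parameters: gamma1 > b1 implies negative death rate")
  mu2 <- if (is.na(fit$mu2)) 0 else fit$mu2
  if (is.na(fit$gamma2)) {
    b2 <- 0; d2 <- 0
  } else {
    d2 <- d1
    b2 <- fit$gamma2 + d2
    if (b2 < 0) stop("inadmissible parameters: gamma2 < -d1")
  }
  model_params(fit$mu1, b1, d1, mu2, b2, d2, d_equal = TRUE)
}

# ---- transforms to/from the unconstrained search space ---------------------
.fit_order <- c("mu1", "ratio", "gamma1", "mu2", "gamma2", "lam")

fit_free_names <- function(init, fixed = character()) {
  nm <- .fit_order[!is.na(unlist(init[.fit_order]))]
  setdiff(nm, fixed)
}

fit_to_vec <- function(fit, free) {
  vapply(free, function(nm) {
    v <- fit[[nm]]
    if (nm == "lam") qlogis(min(max(v, 1e-12), 1 - 1e-12)) else log(v)
  }, numeric(1))
}

vec_to_fit <- function(x, template, free) {
  out <- template
  for (i in seq_along(free)) {
    nm <- free[i]
    out[[nm]] <- if (nm == "lam") plogis(x[i]) else exp(x[i])
  }
  out
}

#' Log prior density of the search parameters
#'
#' Lognormal priors on the adenoma initiation rate `mu1` and the adenoma
#' birth rate `b1 = mu1 / ratio`; every other parameter carries an improper
#' flat prior on its admissible range (contributing 0).
#'
#' @param fit a [fit_params()] object.
#' @param control a [crc_control()]; priors apply only when
#'   `control$use_priors` is TRUE.
#' @export
log_prior <- function(fit, control = crc_control()) {
  if (!isTRUE(control$use_priors)) return(0)
  mu1 <- fit$mu1; b1 <- fit$mu1 / fit$ratio
  if (!is.finite(mu1) || mu1 <= 0 || !is.finite(b1) || b1 <= 0) return(-Inf)
  dlnorm(mu1, control$prior_mu1[["meanlog"]], control$prior_mu1[["sdlog"]],
         log = TRUE) +
    dlnorm(b1, control$prior_b1[["meanlog"]], control$prior_b1[["sdlog"]],
           log = TRUE)
}

log_posterior <- function(fit, obs, control, loglik = composite_loglik) {
  lp <- log_prior(fit, control)
  if (!is.finite(lp)) return(list(post = -Inf, ll = -Inf, prior = lp))
  ll <- tryCatch(loglik(fit, obs, control = control), error = function(e) -Inf)
  list(post = ll + lp, ll = ll, prior = lp)
}

#' Maximum-likelihood fit by Nelder-Mead
#'
#' Maximizes the composite log-likelihood (plus log prior if enabled) over
#' the free entries of `init`, on log scale (logit scale for `lam`).
#'
#' @param obs a `crc_obs` data.frame.
#' @param init a [fit_params()] starting point; entries set `NA` are
#'   excluded from the model, entries named in `fixed` are held at their
#'   initial value.
#' @param control a [crc_control()].
#' @param fixed character vector of parameter names to hold fixed.
#' @param hessian compute a finite-difference Hessian of the negative
#'   log-posterior at the optimum (in the transformed space).
#' @param maxit Nelder-Mead iteration cap.
#' @param loglik log-likelihood function (signature `(fit, obs, control)`),
#'   default [composite_loglik()].
#' @return list of class `crc_fit` with elements `par` (a
#'   [fit_params()]), `loglik`, `convergence`, `counts` and optionally
#'   `hessian` and `free`.
#' @export
mle_fit <- function(obs, init, control = crc_control(), fixed = character(),
                    hessian = FALSE, maxit = 2000,
                    loglik = composite_loglik) {
  obs <- validate_observations(obs)
  free <- fit_free_names(init, fixed)
  if (length(free) == 0) stop("no free parameters")
  x0 <- fit_to_vec(init, free)
  negpost <- function(x) {
    fit <- vec_to_fit(x, init, free)
    v <- -log_posterior(fit, obs, control, loglik)$post
    # large finite penalty keeps the simplex alive when a distant point
    # zeroes out an extreme observation
    if (!is.finite(v)) v <- 1e12 + sum((x - x0)^2)
    v
  }
  opt <- if (length(free) == 1) {
    optim(x0, negpost, method = "Brent", lower = x0 - 6, upper = x0 + 6,
          control = list(maxit = maxit), hessian = hessian)
  } else {
    optim(x0, negpost, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-10), hessian = hessian)
  }
  best <- vec_to_fit(opt$par, init, free)
  out <- list(par = best, loglik = -opt$value, convergence = opt$convergence,
              counts = opt$counts, free = free,
              hessian = if (hessian) opt$hessian else NULL)
  if (opt$convergence != 0)
    warning("Nelder-Mead did not report convergence (code ",
            opt$convergence, "); returning best point found")
  class(out) <- "crc_fit"
  out
}

#' @export
print.crc_fit <- function(x, ...) {
  cat("Composite-likelihood fit (log-likelihood ",
      format(x$loglik, digits = 8), ")\n", sep = "")
  print(x$par)
  invisible(x)
}

#' Wald confidence interval for a fitted parameter
#'
#' Uses the observed information (finite-difference Hessian of the negative
#' log-posterior in the transformed space) from [mle_fit()] run with
#' `hessian = TRUE`; the interval is symmetric on log scale.
#'
#' @param fit a `crc_fit` with a Hessian.
#' @param param parameter name (one of the free parameters).
#' @param level confidence level.
#' @return `c(lower, estimate, upper)` on the natural scale.
#' @export
fit_confint <- function(fit, param, level = 0.95) {
  if (is.null(fit$hessian)) stop("fit was run without hessian = TRUE")
  i <- match(param, fit$free)
  if (is.na(i)) stop("parameter ", param, " was not free in this fit")
  V <- solve(fit$hessian)
  se <- sqrt(V[i, i])
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- unname(fit_to_vec(fit$par, fit$free)[i])
  tr <- function(x) if (param == "lam") plogis(x) else exp(x)
  c(lower = tr(est - z * se), estimate = tr(est), upper = tr(est + z * se))
}

#' Adaptive Metropolis MCMC over the search parameters
#'
#' Random-walk Metropolis on the transformed (log / logit) parameter space
#' with diagonal proposal covariance.  The global proposal scale follows a
#' Robbins-Monro recursion targeting the requested acceptance rate and the
#' per-coordinate scales track the running standard deviation of the chain;
#' both adaptations freeze after half the chain, so the second half is a
#' fixed-kernel Metropolis sample.
#'
#' @param obs a `crc_obs` data.frame.
#' @param init a [fit_params()] starting point with finite posterior.
#' @param n_steps chain length (the classic protocol uses 10,000).
#' @param control a [crc_control()].
#' @param fixed parameters held fixed (see [mle_fit()]).
#' @param target_accept target acceptance rate (default 0.3).
#' @param seed optional RNG seed.
#' @param loglik log-likelihood function, default [composite_loglik()].
#' @return list of class `crc_chain`: `samples` (data.frame of natural-scale
#'   parameters with `loglik`, `logprior`, `accepted`), `acceptance`
#'   (post-freeze rate), `free`, `n_adapt`.
#' @export
adaptive_mcmc <- function(obs, init, n_steps = 10000,
                          control = crc_control(), fixed = character(),
                          target_accept = 0.3, seed = NULL,
                          loglik = composite_loglik) {
  if (!is.null(seed)) set.seed(seed)
  obs <- validate_observations(obs)
  free <- fit_free_names(init, fixed)
  d <- length(free)
  x <- fit_to_vec(init, free)
  cur <- log_posterior(vec_to_fit(x, init, free), obs, control, loglik)
  if (!is.finite(cur$post)) stop("initial point has non-finite posterior")
  n_adapt <- floor(n_steps / 2)
  ls <- log(2.38 / sqrt(d)) - 2           # global log-scale, adapted
  sd_vec <- rep(0.1, d)                   # per-coordinate scales, adapted
  mean_run <- x; m2_run <- rep(0, d)
  out <- matrix(NA_real_, n_steps, d + 3,
                dimnames = list(NULL, c(free, "loglik", "logprior", "accepted")))
  acc_post <- 0
  for (i in seq_len(n_steps)) {
    prop <- x + exp(ls) * sd_vec * rnorm(d)
    cand <- log_posterior(vec_to_fit(prop, init, free), obs, control, loglik)
    alpha <- min(1, exp(cand$post - cur$post))
    accepted <- runif(1) < alpha
    if (accepted) { x <- prop; cur <- cand }
    if (i <= n_adapt) {
      ls <- ls + min(1, 5 / i^0.7) * (alpha - target_accept)
      delta <- x - mean_run
      mean_run <- mean_run + delta / i
      m2_run <- m2_run + delta * (x - mean_run)
      if (i > 100) sd_vec <- sqrt(m2_run / (i - 1) + 1e-8)
    } else if (accepted) acc_post <- acc_post + 1
    fit_i <- vec_to_fit(x, init, free)
    out[i, ] <- c(unlist(fit_i[free]), cur$ll, cur$prior, accepted)
  }
  structure(list(samples = as.data.frame(out),
                 acceptance = acc_post / (n_steps - n_adapt),
                 free = free, n_adapt = n_adapt,
                 init = init, control = control),
            class = "crc_chain")
}

#' @export
print.crc_chain <- function(x, ...) {
  cat("Adaptive Metropolis chain: ", nrow(x$samples), " steps over (",
      paste(x$free, collapse = ", "), "); post-adaptation acceptance ",
      format(x$acceptance, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Posterior summaries of an MCMC chain
#'
#' `posterior_mode()` returns the sampled state with the highest posterior;
#' `credible_interval()` equal-tailed quantile intervals from the
#' post-adaptation half of the chain.
#'
#' @param chain a `crc_chain`.
#' @param param parameter name.
#' @param level credibility level.
#' @export
posterior_mode <- function(chain) {
  s <- chain$samples
  post <- s$loglik + s$logprior
  s[which.max(post), chain$free, drop = FALSE]
}

#' @rdname posterior_mode
#' @export
credible_interval <- function(chain, param, level = 0.95) {
  s <- chain$samples[-seq_len(chain$n_adapt), , drop = FALSE]
  a <- (1 - level) / 2
  quantile(s[[param]], c(a, 1 - a), names = FALSE)
}

#' Likelihood surface over a parameter grid
#'
#' Evaluates a log-likelihood over each row of a parameter grid, e.g. to
#' draw (mu2, b2) identifiability landscapes.
#'
#' @param obs a `crc_obs` data.frame.
#' @param grid data.frame whose columns are [fit_params()] names (missing
#'   ones are taken from `base`).
#' @param base a [fit_params()] supplying the non-varied parameters.
#' @param control a [crc_control()].
#' @param loglik log-likelihood function, default [composite_loglik()].
#' @return `grid` with an added `loglik` column.
#' @export
grid_search <- function(obs, grid, base, control = crc_control(),
                        loglik = composite_loglik) {
  obs <- validate_observations(obs)
  grid$loglik <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- base
    for (nm in intersect(names(grid), .fit_order)) fit[[nm]] <- grid[[nm]][i]
    tryCatch(loglik(fit, obs, control = control), error = function(e) -Inf)
  }, numeric(1))
  grid
}
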