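th <- sim_params()

test_that("search parameterization round-trips to model rates", {
  fit <- fit_params(3.1, 3.1 / 9, 0.2, 1e-5, 0.4, 0.4)
  m <- as_model_params(fit)
  expect_equal(m$b1, 9)
  expect_equal(m$d1, 8.8)
  expect_equal(m$b2, 9.2)
  expect_equal(m$d2, 8.8)     # d2 = d1 restriction
  expect_error(as_model_params(fit_params(1, 1, 2)), "inadmissible")
})

test_that("mixture likelihood follows the zero-bin branching rule", {
  zero <- observations("A", 1, -1, 0, 1)
  pos <- observations("A", 1, 0, 10, 1)
  base0 <- adenoma_pmf(th, 1, 0)
  expect_equal(mixture_likelihood(th, 0, pos),
               adenoma_bin_likelihood(th, pos))
  expect_equal(mixture_likelihood(th, 1, zero), 1)
  # 0.4 + 0.6 * (1-p)^r at the one-year-old compartment
  expect_equal(mixture_likelihood(th, 0.4, zero), 0.4 + 0.6 * base0,
               tolerance = 1e-10)
  expect_equal(mixture_likelihood(th, 0.4, zero), 0.663, tolerance = 1e-3)
  expect_equal(mixture_likelihood(th, 0.4, pos),
               0.6 * adenoma_bin_likelihood(th, pos))
})

test_that("composite log-likelihood is weighted, exchangeable, and empty-safe", {
  empty <- observations(character(), numeric(), numeric(), numeric(),
                        numeric())
  expect_equal(composite_loglik(th, empty), 0)
  obs <- sim_cohort_small()$obs
  fit <- fit_params(3.1, 3.1 / 9, 0.2, 1e-5, 0.4, 0.4)
  ll <- composite_loglik(fit, obs)
  expect_true(is.finite(ll))
  # weight w equals w identical rows
  row <- obs[which(obs$compartment == "M" & obs$weight == 1)[1], ]
  double_row <- rbind(row, row)
  row2 <- row; row2$weight <- 2
  expect_equal(composite_loglik(fit, validate_observations(double_row)),
               composite_loglik(fit, validate_observations(row2)),
               tolerance = 1e-10)
  # order invariance
  expect_equal(composite_loglik(fit, obs[sample(nrow(obs)), ]), ll,
               tolerance = 1e-9)
})

test_that("log prior matches the closed-form lognormal densities", {
  ctrl <- crc_control(use_priors = TRUE)
  fit <- fit_params(3100, 3100 / 9, 0.2)
  expect_equal(log_prior(fit, ctrl),
               dlnorm(3100, log(3100), 1 / 25, log = TRUE) +
                 dlnorm(9, log(9), 1 / 3, log = TRUE))
  expect_equal(log_prior(fit, crc_control(use_priors = FALSE)), 0)
  # density maximum over a symmetric log-grid sits at the median
  grid <- 3100 * exp(seq(-0.2, 0.2, length.out = 41))
  lp <- vapply(grid, function(m)
    log_prior(fit_params(m, m / 9, 0.2), ctrl), numeric(1))
  expect_equal(grid[which.max(lp)], 3100 * exp(-1 / 25^2),
               tolerance = 0.02)  # lognormal mode, slightly below median
  # proper: integrates to one over a wide grid (mu1 direction)
  f <- function(x) exp(dlnorm(x, log(3100), 1 / 25, log = TRUE))
  expect_equal(integrate(f, 2000, 5000)$value, 1, tolerance = 1e-6)
})

test_that("prevalence-only likelihood reduces to the Bernoulli model", {
  # exact presence/absence rows (upper = 0 encodes M = 0)
  obs <- observations(rep("M", 2), c(50, 50), c(-1, 3272 * 0),
                      c(0, Inf), c(80, 20))
  obs$lower <- c(-1, 0); obs$upper <- c(0, Inf)
  obs <- validate_observations(obs)
  p1 <- 1 - exp(immigration_pgf(0, 50, th))
  expect_equal(prevalence_only_loglik(th, obs),
               80 * log(1 - p1) + 20 * log(p1), tolerance = 1e-8)
  # mu2 = 0: all-no-cancer data is certain, any cancer impossible
  th0 <- model_params(3.1, 9, 8.8, 0, 9.2, 8.8)
  none <- observations("M", 50, -1, 0, 10)
  expect_equal(prevalence_only_loglik(th0, none), 0, tolerance = 1e-10)
  some <- observations("M", 50, 0, Inf, 1)
  expect_equal(prevalence_only_loglik(th0, some), -Inf)
})

test_that("a one-parameter fit recovers the generating net growth rate", {
  cohort <- nb_size_sample(2500, seed = 515)
  obs <- cohort_to_observations(cohort, compartments = "A")
  init <- fit_params(3.1, 3.1 / 9, 0.12)
  fit <- mle_fit(obs, init, fixed = c("mu1", "ratio"), hessian = TRUE)
  ci <- fit_confint(fit, "gamma1")
  expect_lt(ci["lower"], 0.2)
  expect_gt(ci["upper"], 0.2)
  expect_equal(unname(ci["estimate"]), 0.2, tolerance = 0.05)
  # a perturbed start converges to the same optimum
  fit2 <- mle_fit(obs, fit_params(3.1, 3.1 / 9, 0.3),
                  fixed = c("mu1", "ratio"))
  expect_equal(fit2$par$gamma1, fit$par$gamma1, tolerance = 1e-3)
})

test_that("grid search equals the likelihood at a single point and finds the truth cell", {
  obs <- sim_cohort_small()$obs
  base <- fit_params(3.1, 3.1 / 9, 0.2, 1e-5, 0.4, 0.4)
  g1 <- grid_search(obs, data.frame(gamma2 = 0.4), base)
  expect_equal(g1$loglik, composite_loglik(base, obs), tolerance = 1e-9)
  grid <- expand.grid(gamma1 = c(0.1, 0.2, 0.4))
  gs <- grid_search(obs, grid, base)
  expect_equal(grid$gamma1[which.max(gs$loglik)], 0.2)
})

test_that("adaptive MCMC tunes to its target acceptance and samples the prior
           under a flat likelihood", {
  obs <- observations("A", 10, -1, 100, 1)
  flat <- function(fit, obs, control) 0
  ctrl <- crc_control(use_priors = TRUE)
  ch <- adaptive_mcmc(obs, fit_params(3100, 3100 / 9, 0.1), n_steps = 3000,
                      seed = 33, control = ctrl, loglik = flat)
  expect_equal(nrow(ch$samples), 3000)
  expect_gt(ch$acceptance, 0.15)
  expect_lt(ch$acceptance, 0.45)
  # with a flat likelihood the chain samples the mu1 prior: lognormal with
  # sdlog = 1/25
  tail_half <- ch$samples$mu1[-seq_len(ch$n_adapt)]
  expect_equal(sd(log(tail_half)), 1 / 25, tolerance = 0.25)
  expect_equal(median(tail_half), 3100, tolerance = 0.02)
  # seeded chains are identical
  ch2 <- adaptive_mcmc(obs, fit_params(3100, 3100 / 9, 0.1), n_steps = 3000,
                       seed = 33, control = ctrl, loglik = flat)
  expect_identical(ch$samples, ch2$samples)
})
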