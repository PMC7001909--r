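# Shared fixtures: the biologically motivated simulation parameter set and
# small synthetic data sets, built lazily and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# one-sided Kolmogorov-Smirnov style distance between an empirical sample
# and a discrete model CDF, evaluated on a log-spaced grid
ks_distance <- function(x, cdf, grid = NULL) {
  if (is.null(grid))
    grid <- unique(c(0:10, round(exp(seq(log(10), log(max(x) + 10),
                                         length.out = 300)))))
  max(abs(ecdf(x)(grid) - cdf(grid)))
}

ks_crit_01 <- function(n) 1.63 / sqrt(n)   # alpha = 0.01

# cohort of the simulation study (resistant fraction 0.4), reduced scale
sim_cohort_small <- function() fixture("sim_cohort_small", function() {
  set.seed(20240301)
  co <- hybrid_cohort(sim_params(), 8000, ages = 1:80, lam = 0.4)
  list(cohort = co, obs = cohort_to_observations(co))
})

# direct negative-binomial draws of adenoma sizes at uniform ages
nb_size_sample <- function(n, theta = sim_params(), ages = 1:80,
                           seed = 20240302) {
  set.seed(seed)
  age <- sample(ages, n, replace = TRUE)
  A <- numeric(n)
  for (a in unique(age)) {
    idx <- age == a
    nb <- nb_params(theta, a)
    A[idx] <- rnbinom(sum(idx), size = nb$r, prob = exp(nb$log1mp))
  }
  data.frame(id = seq_len(n), age = age, A = A, M = 0)
}
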