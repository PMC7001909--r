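th <- sim_params()

test_that("nothing happens without immigration; seeded paths are reproducible", {
  th0 <- model_params(0, 9, 8.8, 1e-5, 9.2, 8.8)
  run <- gillespie_run(th0, 20, seed = 1)
  expect_true(all(run$A == 0) && all(run$M == 0))
  a <- gillespie_run(th, 15, seed = 42)
  b <- gillespie_run(th, 15, seed = 42)
  expect_identical(a, b)
  set.seed(7)
  c1 <- hybrid_cohort(th, 50, ages = 1:40)
  set.seed(7)
  c2 <- hybrid_cohort(th, 50, ages = 1:40)
  expect_identical(c1, c2)
})

test_that("exact Gillespie mean matches the analytic immigration-birth-death mean", {
  set.seed(101)
  n <- 2500
  A10 <- vapply(seq_len(n), function(i)
    gillespie_cpp(crcbranch:::as_par_vector(th), 10, 0, 0, 1e8)$A[1],
    numeric(1))
  m <- adenoma_mean(th, 10)      # 3.1 (e^2 - 1)/0.2 ~ 99.0
  expect_equal(m, 99.0, tolerance = 1e-3)
  se <- sd(A10) / sqrt(n)
  expect_lt(abs(mean(A10) - m), 3 * se)
})

test_that("exact simulation at mu2 = 0 is KS-indistinguishable from the negative binomial", {
  th0 <- model_params(3.1, 9, 8.8, 0, 0, 0)
  set.seed(202)
  n <- 2000
  A <- vapply(seq_len(n), function(i)
    gillespie_cpp(crcbranch:::as_par_vector(th0), 12, 0, 0, 1e8)$A[1],
    numeric(1))
  nb <- nb_params(th0, 12)
  D <- ks_distance(A, function(k) pnbinom(k, size = nb$r,
                                          prob = exp(nb$log1mp)))
  expect_lt(D, ks_crit_01(n))
})

test_that("tau-leaping agrees with exact simulation in distribution", {
  set.seed(303)
  n <- 1200
  ex <- vapply(seq_len(n), function(i)
    gillespie_cpp(crcbranch:::as_par_vector(th), 20, 0, 0, 1e8)$A[1],
    numeric(1))
  hy <- hybrid_cohort(th, n, ages = rep(20, n))$A
  grid <- unique(round(exp(seq(0, log(max(ex, hy) + 10), length.out = 200))))
  D <- max(abs(ecdf(ex)(grid) - ecdf(hy)(grid)))
  # two-sample KS at alpha = 0.01
  expect_lt(D, 1.63 * sqrt(2 / n))
})

test_that("hybrid cohort moments match the adenoma marginal at several ages", {
  co <- sim_cohort_small()$cohort
  live <- co[!co$resistant, ]
  for (a in c(20, 40, 60)) {
    x <- live$A[live$age == a]
    m <- adenoma_mean(th, a, include_mu2 = TRUE)
    v_theory <- {
      nb <- nb_params(th, a, include_mu2 = TRUE)
      nb$r * nb$p / (1 - nb$p)^2
    }
    expect_lt(abs(mean(x) - m), 4 * sqrt(v_theory / length(x)))
  }
})

test_that("the resistant fraction produces all-zero individuals", {
  set.seed(9)
  co <- hybrid_cohort(th, 300, ages = 1:50, lam = 1)
  expect_true(all(co$A == 0) && all(co$M == 0))
})

test_that("cohort binning conserves individuals and top-codes huge lesions", {
  co <- data.frame(id = 1:4, age = c(50, 50, 60, 60),
                   A = c(0, 5e5, 2e6, 0), M = c(0, 0, 0, 1e13))
  obs <- cohort_to_observations(co)
  expect_equal(sum(obs$weight[obs$compartment == "A"]), 4)
  expect_equal(sum(obs$weight[obs$compartment == "M"]), 4)
  big <- obs[obs$compartment == "M" & obs$lower > 0, ]
  expect_true(is.infinite(big$upper))   # 1e13 cells is top-coded
  zero <- obs[obs$lower < 0, ]
  expect_true(all(zero$upper == mm_to_cells(0.5)))
})

test_that("synthetic registry bookkeeping is internally consistent", {
  reg <- fixture("synth_registry", function()
    synth_registry(th, 6000, lam = 0.3, max_age = 60, seed = 404))
  r <- reg$registry
  # at-risk counts decrease by exactly the incident counts
  expect_equal(diff(r$at_risk_count), -r$incident_count[-1])
  expect_equal(r$at_risk_count[1], 6000 - r$incident_count[1])
  # incident sizes are at or above the detection threshold
  expect_true(all(reg$cancer$size_mm >= reg$truth$detect_mm))
  # zero-detection world: no incidence
  reg0 <- synth_registry(model_params(3.1, 9, 8.8, 0, 9.2, 8.8), 500,
                         max_age = 40, seed = 1)
  expect_true(all(reg0$registry$incident_count == 0))
  expect_equal(nrow(reg0$cancer), 0)
})
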