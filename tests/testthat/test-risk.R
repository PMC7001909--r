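th <- sim_params()

test_that("no transformation means no cancer risk at any adenoma size", {
  th0 <- model_params(3.1, 9, 8.8, 0, 9.2, 8.8)
  expect_equal(p_no_cancer_given_A(th0, 50, c(0, 10, 1e4)), rep(1, 3))
  expect_equal(cancer_risk_given_adenoma(th0, 50, -1, Inf), 0)
  tab <- risk_table(th0, ages = c(40, 60))
  expect_true(all(tab$probability == 0))
})

test_that("P(M = 0 | A = k) is nonincreasing in k and vanishes for huge k", {
  t <- 50
  ks <- c(0, 10, 100, 1000, 3000, 1e4, 1e5, 1e6, 1e7)
  q <- p_no_cancer_given_A(th, t, ks, exact_marginal = TRUE)
  expect_true(all(diff(q) <= 1e-10))
  expect_true(all(q >= 0 & q <= 1))
  expect_lt(q[length(q)], 0.01)
})

test_that("Bayes consistency: conditional times marginal sums to P(M = 0)", {
  t <- 20                      # adenoma mass concentrated below 2^15 cells
  co <- crcbranch:::joint_coef_m0(th, t, 32768)
  pm0 <- exp(immigration_pgf(0, t, th))
  nb <- nb_params(th, t, include_mu2 = TRUE)
  covered <- pnbinom(32767, size = nb$r, prob = exp(nb$log1mp))
  expect_equal(sum(co), pm0, tolerance = max(1e-4, 1 - covered))
  # and the FFT coefficients against conditional * marginal
  ks <- c(0, 5, 50, 500)
  q <- p_no_cancer_given_A(th, t, ks, exact_marginal = TRUE)
  # different contour radii between the two FFT extractions leave ~1e-6
  # relative quadrature differences
  expect_equal(q * dnbinom(ks, size = nb$r, prob = exp(nb$log1mp)),
               co[ks + 1], tolerance = 1e-4)
})

test_that("the large-size tail calibration is continuous with the exact region", {
  t <- 60
  q <- p_no_cancer_given_A(th, t, c(3499, 3500), exact_marginal = TRUE)
  expect_equal(q[1], q[2], tolerance = 2e-3)
  r1 <- cancer_risk_given_adenoma(th, t, 100, 3999, exact_marginal = TRUE)
  r2 <- cancer_risk_given_adenoma(th, t, 100, 4001, exact_marginal = TRUE)
  expect_equal(r1, r2, tolerance = 5e-3)
})

test_that("risk increases with the range's lower bound and with age", {
  t <- 60
  r_small <- cancer_risk_given_adenoma(th, t, 100, 1000)
  r_mid <- cancer_risk_given_adenoma(th, t, 50000, 500000)
  expect_lt(r_small, r_mid)
  by_age <- vapply(c(30, 45, 60, 75), function(a)
    cancer_risk_given_adenoma(th, a, 2500, 25000), numeric(1))
  expect_true(all(diff(by_age) > 0))
})

test_that("the resistant fraction cancels for detected adenomas only", {
  t <- 50
  r0 <- cancer_risk_given_adenoma(th, t, 100, 10000, lam = 0)
  r4 <- cancer_risk_given_adenoma(th, t, 100, 10000, lam = 0.4)
  expect_equal(r0, r4, tolerance = 1e-12)
  z0 <- cancer_risk_given_adenoma(th, t, -1, 10000, lam = 0)
  z4 <- cancer_risk_given_adenoma(th, t, -1, 10000, lam = 0.4)
  expect_lt(z4, z0)   # resistant mass dilutes the zero-containing range
})

test_that("risk table has the calculator shape and is monotone in age", {
  # size buckets sized to the simulation-study compartment scale
  rgs <- list(c(0.5, 1), c(1, 2), c(2, 5), c(5, Inf))
  tab <- fixture("risk_table_small", function()
    risk_table(th, ages = seq(30, 70, by = 10), mm_ranges = rgs))
  expect_equal(nrow(tab), 4 * 5)
  # NA only where the conditioning event has no mass (largest bucket at
  # the youngest age)
  expect_true(all(is.na(tab$probability[tab$age == 30 & tab$mm_low == 5]) |
                    tab$age[is.na(tab$probability)] == 30))
  ok <- !is.na(tab$probability)
  expect_true(all(tab$probability[ok] >= 0 & tab$probability[ok] <= 1))
  for (lo in unique(tab$mm_low)) {
    p <- tab$probability[tab$mm_low == lo]
    expect_true(all(diff(p[!is.na(p)]) > -1e-10))
  }
  # larger lesions carry more risk at fixed age
  at60 <- tab$probability[tab$age == 60]
  expect_true(all(diff(at60) > 0))
  # a conditioning event without probability mass is reported as NA
  tight <- risk_table(model_params(13200, 9, 8.835, 1.38e-7, 10.595, 8.835),
                      ages = 30, mm_ranges = list(c(1, 5)))
  expect_true(is.na(tight$probability))
})

test_that("degenerate and empty ranges are rejected", {
  expect_error(cancer_risk_given_adenoma(th, 50, 100, 100), "degenerate")
  thr <- model_params(13200, 9, 8.835, 1.38e-7, 10.595, 8.835)
  # with a very tight marginal this range has no mass
  expect_error(cancer_risk_given_adenoma(thr, 50, 100, 1000), "negligible")
})
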