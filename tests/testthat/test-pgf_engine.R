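th <- sim_params()

test_that("single-clone PGF satisfies its boundary cases", {
  s <- c(0, 0.3, 0.8, 1)
  expect_equal(single_clone_pgf(s, 0, th), rep(1, 4))
  th0 <- model_params(3.1, 9, 8.8, 0, 9.2, 8.8)     # mu2 = 0
  expect_equal(single_clone_pgf(s, c(5, 40), th0),
               matrix(1, 2, 4), tolerance = 1e-9)
  f <- single_clone_pgf(0.5, c(1, 5, 20), th)
  expect_true(all(f > 0 & f <= 1))
})

test_that("the two immigration-integral routes and an independent ODE solver agree", {
  skip_if_not_installed("deSolve")
  s_grid <- c(0, 0.2, 0.5, 0.9, 0.99)
  for (t in c(10, 50)) {
    a <- immigration_pgf(s_grid, t, th, method = "rk45")
    b <- immigration_pgf(s_grid, t, th, method = "quadrature")
    expect_equal(a, b, tolerance = 1e-6)
    expect_true(all(a <= 1e-8))
  }
  # deSolve::lsoda as an independent oracle for f and its integral
  s <- 0.9; t <- 50
  h <- function(u) {
    E <- exp(-th$gamma2 * u)
    (th$d2 * (1 - s) + (th$b2 * s - th$d2) * E) /
      (th$b2 * (1 - s) + (th$b2 * s - th$d2) * E)
  }
  rhs <- function(u, y, p)
    list(c(th$b1 * y[1]^2 - (th$b1 + th$d1 + th$mu2) * y[1] + th$d1 +
             th$mu2 * h(u), y[1] - 1))
  sol <- deSolve::ode(c(1, 0), c(0, t), rhs, NULL, rtol = 1e-11, atol = 1e-13)
  expect_equal(immigration_pgf(s, t, th), unname(th$mu1 * sol[2, 3]),
               tolerance = 1e-6)
})

test_that("immigration PGF normalizes and vanishes without immigration", {
  expect_equal(immigration_pgf(1, 50, th), 0, tolerance = 1e-8)
  th_no_imm <- model_params(0, 9, 8.8, 1e-5, 9.2, 8.8)
  expect_equal(immigration_pgf(c(0, 0.5), 50, th_no_imm), c(0, 0))
})

test_that("exact mean identities hold for both compartments", {
  t <- 50
  # E[M(t)] from the derivative of log G at s = 1 vs the closed form
  pr <- crcbranch:::pgf_profile(th, 1, t, mode = "M", order = 2)
  g2 <- th$gamma2; g1p <- th$gamma1 - th$mu2
  EM <- th$mu1 * th$mu2 *
    ((exp(g2 * t) - 1) / g2 - (exp(g1p * t) - 1) / g1p) / (g2 - g1p)
  expect_equal(th$mu1 * Re(pr$Ig)[1, 1], EM, tolerance = 1e-7)
  # E[A(t)] (exact marginal) the same way
  pa <- crcbranch:::pgf_profile(th, 1, t, mode = "A", s0 = 1, order = 2)
  expect_equal(th$mu1 * Re(pa$Ig)[1, 1],
               adenoma_mean(th, t, include_mu2 = TRUE), tolerance = 1e-7)
})

test_that("exact contour CDF is a valid, monotone CDF", {
  t <- 50
  Ns <- c(0, 1, 5, 20, 100, 500)
  cdf <- exact_cdf_small(th, t, Ns)
  expect_true(all(diff(cdf) > 0))
  expect_true(all(cdf >= 0 & cdf <= 1))
  # CDF at zero equals the empty-compartment probability G(0, t)
  expect_equal(cdf[1], exp(immigration_pgf(0, t, th)), tolerance = 1e-6)
  # mu2 = 0: the compartment is always empty
  th0 <- model_params(3.1, 9, 8.8, 0, 9.2, 8.8)
  expect_equal(exact_cdf_small(th0, t, c(0, 10, 100)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("contour extraction is invariant to the quadrature radius", {
  t <- 40
  # rho^-N roundoff amplification limits small radii to small N
  for (rho in c(0.5, 0.7, 0.95)) {
    got <- exact_cdf_small(th, t, c(2, 5, 20), rho = rho, nodes = 2048)
    want <- exact_cdf_small(th, t, c(2, 5, 20))
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("exact CDF increments are nonnegative (G is a proper PGF)", {
  cdf <- exact_cdf_small(th, 50, 0:40)
  expect_true(all(diff(cdf) >= -1e-12))
})
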