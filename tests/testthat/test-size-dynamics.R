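test_that("growth laws evaluate correctly and respect their domains", {
  gl <- gomp_law()
  expect_equal(growth_rate(10, gl), 0)               # vanishes at z = b
  expect_equal(growth_rate(0, gl), 0)                # and at z = 0
  expect_equal(growth_rate(1, gl), 0.616 * log(10))  # r z log(b/z) at z = 1
  expect_error(growth_rate(11, gl), "outside")
  expect_error(growth_rate(-0.1, gl), "outside")
  expect_equal(growth_rate(c(1, 2, 3), const_law()), rep(0.616, 3))
})

test_that("moments of the indicator initial datum match the closed form", {
  g <- size_grid(400, 50)
  expect_equal(tumor_moments(tumor_density(g, 0)), c(mu0 = 0, mu1 = 0))
  mm <- tumor_moments(indicator_density(g))
  expect_equal(mm[["mu0"]], 5 - 0.125)
  expect_equal(mm[["mu1"]], (5^2 - 0.125^2) / 2, tolerance = 1e-3)
  # a coarse, misaligned grid still integrates the indicator exactly in mu0
  g2 <- size_grid(37, 11)
  expect_equal(tumor_moments(indicator_density(g2))[["mu0"]], 4.875)
})

test_that("the division operator conserves tumor mass and counts divisions", {
  g <- size_grid(256, 10)
  mod <- division_model(a = 0.8)
  expect_equal(apply_division(tumor_density(g, 0), mod), rep(0, 256))
  for (seed in 1:5) {
    n <- random_density(g, seed)
    q <- apply_division(n, mod)
    mu1 <- tumor_moments(n)[["mu1"]]
    # first moment of Q vanishes: division never creates or destroys mass
    expect_lt(abs(sum(g$centers * q * g$widths)), 1e-10 * mu1)
    # zeroth moment of Q equals the division count a * mu0
    mu0 <- tumor_moments(n)[["mu0"]]
    expect_equal(sum(q * g$widths), mod$a * mu0, tolerance = 2e-3)
  }
})

test_that("division agrees with an independent brute-force quadrature", {
  for (nc in c(32, 64)) {
    g <- size_grid(nc, 10)
    for (mod in list(division_model(a = 0.8),
                     division_model(a = 1.5, rate_kind = "threshold",
                                    z0 = 1))) {
      n <- tumor_density(g, exp(-(g$centers - 3)^2))
      q <- apply_division(n, mod)
      q_oracle <- division_oracle(n, mod)
      denom <- sum(abs(q_oracle) * g$widths)
      expect_lt(sum(abs(q - q_oracle) * g$widths) / denom, 0.05)
    }
  }
})

test_that("the size stepper transports, reacts and stays nonnegative", {
  g <- size_grid(200, 20)
  law <- const_law(V = 0.5)
  mod <- division_model(a = 1e-9)   # division switched off
  n0 <- indicator_density(g, 1, 3)
  dt <- size_stable_dt(g, law, mod)
  # zero density is a fixed point
  z <- tumor_density(g, 0)
  expect_equal(tumor_step(z, dt, law = law, model = mod)$values, rep(0, 200))
  # transport alone: d(mu1)/dt = V (1 + beta) mu0
  beta <- 0.5
  dtb <- size_stable_dt(g, law, mod, beta = beta)
  n1 <- tumor_step(n0, dtb, beta = beta, law = law, model = mod)
  rate <- (tumor_moments(n1)[["mu1"]] - tumor_moments(n0)[["mu1"]]) / dtb
  expect_equal(rate, 0.5 * (1 + beta) * tumor_moments(n0)[["mu0"]],
               tolerance = 1e-6)
  # CFL violation is rejected with the admissible step in the message
  expect_error(tumor_step(n0, 10 * dt, law = law, model = mod),
               "use dt <=")
  # positivity for random densities under combined division and kill
  mod2 <- division_model(a = 0.8)
  ell <- 0.6
  dt2 <- size_stable_dt(g, law, mod2, ell = ell)
  for (seed in 1:3) {
    n <- random_density(g, seed)
    for (s in 1:10) n <- tumor_step(n, dt2, ell = ell, law = law,
                                    model = mod2)
    expect_true(all(n$values >= 0))
  }
})

test_that("number growth follows exp((a - ell) t) for constant coefficients", {
  g <- size_grid(300, 15)
  law <- const_law(V = 0.3)
  mod <- division_model(a = 0.9)
  ell <- 0.4
  dt <- size_stable_dt(g, law, mod, ell = ell) / 16
  n <- indicator_density(g, 0.5, 3)
  mu0_0 <- tumor_moments(n)[["mu0"]]
  nsteps <- 800L
  for (s in seq_len(nsteps)) n <- tumor_step(n, dt, ell = ell, law = law,
                                             model = mod)
  tfin <- nsteps * dt
  expect_equal(tumor_moments(n)[["mu0"]], mu0_0 * exp((0.9 - 0.4) * tfin),
               tolerance = 0.02)
})

test_that("the power method recovers the exact eigenvalue lambda = a", {
  g <- size_grid(400, 50)
  ep <- leading_eigenpair(const_law(), division_model(a = 0.8), g,
                          tol = 1e-8)
  expect_lt(abs(ep$lambda - 0.8) / 0.8, 0.01)
  expect_true(all(ep$profile$values >= 0))
  expect_equal(tumor_moments(ep$profile)[["mu0"]], 1, tolerance = 1e-12)
  expect_lt(ep$residual, 1e-3)
})

test_that("Gompertz eigenpairs rescale in time with (a, r)", {
  g <- size_grid(256, 10)
  ep1 <- leading_eigenpair(gomp_law(),
                           division_model(a = 0.8, rate_kind = "threshold",
                                          z0 = 1), g, tol = 1e-8)
  ep2 <- leading_eigenpair(growth_law("gompertz", r = 2 * 0.616, b = 10),
                           division_model(a = 1.6, rate_kind = "threshold",
                                          z0 = 1), g, tol = 1e-8)
  expect_equal(ep2$lambda / ep1$lambda, 2, tolerance = 1e-4)
  expect_lt(sum(abs(ep1$profile$values - ep2$profile$values) * g$widths),
            1e-3)
})

test_that("growth enhancement only rescales the constant-coefficient profile", {
  g <- size_grid(400, 50)
  beta <- 0.6
  ep0 <- leading_eigenpair(const_law(), division_model(a = 0.8), g,
                           tol = 1e-8)
  epb <- leading_eigenpair(const_law(), division_model(a = 0.8), g,
                           tol = 1e-8, beta = beta)
  expect_equal(epb$lambda, ep0$lambda, tolerance = 1e-3)
  pred <- stats::approx(c(0, g$centers, g$z_max),
                        c(0, ep0$profile$values, 0),
                        xout = g$centers / (1 + beta), rule = 2)$y /
    (1 + beta)
  # first-order upwind: the L1 gap shrinks ~O(h); 0.06 measured at 400
  # cells, 0.03 at 800
  expect_lt(sum(abs(epb$profile$values - pred) * g$widths), 0.1)
})
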