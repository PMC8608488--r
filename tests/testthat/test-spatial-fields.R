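test_that("the masked disc approximates the unit disc", {
  g <- make_disc_grid(64)
  expect_lt(abs(g$n_masked * g$area - pi), 4 / 64)
  expect_true(any(g$x == min(abs(g$x)) & g$y == min(abs(g$y))))
  expect_true(all(g$x^2 + g$y^2 < 1))           # corner cells masked out
  expect_error(make_disc_grid(4))
})

test_that("Gaussian form functions have the right peak and mass", {
  g <- make_disc_grid(64)
  f <- gaussian_field(g, A = 1, xi2 = 0.02)
  # the nearest cell center sits h/sqrt(2) from the origin, so evaluate
  # the closed form there rather than at the exact peak
  i0 <- which.min(g$x^2 + g$y^2)
  r2 <- g$x[i0]^2 + g$y[i0]^2
  expect_equal(f$values[i0], exp(-r2 / 0.04) / (2 * pi * 0.02),
               tolerance = 1e-12)
  expect_equal(max(f$values), 1 / (2 * pi * 0.02), tolerance = 0.02)
  expect_equal(gaussian_field(g, A = 0, xi2 = 0.02)$values,
               rep(0, g$n_masked))
  expect_equal(integrate_field(f), 1, tolerance = 1e-3)
})

test_that("weighted integrals match closed-form Gaussian products", {
  g <- make_disc_grid(64)
  expect_equal(integrate_weighted(scalar_field(g, 0),
                                  gaussian_field(g, 1, 0.02)), 0)
  # w = delta-Gaussian against a constant: linearity
  dlt <- gaussian_field(g, 1, 0.02)
  k <- 2.5
  expect_equal(integrate_weighted(scalar_field(g, k), dlt),
               k * integrate_field(dlt))
  # two offset Gaussians against the planar product integral
  g1 <- gaussian_field(g, 1, 0.05, center = c(0.1, 0))
  g2 <- gaussian_field(g, 2, 0.08, center = c(-0.1, 0.2))
  expect_equal(integrate_weighted(g1, g2),
               gaussian_product_integral(1, 0.05, c(0.1, 0),
                                         2, 0.08, c(-0.1, 0.2)),
               tolerance = 5e-3)
})

test_that("the chemotactic potential solves the radial Neumann problem", {
  g <- make_disc_grid(64)
  sig <- gaussian_field(g, 0.002, 0.05)
  expect_equal(solve_potential(sig, K = 1, strength = 0)$values,
               rep(0, g$n_masked))
  phi <- solve_potential(sig, K = 1, strength = 0.5)
  expect_lt(abs(mean(phi$values)), 1e-12)       # gauge
  expect_lt(attr(phi, "residual"), 1e-10)
  # independent radial two-point boundary-value oracle
  mg <- mean(sig$values)
  srad <- function(r) 0.5 * (0.002 / (2 * pi * 0.05) *
                               exp(-r^2 / (2 * 0.05)) - mg)
  phip <- function(r) {
    sapply(r, function(rr) {
      if (rr < 1e-12) return(0)
      -stats::integrate(function(p) srad(p) * p, 0, rr)$value / rr
    })
  }
  rcell <- sqrt(g$x^2 + g$y^2)
  rs <- sort(unique(c(0, rcell)))
  phv <- cumsum(c(0, vapply(seq_along(rs)[-1], function(i)
    stats::integrate(phip, rs[i - 1], rs[i])$value, numeric(1))))
  ph <- stats::approx(rs, phv, xout = rcell, rule = 2)$y
  ph <- ph - mean(ph)
  expect_lt(sqrt(sum((ph - phi$values)^2) / sum(ph^2)), 0.02)
})

test_that("the field stepper matches the per-cell reaction oracle", {
  g <- make_disc_grid(32)
  phi <- scalar_field(g, 0)                     # chi irrelevant
  u <- scalar_field(g, 0)
  gain <- 2
  loss <- 0.5
  dt <- 0.02
  nstep <- 200L
  for (s in seq_len(nstep))
    u <- advance_field(u, phi, chi = 0, D = 1e-5, gain = gain,
                       loss_rate = loss, dt = dt)
  tfin <- nstep * dt
  # interior cells follow u(t) = (gain/loss) (1 - exp(-loss t)) when
  # diffusion is negligible
  ctr <- which.min(g$x^2 + g$y^2)
  expect_equal(u$values[ctr], gain / loss * (1 - exp(-loss * tfin)),
               tolerance = 5e-3)
  # zero stays zero
  z <- advance_field(scalar_field(g, 0), phi, chi = 0, D = 0.05,
                     gain = 0, loss_rate = 0, dt = 0.1)
  expect_equal(z$values, rep(0, g$n_masked))
})

test_that("diffusion with absorbing boundary obeys the maximum principle", {
  g <- make_disc_grid(32)
  phi <- scalar_field(g, 0)
  set.seed(7)
  u <- scalar_field(g, stats::runif(g$n_masked))
  sup <- max(u$values)
  for (s in 1:30) {
    u <- advance_field(u, phi, chi = 0, D = 0.1, gain = 0,
                       loss_rate = 0.2, dt = 0.05)
    expect_lte(max(u$values), sup + 1e-12)
    expect_true(all(u$values >= 0))
    sup <- max(u$values)
  }
})

test_that("advection preserves positivity under its stability bound", {
  g <- make_disc_grid(32)
  phi <- solve_potential(gaussian_field(g, 0.002, 0.05), K = 0.001,
                         strength = 1)
  dt_ok <- advection_stable_dt(phi, chi = 0.864)
  set.seed(11)
  u <- scalar_field(g, stats::runif(g$n_masked))
  for (s in 1:20) {
    u <- advance_field(u, phi, chi = 0.864, D = 0.01, gain = 0,
                       loss_rate = 0, dt = min(dt_ok, 0.05))
    expect_true(all(u$values >= 0))
  }
  expect_error(advance_field(u, phi, chi = 0.864, D = 0.01,
                             dt = 10 * dt_ok), "use dt <=")
})

test_that("the kill-rate diagnostic converges under grid refinement", {
  run_at <- function(n_axis) {
    g <- make_disc_grid(n_axis)
    dlt <- gaussian_field(g, 1, 0.05)
    phi <- solve_potential(gaussian_field(g, 0.002, 0.05), K = 0.01,
                           strength = 1)
    u <- scalar_field(g, 0)
    for (s in 1:40)
      u <- advance_field(u, phi, chi = 0.864, D = 0.05, gain = 1,
                         loss_rate = 0.18, dt = 0.05)
    integrate_weighted(u, dlt)
  }
  v16 <- run_at(16); v32 <- run_at(32); v64 <- run_at(64)
  expect_lt(abs(v64 - v32), abs(v32 - v16))
})
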