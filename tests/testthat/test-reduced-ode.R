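fig3_params <- function(a = 0.8, m = 2, ...) {
  ode_params(a = a, V = 0.616, delta = 1, S = 1.5, k_r = 1.25, k_c = 0.1,
             m = m, ...)
}

test_that("the right-hand side vanishes at the closed-form equilibria", {
  p <- fig3_params()
  expect_equal(ode_rhs(rep(0, 5), p), rep(0, 5))       # healthy state
  eq <- ode_equilibria(p)
  expect_equal(unname(eq$NP),
               c(0.18 * 0.64 / (0.616 * 1.5), 0.18 * 0.8 / 1.5, 0.8, 0, 0))
  expect_lt(max(abs(ode_rhs(eq$NP, p))), 1e-12)
  # c = a/delta freezes the tumor cell count exactly
  st <- c(1, 2, p$a / p$delta, 0.3, 0.1)
  expect_identical(ode_rhs(st, p)[1L], 0)
  # substitution across random parameter draws, for every admissible state
  for (seed in 1:10) {
    pr <- random_ode_params(seed)
    eqr <- ode_equilibria(pr)
    nrm <- function(s) max(abs(ode_rhs(s, pr)))
    if (eqr$NP_admissible)
      expect_lt(nrm(eqr$NP), 1e-10 * (1 + sqrt(sum(eqr$NP^2))))
    if (eqr$P_admissible)
      expect_lt(nrm(eqr$P), 1e-10 * (1 + sqrt(sum(eqr$P^2))))
  }
})

test_that("NP admissibility is the critical-mass condition", {
  p <- fig3_params()
  eq <- ode_equilibria(p)
  expect_equal(eq$NP[["mu1"]], 0.096)
  expect_true(eq$NP_admissible)                 # 0.096 < m = 2
  p2 <- fig3_params(m = 0.05)
  expect_false(ode_equilibria(p2)$NP_admissible)
  # mu1_NP <= m iff a/delta <= m S / gamma
  for (seed in 11:25) {
    pr <- random_ode_params(seed)
    eqr <- ode_equilibria(pr)
    expect_identical(eqr$NP_admissible,
                     pr$a / pr$delta <= pr$m * pr$S / pr$gamma)
  }
})

test_that("mu1_P minus m reduces to the rational form in a/delta", {
  for (seed in 1:15) {
    pr <- random_ode_params(seed)
    pr$psi_bar <- 1
    eqr <- ode_equilibria(pr)
    x <- pr$a / pr$delta
    ratio <- (pr$gamma * x - pr$m * pr$S) /
      (pr$S - eqr$Q1 * x - eqr$Q2 * x^2)
    Q <- pr$k_r * pr$a / (pr$delta * pr$tau)
    kk <- pr$k_c * pr$a / (pr$gamma_r * pr$delta)
    mu1P <- (pr$gamma * x - Q * pr$m - kk * Q * pr$m) /
      (pr$S - Q - kk * Q)
    expect_equal(mu1P - pr$m, ratio, tolerance = 1e-10)
  }
})

test_that("X2 zeroes the denominator and orders the regimes", {
  p <- ode_params(k_r = 1.25, k_c = 0.1, tau = 1, gamma_r = 1, S = 1.5)
  eq <- ode_equilibria(p)
  expect_equal(eq$X2, (-10 + sqrt(100 + 4 * 1.5 / 0.125)) / 2)
  expect_equal(1.5 - eq$Q1 * eq$X2 - eq$Q2 * eq$X2^2, 0, tolerance = 1e-12)
})

test_that("both regime tables are reproduced across their intervals", {
  # small critical mass: m < gamma X2 / S -> NP | P | none
  p_small <- fig3_params(m = 0.05, gamma = 0.18)
  rt <- ode_x2_threshold(p_small, x = c(0.01, 0.2, 0.3, 0.6, 1.05, 1.2, 3))
  xm <- p_small$m * p_small$S / p_small$gamma          # 0.4167
  X2 <- rt$X2                                          # 1.0828
  expect_match(rt$case, "small")
  for (i in seq_len(nrow(rt$regimes))) {
    x <- rt$regimes$x[i]
    want <- if (x < xm) "NP" else if (x < X2) "P" else "none"
    expect_identical(rt$regimes$regime[i], want)
  }
  # large critical mass: m > gamma X2 / S -> NP | NP+P | none
  p_large <- fig3_params(m = 2)
  rt2 <- ode_x2_threshold(p_large, x = c(0.5, 1, 2, 8, 16, 17, 30))
  xm2 <- p_large$m * p_large$S / p_large$gamma         # 16.67
  expect_match(rt2$case, "large")
  for (i in seq_len(nrow(rt2$regimes))) {
    x <- rt2$regimes$x[i]
    want <- if (x < rt2$X2) "NP" else if (x < xm2) "NP+P" else "none"
    expect_identical(rt2$regimes$regime[i], want)
  }
})

test_that("stability splits into damped and oscillatory returns", {
  expect_equal(ode_stability(fig3_params(), "H")$eigenvalues[1L], 0.8)
  expect_identical(ode_stability(fig3_params(), "H")$classification,
                   "unstable")
  # gamma < 4a: complex pair with real part -gamma/2
  st <- ode_stability(fig3_params(), "NP")
  expect_identical(st$regime, "oscillatory")
  cplx <- st$eigenvalues[Im(st$eigenvalues) != 0]
  expect_equal(unique(Re(cplx)), -0.18 / 2)
  # gamma > 4a: all real negative
  st2 <- ode_stability(fig3_params(a = 0.3, gamma = 1.5), "NP")
  expect_identical(st2$regime, "damped")
  expect_true(all(Im(st2$eigenvalues) == 0 & Re(st2$eigenvalues) < 0))
  # closed form against a finite-difference Jacobian across draws
  for (seed in 1:8) {
    pr <- random_ode_params(seed, m = 1e6)   # keep NP admissible
    eqr <- ode_equilibria(pr)
    J <- tumimm:::numeric_jacobian(function(s) ode_rhs(s, pr), eqr$NP)
    ev_fd <- sort(Re(eigen(J, only.values = TRUE)$values))
    ev_cf <- sort(Re(ode_stability(pr, "NP")$eigenvalues))
    expect_equal(ev_fd, ev_cf, tolerance = 1e-6)
  }
})

test_that("trajectories converge to NP or blow up with the division rate", {
  p <- fig3_params(a = 0.5)
  eq <- ode_equilibria(p)
  # small perturbation returns to NP
  tr <- ode_integrate(p, eq$NP * c(1.01, 1.01, 1.01, 1, 1), horizon = 300)
  fin <- unlist(tr$series[nrow(tr$series), -1])
  expect_lt(max(abs(fin - eq$NP) / pmax(eq$NP, 1e-8)), 1e-4)
  expect_false(tr$escaped)
  # small a from the reference initial state: c tends to a/delta
  init <- c(4.875, 12.4921875, 0, 0, 0)
  trs <- ode_integrate(fig3_params(a = 0.5), init, horizon = 500)
  expect_equal(trs$series$c[nrow(trs$series)], 0.5, tolerance = 1e-3)
  # large a: blow-up flagged, c plateaus below the equilibrium value
  trb <- ode_integrate(fig3_params(a = 20), init, horizon = 500)
  expect_true(trb$escaped)
  expect_lt(trb$series$c[nrow(trb$series)], 20 / 1)
})

test_that("quadratic activation restores damping for aggressive tumors", {
  init <- c(4.875, 12.4921875, 0, 0, 0)
  a <- 20
  lin <- ode_integrate(fig3_params(a = a), init, horizon = 200)
  qd <- ode_integrate(fig3_params(a = a, g_mode = "quadratic"), init,
                      horizon = 200)
  expect_true(lin$escaped)
  expect_false(qd$escaped)
})
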