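# Shared fixtures and independent oracles, built in code.

const_law <- function(V = 0.616) growth_law("constant", V = V)
gomp_law <- function() growth_law("gompertz", r = 0.616, b = 10)

# Constant-coefficient validation parameters (no growth enhancement).
const_params <- function(a = 0.8, ...) {
  model_params(growth = const_law(), division = division_model(a = a),
               A_b1 = 0, ...)
}

# Random nonnegative density on a grid, reproducible.
random_density <- function(grid, seed) {
  set.seed(seed)
  tumor_density(grid, stats::runif(grid$n_cells))
}

# Independent brute-force discretization of the binary division
# operator: every mother cell j sends rate a(z_j) n_j w_j to two
# daughters at z_j / 2, deposited by linear splitting between the two
# bracketing cells. Structurally different from the interpolated-gain
# scheme in apply_division, so it serves as a cross-check.
division_oracle <- function(n, model) {
  grid <- n$grid
  z <- grid$centers
  w <- grid$widths
  rate <- model$a * if (model$rate_kind == "constant") rep(1, length(z)) else
    as.numeric(z >= model$z0)
  gain <- numeric(grid$n_cells)
  for (j in seq_len(grid$n_cells)) {
    flux <- rate[j] * n$values[j] * w[j]   # dividing cells / time
    if (flux == 0) next
    zd <- z[j] / 2
    k <- findInterval(zd, z)
    if (k == 0) {
      gain[1L] <- gain[1L] + 2 * flux
    } else if (k >= grid$n_cells) {
      gain[grid$n_cells] <- gain[grid$n_cells] + 2 * flux
    } else {
      wr <- (zd - z[k]) / (z[k + 1L] - z[k])
      gain[k] <- gain[k] + 2 * flux * (1 - wr)
      gain[k + 1L] <- gain[k + 1L] + 2 * flux * wr
    }
  }
  gain / w - rate * n$values
}

# Closed-form integral of the product of two planar Gaussian bumps
# (integration over the whole plane).
gaussian_product_integral <- function(A1, xi2_1, c1, A2, xi2_2, c2) {
  s <- xi2_1 + xi2_2
  A1 * A2 / (2 * pi * s) * exp(-sum((c1 - c2)^2) / (2 * s))
}

# Random positive ODE parameter draw, reproducible.
random_ode_params <- function(seed, m = NULL) {
  set.seed(seed)
  r <- function(lo, hi) stats::runif(1, lo, hi)
  ode_params(a = r(0.2, 3), V = r(0.3, 1), delta = r(0.5, 2),
             S = r(0.5, 3), gamma = r(0.1, 2), gamma_r = r(0.3, 2),
             tau = r(0.3, 2), k_r = r(0.3, 2), k_c = r(0.05, 0.5),
             m = if (is.null(m)) r(0.1, 3) else m)
}
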