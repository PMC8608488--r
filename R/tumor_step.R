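#' Stable time step for the size stepper
#'
#' Positivity bound for the explicit upwind transport combined with the
#' explicit reaction part: `dt <= 0.9 / (max V (1+beta)/h + a + ell)`, so
#' the total explicit loss coefficient of any cell stays below 0.9.
#'
#' @param grid a [size_grid()].
#' @param law a [growth_law()].
#' @param model a [division_model()].
#' @param beta protumor growth enhancement (>= 0).
#' @param ell immune kill rate (1/time, >= 0).
#' @return The admissible time step.
#' @export
size_stable_dt <- function(grid, law, model, beta = 0, ell = 0) {
  vmax <- max(growth_rate(grid$edges, law)) * (1 + beta)
  0.9 / (vmax / min(grid$widths) + model$a + ell)
}

#' Advance the tumor density one time step
#'
#' One explicit Euler step of the growth-fragmentation equation
#' `dn/dt + d/dz(V(z)(1+beta) n) = Q(n) - ell n` with inflow boundary
#' `n(t, 0) = 0`. Transport is first-order upwind on the finite-volume
#' grid (the growth velocity is nonnegative, so upwinding is one-sided);
#' division and immune kill are explicit. Under the CFL constraint of
#' [size_stable_dt()] the update preserves nonnegativity.
#'
#' For a constant growth law the domain is a truncation of the half-line:
#' mass crossing `z_max` flows out and is accumulated in the
#' `"outflux_mass"` attribute of the result so truncation error can be
#' monitored.
#'
#' @param n a [tumor_density()].
#' @param dt time step; must satisfy [size_stable_dt()].
#' @param beta protumor enhancement of the growth rate (dimensionless).
#' @param ell immune kill rate (1/time).
#' @param law a [growth_law()].
#' @param model a [division_model()].
#' @return The advanced [tumor_density()]; attribute `outflux_mass` holds
#'   the first moment lost through `z = z_max` during the step.
#' @export
tumor_step <- function(n, dt, beta = 0, ell = 0, law, model) {
  stopifnot(inherits(n, "tumor_density"), beta >= 0, ell >= 0, dt > 0)
  grid <- n$grid
  dt_ok <- size_stable_dt(grid, law, model, beta, ell)
  if (dt > dt_ok * (1 + 1e-12))
    stop(sprintf("tumor_step: dt = %g violates stability; use dt <= %g",
                 dt, dt_ok))
  v_edge <- growth_rate(grid$edges, law) * (1 + beta)
  # upwind fluxes: F_{i+1/2} = v(edge) * n_i; inflow F_{1/2} = 0
  flux <- c(0, v_edge[-1L] * n$values)
  outflux <- flux[length(flux)]              # crosses z_max (0 for Gompertz)
  dvals <- (flux[-length(flux)] - flux[-1L]) / grid$widths
  q <- apply_division(n, model)
  new_vals <- n$values + dt * (dvals + q - ell * n$values)
  new_vals[new_vals < 0 & new_vals > -1e-14 * max(abs(new_vals))] <- 0
  out <- tumor_density(grid, new_vals)
  attr(out, "outflux_mass") <- dt * outflux * grid$z_max
  out
}
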