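# Outward face velocities of the chemotactic drift chi * grad(phi), one
# column per direction (+x,-x,+y,-y); zero on mask-boundary faces, where
# the potential satisfies the zero-flux condition.
face_velocities <- function(phi, chi) {
  grid <- phi$grid
  v <- matrix(0, grid$n_masked, 4L)
  for (k in 1:4) {
    j <- grid$nb[, k]
    has <- !is.na(j)
    v[has, k] <- chi * (phi$values[j[has]] - phi$values[has]) / grid$h
  }
  v
}

#' Stable time step for the explicit advection part
#'
#' The upwind advection update is positivity-preserving for
#' `dt <= 0.9 h / max_i sum_faces v_i^+`; diffusion is implicit and the
#' cell-local loss term is treated implicitly, so neither restricts `dt`.
#'
#' @param phi the chemotactic potential, a [scalar_field()].
#' @param chi chemotactic sensitivity (> 0).
#' @return Admissible time step (Inf if the drift vanishes).
#' @export
advection_stable_dt <- function(phi, chi) {
  v <- face_velocities(phi, chi)
  vout <- max(rowSums(pmax(v, 0)))
  if (vout <= 0) return(Inf)
  0.9 * phi$grid$h / vout
}

# Cholesky factor of (I - dt * D * L_dirichlet), cached per (D, dt).
diffusion_factor <- function(grid, D, dt) {
  key <- sprintf("diff_%.17g_%.17g", D, dt)
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  n <- grid$n_masked
  A <- Matrix::Diagonal(n) - (dt * D) * dirichlet_laplacian(grid)
  f <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  grid$cache[[key]] <- f
  f
}

#' Advance an immune-cell field one time step
#'
#' One operator-splitting step of the convection-diffusion-reaction
#' equation `du/dt + div(u chi grad phi - D grad u) = gain - loss * u`
#' with homogeneous Dirichlet condition on the disc boundary (immune
#' cells far from the tumor are non-activated): explicit upwind
#' advection along the chemotactic drift, then the reaction with
#' explicit gain and implicit cell-local loss, then implicit (backward
#' Euler) diffusion. Every substep maps nonnegative fields to
#' nonnegative fields provided `dt` satisfies [advection_stable_dt()].
#'
#' @param u the field to advance, a [scalar_field()].
#' @param phi chemotactic potential on the same grid.
#' @param chi chemotactic sensitivity (>= 0).
#' @param D diffusion coefficient (> 0).
#' @param gain source term, a [scalar_field()] or scalar (>= 0).
#' @param loss_rate cell-local loss rate, a [scalar_field()] or scalar
#'   (>= 0).
#' @param dt time step.
#' @return The advanced [scalar_field()].
#' @export
advance_field <- function(u, phi, chi, D, gain = 0, loss_rate = 0, dt) {
  stopifnot(inherits(u, "scalar_field"), inherits(phi, "scalar_field"),
            chi >= 0, D > 0, dt > 0)
  grid <- u$grid
  gv <- if (inherits(gain, "scalar_field")) gain$values else
    rep(gain, grid$n_masked)
  lv <- if (inherits(loss_rate, "scalar_field")) loss_rate$values else
    rep(loss_rate, grid$n_masked)
  if (any(gv < 0) || any(lv < 0))
    stop("advance_field: gain and loss_rate must be nonnegative")
  dt_ok <- advection_stable_dt(phi, chi)
  if (dt > dt_ok * (1 + 1e-12))
    stop(sprintf("advance_field: dt = %g violates advection stability; use dt <= %g",
                 dt, dt_ok))
  # explicit upwind advection
  v <- face_velocities(phi, chi)
  adv <- numeric(grid$n_masked)
  for (k in 1:4) {
    j <- grid$nb[, k]
    un <- ifelse(is.na(j), 0, u$values[j])
    adv <- adv + ifelse(v[, k] > 0, v[, k] * u$values, v[, k] * un)
  }
  u1 <- u$values - dt * adv / grid$h
  # reaction: explicit gain, implicit local loss
  u2 <- (u1 + dt * gv) / (1 + dt * lv)
  # implicit diffusion
  u3 <- as.numeric(Matrix::solve(diffusion_factor(grid, D, dt), u2,
                                 system = "A"))
  u3[u3 < 0] <- 0          # roundoff guard; the scheme is monotone
  scalar_field(grid, u3)
}
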