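# Sparse upwind advection operator for the drift chi*f*grad(Phi):
# row i of A_adv gives (div(u v))_i, built face-by-face so it is the
# exact linearization of the explicit upwind flux used by the stepper.
advection_operator <- function(phi, chi) {
  grid <- phi$grid
  v <- face_velocities(phi, chi)
  n <- grid$n_masked
  ii <- jj <- integer(0)
  xx <- numeric(0)
  diagv <- numeric(n)
  for (k in 1:4) {
    j <- grid$nb[, k]
    has <- !is.na(j)
    vout <- v[, k]
    up <- has & vout > 0          # outflow: carries u_i
    dn <- has & vout <= 0         # inflow: carries u_j
    diagv[up] <- diagv[up] + vout[up] / grid$h
    ii <- c(ii, which(dn)); jj <- c(jj, j[dn])
    xx <- c(xx, vout[dn] / grid$h)
  }
  Matrix::sparseMatrix(i = c(ii, 1:n), j = c(jj, 1:n),
                       x = c(xx, diagv), dims = c(n, n))
}

#' Predict the equilibrium tumor mass from the stationary system
#'
#' At an equilibrium of the coupled model with no growth enhancement
#' (`A_b1 = 0`) the kill rate delivered by the effector cells must equal
#' the Malthus eigenvalue: `int delta C dx = lambda`. For a candidate
#' tumor mass `mu1` the stationary concentrations solve the
#' convection-diffusion-reaction system with cytokines at their fixed
#' point `I = psi(mu1)/tau`; the nonlinear coupling between `C` and
#' `C_r` is resolved by damped fixed-point iteration and the scalar
#' constraint is solved for the smallest positive root by bracketing
#' from zero (the trivial state `mu1 = 0` always satisfies the system
#' with `lambda` replaced by 0).
#'
#' @param params a [model_params()] with `A_b1 = 0`.
#' @param lam the Malthus eigenvalue from [leading_eigenpair()].
#' @param n_axis spatial resolution used for the stationary solves.
#' @param mu1_upper upper end of the root bracket.
#' @param tol relative tolerance of the root.
#' @param fp_damping,fp_tol,fp_max damping, tolerance and cap of the
#'   fixed-point iteration on the `C`/`C_r` coupling.
#' @return List of class `equilibrium_prediction`: `mu1` (the predicted
#'   equilibrium mass), `kill_rate` at the root, the stationary fields
#'   `C`, `C_r`, cytokine level `I`, and the bracketing diagnostics.
#' @export
predict_equilibrium_mass <- function(params, lam, n_axis = 64,
                                     mu1_upper = NULL, tol = 1e-8,
                                     fp_damping = 0.5, fp_tol = 1e-10,
                                     fp_max = 200L) {
  stopifnot(inherits(params, "model_params"), lam >= 0)
  if (lam == 0)     # the trivial zero of the constraint map
    return(structure(list(mu1 = 0, kill_rate = 0, lambda = 0,
                          C = NULL, C_r = NULL, I = 0,
                          bracket = c(0, 0), iterations = 0L),
                     class = "equilibrium_prediction"))
  if (params$A_b1 != 0)
    stop("predict_equilibrium_mass: requires A_b1 = 0 (decoupled eigenvalue)")
  grid <- make_disc_grid(n_axis)
  delta_f <- gaussian_field(grid, params$A, params$xi2)
  sigma_f <- gaussian_field(grid, params$A_sigma, params$xi2_sigma)
  theta_f <- gaussian_field(grid, params$A_theta, params$xi2_theta)
  Sr_f <- protumor_source_field(grid, params)
  L <- dirichlet_laplacian(grid)
  Phi <- solve_potential(sigma_f, params$K, 1)   # unit-strength potential

  kill_at <- function(mu1) {
    st <- stationary_fields(mu1, params, grid, delta_f, theta_f, Sr_f,
                            L, Phi, fp_damping, fp_tol, fp_max)
    st$kill
  }
  # bracket the smallest positive root of kill(mu1) - lam from 0 upward
  if (is.null(mu1_upper))
    mu1_upper <- max(10 * lam * params$gamma / params$S, 10 * params$m, 1)
  probes <- mu1_upper * 2^seq(-20, 0, by = 1)
  flo <- -lam                       # kill(0) = 0
  lo <- 0
  hi <- NA_real_
  for (q in probes) {
    fq <- kill_at(q) - lam
    if (fq > 0) { hi <- q; break }
    lo <- q; flo <- fq
  }
  if (is.na(hi))
    stop("predict_equilibrium_mass: no admissible equilibrium — the ",
         "stationary kill rate never reaches lambda on the bracket")
  root <- stats::uniroot(function(m1) kill_at(m1) - lam,
                         lower = lo, upper = hi, f.lower = flo,
                         tol = tol * hi)
  st <- stationary_fields(root$root, params, grid, delta_f, theta_f, Sr_f,
                          L, Phi, fp_damping, fp_tol, fp_max)
  structure(list(mu1 = root$root, kill_rate = st$kill, lambda = lam,
                 C = st$C, C_r = st$C_r, I = st$I,
                 bracket = c(lo, hi), iterations = root$iter),
            class = "equilibrium_prediction")
}

#' @export
print.equilibrium_prediction <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_prediction> mu1 = %.6g (kill rate %.6g vs lambda %.6g)\n",
    x$mu1, x$kill_rate, x$lambda))
  invisible(x)
}

# Stationary immune fields for a frozen tumor mass mu1.
stationary_fields <- function(mu1, params, grid, delta_f, theta_f, Sr_f,
                              L, Phi, damping, fp_tol, fp_max) {
  p <- params
  n <- grid$n_masked
  I <- psi_threshold(mu1, p$m, p$psi_bar) / p$tau
  fval <- mm_response(mu1, p$eta)
  phi <- scalar_field(grid, fval * Phi$values)
  Aadv <- advection_operator(phi, p$chi)
  base <- Aadv - p$D * L
  gS <- rep(activation_g(mu1, p$g_mode) * p$S, n)
  Cr <- numeric(n)
  C <- numeric(n)
  for (it in seq_len(fp_max)) {
    AC <- base + Matrix::Diagonal(n, p$gamma + p$k_r * I * theta_f$values +
                                    p$k_c * Cr)
    C_new <- as.numeric(Matrix::solve(AC, gS))
    rhs_r <- I * (Sr_f$values + p$k_r * theta_f$values * C_new)
    ACr <- base + Matrix::Diagonal(n, rep(p$gamma_r, n))
    Cr_new <- as.numeric(Matrix::solve(ACr, rhs_r))
    dC <- max(abs(C_new - C)) + max(abs(Cr_new - Cr))
    C <- damping * C_new + (1 - damping) * C
    Cr <- damping * Cr_new + (1 - damping) * Cr
    if (dC < fp_tol * (1 + max(abs(C)))) break
    if (I == 0) { C <- C_new; Cr <- Cr_new; break }  # linear: one solve
  }
  list(C = scalar_field(grid, pmax(C, 0)),
       C_r = scalar_field(grid, pmax(Cr, 0)),
       I = I,
       kill = sum(delta_f$values * C) * grid$area)
}
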