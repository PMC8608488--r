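# Sparse operators on the masked disc grid, cached per grid.
#
# Dirichlet Laplacian: ghost value 0 at mask-boundary faces, two-point
# flux; row i: sum_faces (u_nb - u_i)/h^2, boundary face contributes
# -2 u_i / h^2 (face value 0 at distance h/2).
dirichlet_laplacian <- function(grid) {
  key <- "lap_dirichlet"
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  n <- grid$n_masked
  nb <- grid$nb
  ii <- jj <- integer(0)
  xx <- numeric(0)
  diagv <- numeric(n)
  for (k in 1:4) {
    has <- !is.na(nb[, k])
    ii <- c(ii, which(has)); jj <- c(jj, nb[has, k])
    xx <- c(xx, rep(1, sum(has)))
    diagv <- diagv - ifelse(has, 1, 2)
  }
  L <- Matrix::sparseMatrix(i = c(ii, 1:n), j = c(jj, 1:n),
                            x = c(xx, diagv), dims = c(n, n)) / grid$h^2
  grid$cache[[key]] <- L
  L
}

# Neumann Laplacian: only interior faces (zero-flux closure on the mask
# boundary); singular with constant nullspace.
neumann_laplacian <- function(grid) {
  key <- "lap_neumann"
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  n <- grid$n_masked
  nb <- grid$nb
  ii <- jj <- integer(0)
  xx <- numeric(0)
  diagv <- numeric(n)
  for (k in 1:4) {
    has <- !is.na(nb[, k])
    ii <- c(ii, which(has)); jj <- c(jj, nb[has, k])
    xx <- c(xx, rep(1, sum(has)))
    diagv <- diagv - ifelse(has, 1, 0)
  }
  L <- Matrix::sparseMatrix(i = c(ii, 1:n), j = c(jj, 1:n),
                            x = c(xx, diagv), dims = c(n, n)) / grid$h^2
  grid$cache[[key]] <- L
  L
}

# LU factor of the bordered Neumann system [[-K L, 1], [area^T, 0]]:
# enforces the zero-mean gauge and absorbs the nullspace.
neumann_solver <- function(grid, K) {
  key <- sprintf("neumann_solver_%.17g", K)
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  n <- grid$n_masked
  L <- neumann_laplacian(grid)
  A <- rbind(cbind(-K * L, Matrix::Matrix(1, n, 1)),
             cbind(Matrix::Matrix(grid$area, 1, n), Matrix::Matrix(0, 1, 1)))
  f <- Matrix::lu(A)
  grid$cache[[key]] <- f
  f
}

#' Solve for the chemotactic potential
#'
#' Solves the elliptic problem `-div(K grad phi) = strength * sigma~` on
#' the masked disc with zero normal flux on the boundary, where `sigma~`
#' is `sigma` projected to zero mean over the disc (the Neumann problem
#' is solvable only for zero-mean sources; the projection subtracts a
#' spatial constant and therefore does not change the gradient that
#' drives the chemotactic drift). The gauge is fixed by zero mean of
#' `phi`.
#'
#' @param sigma a [scalar_field()], the chemoattractant form function.
#' @param K potential diffusion coefficient (> 0).
#' @param strength source strength, typically the Michaelis-Menten
#'   response `f(mu1)` of the tumor mass (>= 0).
#' @return A [scalar_field()] `phi` with zero mean; attribute
#'   `"residual"` carries the discrete residual norm.
#' @export
solve_potential <- function(sigma, K, strength) {
  stopifnot(inherits(sigma, "scalar_field"), K > 0, strength >= 0)
  grid <- sigma$grid
  if (strength == 0) {
    phi <- scalar_field(grid, 0)
    attr(phi, "residual") <- 0
    return(phi)
  }
  rhs <- strength * (sigma$values - mean(sigma$values))
  stopifnot(abs(sum(rhs) * grid$area) <= 1e-10 * (1 + sum(abs(rhs)) * grid$area))
  sol <- Matrix::solve(neumann_solver(grid, K), c(rhs, 0))
  vals <- as.numeric(sol)[seq_len(grid$n_masked)]
  vals <- vals - mean(vals)
  L <- neumann_laplacian(grid)
  res <- sqrt(sum((as.numeric(-K * (L %*% vals)) - rhs)^2) * grid$area)
  phi <- scalar_field(grid, vals)
  attr(phi, "residual") <- res
  phi
}
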