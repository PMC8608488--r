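#' Uniform finite-volume grid in the cell-size variable
#'
#' Builds a uniform grid of `n_cells` finite-volume cells on `[0, z_max]`.
#' The size variable `z` is the volume of a tumor cell; densities live at
#' cell centers and integrals are midpoint sums.
#'
#' @param n_cells number of cells (>= 4).
#' @param z_max upper end of the size domain. For the Gompertz growth law
#'   this is the maximal size `b`; for constant growth it is a truncation
#'   of the half-line, chosen large enough that boundary loss is negligible.
#' @return An object of class `size_grid` with fields `edges`, `centers`,
#'   `widths`, `n_cells`, `z_max`.
#' @export
size_grid <- function(n_cells, z_max) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 4,
            is.numeric(z_max), length(z_max) == 1L, z_max > 0)
  n_cells <- as.integer(n_cells)
  edges <- seq(0, z_max, length.out = n_cells + 1L)
  structure(list(
    n_cells = n_cells,
    z_max   = z_max,
    edges   = edges,
    centers = 0.5 * (edges[-1L] + edges[-(n_cells + 1L)]),
    widths  = diff(edges)
  ), class = "size_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("<size_grid> %d cells on [0, %g], h = %g\n",
              x$n_cells, x$z_max, x$widths[1L]))
  invisible(x)
}

#' Tumor cell growth law
#'
#' Either a constant growth rate `V` or the Gompertz law
#' `V(z) = r z log(b / z)`, which vanishes at `z = 0` and at the maximal
#' size `b` and so confines the population to `[0, b]`.
#'
#' @param kind `"constant"` or `"gompertz"`.
#' @param V constant growth rate (size/time), `kind = "constant"` only.
#' @param r intrinsic rate (1/time), Gompertz only.
#' @param b maximal cell size, Gompertz only.
#' @return An object of class `growth_law`.
#' @export
growth_law <- function(kind = c("constant", "gompertz"), V = NULL,
                       r = NULL, b = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.numeric(V), length(V) == 1L, V > 0)
    structure(list(kind = kind, V = V), class = "growth_law")
  } else {
    stopifnot(is.numeric(r), length(r) == 1L, r > 0,
              is.numeric(b), length(b) == 1L, b > 0)
    structure(list(kind = kind, r = r, b = b), class = "growth_law")
  }
}

#' @export
print.growth_law <- function(x, ...) {
  if (x$kind == "constant")
    cat(sprintf("<growth_law> constant, V = %g\n", x$V))
  else
    cat(sprintf("<growth_law> Gompertz, r = %g, b = %g\n", x$r, x$b))
  invisible(x)
}

#' Evaluate the growth velocity at sizes z
#'
#' @param z numeric vector of sizes.
#' @param law a [growth_law()].
#' @return Growth velocities `V(z)`, same length as `z`.
#' @export
growth_rate <- function(z, law) {
  stopifnot(inherits(law, "growth_law"), is.numeric(z))
  if (law$kind == "constant") return(rep(law$V, length(z)))
  if (any(z < 0 | z > law$b))
    stop("growth_rate: z outside [0, b] for the Gompertz law")
  v <- numeric(length(z))
  pos <- z > 0 & z < law$b
  v[pos] <- law$r * z[pos] * log(law$b / z[pos])
  v
}

#' Binary cell-division model
#'
#' Division of a mother cell of size `2z` into two daughters of size `z`,
#' at frequency `a(z)` which is either constant or a threshold rate
#' `a * 1{z >= z0}` that forbids division of the smallest cells.
#'
#' @param a division frequency (1/time).
#' @param rate_kind `"constant"` or `"threshold"`.
#' @param z0 size threshold below which cells do not divide
#'   (`rate_kind = "threshold"` only; default 1).
#' @return An object of class `division_model`.
#' @export
division_model <- function(a, rate_kind = c("constant", "threshold"),
                           z0 = 1) {
  rate_kind <- match.arg(rate_kind)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(z0), length(z0) == 1L, z0 >= 0)
  structure(list(kind = "binary", rate_kind = rate_kind, a = a, z0 = z0),
            class = "division_model")
}

#' @export
print.division_model <- function(x, ...) {
  if (x$rate_kind == "constant")
    cat(sprintf("<division_model> binary, a = %g (constant)\n", x$a))
  else
    cat(sprintf("<division_model> binary, a = %g for z >= %g\n", x$a, x$z0))
  invisible(x)
}

division_rate <- function(z, model) {
  if (model$rate_kind == "constant") rep(model$a, length(z))
  else model$a * as.numeric(z >= model$z0)
}

#' Size-resolved tumor cell density
#'
#' @param grid a [size_grid()].
#' @param values nonnegative per-cell densities (cells per unit size) at
#'   the cell centers; a scalar is recycled.
#' @return An object of class `tumor_density`.
#' @export
tumor_density <- function(grid, values) {
  stopifnot(inherits(grid, "size_grid"))
  if (length(values) == 1L) values <- rep(values, grid$n_cells)
  stopifnot(length(values) == grid$n_cells)
  if (any(values < 0)) stop("tumor_density: negative values")
  structure(list(grid = grid, values = as.numeric(values)),
            class = "tumor_density")
}

#' @export
print.tumor_density <- function(x, ...) {
  mm <- tumor_moments(x)
  cat(sprintf("<tumor_density> %d cells on [0, %g]; mu0 = %.6g, mu1 = %.6g\n",
              x$grid$n_cells, x$grid$z_max, mm[["mu0"]], mm[["mu1"]]))
  invisible(x)
}

#' Indicator initial datum on a size interval
#'
#' The reference initial condition: density 1 for `z` in `[lo, hi]`, 0
#' elsewhere, represented by exact cell averages of the indicator.
#'
#' @param grid a [size_grid()].
#' @param lo,hi support of the indicator (default `[0.125, 5]`).
#' @return A [tumor_density()].
#' @export
indicator_density <- function(grid, lo = 0.125, hi = 5) {
  stopifnot(hi > lo, lo >= 0, hi <= grid$z_max)
  el <- grid$edges[-(grid$n_cells + 1L)]
  er <- grid$edges[-1L]
  overlap <- pmax(0, pmin(er, hi) - pmax(el, lo))
  tumor_density(grid, overlap / grid$widths)
}

#' Number and mass moments of a tumor density
#'
#' Returns the total cell number `mu0 = int n dz` and total tumor mass
#' `mu1 = int z n dz` as midpoint sums on the density's grid.
#'
#' @param n a [tumor_density()].
#' @return Named numeric vector `c(mu0 = ..., mu1 = ...)`.
#' @export
tumor_moments <- function(n) {
  stopifnot(inherits(n, "tumor_density"))
  w <- n$grid$widths
  c(mu0 = sum(n$values * w), mu1 = sum(n$grid$centers * n$values * w))
}
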