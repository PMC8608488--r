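#' Cartesian finite-volume grid masked to the unit disc
#'
#' Builds `n_axis` x `n_axis` square cells on the bounding box `[-1,1]^2`
#' and masks in the cells whose center lies inside the unit disc
#' (embedded-boundary, staircase geometry). All spatial fields live on
#' the masked cells; faces between a masked and an unmasked cell form the
#' discrete disc boundary.
#'
#' @param n_axis cells per axis (>= 8).
#' @return Object of class `disc_grid` with fields `n_axis`, `h` (cell
#'   side), `area` (cell area), `x`, `y` (centers of masked cells),
#'   `n_masked`, `nb` (n_masked x 4 matrix of masked-neighbor indices in
#'   the order +x, -x, +y, -y; `NA` marks a boundary face), and sparse
#'   operator caches.
#' @export
make_disc_grid <- function(n_axis) {
  stopifnot(is.numeric(n_axis), length(n_axis) == 1L, n_axis >= 8)
  n_axis <- as.integer(n_axis)
  h <- 2 / n_axis
  ax <- -1 + (seq_len(n_axis) - 0.5) * h
  cx <- rep(ax, times = n_axis)
  cy <- rep(ax, each = n_axis)
  inside <- cx^2 + cy^2 < 1
  id <- integer(n_axis * n_axis)       # 0 = outside
  id[inside] <- seq_len(sum(inside))
  full <- matrix(id, n_axis, n_axis)   # [ix, iy]
  ixs <- ((which(inside) - 1L) %% n_axis) + 1L
  iys <- ((which(inside) - 1L) %/% n_axis) + 1L
  pick <- function(ix, iy) {
    ok <- ix >= 1L & ix <= n_axis & iy >= 1L & iy <= n_axis
    out <- rep(NA_integer_, length(ix))
    out[ok] <- full[cbind(ix[ok], iy[ok])]
    out[!is.na(out) & out == 0L] <- NA_integer_
    out
  }
  nb <- cbind(px = pick(ixs + 1L, iys), mx = pick(ixs - 1L, iys),
              py = pick(ixs, iys + 1L), my = pick(ixs, iys - 1L))
  structure(list(
    n_axis = n_axis, h = h, area = h * h,
    x = cx[inside], y = cy[inside],
    n_masked = sum(inside), nb = nb,
    cache = new.env(parent = emptyenv())
  ), class = "disc_grid")
}

#' @export
print.disc_grid <- function(x, ...) {
  cat(sprintf("<disc_grid> %dx%d box, %d masked cells, area %.5f (pi = %.5f)\n",
              x$n_axis, x$n_axis, x$n_masked, x$n_masked * x$area, pi))
  invisible(x)
}

#' Space-resolved scalar field on the disc grid
#'
#' @param grid a [make_disc_grid()] grid.
#' @param values per-masked-cell values; a scalar is recycled.
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values = 0) {
  stopifnot(inherits(grid, "disc_grid"))
  if (length(values) == 1L) values <- rep(values, grid$n_masked)
  stopifnot(length(values) == grid$n_masked)
  structure(list(grid = grid, values = as.numeric(values)),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d cells; range [%.4g, %.4g]; integral %.6g\n",
              x$grid$n_masked, min(x$values), max(x$values),
              sum(x$values) * x$grid$area))
  invisible(x)
}

#' Gaussian form function on the disc
#'
#' Evaluates `A / (2 pi xi2) * exp(-|x - center|^2 / (2 xi2))` at the
#' masked cell centers: a bivariate Gaussian bump of total mass `A` (up
#' to the mass outside the disc) and variance `xi2`, used for the kill
#' weight, the chemoattractant source, the conversion kernel and the
#' growth-enhancement kernel.
#'
#' @param grid a [make_disc_grid()] grid.
#' @param A amplitude (total mass of the untruncated Gaussian).
#' @param xi2 variance (length^2), > 0.
#' @param center length-2 center, default the origin.
#' @return A [scalar_field()].
#' @export
gaussian_field <- function(grid, A, xi2, center = c(0, 0)) {
  stopifnot(A >= 0, xi2 > 0, length(center) == 2L)
  r2 <- (grid$x - center[1L])^2 + (grid$y - center[2L])^2
  scalar_field(grid, A / (2 * pi * xi2) * exp(-r2 / (2 * xi2)))
}

#' Weighted integral of a field over the disc
#'
#' Computes the midpoint-rule integral `int_Omega w u dx` over the masked
#' cells; with `w` a kill or enhancement kernel this yields the immune
#' kill rate, the growth enhancement and the immune strength diagnostics.
#'
#' @param u,w [scalar_field()]s on the same grid.
#' @return A scalar.
#' @export
integrate_weighted <- function(u, w) {
  stopifnot(inherits(u, "scalar_field"), inherits(w, "scalar_field"))
  if (!identical(u$grid$n_axis, w$grid$n_axis) ||
      u$grid$n_masked != w$grid$n_masked)
    stop("integrate_weighted: fields live on different grids")
  sum(u$values * w$values) * u$grid$area
}

#' Integral of a field over the disc
#'
#' @param u a [scalar_field()].
#' @return `int_Omega u dx` by the midpoint rule.
#' @export
integrate_field <- function(u) {
  stopifnot(inherits(u, "scalar_field"))
  sum(u$values) * u$grid$area
}
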