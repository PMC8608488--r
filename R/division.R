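#' Apply the binary division operator
#'
#' Evaluates `Q(n)(z) = 4 a(2z) n(2z) - a(z) n(z)`: cells of size `2z`
#' split into two daughters of size `z`. The gain term is interpolated
#' linearly onto the grid and then rescaled by a single multiplicative
#' factor so that the discrete first moment of `Q(n)` vanishes exactly —
#' division redistributes cell sizes but never creates or destroys tumor
#' mass, and the discretization enforces that structural identity rather
#' than approximating it.
#'
#' @param n a [tumor_density()].
#' @param model a [division_model()].
#' @return Numeric vector, `Q(n)` per grid cell (cells/(size x time)).
#' @export
apply_division <- function(n, model) {
  stopifnot(inherits(n, "tumor_density"), inherits(model, "division_model"))
  grid <- n$grid
  z <- grid$centers
  w <- grid$widths
  loss <- division_rate(z, model) * n$values
  # n(2z) by linear interpolation of cell-center values; 0 outside [0, z_max]
  n2 <- interp_density(grid, n$values, 2 * z)
  gain <- 4 * division_rate(2 * z, model) * n2
  m_loss <- sum(z * loss * w)
  m_gain <- sum(z * gain * w)
  if (m_gain > 0) gain <- gain * (m_loss / m_gain)
  gain - loss
}

# Linear interpolation of per-cell density values at query points zq,
# with value 0 at z = 0 (inflow boundary) and beyond z_max.
interp_density <- function(grid, values, zq) {
  xs <- c(0, grid$centers, grid$z_max)
  ys <- c(0, values, 0)
  out <- stats::approx(xs, ys, xout = pmin(zq, grid$z_max),
                       method = "linear", rule = 2)$y
  out[zq > grid$z_max] <- 0
  out
}
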