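#' Parameters of the reduced five-state ODE model
#'
#' The space-homogeneous simplification of the coupled model: constant
#' growth `V` and division rate `a`, scalar kill strength `delta`,
#' constant effector source `S`, linear (or quadratic) activation, and
#' the same cytokine relay. The reference values `V = 0.616`,
#' `delta = 1`, `S = 1.5`, `k_r = 1.25`, `k_c = 0.1`, `m = 2` are the
#' published ODE scenario; `gamma` defaults to the published 0.18 and
#' `gamma_r`, `tau`, `psi_bar` to 1 (package defaults).
#'
#' @param a tumor division rate (> 0).
#' @param V tumor growth rate (> 0).
#' @param delta kill strength of the effector cells (> 0).
#' @param S effector source (> 0).
#' @param gamma,gamma_r effector / protumor death rates (> 0).
#' @param tau cytokine damping rate (> 0).
#' @param k_r,k_c conversion and suppression rates (> 0).
#' @param b1 protumor growth-enhancement coefficient (>= 0).
#' @param m critical tumor mass (>= 0).
#' @param psi_bar cytokine activation slope (> 0).
#' @param g_mode `"linear"` or `"quadratic"` effector activation.
#' @return Object of class `ode_params`.
#' @export
ode_params <- function(a = 0.8, V = 0.616, delta = 1, S = 1.5,
                       gamma = 0.18, gamma_r = 1, tau = 1,
                       k_r = 1.25, k_c = 0.1, b1 = 0, m = 2,
                       psi_bar = 1, g_mode = c("linear", "quadratic")) {
  g_mode <- match.arg(g_mode)
  stopifnot(a > 0, V > 0, delta > 0, S > 0, gamma > 0, gamma_r > 0,
            tau > 0, k_r > 0, k_c > 0, b1 >= 0, m >= 0, psi_bar > 0)
  structure(mget(c("a", "V", "delta", "S", "gamma", "gamma_r", "tau",
                   "k_r", "k_c", "b1", "m", "psi_bar", "g_mode")),
            class = "ode_params")
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf(
    "<ode_params> a=%g V=%g delta=%g S=%g gamma=%g gamma_r=%g tau=%g\n",
    x$a, x$V, x$delta, x$S, x$gamma, x$gamma_r, x$tau))
  cat(sprintf("             k_r=%g k_c=%g b1=%g m=%g psi_bar=%g g=%s\n",
              x$k_r, x$k_c, x$b1, x$m, x$psi_bar, x$g_mode))
  invisible(x)
}

#' Right-hand side of the reduced ODE system
#'
#' The state is `(mu0, mu1, c, c_r, I)`: tumor cell number and mass,
#' effector, protumor and cytokine concentrations. The derivatives are
#' `mu0' = mu0 (a - delta c)`, `mu1' = V (1 + b1 c_r) mu0 - delta mu1 c`,
#' `c' = g(mu1) S - gamma c - k_r c I - k_c c c_r`,
#' `c_r' = k_r c I - gamma_r c_r`, `I' = psi(mu1) - tau I`.
#'
#' @param state numeric length-5 vector `(mu0, mu1, c, c_r, I)`.
#' @param params an [ode_params()].
#' @return The derivative 5-vector.
#' @export
ode_rhs <- function(state, params) {
  stopifnot(length(state) == 5L, inherits(params, "ode_params"))
  mu0 <- state[[1L]]; mu1 <- state[[2L]]; cc <- state[[3L]]
  cr <- state[[4L]]; I <- state[[5L]]
  p <- params
  c(mu0 * (p$a - p$delta * cc),
    p$V * (1 + p$b1 * cr) * mu0 - p$delta * mu1 * cc,
    activation_g(mu1, p$g_mode) * p$S - p$gamma * cc - p$k_r * cc * I -
      p$k_c * cc * cr,
    p$k_r * cc * I - p$gamma_r * cr,
    psi_threshold(mu1, p$m, p$psi_bar) - p$tau * I)
}

#' Closed-form equilibria of the reduced ODE model
#'
#' Returns the three candidate equilibria with their admissibility:
#' \describe{
#'   \item{H}{the healthy state, all components zero.}
#'   \item{NP}{residual tumor and no protumor cells:
#'     `(gamma a^2/(delta V S), gamma a/(delta S), a/delta, 0, 0)`,
#'     admissible iff its tumor mass does not exceed the critical mass
#'     `m` (equivalently `a/delta < m S / gamma`), so the cytokine relay
#'     stays silent.}
#'   \item{P}{equilibrium with protumor cells, built from the tumor
#'     mass `mu1_P = (gamma a/delta - Q m - k_c a/(gamma_r delta) Q m) /
#'     (S - Q - k_c a/(gamma_r delta) Q)` with `Q = psi_bar k_r a /
#'     (delta tau)`; admissible iff `mu1_P > m` and the numerator and
#'     denominator share their sign (positivity).}
#' }
#' The closed forms hold for the linear activation `g(mu1) = mu1`; the
#' published formulas correspond to `psi_bar = 1` and generalize by
#' scaling `Q` with `psi_bar`.
#'
#' @param params an [ode_params()].
#' @return Object of class `equilibrium_set`: named states `H`, `NP`,
#'   `P` (each a 5-vector or `NULL` with a reason), admissibility flags,
#'   and the derived scalars `Q`, `Q1`, `Q2`, `X2`.
#' @export
ode_equilibria <- function(params) {
  p <- params
  stopifnot(inherits(p, "ode_params"))
  if (p$g_mode != "linear")
    stop("ode_equilibria: closed forms require the linear activation law")
  x <- p$a / p$delta
  H <- c(mu0 = 0, mu1 = 0, c = 0, c_r = 0, I = 0)
  NP <- c(mu0 = p$gamma * p$a^2 / (p$delta * p$V * p$S),
          mu1 = p$gamma * p$a / (p$delta * p$S),
          c = p$a / p$delta, c_r = 0, I = 0)
  np_adm <- NP[["mu1"]] <= p$m
  Q <- p$psi_bar * p$k_r * p$a / (p$delta * p$tau)
  kk <- p$k_c * p$a / (p$gamma_r * p$delta)
  num <- p$gamma * x - Q * p$m - kk * Q * p$m
  den <- p$S - Q - kk * Q
  P <- NULL
  p_adm <- FALSE
  p_reason <- NULL
  if (den == 0 || num / den <= 0) {
    p_reason <- "mu1_P not positive (sign condition on numerator/denominator fails)"
  } else {
    mu1P <- num / den
    if (mu1P <= p$m) {
      p_reason <- sprintf("mu1_P = %.6g <= m: cytokine relay silent, state collapses to NP form", mu1P)
    } else {
      psiP <- psi_threshold(mu1P, p$m, p$psi_bar)
      # c_r = k_r c I / gamma_r with c = a/delta, I = psi/tau
      crP <- (p$k_r * x / p$tau) * psiP / p$gamma_r
      IP <- psiP / p$tau
      mu0P <- p$a * mu1P / (p$V * (1 + p$b1 * crP))
      P <- c(mu0 = mu0P, mu1 = mu1P, c = x, c_r = crP, I = IP)
      p_adm <- TRUE
    }
  }
  Q1 <- p$psi_bar * p$k_r / p$tau
  Q2 <- p$psi_bar * p$k_c * p$k_r / (p$gamma_r * p$tau)
  X2 <- (-Q1 / Q2 + sqrt((Q1 / Q2)^2 + 4 * p$S / Q2)) / 2
  structure(list(H = H, NP = NP, P = P,
                 NP_admissible = np_adm,
                 NP_reason = if (np_adm) NULL else
                   sprintf("mu1_NP = %.6g > m = %g activates the cytokine relay",
                           NP[["mu1"]], p$m),
                 P_admissible = p_adm, P_reason = p_reason,
                 Q = Q, Q1 = Q1, Q2 = Q2, X2 = X2,
                 params = p),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set>\n  H : all zero (always an equilibrium)\n")
  cat(sprintf("  NP: mu1 = %.6g, c = %.6g  [%s]\n", x$NP[["mu1"]],
              x$NP[["c"]],
              if (x$NP_admissible) "admissible" else "not admissible"))
  if (!is.null(x$P))
    cat(sprintf("  P : mu1 = %.6g, c_r = %.6g  [admissible]\n",
                x$P[["mu1"]], x$P[["c_r"]]))
  else cat(sprintf("  P : absent (%s)\n", x$P_reason))
  cat(sprintf("  Q = %.4g, Q1 = %.4g, Q2 = %.4g, X2 = %.4g\n",
              x$Q, x$Q1, x$Q2, x$X2))
  invisible(x)
}

#' Competitiveness threshold X2 and the admissibility regimes
#'
#' `X2` is the nonnegative root of `S - Q1 x - Q2 x^2` in the
#' competitiveness ratio `x = a/delta`, with `Q1 = psi_bar k_r/tau` and
#' `Q2 = psi_bar k_c k_r/(gamma_r tau)`. Together with the boundary
#' `x = m S / gamma` it partitions the ratio axis into the admissibility
#' regimes of the NP and P equilibria, which differ between the
#' small-critical-mass case `m < gamma X2 / S` and the large case
#' `m > gamma X2 / S`:
#' \itemize{
#'   \item `m < gamma X2 / S`: NP alone for `x < mS/gamma`, P alone for
#'     `mS/gamma < x < X2`, none for `x >= X2` (the tumor mass blows
#'     up).
#'   \item `m > gamma X2 / S`: NP alone for `x < X2`, NP and P coexist
#'     for `X2 < x < mS/gamma`, none for `x > mS/gamma`.
#' }
#'
#' @param params an [ode_params()].
#' @param x optional competitiveness ratios `a/delta` at which to report
#'   the regime; defaults to the ratio of `params`.
#' @return List of class `regime_table`: `X2`, `case` (small or large
#'   critical mass), and data frame `regimes` with columns `x`,
#'   `NP_admissible`, `P_admissible`, `regime`.
#' @export
ode_x2_threshold <- function(params, x = NULL) {
  p <- params
  stopifnot(inherits(p, "ode_params"))
  eq0 <- ode_equilibria(p)
  X2 <- eq0$X2
  xm <- p$m * p$S / p$gamma
  small_m <- p$m < p$gamma * X2 / p$S
  if (is.null(x)) x <- p$a / p$delta
  rows <- lapply(x, function(xi) {
    pp <- p
    pp$a <- xi * p$delta     # probe the ratio, keeping delta
    eq <- ode_equilibria(pp)
    regime <- if (eq$NP_admissible && eq$P_admissible) "NP+P"
    else if (eq$NP_admissible) "NP"
    else if (eq$P_admissible) "P"
    else "none"
    data.frame(x = xi, NP_admissible = eq$NP_admissible,
               P_admissible = eq$P_admissible, regime = regime)
  })
  structure(list(X2 = X2, x_m = xm,
                 case = if (small_m) "small critical mass (m < gamma X2 / S)"
                 else "large critical mass (m > gamma X2 / S)",
                 regimes = do.call(rbind, rows)),
            class = "regime_table")
}

#' @export
print.regime_table <- function(x, ...) {
  cat(sprintf("<regime_table> X2 = %.6g, mS/gamma = %.6g; %s\n",
              x$X2, x$x_m, x$case))
  print(x$regimes, row.names = FALSE)
  invisible(x)
}

#' Linear stability of an ODE equilibrium
#'
#' \describe{
#'   \item{H}{eigenvalues `{a, 0, -gamma, -gamma_r, -tau}`; the positive
#'     eigenvalue `a` makes the healthy state linearly unstable — any
#'     tumor seed grows.}
#'   \item{NP}{eigenvalues `{-gamma_r, -tau, -a,
#'     (-gamma +- sqrt(gamma (gamma - 4a)))/2}`; always stable when
#'     admissible, with a damped (all real, `gamma > 4a`) or oscillatory
#'     (complex pair, `gamma < 4a`) return.}
#'   \item{P}{no closed form (the Jacobian is full); eigenvalues of a
#'     central finite-difference Jacobian are returned.}
#' }
#'
#' @param params an [ode_params()].
#' @param which `"H"`, `"NP"` or `"P"`.
#' @return List of class `ode_stability` with `eigenvalues`,
#'   `classification` and `regime` (`"damped"`/`"oscillatory"` for NP).
#' @export
ode_stability <- function(params, which = c("NP", "H", "P")) {
  which <- match.arg(which)
  p <- params
  eq <- ode_equilibria(p)
  if (which == "H") {
    ev <- c(p$a, 0, -p$gamma, -p$gamma_r, -p$tau)
    return(structure(list(which = "H", eigenvalues = ev,
                          classification = "unstable",
                          regime = NA_character_),
                     class = "ode_stability"))
  }
  if (which == "NP") {
    disc <- p$gamma * (p$gamma - 4 * p$a)
    pair <- if (disc >= 0) (-p$gamma + c(1, -1) * sqrt(disc)) / 2
    else complex(real = -p$gamma / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
    ev <- c(-p$gamma_r, -p$tau, -p$a, pair)
    return(structure(list(which = "NP", eigenvalues = ev,
                          classification = "stable",
                          regime = if (p$gamma > 4 * p$a) "damped"
                          else "oscillatory"),
                     class = "ode_stability"))
  }
  if (!eq$P_admissible)
    stop("ode_stability: the P equilibrium is not admissible: ", eq$P_reason)
  J <- numeric_jacobian(function(s) ode_rhs(s, p), eq$P)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(which = "P", eigenvalues = ev,
                 classification = if (max(Re(ev)) < 0) "stable"
                 else "unstable",
                 regime = NA_character_),
            class = "ode_stability")
}

#' @export
print.ode_stability <- function(x, ...) {
  cat(sprintf("<ode_stability> %s: %s", x$which, x$classification))
  if (!is.na(x$regime)) cat(sprintf(" (%s)", x$regime))
  cat("\n  eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

# Central finite-difference Jacobian.
numeric_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- pmax(1e-6, 1e-6 * abs(x))
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}

#' Integrate the reduced ODE system
#'
#' Adaptive integration (lsoda with root-finding) of the reduced model.
#' The dynamics preserve nonnegativity of all components for nonnegative
#' initial data; integration stops early, flagged as escape, once the
#' tumor mass exceeds `blowup_factor * max(1, mu1(0))` — a finite proxy
#' for blow-up.
#'
#' @param params an [ode_params()].
#' @param init nonnegative length-5 initial state `(mu0, mu1, c, c_r,
#'   I)`.
#' @param horizon final time.
#' @param dt output spacing of the returned trajectory.
#' @param blowup_factor escape threshold factor (default 1e6).
#' @param rtol,atol solver tolerances.
#' @return List of class `ode_trajectory`: data frame `series` (columns
#'   `t, mu0, mu1, c, c_r, I`) and logical `escaped`.
#' @export
ode_integrate <- function(params, init, horizon, dt = 0.1,
                          blowup_factor = 1e6, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "ode_params"), length(init) == 5L,
            all(init >= 0), horizon > 0, dt > 0)
  cap <- blowup_factor * max(1, init[2L])
  times <- seq(0, horizon, by = dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  sol <- deSolve::ode(
    y = stats::setNames(as.numeric(init), c("mu0", "mu1", "c", "c_r", "I")),
    times = times,
    func = function(t, y, parms) list(ode_rhs(pmax(y, 0), params)),
    parms = NULL, method = "lsodar",
    rootfunc = function(t, y, parms) y[2L] - cap,
    rtol = rtol, atol = atol)
  series <- as.data.frame(sol)
  names(series)[1L] <- "t"
  escaped <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  structure(list(series = series, escaped = escaped,
                 params = params, blowup_cap = cap),
            class = "ode_trajectory")
}

#' @export
print.ode_trajectory <- function(x, ...) {
  s <- x$series
  nf <- nrow(s)
  cat(sprintf("<ode_trajectory> %d points to t = %.4g%s\n", nf, s$t[nf],
              if (x$escaped) " (stopped: tumor mass blow-up)" else ""))
  cat(sprintf("  final: mu1 = %.6g, c = %.6g, c_r = %.6g, I = %.6g\n",
              s$mu1[nf], s$c[nf], s$c_r[nf], s$I[nf]))
  invisible(x)
}
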