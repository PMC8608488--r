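#' Parameters of the coupled tumor-immune model
#'
#' Assembles the full parameter set of the size- and space-structured
#' model: the tumor growth law and division model, the transport
#' coefficients of the immune-cell equations, the Gaussian form
#' functions (kill weight `delta`, chemoattractant source `sigma`,
#' conversion kernel `theta`, growth-enhancement kernel `b1`), the
#' immune sources, the death rates, and the cytokine relay. The
#' reference values (`A`, `xi2`, `A_sigma`, `xi2_sigma`, `a`, `V`, `r`,
#' `b`, `chi`, `S`, `gamma`) are the published simulation data; every
#' other default is package configuration, flagged `"default"` in the
#' provenance attribute and recorded in run manifests.
#'
#' @param growth a [growth_law()] (default Gompertz, `r = 0.616`,
#'   `b = 10`).
#' @param division a [division_model()] (default threshold rate
#'   `a = 0.8`, `z0 = 1`).
#' @param chi chemotactic sensitivity.
#' @param D diffusion coefficient of the immune cells.
#' @param K diffusion coefficient of the chemotactic signal.
#' @param A,xi2 amplitude and variance of the kill weight `delta`.
#' @param A_sigma,xi2_sigma chemoattractant source Gaussian.
#' @param A_theta,xi2_theta conversion kernel Gaussian.
#' @param A_b1,xi2_b1 growth-enhancement kernel Gaussian (`A_b1 = 0`
#'   switches the enhancement off).
#' @param S homogeneous source amplitude of antitumor cells.
#' @param Sr_amplitude per-spot amplitude of the protumor source (three
#'   Gaussian spots at radius `Sr_radius`, angles 90, 210, 330 degrees).
#' @param Sr_scale global factor on the protumor source (default 1/5).
#' @param Sr_radius,Sr_xi2 geometry of the protumor source spots.
#' @param gamma,gamma_r,gamma_a death rates of antitumor, protumor and
#'   exhausted cells.
#' @param tau cytokine damping rate.
#' @param psi_bar,m cytokine activation slope and critical tumor mass.
#' @param k_c suppression rate of antitumor cells by protumor cells.
#' @param k_r cytokine-driven conversion rate.
#' @param eta Michaelis-Menten constant of the chemotactic response.
#' @param g_mode activation law of effector recruitment, `"linear"`
#'   (`g = mu1`) or `"quadratic"` (`g = mu1^2`).
#' @param alpha fraction of suppressed effector cells that become
#'   exhausted rather than dying (therapy extension), in `[0, 1]`.
#' @return Object of class `model_params`; attribute `provenance` maps
#'   each scalar parameter to `"paper"` or `"default"`.
#' @export
model_params <- function(growth = growth_law("gompertz", r = 0.616, b = 10),
                         division = division_model(a = 0.8,
                                                   rate_kind = "threshold",
                                                   z0 = 1),
                         chi = 0.864, D = 0.05, K = 0.001,
                         A = 1, xi2 = 0.02,
                         A_sigma = 0.002, xi2_sigma = 0.05,
                         A_theta = 1, xi2_theta = 0.08,
                         A_b1 = 0.1, xi2_b1 = 0.02,
                         S = 5,
                         Sr_amplitude = 2, Sr_scale = 1 / 5,
                         Sr_radius = 0.7, Sr_xi2 = 0.02,
                         gamma = 0.18, gamma_r = 1, gamma_a = 0.18,
                         tau = 1, psi_bar = 1, m = 0.12,
                         k_c = 2, k_r = 0.3,
                         eta = 1,
                         g_mode = c("linear", "quadratic"),
                         alpha = 0.5) {
  g_mode <- match.arg(g_mode)
  stopifnot(inherits(growth, "growth_law"), inherits(division, "division_model"),
            chi > 0, D > 0, K > 0, A >= 0, xi2 > 0, A_sigma >= 0,
            xi2_sigma > 0, A_theta >= 0, xi2_theta > 0, A_b1 >= 0,
            xi2_b1 > 0, S >= 0, Sr_amplitude >= 0, Sr_scale >= 0,
            gamma >= 0, gamma_r >= 0, gamma_a >= 0, tau > 0,
            psi_bar > 0, m >= 0, k_c >= 0, k_r >= 0, eta > 0,
            alpha >= 0, alpha <= 1)
  p <- structure(mget(c("growth", "division", "chi", "D", "K", "A", "xi2",
                        "A_sigma", "xi2_sigma", "A_theta", "xi2_theta",
                        "A_b1", "xi2_b1", "S", "Sr_amplitude", "Sr_scale",
                        "Sr_radius", "Sr_xi2", "gamma", "gamma_r",
                        "gamma_a", "tau", "psi_bar", "m", "k_c", "k_r",
                        "eta", "g_mode", "alpha")),
                 class = "model_params")
  paper <- c("chi", "A", "xi2", "A_sigma", "xi2_sigma", "S", "gamma",
             "alpha")
  prov <- stats::setNames(ifelse(names(p) %in% paper, "paper", "default"),
                          names(p))
  prov[["growth"]] <- "paper"     # Gompertz r = 0.616, b = 10
  prov[["division"]] <- "paper"   # a = 0.8, z0 = 1
  attr(p, "provenance") <- prov
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  growth:   "); print(x$growth)
  cat("  division: "); print(x$division)
  cat(sprintf("  chi = %g, D = %g, K = %g, S = %g, gamma = %g\n",
              x$chi, x$D, x$K, x$S, x$gamma))
  cat(sprintf("  cytokines: psi_bar = %g, m = %g, tau = %g; k_c = %g, k_r = %g\n",
              x$psi_bar, x$m, x$tau, x$k_c, x$k_r))
  invisible(x)
}

#' Michaelis-Menten response of the chemotactic strength
#'
#' `f(mu1) = mu1 / (eta + mu1)`: saturating, nondecreasing, `f(0) = 0`,
#' bounded by 1.
#'
#' @param mu1 tumor mass (>= 0), vectorized.
#' @param eta half-saturation mass (> 0).
#' @return Values in `[0, 1)`.
#' @export
mm_response <- function(mu1, eta) {
  stopifnot(eta > 0)
  if (any(mu1 < 0)) stop("mm_response: mu1 must be nonnegative")
  mu1 / (eta + mu1)
}

#' Effector-recruitment activation law
#'
#' Linear (`g(mu1) = mu1`) or strengthened quadratic (`g(mu1) = mu1^2`)
#' activation of the antitumor source by the tumor mass.
#'
#' @param mu1 tumor mass (>= 0), vectorized.
#' @param mode `"linear"` or `"quadratic"`.
#' @return `mu1` or `mu1^2`.
#' @export
activation_g <- function(mu1, mode = c("linear", "quadratic")) {
  mode <- match.arg(mode)
  if (any(mu1 < 0)) stop("activation_g: mu1 must be nonnegative")
  if (mode == "linear") mu1 else mu1^2
}

#' Threshold activation of the cytokine signal
#'
#' `psi(mu1) = psi_bar * (mu1 - m)` for `mu1 > m`, 0 otherwise: cytokine
#' production switches on only once the tumor mass exceeds the critical
#' mass `m`, so `psi(0) = psi'(0) = 0` whenever `m > 0`.
#'
#' @param mu1 tumor mass, vectorized.
#' @param m critical tumor mass (>= 0).
#' @param psi_bar activation slope (> 0).
#' @return Cytokine production rates.
#' @export
psi_threshold <- function(mu1, m, psi_bar = 1) {
  stopifnot(m >= 0, psi_bar > 0)
  psi_bar * pmax(mu1 - m, 0)
}

#' Advance the cytokine concentration one step
#'
#' Exact exponential-integrator update of `dI/dt = psi(mu1) - tau I`
#' with the tumor mass frozen over the step:
#' `I <- psi/tau + (I - psi/tau) exp(-tau dt)`.
#'
#' @param I current concentration (>= 0).
#' @param mu1 tumor mass over the step.
#' @param m,psi_bar,tau cytokine parameters.
#' @param dt time step.
#' @return The updated concentration (>= 0).
#' @export
cytokine_step <- function(I, mu1, m, psi_bar, tau, dt) {
  stopifnot(I >= 0, tau > 0, dt > 0)
  fix <- psi_threshold(mu1, m, psi_bar) / tau
  fix + (I - fix) * exp(-tau * dt)
}
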