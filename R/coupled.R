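#' Numerical settings for the coupled simulation
#'
#' @param n_axis spatial cells per axis on the bounding square.
#' @param n_size size cells of the tumor grid.
#' @param z_max size-domain truncation; `NULL` picks `b` for the
#'   Gompertz law and 10x the support of the initial datum for constant
#'   growth (outflow through `z_max` is monitored and warned about).
#' @param dt_max cap on the time step; the actual step also satisfies
#'   the transport stability bounds and is halved as needed.
#' @param escape_factor early-stop factor: integration halts once
#'   `mu1 > escape_factor * mu1(0)` (escape; a finite proxy for
#'   blow-up).
#' @param snapshot_times times at which field/density snapshots are
#'   stored on the result.
#' @return List of class `sim_numerics`.
#' @export
sim_numerics <- function(n_axis = 64, n_size = 256, z_max = NULL,
                         dt_max = 0.05, escape_factor = 1e6,
                         snapshot_times = numeric(0)) {
  stopifnot(n_axis >= 8, n_size >= 16, dt_max > 0, escape_factor > 1)
  structure(list(n_axis = as.integer(n_axis), n_size = as.integer(n_size),
                 z_max = z_max, dt_max = dt_max,
                 escape_factor = escape_factor,
                 snapshot_times = snapshot_times),
            class = "sim_numerics")
}

# Protumor source: three equal Gaussian spots on a circle, away from the
# tumor (bone-marrow-like recruitment sites), times a global scale.
protumor_source_field <- function(grid, params) {
  angs <- c(90, 210, 330) * pi / 180
  vals <- 0
  for (ang in angs) {
    ctr <- params$Sr_radius * c(cos(ang), sin(ang))
    vals <- vals + gaussian_field(grid, params$Sr_amplitude,
                                  params$Sr_xi2, ctr)$values
  }
  scalar_field(grid, params$Sr_scale * vals)
}

#' Run the coupled size- and space-structured simulation
#'
#' Advances the full system by operator splitting, each step in the
#' order: (i) moments of the tumor density; (ii) elliptic solve for the
#' chemotactic potential with strength `f(mu1)`; (iii) immune fields by
#' upwind advection, reactions and implicit diffusion; (iv) exact
#' cytokine update; (v) tumor density by the growth-fragmentation
#' stepper with growth enhancement `beta = int b1 c_r dx` and kill rate
#' `ell = int delta c dx`, both evaluated on the start-of-step fields.
#' The elliptic potential is re-solved every step (quasi-static
#' coupling). Integration stops early once the tumor mass exceeds
#' `escape_factor` times its initial value.
#'
#' Optional therapy extends the system with the exhausted-cell field
#' `c_a` (fed by the fraction `alpha` of the suppression flux
#' `k_c c c_r`): a reactivation schedule returns exhausted cells to the
#' effector pool at rate `T_react`, a blockade schedule clamps both
#' cytokine-driven recruitment terms by `max(0, 1 - T_block)`, and both
#' may be combined.
#'
#' @param params a [model_params()].
#' @param numerics a [sim_numerics()].
#' @param horizon final time.
#' @param init_tumor function(grid) returning the initial
#'   [tumor_density()]; the default is the reference indicator datum on
#'   `[0.125, 5]`. Initial immune fields and cytokines are zero.
#' @param sched_react,sched_block optional [dose_schedule()]s for the
#'   reactivation and blockade drugs.
#' @return Object of class `sim_result`: data frame `series` with
#'   columns `t, mu0, mu1, mubar_c, mu_cr, I, beta` (plus `T_react`,
#'   `T_block`, `mu_ca` when a therapy is active), `outcome` (a
#'   [classify_outcome()] label), `snapshots`, and a run `manifest`.
#' @export
run_tumor_immune <- function(params, numerics = sim_numerics(),
                             horizon, init_tumor = NULL,
                             sched_react = NULL, sched_block = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(numerics, "sim_numerics"), horizon > 0)
  therapy <- !is.null(sched_react) || !is.null(sched_block)
  for (s in list(sched_react, sched_block))
    if (!is.null(s)) {
      stopifnot(inherits(s, "dose_schedule"))
      if (s$t0 >= horizon)
        warning("run_tumor_immune: schedule starts after the horizon")
    }

  z_max <- numerics$z_max
  if (is.null(z_max))
    z_max <- if (params$growth$kind == "gompertz") params$growth$b else 50
  sgrid <- size_grid(numerics$n_size, z_max)
  grid <- make_disc_grid(numerics$n_axis)

  delta_f <- gaussian_field(grid, params$A, params$xi2)
  sigma_f <- gaussian_field(grid, params$A_sigma, params$xi2_sigma)
  theta_f <- gaussian_field(grid, params$A_theta, params$xi2_theta)
  b1_f    <- gaussian_field(grid, params$A_b1, params$xi2_b1)
  Sr_f    <- protumor_source_field(grid, params)

  n <- if (is.null(init_tumor)) indicator_density(sgrid) else
    init_tumor(sgrid)
  stopifnot(inherits(n, "tumor_density"))
  cfield <- scalar_field(grid, 0)
  crfield <- scalar_field(grid, 0)
  cafield <- if (therapy) scalar_field(grid, 0) else NULL
  I <- 0
  T_react <- 0
  T_block <- 0

  mu1_0 <- tumor_moments(n)[["mu1"]]
  t <- 0
  nrec_guess <- 4096L
  rec <- vector("list", 0L)
  snapshots <- list()
  snap_left <- sort(numerics$snapshot_times)
  outflux_total <- 0
  escaped <- FALSE

  record <- function(mm, ell, mucr, beta) {
    row <- c(t = t, mu0 = mm[["mu0"]], mu1 = mm[["mu1"]], mubar_c = ell,
             mu_cr = mucr, I = I, beta = beta)
    if (therapy)
      row <- c(row, T_react = T_react, T_block = T_block,
               mu_ca = if (is.null(cafield)) 0 else integrate_field(cafield))
    row
  }

  step_i <- 0L
  while (t < horizon - 1e-12) {
    mm <- tumor_moments(n)
    mu1 <- mm[["mu1"]]
    ell <- integrate_weighted(cfield, delta_f)
    beta <- integrate_weighted(crfield, b1_f)
    mucr <- integrate_field(crfield)
    rec[[length(rec) + 1L]] <- record(mm, ell, mucr, beta)

    if (length(snap_left) && t >= snap_left[1L] - 1e-12) {
      snapshots[[length(snapshots) + 1L]] <-
        list(t = t, n = n, c = cfield, c_r = crfield, c_a = cafield)
      snap_left <- snap_left[-1L]
    }
    if (mu1 > numerics$escape_factor * mu1_0) {
      escaped <- TRUE
      break
    }

    fval <- mm_response(mu1, params$eta)
    phi <- solve_potential(sigma_f, params$K, fval)

    dt_lim <- min(size_stable_dt(sgrid, params$growth, params$division,
                                 beta = beta, ell = ell),
                  advection_stable_dt(phi, params$chi),
                  horizon - t)
    dt <- numerics$dt_max
    while (dt > dt_lim) dt <- dt / 2     # halving keeps factor cache small

    clamp <- if (!is.null(sched_block)) max(0, 1 - T_block) else 1
    gmu <- activation_g(mu1, params$g_mode)
    c_gain_v <- rep(gmu * params$S, grid$n_masked)
    if (!is.null(sched_react))
      c_gain_v <- c_gain_v + T_react * cafield$values
    c_loss <- scalar_field(grid, params$gamma +
                             params$k_r * I * clamp * theta_f$values +
                             params$k_c * crfield$values)
    cr_gain <- scalar_field(grid, I * clamp *
                              (Sr_f$values +
                                 params$k_r * theta_f$values * cfield$values))
    c_new <- advance_field(cfield, phi, params$chi, params$D,
                           gain = scalar_field(grid, c_gain_v),
                           loss_rate = c_loss, dt)
    cr_new <- advance_field(crfield, phi, params$chi, params$D,
                            gain = cr_gain, loss_rate = params$gamma_r, dt)
    if (therapy) {
      ca_gain <- scalar_field(grid, params$alpha * params$k_c *
                                cfield$values * crfield$values)
      ca_loss <- params$gamma_a +
        if (!is.null(sched_react)) T_react else 0
      cafield <- advance_field(cafield, phi, params$chi, params$D,
                               gain = ca_gain, loss_rate = ca_loss, dt)
    }
    cfield <- c_new
    crfield <- cr_new
    I <- cytokine_step(I, mu1, params$m, params$psi_bar, params$tau, dt)
    n <- tumor_step(n, dt, beta = beta, ell = ell,
                    law = params$growth, model = params$division)
    outflux_total <- outflux_total + attr(n, "outflux_mass")
    if (!is.null(sched_react)) T_react <- drug_step(T_react, t, dt, sched_react)
    if (!is.null(sched_block)) T_block <- drug_step(T_block, t, dt, sched_block)
    t <- t + dt
    step_i <- step_i + 1L
  }
  # final record (unless the loop already recorded this instant)
  last_t <- rec[[length(rec)]][["t"]]
  if (abs(t - last_t) > 1e-12) {
    mm <- tumor_moments(n)
    rec[[length(rec) + 1L]] <- record(mm, integrate_weighted(cfield, delta_f),
                                      integrate_field(crfield),
                                      integrate_weighted(crfield, b1_f))
  }
  series <- as.data.frame(do.call(rbind, rec))
  if (params$growth$kind == "constant" &&
      outflux_total > 1e-6 * max(series$mu1))
    warning(sprintf(
      "run_tumor_immune: %.3g units of tumor mass left through z_max",
      outflux_total))

  out <- structure(list(
    series = series,
    snapshots = snapshots,
    final = list(n = n, c = cfield, c_r = crfield, c_a = cafield, I = I,
                 t = t),
    escaped_early = escaped,
    manifest = list(
      params = params_manifest(params),
      numerics = list(n_axis = numerics$n_axis, n_size = numerics$n_size,
                      z_max = z_max, dt_max = numerics$dt_max,
                      escape_factor = numerics$escape_factor),
      therapy = list(
        react = if (is.null(sched_react)) NULL else unclass(sched_react),
        block = if (is.null(sched_block)) NULL else unclass(sched_block)),
      horizon = horizon, steps = step_i,
      outflux_mass = outflux_total,
      package_version = as.character(utils::packageVersion("tumimm"))
    )), class = "sim_result")
  out$outcome <- classify_outcome(out)
  out
}

params_manifest <- function(params) {
  prov <- attr(params, "provenance")
  flat <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    flat[[nm]] <- list(value = if (is.list(v)) unclass(v) else v,
                       provenance = unname(prov[[nm]]))
  }
  flat
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$series
  cat(sprintf("<sim_result> %d records to t = %.4g; outcome: %s\n",
              nrow(s), s$t[nrow(s)], x$outcome$label))
  cat(sprintf("  final mu1 = %.6g, mubar_c = %.6g, mu_cr = %.3g, I = %.3g\n",
              s$mu1[nrow(s)], s$mubar_c[nrow(s)], s$mu_cr[nrow(s)],
              s$I[nrow(s)]))
  invisible(x)
}

#' Classify a simulation outcome as equilibrium or escape
#'
#' Escape: the tumor mass exceeds `escape_factor` times its initial
#' value while still increasing. Equilibrium: over the trailing window
#' the relative rate of change `|dmu1/dt| / max(mu1, eps)` stays below
#' `rel_tol`. Otherwise undecided.
#'
#' @param result a `sim_result` (or a data frame with columns `t`,
#'   `mu1`).
#' @param escape_factor threshold on `mu1 / mu1(0)` (default 1e3).
#' @param rel_tol relative-slope tolerance for equilibrium (default
#'   1e-5).
#' @param window_frac trailing fraction of the series inspected for the
#'   equilibrium criterion.
#' @param eps mass floor in the relative slope.
#' @return List of class `outcome_label` with `label` in
#'   `{"equilibrium", "escape", "undecided"}` and `evidence` (criterion
#'   and triggering time).
#' @export
classify_outcome <- function(result, escape_factor = 1e3, rel_tol = 1e-5,
                             window_frac = 0.1, eps = 1e-12) {
  s <- if (inherits(result, "sim_result")) result$series else result
  stopifnot(is.data.frame(s), all(c("t", "mu1") %in% names(s)),
            nrow(s) >= 3L)
  nt <- nrow(s)
  dmu <- diff(s$mu1) / diff(s$t)
  above <- which(s$mu1 > escape_factor * s$mu1[1L])
  for (i in above) {
    slope <- dmu[min(i, nt - 1L)]
    if (slope > 0)
      return(structure(list(label = "escape",
                            evidence = list(criterion = sprintf(
                              "mu1 > %g x mu1(0) with dmu1/dt > 0",
                              escape_factor), time = s$t[i])),
                       class = "outcome_label"))
  }
  iw <- which(s$t >= s$t[nt] - window_frac * (s$t[nt] - s$t[1L]))
  iw <- iw[iw < nt]
  if (length(iw) < 2L)
    stop("classify_outcome: trailing window shorter than the series spacing")
  rel <- abs(dmu[iw]) / pmax(s$mu1[iw], eps)
  if (max(rel) < rel_tol)
    return(structure(list(label = "equilibrium",
                          evidence = list(criterion = sprintf(
                            "max |dmu1/dt|/mu1 = %.3g < %g over trailing window",
                            max(rel), rel_tol), time = s$t[iw[1L]])),
                     class = "outcome_label"))
  structure(list(label = "undecided",
                 evidence = list(criterion = sprintf(
                   "trailing max relative slope %.3g >= %g", max(rel),
                   rel_tol), time = s$t[nt])),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("<outcome> %s (%s at t = %.4g)\n", x$label,
              x$evidence$criterion, x$evidence$time))
  invisible(x)
}
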