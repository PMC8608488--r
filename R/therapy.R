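#' Pulsed drug administration schedule
#'
#' The administration protocol: nothing before `t0`, then pulses of
#' constant rate `dose` lasting `pulse_len`, repeated with period
#' `period`. The drug effect decays at rate `decay`. The published
#' reference protocol uses pulse length 1, period 7, decay 0.05 for the
#' reactivation drug and decay 0.0105 for the blockade drug.
#'
#' @param t0 start time of the treatment (>= 0).
#' @param dose administration rate during a pulse (>= 0).
#' @param pulse_len pulse duration (0 < pulse_len <= period).
#' @param period time between pulse starts.
#' @param decay degradation rate of the drug effect (> 0).
#' @return Object of class `dose_schedule`.
#' @export
dose_schedule <- function(t0, dose, pulse_len = 1, period = 7,
                          decay = 0.05) {
  stopifnot(t0 >= 0, dose >= 0, pulse_len > 0, period >= pulse_len,
            decay > 0)
  structure(list(t0 = t0, dose = dose, pulse_len = pulse_len,
                 period = period, decay = decay),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf(
    "<dose_schedule> t0 = %g, dose = %g, pulses %g every %g, decay = %g\n",
    x$t0, x$dose, x$pulse_len, x$period, x$decay))
  invisible(x)
}

#' Administration rate at time t
#'
#' @param t time (>= 0), vectorized.
#' @param sched a [dose_schedule()].
#' @return The rate `kappa(t)`: `dose` inside a pulse, 0 otherwise.
#' @export
dose_rate <- function(t, sched) {
  stopifnot(inherits(sched, "dose_schedule"), all(t >= 0))
  s <- t - sched$t0
  on <- s >= 0 & (s %% sched$period) < sched$pulse_len
  ifelse(on, sched$dose, 0)
}

# Pulse-edge times of the schedule inside (t, t + dt].
pulse_edges <- function(t, dt, sched) {
  lo <- t
  hi <- t + dt
  if (hi <= sched$t0) return(numeric(0))
  k0 <- max(0, floor((lo - sched$t0) / sched$period) - 1)
  k1 <- floor((hi - sched$t0) / sched$period) + 1
  ks <- k0:k1
  ed <- c(sched$t0 + ks * sched$period,
          sched$t0 + ks * sched$period + sched$pulse_len, sched$t0)
  sort(unique(ed[ed > lo & ed < hi]))
}

#' Advance a drug effect one time step
#'
#' Exact exponential-integrator update of `dT/dt = kappa(t) - decay * T`
#' with `kappa` piecewise constant; the step is subdivided at pulse
#' edges so every substep sees a constant administration rate.
#'
#' @param T current drug effect (>= 0).
#' @param t current time.
#' @param dt time step (> 0).
#' @param sched a [dose_schedule()].
#' @return The drug effect at `t + dt`.
#' @export
drug_step <- function(T, t, dt, sched) {
  stopifnot(T >= 0, dt > 0)
  pts <- c(t, pulse_edges(t, dt, sched), t + dt)
  for (i in seq_len(length(pts) - 1L)) {
    len <- pts[i + 1L] - pts[i]
    kap <- dose_rate(pts[i] + len / 2, sched)
    fix <- kap / sched$decay
    T <- fix + (T - fix) * exp(-sched$decay * len)
  }
  T
}
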