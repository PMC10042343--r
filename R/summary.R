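# Run diagnostics derived from a trajectory: collapse time, switching
# counts, virulence duty cycles, deviation from the analytic equilibria.

# trapezoidal time-average of a sampled signal
time_mean <- function(t, x) {
  if (length(t) < 2L) return(x[1])
  dt <- diff(t)
  sum((x[-1] + x[-length(x)]) / 2 * dt) / (t[length(t)] - t[1])
}

# piecewise-constant virulence duty cycle reconstructed from switch events
duty_cycle <- function(t0, t1, init_state, switch_times, switch_states) {
  ts <- c(t0, switch_times, t1)
  vs <- c(init_state, switch_states)
  sum(diff(ts) * vs) / (t1 - t0)
}

#' Summarise a simulated trajectory
#'
#' Computes the run diagnostics: first collapse time (operating energy
#' exhausted), switch counts and virulence duty cycle per relay, the
#' terminal state, and the relative deviation of the late-window
#' time-averaged populations from the analytic equilibrium.
#'
#' @param traj An [integrate_model()] trajectory.
#' @param analytic Equilibrium to compare against: an `lvhpr_equilibrium`
#'   (single-pair models) or a list of three (three-pair model). Computed
#'   from the trajectory's own parameters when `NULL`.
#' @param late_frac Fraction of the simulated time span (from the end)
#'   used as the averaging window (default 0.2).
#' @return An object of class `lvhpr_summary`: a list with
#'   `collapse_time` (`NA` if none), `n_switches` (named integer vector),
#'   `duty_cycle` (named numeric vector, fraction of time at `v = 1`),
#'   `terminal_state`, `equilibrium_deviation` (relative L2 distance) and
#'   `late_window` (the `[from, to]` interval used).
#' @export
summarize_run <- function(traj, analytic = NULL, late_frac = 0.2) {
  stopifnot(inherits(traj, "lvhpr_trajectory"), late_frac > 0, late_frac <= 1)
  st <- traj$states
  ev <- traj$events
  t0 <- st$t[1]; t1 <- st$t[nrow(st)]

  collapse_time <- if (any(ev$kind == "collapse"))
    min(ev$time[ev$kind == "collapse"]) else NA_real_

  relays <- switch(traj$model,
                   one_energy = "E1",
                   two_energy_three_pair = c("E1", "E2"),
                   character(0))
  n_switches <- integer(0); dc <- numeric(0)
  for (r in relays) {
    sw <- ev[ev$kind == "relay_switch" & ev$relay == r, , drop = FALSE]
    n_switches[r] <- nrow(sw)
    init_state <- switch(traj$model,
      one_energy = traj$params$relay$state,
      two_energy_three_pair = if (r == "E1") traj$params$relay_E1$state
                              else traj$params$relay_E2$state)
    dc[r] <- duty_cycle(t0, t1, init_state, sw$time, sw$new_state)
  }

  if (is.null(analytic)) {
    analytic <- switch(traj$model,
      campbell = campbell_equilibrium(traj$params$campbell),
      lvhpr_only = lvhpr_equilibrium(traj$params$pair, traj$params$habitat),
      one_energy = lvhpr_equilibrium(traj$params$pair, traj$params$habitat),
      two_energy_three_pair = three_pair_equilibrium(traj$params$pairs,
                                                     traj$params$habitat))
  }
  eq_vec <- if (inherits(analytic, "lvhpr_equilibrium"))
    c(analytic$X_bar, analytic$Y_bar)
  else unlist(lapply(analytic, function(e) c(e$X_bar, e$Y_bar)))
  pop_cols <- switch(traj$model,
    two_energy_three_pair = c("X1", "Y1", "X2", "Y2", "X3", "Y3"),
    c("X1", "Y1"))

  from <- t1 - late_frac * (t1 - t0)
  w <- st$t >= from
  late_means <- vapply(pop_cols, function(cn) time_mean(st$t[w], st[[cn]][w]),
                       numeric(1))
  equilibrium_deviation <- sqrt(sum((late_means - eq_vec)^2)) /
    sqrt(sum(eq_vec^2))

  structure(list(collapse_time = collapse_time,
                 n_switches = n_switches,
                 duty_cycle = dc,
                 terminal_state = st[nrow(st), , drop = FALSE],
                 late_means = late_means,
                 equilibrium_deviation = equilibrium_deviation,
                 late_window = c(from = from, to = t1)),
            class = "lvhpr_summary")
}

#' @export
print.lvhpr_summary <- function(x, ...) {
  cat("<lvhpr_summary>\n")
  cat(sprintf("  collapse_time: %s\n",
              if (is.na(x$collapse_time)) "none" else format(x$collapse_time)))
  if (length(x$n_switches))
    cat("  switches:", paste(sprintf("%s = %d", names(x$n_switches),
                                     x$n_switches), collapse = ", "), "\n")
  if (length(x$duty_cycle))
    cat("  duty cycles:", paste(sprintf("%s = %.4f", names(x$duty_cycle),
                                        x$duty_cycle), collapse = ", "), "\n")
  cat(sprintf("  equilibrium deviation (late window): %.3g\n",
              x$equilibrium_deviation))
  invisible(x)
}
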