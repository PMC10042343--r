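# Hybrid integration engine: continuous ODE evolution (deSolve, lsodar)
# punctuated by relay-switching events located by root-finding. Each root
# stops the integration, the discrete state (relay, clamp, extinction) is
# updated, and integration restarts from the event time, so no switch can
# be stepped over silently.

#' Integrator configuration
#'
#' @param t_end Integration horizon (time units, `> 0`).
#' @param rel_tol,abs_tol Relative/absolute integration tolerances.
#' @param max_step Maximum internal step size (`NULL` = solver default).
#' @param extinction_eps Population floor: a population component crossing
#'   this value downwards is clamped to exactly 0 with an extinction
#'   event. `0` (default) disables the floor; in these models populations
#'   cannot cross zero, they only decay towards it.
#' @param clamp_energy Floor energies at 0 in the stored trajectory.
#' @param sample_dt Output sampling interval (time units).
#' @param max_events Safety cap on discrete events before aborting.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(t_end, rel_tol = 1e-8, abs_tol = 1e-10,
                              max_step = NULL, extinction_eps = 0,
                              clamp_energy = TRUE, sample_dt = 1,
                              max_events = 1e6) {
  stopifnot(t_end > 0, rel_tol > 0, abs_tol > 0, extinction_eps >= 0,
            sample_dt > 0, is.null(max_step) || max_step > 0)
  structure(list(t_end = t_end, rel_tol = rel_tol, abs_tol = abs_tol,
                 max_step = max_step, extinction_eps = extinction_eps,
                 clamp_energy = isTRUE(clamp_energy), sample_dt = sample_dt,
                 max_events = max_events),
            class = "integrator_config")
}

empty_events <- function() {
  data.frame(time = numeric(0), kind = character(0), relay = character(0),
             new_state = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

add_event <- function(events, time, kind, relay = NA_character_,
                      new_state = NA_integer_, detail = "") {
  rbind(events, data.frame(time = time, kind = kind, relay = relay,
                           new_state = new_state, detail = detail,
                           stringsAsFactors = FALSE))
}

# Virulence value at time t for one relay, honouring an ongoing
# smooth-step transition (smooth_dt > 0) or the plain discrete state.
v_at <- function(t, state, trans, smooth_dt) {
  if (smooth_dt > 0 && !is.null(trans)) {
    if (t < trans$t_on + smooth_dt) {
      s <- (t - trans$t_on) / smooth_dt
      s <- min(max(s, 0), 1)
      return(trans$v_from + (trans$v_to - trans$v_from) * (3 * s^2 - 2 * s^3))
    }
  }
  as.numeric(state)
}

#' Simulate a model as a hybrid (event-driven) dynamical system
#'
#' Integrates one of the four model variants with adaptive error control,
#' detecting every energy-threshold crossing by root-finding: at a
#' crossing the integration stops, the virulence relay updates, and
#' integration restarts from the event time. Operating energy reaching 0
#' is a collapse: the host-nested unit disintegrates and the run stops
#' there. Stored energy (E2) reaching 0 is clamped: the E2-to-E1
#' transformation is suppressed until the store recharges.
#'
#' @param model One of `"campbell"`, `"lvhpr_only"`, `"one_energy"`,
#'   `"two_energy_three_pair"`.
#' @param params A named list of parameter objects:
#'   * `campbell`: `list(campbell = campbell_params(...))`
#'   * `lvhpr_only`: `list(pair =, habitat =, v = 1)` (`v` optional,
#'     constant virulence)
#'   * `one_energy`: `list(pair =, habitat =, energy = energy1_params(...),
#'     relay = virulence_relay(...))`
#'   * `two_energy_three_pair`: `list(pairs = list(p1, p2, p3), habitat =,
#'     energy = energy2_params(...), relay_E1 =, relay_E2 =)`
#' @param init Named numeric initial state: `c(X1 =, Y1 =)` plus, per
#'   variant, `X2, Y2, X3, Y3`, `E1`, `E2`.
#' @param cfg An [integrator_config()].
#' @param smooth_dt Smooth-step transition duration: `0` (default) keeps
#'   the discontinuous relay; `> 0` replaces each switch by a C1 ramp of
#'   this duration starting at the detected crossing time.
#' @return An object of class `lvhpr_trajectory`: a list with `states`
#'   (data frame: `t`, populations, energies, virulences, `gamma_t` where
#'   applicable), `events` (data frame: `time`, `kind`, `relay`,
#'   `new_state`, `detail`), and the inputs.
#' @seealso [summarize_run()], [run_scenario()]
#' @export
#' @examples
#' pair <- pair_params(1, 1, 1, 1)
#' hab <- habitat_params(H = 4, kappa = 2, sigma = 1, q = 2)
#' eq <- lvhpr_equilibrium(pair, hab)
#' traj <- integrate_model("lvhpr_only", list(pair = pair, habitat = hab),
#'                         init = c(X1 = eq$X_bar, Y1 = eq$Y_bar),
#'                         cfg = integrator_config(t_end = 10))
#' tail(traj$states, 2)  # stays at the fixed point
integrate_model <- function(model, params, init, cfg, smooth_dt = 0) {
  model <- match.arg(model, c("campbell", "lvhpr_only", "one_energy",
                              "two_energy_three_pair"))
  stopifnot(inherits(cfg, "integrator_config"), smooth_dt >= 0)

  hab <- params$habitat
  state_names <- switch(model,
    campbell = c("X1", "Y1"),
    lvhpr_only = c("X1", "Y1"),
    one_energy = c("X1", "Y1", "E1"),
    two_energy_three_pair = c("X1", "Y1", "X2", "Y2", "X3", "Y3", "E1", "E2"))
  if (!all(state_names %in% names(init)))
    stop("init must provide components: ", paste(state_names, collapse = ", "),
         call. = FALSE)
  y <- unname(init[state_names])
  if (any(!is.finite(y)) || any(y[grep("^[XY]", state_names)] < 0))
    stop("initial state must be finite with nonnegative populations",
         call. = FALSE)

  # --- variant-specific closures -------------------------------------
  pop_idx <- grep("^[XY]", state_names)
  e1_idx <- match("E1", state_names)
  e2_idx <- match("E2", state_names)

  relay1 <- relay2 <- NULL
  if (model == "one_energy") {
    stopifnot(inherits(params$pair, "pair_params"),
              inherits(hab, "habitat_params"),
              inherits(params$energy, "energy1_params"),
              inherits(params$relay, "virulence_relay"))
    relay1 <- params$relay
  } else if (model == "two_energy_three_pair") {
    stopifnot(length(params$pairs) == 3L,
              inherits(hab, "habitat_params"),
              inherits(params$energy, "energy2_params"),
              inherits(params$relay_E1, "virulence_relay"),
              inherits(params$relay_E2, "virulence_relay"))
    relay1 <- params$relay_E1
    relay2 <- params$relay_E2
  } else if (model == "lvhpr_only") {
    stopifnot(inherits(params$pair, "pair_params"),
              inherits(hab, "habitat_params"))
  } else {
    stopifnot(inherits(params$campbell, "campbell_params"))
  }
  v_const <- if (model == "lvhpr_only") {
    v0 <- if (is.null(params$v)) 1 else params$v
    stopifnot(v0 >= 0, v0 <= 1)
    v0
  } else NA_real_

  trans1 <- trans2 <- NULL     # ongoing smooth transitions
  e2_armed <- TRUE             # E2 zero-crossing root armed?

  deriv <- local({
    switch(model,
      campbell = {
        p <- params$campbell
        function(t, y, v1, v2) {
          X <- y[1]; Y <- y[2]
          list(c(X * (p$a1 * (1 - X / p$L) - p$a2 * Y),
                 Y * (-p$b1 + p$b2 * X)))
        }
      },
      lvhpr_only = {
        p <- params$pair
        asH <- p$a0 * hab$sigma / hab$H; bsH <- p$b0 * hab$sigma / hab$H
        kH <- hab$kappa * hab$H; q <- hab$q
        function(t, y, v1, v2) {
          X <- y[1]; Y <- y[2]
          list(v_const * c(X * (p$a1 * (1 - (X + Y / q) / kH) - asH * Y),
                           Y * (-p$b1 + bsH * X)))
        }
      },
      one_energy = {
        p <- params$pair; en <- params$energy
        asH <- p$a0 * hab$sigma / hab$H; bsH <- p$b0 * hab$sigma / hab$H
        kH <- hab$kappa * hab$H; q <- hab$q; aH <- en$alpha * hab$H
        function(t, y, v1, v2) {
          X <- y[1]; Y <- y[2]
          g <- if (t > en$t0_degen) en$gamma * exp(-en$d * (t - en$t0_degen)) else en$gamma
          list(c(v1 * X * (p$a1 * (1 - (X + Y / q) / kH) - asH * Y),
                 v1 * Y * (-p$b1 + bsH * X),
                 -aH - en$beta * v1 * X + g * v1 * Y))
        }
      },
      two_energy_three_pair = {
        ps <- params$pairs; en <- params$energy
        a1v <- vapply(ps, `[[`, numeric(1), "a1")
        a0v <- vapply(ps, `[[`, numeric(1), "a0") * hab$sigma / hab$H
        b1v <- vapply(ps, `[[`, numeric(1), "b1")
        b0v <- vapply(ps, `[[`, numeric(1), "b0") * hab$sigma / hab$H
        kH <- hab$kappa * hab$H; q <- hab$q; a1H <- en$alpha1 * hab$H
        function(t, y, v1, v2) {
          X <- y[c(1, 3, 5)]; Y <- y[c(2, 4, 6)]
          E2 <- y[8]
          vv <- c(v1, v2, v2)
          load <- (sum(X) + sum(Y) / q) / kH
          dX <- vv * X * (a1v * (1 - load) - a0v * Y)
          dY <- vv * Y * (-b1v + b0v * X)
          g1 <- if (E2 <= 0) 0 else en$gamma1
          dE1 <- -a1H + (g1 / en$theta) * v1 * Y[1] +
            en$gamma2 * v2 * Y[2] - en$gamma3 * v2 * Y[3]
          dE2 <- -en$alpha2 * E2 + en$e2_gain_sign * g1 * v1 * Y[1] +
            en$gamma3 * en$theta * v2 * Y[3]
          list(c(dX[1], dY[1], dX[2], dY[2], dX[3], dY[3], dE1, dE2))
        }
      })
  })

  # --- main loop ------------------------------------------------------
  t_end <- cfg$t_end
  sample_times <- unique(c(seq(0, t_end, by = cfg$sample_dt), t_end))
  events <- empty_events()
  rows <- list(); nrows <- 0L
  push_rows <- function(mat) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- mat
  }
  t_cur <- 0
  terminal <- FALSE
  n_events <- 0L

  gamma_at <- if (model == "one_energy") {
    en <- params$energy
    function(t) gamma_decay(en$gamma, en$d, t, en$t0_degen)
  } else NULL

  repeat {
    v1s <- if (!is.null(relay1)) relay1$state else NA_integer_
    v2s <- if (!is.null(relay2)) relay2$state else NA_integer_

    # root functions for this segment: active relay thresholds, energy
    # floors, optional extinction floors
    root_labels <- character(0)
    thr1 <- thr2 <- NA_real_
    if (!is.null(relay1)) {
      thr1 <- if (v1s == 1L) relay1$E_upper else relay1$E_lower
      root_labels <- c(root_labels, "relay1")
    }
    if (!is.null(relay2)) {
      thr2 <- if (v2s == 1L) relay2$E_upper else relay2$E_lower
      root_labels <- c(root_labels, "relay2")
    }
    if (!is.na(e1_idx)) root_labels <- c(root_labels, "collapse")
    if (!is.na(e2_idx) && e2_armed) root_labels <- c(root_labels, "e2_zero")
    ext_idx <- integer(0)
    if (cfg$extinction_eps > 0) {
      ext_idx <- pop_idx[y[pop_idx] > cfg$extinction_eps]
      root_labels <- c(root_labels, paste0("ext_", state_names[ext_idx]))
    }

    l_trans1 <- trans1; l_trans2 <- trans2
    func <- function(t, y, parms) {
      deriv(t, y,
            if (is.na(v1s)) NA_real_ else v_at(t, v1s, l_trans1, smooth_dt),
            if (is.na(v2s)) NA_real_ else v_at(t, v2s, l_trans2, smooth_dt))
    }
    rootfunc <- if (length(root_labels)) {
      function(t, y, parms) {
        g <- numeric(0)
        if (!is.null(relay1)) g <- c(g, y[e1_or_e(model, e1_idx)] - thr1)
        if (!is.null(relay2)) g <- c(g, y[e2_idx] - thr2)
        if (!is.na(e1_idx)) g <- c(g, y[e1_idx])
        if (!is.na(e2_idx) && e2_armed) g <- c(g, y[e2_idx])
        if (length(ext_idx)) g <- c(g, y[ext_idx] - cfg$extinction_eps)
        g
      }
    } else NULL

    tt <- sample_times[sample_times > t_cur]
    tt <- c(t_cur, tt)
    if (length(tt) < 2L) break

    args <- list(y = y, times = tt, func = func, parms = NULL,
                 method = if (is.null(rootfunc)) "lsoda" else "lsodar",
                 rtol = cfg$rel_tol, atol = cfg$abs_tol)
    if (!is.null(rootfunc)) args$rootfunc <- rootfunc
    if (!is.null(cfg$max_step)) args$hmax <- cfg$max_step
    out <- suppressWarnings(do.call(deSolve::ode, args))
    istate <- attr(out, "istate")[1]
    if (istate < 0)
      stop(sprintf("integration failed (istate = %d) at t = %g", istate, t_cur),
           call. = FALSE)

    mat <- unclass(out)
    # decorate with virulence / gamma columns for storage
    extra <- NULL
    if (model == "one_energy") {
      vcol <- vapply(mat[, 1], v_at, numeric(1), state = v1s,
                     trans = l_trans1, smooth_dt = smooth_dt)
      extra <- cbind(vE1 = vcol, gamma_t = gamma_at(mat[, 1]))
    } else if (model == "two_energy_three_pair") {
      extra <- cbind(
        vE1 = vapply(mat[, 1], v_at, numeric(1), state = v1s,
                     trans = l_trans1, smooth_dt = smooth_dt),
        vE2 = vapply(mat[, 1], v_at, numeric(1), state = v2s,
                     trans = l_trans2, smooth_dt = smooth_dt))
    }
    seg <- if (!is.null(extra)) cbind(mat, extra) else mat
    push_rows(if (t_cur == 0) seg else seg[-1, , drop = FALSE])

    troot <- attr(out, "troot")
    y <- unname(mat[nrow(mat), -1])
    if (any(!is.finite(y)))
      stop(sprintf("non-finite state at t = %g; aborting", mat[nrow(mat), 1]),
           call. = FALSE)

    if (istate != 3 || is.null(troot) || !length(troot)) break  # reached t_end
    t_cur <- troot[1]
    iroot <- which(attr(out, "iroot") != 0)
    if (!length(iroot))
      stop("event detection failure: root reported without indicator",
           call. = FALSE)
    fired <- root_labels[iroot]

    n_events <- n_events + length(fired)
    if (n_events > cfg$max_events)
      stop("event cap exceeded; the scenario switches faster than max_events allows",
           call. = FALSE)

    # deterministic processing order: E1 relay, E2 relay, collapse,
    # E2 clamp, extinctions
    n_state_cols <- length(state_names)
    vcol1 <- 1L + n_state_cols + 1L   # vE1 column in the stored matrix
    vcol2 <- vcol1 + 1L               # vE2 column (three-pair model)
    last_row <- nrow(rows[[nrows]])
    for (lab in c("relay1", "relay2", "collapse", "e2_zero",
                  fired[startsWith(fired, "ext_")])) {
      if (!lab %in% fired) next
      if (lab == "relay1") {
        vprev <- v_at(t_cur, relay1$state, trans1, smooth_dt)
        relay1 <- relay_update(relay1, thr1)
        # snap the energy onto the threshold so a replay of the stored
        # trace through relay_update reproduces the switch exactly
        y[e1_idx] <- thr1
        rows[[nrows]][last_row, e1_idx + 1L] <- thr1
        if (model %in% c("one_energy", "two_energy_three_pair") &&
            smooth_dt == 0)
          rows[[nrows]][last_row, vcol1] <- relay1$state
        events <- add_event(events, t_cur, "relay_switch", "E1",
                            relay1$state,
                            sprintf("E crossed %g", thr1))
        if (smooth_dt > 0)
          trans1 <- list(t_on = t_cur, v_from = vprev,
                         v_to = as.numeric(relay1$state))
      } else if (lab == "relay2") {
        vprev <- v_at(t_cur, relay2$state, trans2, smooth_dt)
        relay2 <- relay_update(relay2, thr2)
        y[e2_idx] <- thr2
        rows[[nrows]][last_row, e2_idx + 1L] <- thr2
        if (smooth_dt == 0)
          rows[[nrows]][last_row, vcol2] <- relay2$state
        events <- add_event(events, t_cur, "relay_switch", "E2",
                            relay2$state,
                            sprintf("E crossed %g", thr2))
        if (smooth_dt > 0)
          trans2 <- list(t_on = t_cur, v_from = vprev,
                         v_to = as.numeric(relay2$state))
      } else if (lab == "collapse") {
        y[e1_idx] <- 0
        rows[[nrows]][last_row, e1_idx + 1L] <- 0
        events <- add_event(events, t_cur, "collapse",
                            detail = "operating energy exhausted; unit disintegrates")
        terminal <- TRUE
      } else if (lab == "e2_zero") {
        y[e2_idx] <- 0
        rows[[nrows]][last_row, e2_idx + 1L] <- 0
        e2_armed <- FALSE
        events <- add_event(events, t_cur, "clamp", relay = "E2",
                            detail = "stored energy exhausted; E2->E1 transformation suppressed")
      } else if (startsWith(lab, "ext_")) {
        comp <- sub("^ext_", "", lab)
        ci <- match(comp, state_names)
        y[ci] <- 0
        # patch the stored row so no sub-floor population is kept
        rows[[nrows]][nrow(rows[[nrows]]), ci + 1L] <- 0
        events <- add_event(events, t_cur, "extinction", detail = comp)
      }
    }
    if (!e2_armed && y[e2_idx] > 10 * cfg$abs_tol + 1e-12) e2_armed <- TRUE
    if (terminal || t_cur >= t_end) break
  }

  states <- as.data.frame(do.call(rbind, rows[seq_len(nrows)]))
  cn <- c("t", state_names)
  if (model == "one_energy") cn <- c(cn, "vE1", "gamma_t")
  if (model == "two_energy_three_pair") cn <- c(cn, "vE1", "vE2")
  names(states) <- cn
  states <- states[!duplicated(states$t), , drop = FALSE]
  rownames(states) <- NULL
  # floor tiny negative numerical excursions
  for (nm in state_names) {
    neg <- states[[nm]] < 0
    if (any(neg)) states[[nm]][neg] <- 0
  }

  structure(list(model = model, params = params, init = init, cfg = cfg,
                 smooth_dt = smooth_dt, states = states, events = events),
            class = "lvhpr_trajectory")
}

# E index helper: relay1 listens on E1 in both energy-bearing models
e1_or_e <- function(model, e1_idx) e1_idx

#' @export
print.lvhpr_trajectory <- function(x, ...) {
  cat(sprintf("<lvhpr_trajectory> model = %s, %d samples over t in [%g, %g], %d events\n",
              x$model, nrow(x$states), min(x$states$t), max(x$states$t),
              nrow(x$events)))
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat("  events:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
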