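# Energy-dependent virulence: the two-threshold hysteresis relay and the
# smooth-step temporal interpolation.

#' Two-threshold virulence relay with hysteresis
#'
#' Virulence is a binary switch driven by an energy level through two
#' thresholds: when energy drops to `E_lower` the parasite pair becomes
#' maximally virulent (`v = 1`) and stays virulent until energy recovers to
#' `E_upper`, where it is tamed again (`v = 0`). Inside the band the relay
#' remembers its previous state (relay hysteresis).
#'
#' The initial state defaults to the energy-consistent value: `v = 1` if
#' `E0 <= E_lower`, `v = 0` if `E0 >= E_upper`, and `v = 0` inside the band
#' (the host starts untroubled).
#'
#' @param E_lower,E_upper Energy thresholds, `0 < E_lower < E_upper`.
#' @param state Initial binary state (0 or 1); overrides `E0` if given.
#' @param E0 Initial energy used to derive the default state.
#' @return An object of class `virulence_relay` with fields `E_lower`,
#'   `E_upper`, `state`.
#' @seealso [relay_update()], [relay_replay()], [smoothstep()]
#' @export
#' @examples
#' r <- virulence_relay(1, 2, E0 = 1.5)
#' r$state                        # 0: starts untroubled inside the band
#' relay_update(r, 0.5)$state     # 1: energy hit the lower threshold
virulence_relay <- function(E_lower, E_upper, state = NULL, E0 = NULL) {
  stopifnot(is.numeric(E_lower), is.numeric(E_upper),
            length(E_lower) == 1L, length(E_upper) == 1L)
  if (!(E_lower > 0 && E_upper > E_lower))
    stop("thresholds must satisfy 0 < E_lower < E_upper", call. = FALSE)
  if (is.null(state)) {
    state <- if (is.null(E0)) 0L
    else if (E0 <= E_lower) 1L
    else 0L
  }
  if (!state %in% c(0L, 1L)) stop("relay state must be 0 or 1", call. = FALSE)
  structure(list(E_lower = E_lower, E_upper = E_upper, state = as.integer(state)),
            class = "virulence_relay")
}

#' Update a virulence relay from the current energy level
#'
#' Implements the hysteresis rule: `v = 1` if `E <= E_lower`; `v = 0` if
#' `E >= E_upper`; otherwise the previous state is retained. Energies
#' landing exactly on a threshold are treated as having reached it.
#'
#' @param relay A [virulence_relay()].
#' @param E Current energy level (`>= 0`).
#' @return The relay with its `state` field updated.
#' @export
relay_update <- function(relay, E) {
  stopifnot(inherits(relay, "virulence_relay"))
  if (E <= relay$E_lower) relay$state <- 1L
  else if (E >= relay$E_upper) relay$state <- 0L
  relay
}

#' Replay an energy trace through a relay
#'
#' Processes a whole energy trajectory sequentially, returning the
#' virulence state after each sample. Deterministic: the output depends
#' only on the trace and the initial relay state, so a stored trajectory
#' can be validated by replay.
#'
#' @param relay A [virulence_relay()] holding the initial state.
#' @param E_trace Numeric vector of energy samples in time order.
#' @return Integer vector of states, one per sample.
#' @export
relay_replay <- function(relay, E_trace) {
  stopifnot(inherits(relay, "virulence_relay"), is.numeric(E_trace))
  out <- integer(length(E_trace))
  s <- relay$state
  lo <- relay$E_lower
  hi <- relay$E_upper
  for (i in seq_along(E_trace)) {
    e <- E_trace[i]
    if (e <= lo) s <- 1L else if (e >= hi) s <- 0L
    out[i] <- s
  }
  out
}

#' Smooth-step virulence interpolation
#'
#' A C1 polynomial ramp replacing the relay's discontinuous jump: for a
#' rising transition starting at `t0` with duration `delta_t`,
#' \deqn{v(t) = 3s^2 - 2s^3, \quad s = (t - t_0)/\Delta t,}
#' clamped to 0 before `t0` and 1 after `t0 + delta_t`. The falling
#' direction is its mirror image (1 minus the rising value). The ramp is
#' continuous with zero slope at both junctions, and converges pointwise to
#' the instantaneous step as `delta_t` shrinks to zero.
#'
#' @param t Time (vectorised).
#' @param t0 Transition onset time.
#' @param delta_t Transition duration (`> 0`).
#' @param direction `"rising"` (0 to 1) or `"falling"` (1 to 0).
#' @return Virulence value(s) in `[0, 1]`.
#' @export
#' @examples
#' smoothstep(c(0, 0.5, 1), t0 = 0, delta_t = 1)   # 0, 0.5, 1
smoothstep <- function(t, t0, delta_t, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(delta_t), length(delta_t) == 1L, delta_t > 0)
  s <- pmin(pmax((t - t0) / delta_t, 0), 1)
  v <- 3 * s^2 - 2 * s^3
  if (direction == "falling") v <- 1 - v
  v
}
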