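# Right-hand sides of every ODE system: the logistic host-phage model,
# the single-pair host-nested model, the one-energy budget with
# hyperparasite degeneration, and the two-energy three-pair system.

#' Right-hand side of the logistic host--phage model
#'
#' @param state Named numeric vector `c(X =, Y =)`, both `>= 0`.
#' @param p A [campbell_params()] object.
#' @return Numeric vector `c(dX =, dY =)`.
#' @export
#' @examples
#' rhs_campbell(c(X = 1, Y = 1), campbell_params(1, 1, 1, 1, 2))
rhs_campbell <- function(state, p) {
  stopifnot(inherits(p, "campbell_params"))
  X <- state[["X"]]; Y <- state[["Y"]]
  c(dX = X * (p$a1 * (1 - X / p$L) - p$a2 * Y),
    dY = Y * (-p$b1 + p$b2 * X))
}

#' Right-hand side of the single-pair host-nested model
#'
#' The Lotka-Volterra pair with habitat restriction shared between
#' parasite and hyperparasite (each hyperparasite occupies `1/q` of a
#' parasite's share) and encounter-scaled infection rates, the whole
#' dynamics gated by virulence `v`:
#' \deqn{\dot X = v X\left(a_1\left(1 - \frac{X + Y/q}{\kappa H}\right) -
#'   \frac{a_0\sigma}{H} Y\right), \qquad
#'   \dot Y = v Y\left(-b_1 + \frac{b_0\sigma}{H} X\right).}
#' With `v = 0` the pair is dormant: both derivatives are exactly zero.
#'
#' @param state Named numeric vector `c(X =, Y =)`.
#' @param pair A [pair_params()] object.
#' @param hab A [habitat_params()] object.
#' @param v Virulence in `[0, 1]`.
#' @return Numeric vector `c(dX =, dY =)`.
#' @export
rhs_lvhpr <- function(state, pair, hab, v = 1) {
  stopifnot(inherits(pair, "pair_params"), inherits(hab, "habitat_params"),
            v >= 0, v <= 1)
  X <- state[["X"]]; Y <- state[["Y"]]
  c(dX = v * X * (pair$a1 * (1 - (X + Y / hab$q) / (hab$kappa * hab$H)) -
                    (pair$a0 * hab$sigma / hab$H) * Y),
    dY = v * Y * (-pair$b1 + (pair$b0 * hab$sigma / hab$H) * X))
}

#' Degenerating catalytic production rate
#'
#' After onset `t0` the hyperparasite's catalytic energy production rate
#' decays exponentially, `d(gamma)/dt = -d * gamma`, so
#' `gamma(t) = gamma0 * exp(-d (t - t0))` for `t > t0` and `gamma0`
#' before. One half of the catalytic power is lost per half-time
#' `ln(2)/d`.
#'
#' @param gamma0 Initial catalytic rate.
#' @param d Decay (degeneration) rate, `>= 0`.
#' @param t Time (vectorised).
#' @param t0 Degeneration onset time.
#' @return `gamma(t)`.
#' @export
#' @examples
#' gamma_decay(1, d = 0.1, t = log(2) / 0.1, t0 = 0)  # 0.5
gamma_decay <- function(gamma0, d, t, t0) {
  stopifnot(d >= 0)
  ifelse(t <= t0, gamma0, gamma0 * exp(-d * (t - t0)))
}

#' Energy balance of the one-energy model
#'
#' `dE/dt = -alpha*H - beta*v*X + gamma_t*v*Y`: the host system drains
#' energy permanently, the virulent parasite consumes it, the virulent
#' hyperparasite catalyses new energy at the (possibly degenerated)
#' rate `gamma_t`.
#'
#' @param state Named numeric vector with components `X` and `Y`.
#' @param p An [energy1_params()] object.
#' @param hab A [habitat_params()] object.
#' @param v Virulence in `[0, 1]`.
#' @param gamma_t Current catalytic rate; defaults to
#'   [gamma_decay()] evaluated from `p` at time `t`.
#' @param t Time, used only for the default `gamma_t`.
#' @return `dE/dt` (scalar).
#' @export
rhs_energy1 <- function(state, p, hab, v, gamma_t = NULL, t = 0) {
  stopifnot(inherits(p, "energy1_params"), inherits(hab, "habitat_params"))
  if (is.null(gamma_t)) gamma_t <- gamma_decay(p$gamma, p$d, t, p$t0_degen)
  -p$alpha * hab$H - p$beta * v * state[["X"]] + gamma_t * v * state[["Y"]]
}

#' Right-hand side of the three-pair population system
#'
#' Each pair follows the host-nested form with its own rate constants,
#' but the logistic crowding term uses the total habitat load over all
#' three pairs, `sum(X_i) + (1/q) sum(Y_i)`. Pair 1 is gated by the
#' E1-driven virulence `vE1`, pairs 2 and 3 by the E2-driven `vE2`.
#'
#' @param state Named numeric vector `c(X1,Y1,X2,Y2,X3,Y3)`.
#' @param pairs List of three [pair_params()] objects.
#' @param hab A [habitat_params()] object.
#' @param vE1,vE2 Virulences in `[0, 1]`.
#' @return Named numeric vector of the six derivatives.
#' @export
rhs_three_pair <- function(state, pairs, hab, vE1, vE2) {
  stopifnot(length(pairs) == 3L, inherits(hab, "habitat_params"))
  X <- c(state[["X1"]], state[["X2"]], state[["X3"]])
  Y <- c(state[["Y1"]], state[["Y2"]], state[["Y3"]])
  load <- (sum(X) + sum(Y) / hab$q) / (hab$kappa * hab$H)
  v <- c(vE1, vE2, vE2)
  dX <- dY <- numeric(3)
  for (k in 1:3) {
    pk <- pairs[[k]]
    dX[k] <- v[k] * X[k] * (pk$a1 * (1 - load) - (pk$a0 * hab$sigma / hab$H) * Y[k])
    dY[k] <- v[k] * Y[k] * (-pk$b1 + (pk$b0 * hab$sigma / hab$H) * X[k])
  }
  c(dX1 = dX[1], dY1 = dY[1], dX2 = dX[2], dY2 = dY[2], dX3 = dX[3], dY3 = dY[3])
}

#' Energy balances of the two-energy model
#'
#' \deqn{\dot E_1 = -\alpha_1 H + \gamma_1\theta^{-1} v_{E1} Y_1 +
#'   \gamma_2 v_{E2} Y_2 - \gamma_3 v_{E2} Y_3}
#' \deqn{\dot E_2 = -\alpha_2 E_2 \pm \gamma_1 v_{E1} Y_1 +
#'   \gamma_3\theta\, v_{E2} Y_3}
#' Pair 1 transforms stored energy E2 into operating energy E1 (so by
#' default its term drains E2: sign `-`, see [energy2_params()]), pair 2
#' catalyses fresh E1, pair 3 converts E1 back into E2 at ratio `theta`.
#'
#' When `E2 <= 0` the E2-to-E1 transformation terms are suppressed
#' (`gamma1` contributes nothing to either balance): an empty store
#' cannot be transformed, and energy must not be created from it.
#'
#' @param state Named numeric vector with components `Y1`, `Y3` (and `E2`;
#'   `Y2` is used for the E1 balance).
#' @param p An [energy2_params()] object.
#' @param hab A [habitat_params()] object.
#' @param vE1,vE2 Virulences in `[0, 1]`.
#' @return Numeric vector `c(dE1 =, dE2 =)`.
#' @export
rhs_energy2 <- function(state, p, hab, vE1, vE2) {
  stopifnot(inherits(p, "energy2_params"), inherits(hab, "habitat_params"))
  Y1 <- state[["Y1"]]; Y2 <- state[["Y2"]]; Y3 <- state[["Y3"]]
  E2 <- state[["E2"]]
  g1 <- if (E2 <= 0) 0 else p$gamma1
  dE1 <- -p$alpha1 * hab$H + (g1 / p$theta) * vE1 * Y1 +
    p$gamma2 * vE2 * Y2 - p$gamma3 * vE2 * Y3
  dE2 <- -p$alpha2 * E2 + p$e2_gain_sign * g1 * vE1 * Y1 +
    p$gamma3 * p$theta * vE2 * Y3
  c(dE1 = dE1, dE2 = dE2)
}
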