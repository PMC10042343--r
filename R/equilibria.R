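# Closed-form equilibria: analytic oracles for the dynamic models.

new_equilibrium <- function(X_bar, Y_bar, feasible = TRUE) {
  structure(list(X_bar = X_bar, Y_bar = Y_bar, feasible = feasible),
            class = "lvhpr_equilibrium")
}

#' @export
print.lvhpr_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium: X_bar = %g, Y_bar = %g%s\n", x$X_bar, x$Y_bar,
              if (!x$feasible) "  [coexistence infeasible: boundary equilibrium]" else ""))
  invisible(x)
}

#' Equilibrium of the logistic host--phage model
#'
#' The coexistence fixed point of the Campbell equations:
#' \deqn{\bar X = b_1/b_2, \qquad \bar Y = (a_1/a_2)(1 - b_1/(b_2 L)).}
#' `Y_bar` is positive only when the habitat ceiling exceeds the phage's
#' break-even host density (`b1 < b2*L`); otherwise the phage goes extinct
#' and the boundary equilibrium `(L, 0)` is returned with `feasible = FALSE`.
#'
#' @param p A [campbell_params()] object.
#' @return An `lvhpr_equilibrium` with fields `X_bar`, `Y_bar`, `feasible`.
#' @export
#' @examples
#' campbell_equilibrium(campbell_params(2, 0.5, 1, 2, 4))  # X = 0.5, Y = 3.5
campbell_equilibrium <- function(p) {
  stopifnot(inherits(p, "campbell_params"))
  X_bar <- p$b1 / p$b2
  Y_bar <- (p$a1 / p$a2) * (1 - p$b1 / (p$b2 * p$L))
  if (Y_bar < 0) new_equilibrium(p$L, 0, feasible = FALSE)
  else new_equilibrium(X_bar, Y_bar)
}

#' Effective mass-action rates of the host-nested model
#'
#' Encounters between a parasite and its hyperparasite happen with
#' probability `sigma*X*Y/H` per unit time, which turns the encounter
#' constants into effective mass-action coefficients
#' `a2_eff = a0*sigma/H` and `b2_eff = b0*sigma/H`: infection pressure
#' dilutes as the shared host habitat grows.
#'
#' @param pair A [pair_params()] object.
#' @param hab A [habitat_params()] object.
#' @return Named numeric vector `c(a2_eff =, b2_eff =)`.
#' @export
lvhpr_effective_rates <- function(pair, hab) {
  stopifnot(inherits(pair, "pair_params"), inherits(hab, "habitat_params"))
  c(a2_eff = pair$a0 * hab$sigma / hab$H,
    b2_eff = pair$b0 * hab$sigma / hab$H)
}

#' Coexistence equilibrium of the host-nested (LVhpr) model
#'
#' The fixed point of the single-pair host-nested equations with full
#' virulence:
#' \deqn{\bar X = \frac{b_1}{b_0\sigma} H, \qquad
#'   \bar Y = \frac{a_1 (b_0\sigma - b_1/\kappa)\, q}{(q a_0 \sigma +
#'   a_1/\kappa)\, b_0 \sigma} H.}
#' Both are proportional to the host population `H`: parasite and
#' hyperparasite loads are synchronised with their common host.
#'
#' Coexistence requires `b0*sigma*kappa > b1` (the habitat must support
#' enough parasites to feed the hyperparasite). When it fails the
#' hyperparasite goes extinct; the logistic boundary equilibrium
#' `(kappa*H, 0)` is returned with `feasible = FALSE` rather than a
#' negative population.
#'
#' @inheritParams lvhpr_effective_rates
#' @return An `lvhpr_equilibrium` with fields `X_bar`, `Y_bar`, `feasible`.
#' @export
#' @examples
#' lvhpr_equilibrium(pair_params(1, 1, 1, 1),
#'                   habitat_params(H = 4, kappa = 2, sigma = 1, q = 2))
lvhpr_equilibrium <- function(pair, hab) {
  stopifnot(inherits(pair, "pair_params"), inherits(hab, "habitat_params"))
  bs <- pair$b0 * hab$sigma
  if (bs * hab$kappa <= pair$b1) {
    return(new_equilibrium(hab$kappa * hab$H, 0, feasible = FALSE))
  }
  X_bar <- (pair$b1 / bs) * hab$H
  Y_bar <- (pair$a1 * (bs - pair$b1 / hab$kappa) * hab$q /
              ((hab$q * pair$a0 * hab$sigma + pair$a1 / hab$kappa) * bs)) * hab$H
  new_equilibrium(X_bar, Y_bar)
}

#' Joint equilibrium of three pairs sharing one habitat
#'
#' With all virulences held at 1 the three pairs share the logistic
#' crowding term, so each hyperparasite equation still pins its parasite at
#' `X_k = (b_k1/(b_k0 sigma)) H`, while the three parasite equations become
#' a linear system in the hyperparasite loads, solved here in closed form.
#'
#' @param pairs A list of three [pair_params()] objects.
#' @param hab A [habitat_params()] object.
#' @return A list of three `lvhpr_equilibrium` objects (one per pair).
#'   `feasible = FALSE` on all of them if the joint solution would drive
#'   any hyperparasite negative or the parasites alone overfill the
#'   habitat.
#' @export
three_pair_equilibrium <- function(pairs, hab) {
  stopifnot(is.list(pairs), length(pairs) == 3L,
            all(vapply(pairs, inherits, logical(1), "pair_params")),
            inherits(hab, "habitat_params"))
  X <- vapply(pairs, function(p) (p$b1 / (p$b0 * hab$sigma)) * hab$H, numeric(1))
  # a_k1 (1 - (sum X + sum Y / q) / (kappa H)) = a_k0 sigma Y_k / H
  # => Y_k = c_k (A - S/(q kappa H)),  c_k = a_k1 H / (a_k0 sigma),
  #    A = 1 - sum(X)/(kappa H),  S = sum(Y)
  ck <- vapply(pairs, function(p) p$a1 * hab$H / (p$a0 * hab$sigma), numeric(1))
  A <- 1 - sum(X) / (hab$kappa * hab$H)
  S <- sum(ck) * A / (1 + sum(ck) / (hab$q * hab$kappa * hab$H))
  Y <- ck * (A - S / (hab$q * hab$kappa * hab$H))
  feasible <- A > 0 && all(Y > 0)
  lapply(seq_len(3L), function(k) new_equilibrium(X[k], Y[k], feasible))
}
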