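# Parameter containers. All quantities are in abstract model units
# (population, time, energy); the models are unitless by construction.

stop_if_not_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single finite positive number, got %s",
                   nms[i], deparse(v)), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Parameters of the logistic host--phage (Campbell) model
#'
#' The basic two-population model of a host `X` limited by its habitat and
#' preyed on by a phage `Y`:
#' \deqn{dX/dt = X (a_1 (1 - X/L) - a_2 Y), \qquad dY/dt = Y (-b_1 + b_2 X).}
#'
#' @param a1 Growth rate of the host absent the phage (1/time).
#' @param a2 Fitness cost per phage to an infected host (1/(time * pop)).
#' @param b1 Death rate of the phage absent the host (1/time); entered
#'   positive, it appears with a minus sign in the dynamics.
#' @param b2 Fitness gain per host to the phage (1/(time * pop)).
#' @param L Maximum host population the habitat can sustainably feed (pop).
#'
#' @return An object of class `campbell_params`.
#' @seealso [campbell_equilibrium()], [rhs_campbell()]
#' @export
#' @examples
#' campbell_params(a1 = 2, a2 = 0.5, b1 = 1, b2 = 2, L = 4)
campbell_params <- function(a1, a2, b1, b2, L) {
  stop_if_not_positive(a1 = a1, a2 = a2, b1 = b1, b2 = b2, L = L)
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, L = L),
            class = "campbell_params")
}

#' Rate constants of one parasite--hyperparasite pair
#'
#' In the host-nested model the infection terms are scaled by the
#' encounter probability between parasite and hyperparasite, so the pair
#' is described by intrinsic rates (`a1`, `b1`) and encounter-scaled
#' constants (`a0`, `b0`) rather than raw mass-action coefficients.
#'
#' @param a1 Parasite growth rate absent the hyperparasite (1/time).
#' @param a0 Encounter-scaled infection-cost constant.
#' @param b1 Hyperparasite decay rate absent the parasite (1/time).
#' @param b0 Encounter-scaled fitness-gain constant.
#'
#' @return An object of class `pair_params`.
#' @seealso [lvhpr_effective_rates()], [lvhpr_equilibrium()]
#' @export
pair_params <- function(a1, a0, b1, b0) {
  stop_if_not_positive(a1 = a1, a0 = a0, b1 = b1, b0 = b0)
  structure(list(a1 = a1, a0 = a0, b1 = b1, b0 = b0), class = "pair_params")
}

#' Habitat parameters shared by all pairs nested in one host
#'
#' @param H Host population size (pop). Treated as a constant parameter:
#'   the host is assumed to change slowly relative to the parasite and
#'   hyperparasite reproduction cycles.
#' @param kappa Parasite capacity of the hosts: parasites sustainable per
#'   host, so the logistic ceiling is `L = kappa * H`.
#' @param sigma Encounter constant: the parasite--hyperparasite encounter
#'   probability per unit time is `sigma * X * Y / H`.
#' @param q Efficiency quotient of hyperparasites versus parasites in using
#'   the host as habitat; `q > 1`, each hyperparasite occupies `1/q` of a
#'   parasite's habitat share.
#'
#' @return An object of class `habitat_params`.
#' @export
habitat_params <- function(H, kappa, sigma, q) {
  stop_if_not_positive(H = H, kappa = kappa, sigma = sigma, q = q)
  if (q <= 1) stop("efficiency quotient 'q' must exceed 1", call. = FALSE)
  structure(list(H = H, kappa = kappa, sigma = sigma, q = q),
            class = "habitat_params")
}

#' Energy budget of the one-energy homeostasis model
#'
#' Operating energy obeys `dE/dt = -alpha*H - beta*v*X + gamma(t)*v*Y`,
#' where `v` is the (relay-controlled) virulence and `gamma(t)` may decay
#' exponentially after a degeneration onset, modelling the hyperparasite
#' losing its catalytic power.
#'
#' @param alpha Permanent energy consumption rate of the host system, per
#'   host (energy/time/pop).
#' @param beta Energy consumption rate of the virulent parasite
#'   (energy/time per parasite).
#' @param gamma Catalytic energy production rate of the virulent
#'   hyperparasite (energy/time per hyperparasite).
#' @param d Degeneration (decay) rate of `gamma` (1/time, `>= 0`).
#' @param t0_degen Degeneration onset time; `Inf` disables degeneration.
#'
#' @return An object of class `energy1_params`.
#' @seealso [gamma_decay()], [rhs_energy1()]
#' @export
energy1_params <- function(alpha, beta, gamma, d = 0, t0_degen = Inf) {
  stop_if_not_positive(alpha = alpha, beta = beta, gamma = gamma)
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d >= 0,
            is.numeric(t0_degen), length(t0_degen) == 1L, t0_degen > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 d = d, t0_degen = t0_degen),
            class = "energy1_params")
}

#' Energy budget of the two-energy, three-pair homeostasis model
#'
#' Operating energy `E1` and stored (isolation) energy `E2` are coupled to
#' the three pairs: pair 1 transforms E2 into E1, pair 2 catalyses new E1,
#' pair 3 transforms E1 into E2 at conversion ratio `theta`.
#'
#' By default the E2 balance carries `-gamma1*vE1*Y1` (E2 is consumed when
#' transformed into E1), which yields the exact conservation law
#' `theta*E1 + E2 = const` in the pure-transformation limit
#' (`alpha1 = alpha2 = gamma2 = 0`). Set `e2_gain_sign = +1` to use the
#' alternative convention in which that term enters with a plus sign
#' (it breaks the conservation law and is provided for comparison only).
#'
#' @param alpha1 Permanent E1 consumption rate per host (energy/time/pop).
#'   May be 0 to study the pure-transformation limit.
#' @param alpha2 Permanent decay rate of the isolation material E2 (1/time;
#'   multiplies E2). May be 0.
#' @param gamma1 E2-to-E1 transformation rate via hyperparasite Y1.
#' @param gamma2 De-novo E1 catalysis rate via hyperparasite Y2. May be 0:
#'   with `alpha1 = alpha2 = gamma2 = 0` the only energy flows are the
#'   Y1/Y3 transformations and `theta*E1 + E2` is conserved exactly.
#' @param gamma3 E1-to-E2 transformation rate via hyperparasite Y3.
#' @param theta Energy-conversion ratio E1 to E2 (dimensionless,
#'   `0 < theta < 1`, typically small).
#' @param e2_gain_sign Sign of the `gamma1` term in `dE2/dt`: `-1`
#'   (default, mass-balancing) or `+1`.
#'
#' @return An object of class `energy2_params`.
#' @seealso [rhs_energy2()]
#' @export
energy2_params <- function(alpha1, alpha2, gamma1, gamma2, gamma3, theta,
                           e2_gain_sign = -1) {
  stop_if_not_positive(gamma1 = gamma1, gamma3 = gamma3, theta = theta)
  for (nm in c("alpha1", "alpha2", "gamma2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("parameter '%s' must be a single finite nonnegative number", nm),
           call. = FALSE)
  }
  if (theta >= 1) stop("'theta' must lie strictly between 0 and 1", call. = FALSE)
  if (!e2_gain_sign %in% c(-1, 1))
    stop("'e2_gain_sign' must be -1 or +1", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, gamma1 = gamma1,
                 gamma2 = gamma2, gamma3 = gamma3, theta = theta,
                 e2_gain_sign = e2_gain_sign),
            class = "energy2_params")
}

#' @export
print.campbell_params <- function(x, ...) {
  cat("Campbell host-phage parameters:\n")
  cat(sprintf("  a1 = %g, a2 = %g, b1 = %g, b2 = %g, L = %g\n",
              x$a1, x$a2, x$b1, x$b2, x$L))
  invisible(x)
}

#' @export
print.pair_params <- function(x, ...) {
  cat(sprintf("Parasite-hyperparasite pair: a1 = %g, a0 = %g, b1 = %g, b0 = %g\n",
              x$a1, x$a0, x$b1, x$b0))
  invisible(x)
}

#' @export
print.habitat_params <- function(x, ...) {
  cat(sprintf("Habitat: H = %g, kappa = %g, sigma = %g, q = %g (L = kappa*H = %g)\n",
              x$H, x$kappa, x$sigma, x$q, x$kappa * x$H))
  invisible(x)
}
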