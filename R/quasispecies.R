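# Malthusian fitness bookkeeping for a quasispecies: each subpopulation
# grows exponentially at its own fitness, dP_i/dt = m_i P_i. Standalone by
# design: fitness statistics frame the coupled models but are not part of
# their ODE state.

#' A quasispecies of exponentially growing subpopulations
#'
#' @param P Numeric vector of subpopulation sizes (`>= 0`, not all zero).
#' @param m Numeric vector of Malthusian fitness values (per-capita
#'   growth rates, any sign), same length as `P`.
#' @return An object of class `quasispecies`.
#' @export
#' @examples
#' qs <- quasispecies(P = c(3, 1), m = c(2, 0))
#' mean_fitness(qs)      # 1.5
#' fitness_variance(qs)  # 0.75
quasispecies <- function(P, m) {
  stopifnot(is.numeric(P), is.numeric(m), length(P) == length(m),
            length(P) >= 1L, all(is.finite(P)), all(is.finite(m)),
            all(P >= 0))
  if (sum(P) <= 0) stop("total population must be positive", call. = FALSE)
  structure(list(P = P, m = m), class = "quasispecies")
}

#' Subpopulation frequencies
#'
#' @param qs A [quasispecies()].
#' @return `p_i = P_i / sum(P)`; sums to 1.
#' @export
frequencies <- function(qs) {
  stopifnot(inherits(qs, "quasispecies"))
  qs$P / sum(qs$P)
}

#' Mean Malthusian fitness
#'
#' The frequency-weighted average `m_bar = sum(m_i p_i)`.
#' @inheritParams frequencies
#' @return Scalar mean fitness.
#' @export
mean_fitness <- function(qs) {
  sum(qs$m * frequencies(qs))
}

#' Fitness variance
#'
#' `var(m) = sum(m_i^2 p_i) - m_bar^2`, the frequency-weighted second
#' central moment; always nonnegative.
#' @inheritParams frequencies
#' @return Scalar variance.
#' @export
fitness_variance <- function(qs) {
  p <- frequencies(qs)
  max(sum(qs$m^2 * p) - sum(qs$m * p)^2, 0)
}

#' Evolve a quasispecies for a time interval
#'
#' Closed-form exponential growth: `P_i(t + dt) = P_i(t) exp(m_i dt)`.
#' Under constant fitness the mean fitness rises at rate `var(m)`
#' (the fundamental-theorem property), which [fitness_variance()] can be
#' checked against by finite differences.
#'
#' @inheritParams frequencies
#' @param dt Time interval (`>= 0`).
#' @return The evolved [quasispecies()].
#' @export
evolve_exponential <- function(qs, dt) {
  stopifnot(inherits(qs, "quasispecies"), dt >= 0)
  quasispecies(qs$P * exp(qs$m * dt), qs$m)
}

#' Does the quasispecies face an evolutionary problem?
#'
#' A quasispecies faces an evolutionary problem when every subpopulation
#' has negative Malthusian fitness: the whole distribution decays and
#' survival requires shifting the fitness range upwards (e.g. by
#' recruiting catalytic symbionts).
#'
#' @inheritParams frequencies
#' @return `TRUE` if all `m_i < 0`.
#' @export
faces_problem <- function(qs) {
  stopifnot(inherits(qs, "quasispecies"))
  all(qs$m < 0)
}
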