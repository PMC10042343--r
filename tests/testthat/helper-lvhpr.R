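# Shared fixtures: the reference pair/habitat (equilibrium X = 4, Y = 1.6
# at H = 4) and a sampler of random feasible parameter draws.

ref_pair <- function() pair_params(a1 = 1, a0 = 1, b1 = 1, b0 = 1)
ref_hab <- function(H = 4) habitat_params(H = H, kappa = 2, sigma = 1, q = 2)

# random positive parameters satisfying the coexistence condition
# b0 * sigma * kappa > b1
draw_feasible <- function() {
  pair <- pair_params(a1 = runif(1, 0.2, 5), a0 = runif(1, 0.2, 5),
                      b1 = runif(1, 0.2, 2), b0 = runif(1, 0.5, 5))
  kappa_min <- pair$b1 / pair$b0  # with sigma below, ensures feasibility
  hab <- habitat_params(H = runif(1, 0.5, 20),
                        kappa = kappa_min / runif(1, 0.05, 0.8),
                        sigma = 1, q = 1 + runif(1, 0.1, 9))
  list(pair = pair, hab = hab)
}

# cancellation-relative residual of the host-nested RHS at a state:
# each component is compared against the magnitude of its constituent terms
lvhpr_relative_residual <- function(X, Y, pair, hab, v = 1) {
  gx_terms <- c(pair$a1 * (1 - (X + Y / hab$q) / (hab$kappa * hab$H)),
                -(pair$a0 * hab$sigma / hab$H) * Y)
  gy_terms <- c(-pair$b1, (pair$b0 * hab$sigma / hab$H) * X)
  max(abs(sum(gx_terms)) / sum(abs(gx_terms)),
      abs(sum(gy_terms)) / sum(abs(gy_terms)))
}

campbell_relative_residual <- function(X, Y, p) {
  gx_terms <- c(p$a1 * (1 - X / p$L), -p$a2 * Y)
  gy_terms <- c(-p$b1, p$b2 * X)
  max(abs(sum(gx_terms)) / sum(abs(gx_terms)),
      abs(sum(gy_terms)) / sum(abs(gy_terms)))
}
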