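test_that("Campbell equilibrium matches the closed forms and zeroes the vector field", {
  eq <- campbell_equilibrium(campbell_params(a1 = 2, a2 = 0.5, b1 = 1, b2 = 2, L = 4))
  expect_equal(eq$X_bar, 0.5)
  expect_equal(eq$Y_bar, 3.5)
  expect_equal(unname(rhs_campbell(c(X = eq$X_bar, Y = eq$Y_bar),
                                   campbell_params(2, 0.5, 1, 2, 4))),
               c(0, 0))

  # b1 = b2: X_bar = 1; Y_bar -> a1/a2 as the habitat ceiling grows
  eq2 <- campbell_equilibrium(campbell_params(1, 1, 1, 1, L = 1e9))
  expect_equal(eq2$X_bar, 1)
  expect_equal(eq2$Y_bar, 1, tolerance = 1e-8)

  # habitat exactly saturated by the equilibrium host: phage extinct
  eq3 <- campbell_equilibrium(campbell_params(1, 1, b1 = 2, b2 = 1, L = 2))
  expect_equal(eq3$Y_bar, 0)

  expect_error(campbell_params(-1, 1, 1, 1, 1), "positive")
  expect_error(campbell_params(1, 1, 0, 1, 1), "positive")
})

test_that("effective infection rates are encounter constants diluted by the host population", {
  rates <- lvhpr_effective_rates(pair_params(a1 = 1, a0 = 2, b1 = 1, b0 = 3),
                                 habitat_params(H = 4, kappa = 1, sigma = 0.5, q = 2))
  expect_equal(unname(rates), c(2 * 0.5 / 4, 3 * 0.5 / 4))

  r1 <- lvhpr_effective_rates(ref_pair(), ref_hab(H = 2))
  r2 <- lvhpr_effective_rates(ref_pair(), ref_hab(H = 4))
  expect_equal(r1, 2 * r2)
  expect_equal(unname(lvhpr_effective_rates(pair_params(1, 1, 1, 1),
                                            habitat_params(1, 1, 1, 2))),
               c(1, 1))
})

test_that("host-nested equilibrium: closed form, feasibility flag, RHS zero on random draws", {
  eq <- lvhpr_equilibrium(ref_pair(), ref_hab())
  expect_equal(eq$X_bar, 4)
  expect_equal(eq$Y_bar, 1.6)
  expect_true(eq$feasible)

  # hyperparasite infeasible when b0*sigma*kappa <= b1: boundary flagged
  eq0 <- lvhpr_equilibrium(pair_params(1, 1, b1 = 2, b0 = 1),
                           habitat_params(H = 4, kappa = 2, sigma = 1, q = 2))
  expect_false(eq0$feasible)
  expect_equal(eq0$Y_bar, 0)
  expect_equal(eq0$X_bar, 8)  # logistic fixed point kappa*H

  # exact boundary: Y_bar numerator vanishes
  eqb <- lvhpr_equilibrium(pair_params(1, 1, b1 = 2, b0 = 1),
                           habitat_params(H = 4, kappa = 2.0000001, sigma = 1, q = 2))
  expect_lt(eqb$Y_bar, 1e-6)

  set.seed(421)
  for (i in 1:100) {
    d <- draw_feasible()
    eqi <- lvhpr_equilibrium(d$pair, d$hab)
    expect_true(eqi$feasible)
    expect_lt(lvhpr_relative_residual(eqi$X_bar, eqi$Y_bar, d$pair, d$hab), 1e-9)
  }
})

test_that("equilibria are exactly proportional to the host population H", {
  pair <- ref_pair()
  base <- lvhpr_equilibrium(pair, ref_hab(H = 1))
  for (H in c(2, 4, 8, 16)) {
    eq <- lvhpr_equilibrium(pair, ref_hab(H = H))
    expect_identical(eq$X_bar / H, base$X_bar)
    expect_equal(eq$Y_bar / H, base$Y_bar, tolerance = 1e-15)
  }
})

test_that("q -> infinity reduces the host-nested RHS to Campbell with L = kappa*H", {
  set.seed(7)
  pair <- pair_params(1.3, 0.7, 0.9, 1.1)
  for (i in 1:20) {
    H <- runif(1, 1, 10)
    hab <- habitat_params(H = H, kappa = 2.5, sigma = 0.8, q = 1e9)
    eff <- lvhpr_effective_rates(pair, hab)
    camp <- campbell_params(a1 = pair$a1, a2 = eff[["a2_eff"]],
                            b1 = pair$b1, b2 = eff[["b2_eff"]],
                            L = hab$kappa * H)
    st <- c(X = runif(1, 0, 2 * H), Y = runif(1, 0, 2 * H))
    expect_equal(unname(rhs_lvhpr(st, pair, hab, v = 1)),
                 unname(rhs_campbell(st, camp)), tolerance = 1e-6)
  }
})

test_that("three-pair joint equilibrium zeroes all six derivatives", {
  pairs <- list(ref_pair(), pair_params(1.2, 0.8, 0.9, 1.1), ref_pair())
  hab <- habitat_params(H = 4, kappa = 6, sigma = 1, q = 2)
  eqs <- three_pair_equilibrium(pairs, hab)
  expect_true(all(vapply(eqs, `[[`, logical(1), "feasible")))
  st <- c(X1 = eqs[[1]]$X_bar, Y1 = eqs[[1]]$Y_bar,
          X2 = eqs[[2]]$X_bar, Y2 = eqs[[2]]$Y_bar,
          X3 = eqs[[3]]$X_bar, Y3 = eqs[[3]]$Y_bar)
  d <- rhs_three_pair(st, pairs, hab, vE1 = 1, vE2 = 1)
  expect_lt(max(abs(d)), 1e-12)

  # symmetric case solvable by hand: X_k = 4, Y_k = 1.6
  eqs_sym <- three_pair_equilibrium(list(ref_pair(), ref_pair(), ref_pair()), hab)
  expect_equal(vapply(eqs_sym, `[[`, numeric(1), "X_bar"), rep(4, 3))
  expect_equal(vapply(eqs_sym, `[[`, numeric(1), "Y_bar"), rep(1.6, 3))
})
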