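test_that("Campbell RHS: hand-substituted value, extinction boundary, fixed point", {
  p <- campbell_params(1, 1, 1, 1, L = 2)
  expect_equal(unname(rhs_campbell(c(X = 1, Y = 1), p)), c(-0.5, 0))
  expect_equal(rhs_campbell(c(X = 0, Y = 3), p)[["dX"]], 0)
  expect_equal(rhs_campbell(c(X = 3, Y = 0), p)[["dY"]], 0)
  eq <- campbell_equilibrium(p)
  expect_equal(unname(rhs_campbell(c(X = eq$X_bar, Y = eq$Y_bar), p)), c(0, 0))
})

test_that("host-nested RHS: dormancy, hand value, fixed point, per-capita scale covariance", {
  pair <- ref_pair(); hab <- ref_hab()
  expect_equal(unname(rhs_lvhpr(c(X = 3, Y = 2), pair, hab, v = 0)), c(0, 0))
  # X = 4, Y = 0: pure logistic growth term, dX = 4 * (1 - 4/8) = 2
  expect_equal(unname(rhs_lvhpr(c(X = 4, Y = 0), pair, hab, v = 1)), c(2, 0))
  eq <- lvhpr_equilibrium(pair, hab)
  expect_lt(max(abs(rhs_lvhpr(c(X = eq$X_bar, Y = eq$Y_bar), pair, hab, v = 1))),
            1e-10)
  # scaling H and both populations by c leaves per-capita rates unchanged
  set.seed(11)
  for (i in 1:10) {
    X <- runif(1, 0.1, 5); Y <- runif(1, 0.1, 5); cc <- runif(1, 0.5, 10)
    d1 <- rhs_lvhpr(c(X = X, Y = Y), pair, ref_hab(H = 4), v = 1)
    d2 <- rhs_lvhpr(c(X = cc * X, Y = cc * Y), pair, ref_hab(H = 4 * cc), v = 1)
    expect_equal(unname(d2 / c(cc * X, cc * Y)), unname(d1 / c(X, Y)),
                 tolerance = 1e-12)
  }
})

test_that("catalytic rate loses half its power per half-time", {
  d <- 0.37
  expect_identical(gamma_decay(2, d, t = 5, t0 = 10), 2)       # before onset
  expect_equal(gamma_decay(2, d, t = 10 + log(2) / d, t0 = 10), 1)
  expect_equal(gamma_decay(2, d, t = 10 + 2 * log(2) / d, t0 = 10), 0.5)
  expect_identical(gamma_decay(2, d = 0, t = 1e6, t0 = 0), 2)  # no degeneration
})

test_that("one-energy balance: dormant drain, hand value, post-degeneration sign", {
  en <- energy1_params(alpha = 0.1, beta = 0.2, gamma = 1)
  hab <- ref_hab()
  expect_equal(rhs_energy1(c(X = 7, Y = 3), en, hab, v = 0), -0.4)
  expect_equal(rhs_energy1(c(X = 4, Y = 1.6), en, hab, v = 1), 0.4)
  # fully degenerated hyperparasite: all remaining terms negative
  expect_lt(rhs_energy1(c(X = 1, Y = 10), en, hab, v = 1, gamma_t = 0), 0)
})

test_that("three-pair RHS: dormancy, reduction to one pair, shared crowding", {
  pairs <- list(ref_pair(), ref_pair(), ref_pair())
  hab <- habitat_params(H = 4, kappa = 6, sigma = 1, q = 2)
  st <- c(X1 = 2, Y1 = 1, X2 = 3, Y2 = 0.5, X3 = 1, Y3 = 2)
  expect_equal(max(abs(rhs_three_pair(st, pairs, hab, 0, 0))), 0)
  # pairs 2, 3 extinct: pair 1 follows the single-pair equations exactly
  st1 <- c(X1 = 2, Y1 = 1, X2 = 0, Y2 = 0, X3 = 0, Y3 = 0)
  d <- rhs_three_pair(st1, pairs, hab, vE1 = 1, vE2 = 1)
  d_single <- rhs_lvhpr(c(X = 2, Y = 1), ref_pair(), hab, v = 1)
  expect_equal(unname(d[c("dX1", "dY1")]), unname(d_single))
  expect_equal(unname(d[c("dX2", "dY2", "dX3", "dY3")]), rep(0, 4))
  # total load exactly at the ceiling (18 + 12/2 = kappa*H = 24): the
  # logistic factor vanishes and only the infection-cost term remains
  stc <- c(X1 = 6, Y1 = 4, X2 = 6, Y2 = 4, X3 = 6, Y3 = 4)
  dc <- rhs_three_pair(stc, pairs, hab, 1, 1)
  for (k in 1:3) {
    expect_equal(dc[[paste0("dX", k)]], -6 * (1 / 4) * 4)  # -X * a0*sigma/H * Y
  }
})

test_that("two-energy balance: decay-only case, hand value, conservation identity, clamping", {
  hab <- ref_hab()
  en <- energy2_params(alpha1 = 0.1, alpha2 = 0.05, gamma1 = 0.2, gamma2 = 0.3,
                       gamma3 = 0.4, theta = 0.1)
  st <- c(Y1 = 2, Y2 = 1, Y3 = 3, E2 = 2)
  d0 <- rhs_energy2(st, en, hab, vE1 = 0, vE2 = 0)
  expect_equal(unname(d0), c(-0.1 * 4, -0.05 * 2))
  # hand value: dE1 = -0.4 + 0.2/0.1 * 2 = 3.6
  en1 <- energy2_params(alpha1 = 0.1, alpha2 = 0.05, gamma1 = 0.2, gamma2 = 0.3,
                        gamma3 = 0.4, theta = 0.1)
  d1 <- rhs_energy2(st, en1, hab, vE1 = 1, vE2 = 0)
  expect_equal(d1[["dE1"]], 3.6)
  # pure transformation: theta*dE1 + dE2 = 0 at any state
  enc <- energy2_params(alpha1 = 0, alpha2 = 0, gamma1 = 0.2, gamma2 = 0,
                        gamma3 = 0.4, theta = 0.1)
  set.seed(5)
  for (i in 1:20) {
    sti <- c(Y1 = runif(1, 0, 5), Y2 = runif(1, 0, 5), Y3 = runif(1, 0, 5),
             E2 = runif(1, 0.1, 3))
    v1 <- sample(0:1, 1); v2 <- sample(0:1, 1)
    di <- rhs_energy2(sti, enc, hab, v1, v2)
    expect_equal(0.1 * di[["dE1"]] + di[["dE2"]], 0, tolerance = 1e-14)
  }
  # empty store: the E2->E1 transformation contributes nothing
  ste <- c(Y1 = 2, Y2 = 1, Y3 = 0, E2 = 0)
  de <- rhs_energy2(ste, en, hab, vE1 = 1, vE2 = 0)
  expect_equal(de[["dE1"]], -0.4)
  expect_equal(de[["dE2"]], 0)
  # alternative printed sign convention: gamma1 term enters E2 positively
  enp <- energy2_params(alpha1 = 0.1, alpha2 = 0.05, gamma1 = 0.2, gamma2 = 0.3,
                        gamma3 = 0.4, theta = 0.1, e2_gain_sign = 1)
  dp <- rhs_energy2(st, enp, hab, vE1 = 1, vE2 = 0)
  dm <- rhs_energy2(st, en, hab, vE1 = 1, vE2 = 0)
  expect_equal(dp[["dE2"]] - dm[["dE2"]], 2 * 0.2 * 2)
})
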