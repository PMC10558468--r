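test_that("growth-rate ladder is linear from r1 to rN", {
  expect_equal(growth_rates(plasticity_model()), c(1, 0.6, 0.2))
  expect_equal(growth_rates(plasticity_model(n_phenotypes = 5)),
               c(1, 0.8, 0.6, 0.4, 0.2))
  expect_equal(growth_rates(plasticity_model(n_phenotypes = 2, rN = 1)),
               c(1, 1))
  expect_equal(growth_rates(plasticity_model(n_phenotypes = 1)), 1)
  r <- growth_rates(plasticity_model(n_phenotypes = 7, r1 = 2, rN = 0.5))
  expect_equal(r[1], 2)
  expect_equal(r[7], 0.5)
  expect_true(all(diff(r) < 0))
  expect_equal(diff(r), rep(diff(r)[1], 6))  # equal spacing
})

test_that("transition rates follow c(1 +/- lambda) r1", {
  expect_equal(unname(transition_rates(plasticity_model())), c(1, 1))
  m <- plasticity_model(transition_speed = 2, transition_bias = 0.5)
  expect_equal(unname(transition_rates(m)), c(3, 1))
  m0 <- plasticity_model(transition_speed = 0, transition_bias = -0.7)
  expect_equal(unname(transition_rates(m0)), c(0, 0))
})

test_that("parameter invariants are enforced", {
  expect_error(plasticity_model(transition_bias = 1.5), "\\[-1, 1\\]")
  expect_error(plasticity_model(rN = 0), "0 < rN")
  expect_error(plasticity_model(rN = 1.5), "rN <= r1")
  expect_error(plasticity_model(transition_speed = -1), "transition_speed")
  expect_error(plasticity_model(carrying_capacity = 0), "carrying_capacity")
  expect_error(plasticity_model(mD = -0.1), "mD")
  expect_error(plasticity_model(competition_matrix = matrix(1, 2, 2)),
               "3 x 3")
  expect_error(phenotype_rhs(c(1, 0), plasticity_model()), "length")
})

test_that("rhs reproduces hand-evaluated derivatives", {
  m <- plasticity_model()
  # at X = K the growth term vanishes and only transitions act
  expect_equal(phenotype_rhs(c(1, 0, 0), m), c(-1, 1, 0))
  # treatment terms subtract (mD r_i + mI) x_i
  m2 <- update_model(m, mI = 0.5)
  x <- c(0.2, 0.3, 0.1)
  base <- phenotype_rhs(x, m2)
  expect_equal(phenotype_rhs(x, m2, "growth_dependent"),
               base - 1 * c(1, 0.6, 0.2) * x)
  expect_equal(phenotype_rhs(x, m2, "growth_independent"), base - 0.5 * x)
})

test_that("rhs vanishes at the coexistence equilibrium", {
  for (lam in c(-0.8, -0.3, 0, 0.4, 0.9)) {
    for (cc in c(0.2, 1, 5)) {
      m <- plasticity_model(transition_bias = lam, transition_speed = cc)
      eq <- coexistence_equilibrium(m)
      expect_lt(max(abs(phenotype_rhs(eq, m))),
                1e-10 * m$carrying_capacity * m$r1)
    }
  }
})

test_that("transition terms conserve total abundance", {
  # with no treatment, sum(dx) must equal the summed growth terms alone,
  # i.e. the transition fluxes telescope to zero
  for (scaling in c("epithelial_rate", "own_rate")) {
    m <- plasticity_model(n_phenotypes = 5, transition_bias = 0.3,
                          transition_speed = 2,
                          transition_scaling = scaling)
    r <- growth_rates(m)
    K <- m$carrying_capacity
    states <- random_states(100, 5)
    for (k in seq_len(nrow(states))) {
      x <- states[k, ]
      growth_only <- sum(r * x * (1 - sum(x) / K))
      expect_equal(sum(phenotype_rhs(x, m)), growth_only,
                   tolerance = 1e-12)
    }
  }
})

test_that("the nonnegative orthant is forward-invariant", {
  m <- plasticity_model(transition_bias = 0.6)
  # inflow-only derivative at empty compartments
  states <- random_states(50, 3, seed = 7)
  for (k in seq_len(nrow(states))) {
    x <- states[k, ]
    x[sample.int(3, 1)] <- 0
    dx <- phenotype_rhs(x, m)
    expect_true(all(dx[x == 0] >= 0))
  }
  # short simulations from boundary states stay nonnegative
  for (x0 in list(c(0.1, 0, 0), c(0, 0, 0.1), c(0, 0.5, 0))) {
    traj <- simulate(m, x0 = x0, horizon = 20)
    expect_true(all(traj$states >= 0))
  }
})

test_that("an all-ones competition matrix reproduces the shared-K model", {
  m1 <- plasticity_model(transition_bias = 0.25)
  m2 <- plasticity_model(transition_bias = 0.25,
                         competition_matrix = matrix(1, 3, 3))
  states <- random_states(20, 3, seed = 11)
  for (k in seq_len(nrow(states))) {
    expect_identical(phenotype_rhs(states[k, ], m1),
                     phenotype_rhs(states[k, ], m2))
  }
})

test_that("N = 1 degenerates to pure logistic growth", {
  m <- plasticity_model(n_phenotypes = 1)
  x <- 0.3
  expect_equal(phenotype_rhs(x, m), 1 * x * (1 - x / 1))
  traj <- simulate(m, x0 = 0.01, horizon = 50)
  expect_equal(unname(traj$states[nrow(traj$states), 1]), 1,
               tolerance = 1e-6)
})

test_that("analytic Jacobian matches finite differences", {
  skip_if_not_installed("pracma")
  cases <- list(
    plasticity_model(transition_bias = 0.4, mI = 0.6),
    plasticity_model(n_phenotypes = 4, transition_bias = -0.5,
                     transition_speed = 3, mI = 0.2),
    plasticity_model(transition_scaling = "own_rate", mI = 0.3),
    plasticity_model(competition_matrix = matrix(c(1, 0.5, 0.2,
                                                   0.5, 1, 0.5,
                                                   0.2, 0.5, 1), 3, 3),
                     mI = 0.1)
  )
  for (m in cases) {
    x <- random_states(1, m$n_phenotypes, seed = 3)[1, ]
    for (kind in c("none", "growth_dependent", "growth_independent")) {
      J_fd <- pracma::jacobian(function(y) phenotype_rhs(y, m, kind), x)
      expect_equal(phenotype_jacobian(x, m, kind), J_fd, tolerance = 1e-6)
    }
  }
})
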