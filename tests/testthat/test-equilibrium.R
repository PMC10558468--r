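test_that("coexistence equilibrium matches the closed form", {
  expect_equal(coexistence_equilibrium(plasticity_model()), rep(1 / 3, 3))
  expect_equal(coexistence_equilibrium(plasticity_model(transition_bias = 1)),
               c(0, 0, 1))
  expect_equal(coexistence_equilibrium(plasticity_model(transition_bias = -1)),
               c(1, 0, 0))
  # geometric profile with ratio (1 + lambda)/(1 - lambda) = 3
  expect_equal(
    coexistence_equilibrium(plasticity_model(transition_bias = 0.5)),
    c(1, 3, 9) / 13
  )
  expect_error(coexistence_equilibrium(plasticity_model(transition_speed = 0)),
               "c = 0")
})

test_that("equilibrium abundances sum to K and ignore the growth ladder", {
  lams <- seq(-1, 1, length.out = 21)
  for (n in c(1, 2, 3, 6)) {
    for (lam in lams) {
      m <- plasticity_model(n_phenotypes = n, transition_bias = lam,
                            carrying_capacity = 2.5)
      expect_equal(sum(coexistence_equilibrium(m)), 2.5,
                   tolerance = 1e-12)
    }
  }
  base <- coexistence_equilibrium(plasticity_model(transition_bias = 0.3))
  for (rn in c(0.1, 0.5, 0.9)) {
    m <- plasticity_model(transition_bias = 0.3, rN = rn)
    expect_identical(coexistence_equilibrium(m), base)
  }
})

test_that("equilibrium obeys the E<->M mirror symmetry", {
  for (lam in seq(0, 1, by = 0.1)) {
    xp <- coexistence_equilibrium(plasticity_model(n_phenotypes = 5,
                                                   transition_bias = lam))
    xm <- coexistence_equilibrium(plasticity_model(n_phenotypes = 5,
                                                   transition_bias = -lam))
    expect_equal(xp, rev(xm), tolerance = 1e-14)
  }
})

test_that("distribution moments are computed over [0,1] trait scores", {
  u <- distribution_moments(rep(1 / 3, 3))
  expect_equal(u$total, 1)
  expect_equal(sum(u$frequencies), 1, tolerance = 1e-12)
  expect_equal(u$mean_trait, 0.5)
  expect_equal(u$variance, 1 / 6)
  expect_equal(u$third_central_moment, 0)
  pm <- distribution_moments(c(0, 0, 1))
  expect_equal(pm$mean_trait, 1)
  expect_equal(pm$variance, 0)
  expect_equal(pm$third_central_moment, 0)
  # equilibrium at lambda = 0.5: frozen from direct summation over the three
  # outcomes with p = (1, 3, 9)/13 and s = (0, 1/2, 1)
  g <- distribution_moments(c(1, 3, 9) / 13)
  expect_equal(g$mean_trait, 21 / 26)
  expect_equal(g$variance, 33 / 338)
  expect_equal(g$third_central_moment, -9672 / 228488)
  expect_error(distribution_moments(c(0, 0, 0)), "degenerate")
  expect_error(distribution_moments(c(-1, 2, 1)), "nonnegative")
})

test_that("equilibrium heterogeneity peaks at zero bias; skew is odd", {
  lams <- seq(-1, 1, length.out = 21)
  mom <- lapply(lams, function(l) {
    distribution_moments(
      coexistence_equilibrium(plasticity_model(transition_bias = l)))
  })
  vars <- vapply(mom, `[[`, numeric(1), "variance")
  m3 <- vapply(mom, `[[`, numeric(1), "third_central_moment")
  expect_equal(which.max(vars), which(lams == 0))
  expect_equal(vars[1], 0)                      # unidirectional: no spread
  expect_equal(vars[length(vars)], 0)
  expect_equal(m3, -rev(m3), tolerance = 1e-12) # odd in the bias
  expect_equal(m3[lams == 0], 0, tolerance = 1e-12)
})

test_that("coexistence is stable and extinction unstable across (lambda, c)", {
  for (lam in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    for (cc in c(0.1, 1, 10)) {
      m <- plasticity_model(transition_bias = lam, transition_speed = cc)
      co <- stability_report(m)
      expect_identical(co$verdict, "stable")
      expect_lt(co$max_real_part, 0)
      or <- stability_report(m, point = c(0, 0, 0))
      expect_identical(or$verdict, "unstable")
      expect_gt(or$max_real_part, 0)
    }
  }
})

test_that("stability verdict is robust to the growth ladder", {
  m <- plasticity_model(rN = 0.5)
  eq <- coexistence_equilibrium(m)
  expect_identical(eq, coexistence_equilibrium(plasticity_model()))
  expect_identical(stability_report(m, point = eq)$verdict, "stable")
})

test_that("closed-form equilibrium agrees with the simulated fixed point", {
  for (n in 2:4) {
    m <- plasticity_model(n_phenotypes = n, transition_bias = 0.35,
                          transition_speed = 0.8)
    x0 <- numeric(n); x0[1] <- 0.1
    ss <- steady_state(m, x0)
    expect_true(ss$converged)
    expect_lt(max(abs(ss$state - coexistence_equilibrium(m))), 1e-8)
  }
})

test_that("decision boundary solves the equal-mortality polynomial", {
  # reference parameters with the calibrated mI: boundary near -0.089
  lt <- decision_boundary(ref_model_cal)
  expect_lt(lt, 0)
  r <- growth_rates(ref_model_cal)
  f <- sum((ref_model_cal$mD * r - ref_model_cal$mI) *
             coexistence_equilibrium(
               update_model(ref_model_cal, transition_bias = lt)))
  expect_lt(abs(f), 1e-12)
  # N = 2: mean growth rate at bias lambda is 0.6 - 0.4 lambda, so
  # mI = 0.6 puts the boundary exactly at zero bias
  m2 <- plasticity_model(n_phenotypes = 2, mI = 0.6)
  expect_equal(decision_boundary(m2), 0, tolerance = 1e-10)
  # growth-independent mortality dominates for every bias -> no boundary
  expect_true(is.na(decision_boundary(update_model(ref_model, mI = 1.5))))
  expect_error(decision_boundary(plasticity_model(transition_speed = 0,
                                                  mI = 0.5)),
               "c > 0")
})
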