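test_that("post-interaction proportion matches the pair-type enumeration", {
  pars <- altruism_params(b = 0.6, c = 0.05, T_alpha = 0.4, T_beta = 0.1)
  expect_equal(post_interaction_proportion(0.5, pars), 0.575)
  for (p in c(0.1, 0.3, 0.5, 0.9)) {
    expect_equal(post_interaction_proportion(p, pars),
                 enum_post_interaction(p, 0.4, 0.1))
  }
  # equal transmission leaves proportions unchanged; boundaries are fixed
  eq <- altruism_params(b = 0.6, c = 0.05, T_alpha = 0.3, T_beta = 0.3)
  expect_equal(post_interaction_proportion(0.3, eq), 0.3)
  expect_equal(post_interaction_proportion(c(0, 1), pars), c(0, 1))
  expect_error(post_interaction_proportion(1.2, pars), "0, 1")
})

test_that("mean fitness averages pair payoffs correctly", {
  expect_equal(mean_fitness(0, altruism_params(b = 2, c = 0.1)), 1)
  expect_equal(mean_fitness(1, altruism_params(b = 3, c = 0.05)), 3.95)
  # 1 + (b_g - c_g) + p (b - c)
  pars <- altruism_params(b = 2, c = 0.5, b_g = 0.2, c_g = 0.1)
  expect_equal(mean_fitness(0.5, pars), 1 + 0.1 + 0.5 * 1.5)
})

test_that("the recursion fixes p = 0 and p = 1 and maps [0,1] into [0,1]", {
  pars <- altruism_params(b = 3, c = 0.05, T_alpha = 0.3, T_beta = 0.6,
                          VT = 0.7, b_g = 0.2, c_g = 0.1)
  expect_equal(next_generation_proportion(c(0, 1), pars), c(0, 1))
  p_grid <- seq(0, 1, by = 0.05)
  for (VT in c(0.25, 0.6, 1)) {
    pars2 <- altruism_params(b = 5, c = 0.4, T_alpha = 0.8, T_beta = 0.05,
                             VT = VT)
    p_next <- next_generation_proportion(p_grid, pars2)
    expect_true(all(p_next >= 0 & p_next <= 1))
  }
})

test_that("without horizontal transmission altruism declines", {
  pars <- altruism_params(b = 3, c = 0.05, T_alpha = 0, T_beta = 0, VT = 1)
  p <- 0.5
  p_next <- next_generation_proportion(p, pars)
  expect_lt(p_next, p)
  # closed form of the no-transmission recursion
  expect_equal(p_next, p * (1 + p * 3 - 0.05) / (1 + p * (3 - 0.05)))
  # the genetic-allele recursion is the same map
  expect_equal(genetic_next_generation(p, 3, 0.05), p_next)
})

test_that("genetically encoded altruism always declines yet stays neutral in the limit", {
  for (p in c(0.01, 0.2, 0.5, 0.9, 0.99)) {
    expect_lt(genetic_next_generation(p, b_g_allele = 10, c_g_allele = 0.5), p)
    expect_lt(genetic_next_generation(p, b_g_allele = 0.9, c_g_allele = 0.01), p)
  }
  expect_equal(genetic_next_generation(c(0, 1), 2, 0.1), c(0, 1))
  expect_equal(genetic_next_generation(0.4, 2, 1e-12), 0.4, tolerance = 1e-9)
})

test_that("spread condition agrees with the recursion across parameters", {
  set.seed(11)
  for (i in 1:40) {
    pars <- altruism_params(
      b = runif(1, 0.2, 5), c = runif(1, 0.01, 0.9),
      T_alpha = runif(1), T_beta = runif(1), VT = runif(1, 0.05, 1)
    )
    p <- runif(1, 0.01, 0.99)
    dp <- next_generation_proportion(p, pars) - p
    if (abs(dp) > 1e-12) {
      expect_equal(spread_condition(pars, p), dp > 0)
    }
  }
})

test_that("spread with perfect vertical transmission is independent of p", {
  pars <- altruism_params(b = 1, c = 0.05, b_g = 0.3, c_g = 0.2,
                          T_alpha = 0.07, T_beta = 0.12, VT = 1)
  vals <- spread_condition(pars, c(0.001, 0.25, 0.5, 0.75, 0.999))
  expect_length(unique(vals), 1)
  # baseline-adjusted form: b T_a > c (1 - T_b) + (1 + b_g - c_g)(T_b - T_a)
  lhs <- pars$b * pars$T_alpha
  rhs <- pars$c * (1 - pars$T_beta) +
    (1 + pars$b_g - pars$c_g) * (pars$T_beta - pars$T_alpha)
  expect_equal(unique(vals), lhs > rhs)
})

test_that("equal transmission cancels the p and VT dependence of the spread sign", {
  for (T in c(0.05, 0.2, 0.5)) {
    for (VT in c(0.25, 0.5, 1)) {
      above <- equal_T_params(T, bc = (1 - T) / T + 0.01, VT = VT)
      below <- equal_T_params(T, bc = (1 - T) / T - 0.01, VT = VT)
      expect_true(all(spread_condition(above, c(0.01, 0.5, 0.99))))
      expect_false(any(spread_condition(below, c(0.01, 0.5, 0.99))))
    }
  }
})

test_that("critical b/c thresholds take their closed-form values", {
  expect_equal(critical_bc_ratio(0.1, 0.1, c = 0.05), 9)
  expect_equal(critical_bc_ratio(0.01, 0.01, c = 0.05), 99)
  expect_equal(critical_bc_ratio(0.001, 0.001, c = 0.05), 999)
  expect_equal(critical_bc_ratio(0, 0.1, c = 0.05), Inf)
  expect_equal(critical_bc_ratio(0, 0, c = 0.05, VT = 0.5), Inf)
  # equal-T thresholds are (1-T)/T for every c and VT > 0
  for (c in c(0.01, 0.05, 0.2)) {
    for (VT in c(0.25, 1)) {
      expect_equal(critical_bc_ratio(0.2, 0.2, c = c, VT = VT), 4)
    }
  }
})

test_that("closed-form and bisection thresholds agree", {
  set.seed(7)
  for (i in 1:20) {
    Ta <- runif(1, 0.01, 1)
    Tb <- runif(1, 0, 1)
    c <- runif(1, 0.01, 0.5)
    VT <- runif(1, 0.3, 1)
    cf <- critical_bc_ratio(Ta, Tb, c, VT)
    bi <- critical_bc_ratio(Ta, Tb, c, VT, method = "bisection")
    if (is.finite(cf)) {
      expect_equal(bi, cf, tolerance = 1e-6)
    } else {
      expect_equal(bi, Inf)
    }
  }
  # a transmission advantage for alpha lowers the threshold
  expect_lt(critical_bc_ratio(0.2, 0.1, c = 0.05),
            critical_bc_ratio(0.1, 0.1, c = 0.05))
})

test_that("iteration reaches fixation above threshold and loss without transmission", {
  up <- equal_T_params(0.1, bc = 12)  # above the threshold of 9
  traj <- iterate_mixed(0.05, up, generations = 1e4)
  expect_gt(attr(traj, "final_p"), 1 - 1e-6)
  expect_true(all(diff(traj$p) >= 0))

  down <- altruism_params(b = 3, c = 0.05, T_alpha = 0, T_beta = 0)
  traj2 <- iterate_mixed(0.05, down, generations = 2000)
  expect_true(all(diff(traj2$p) <= 0))
  expect_lt(attr(traj2, "final_p"), 0.05)
})

test_that("imperfect vertical transmission slows the spread without moving the endpoint", {
  full <- equal_T_params(0.1, bc = 12, VT = 1)
  half <- equal_T_params(0.1, bc = 12, VT = 0.5)
  t_full <- iterate_mixed(0.05, full, generations = 1e4)
  t_half <- iterate_mixed(0.05, half, generations = 1e4)
  expect_gt(attr(t_full, "final_p"), 1 - 1e-6)
  expect_gt(attr(t_half, "final_p"), 1 - 1e-6)
  cross <- function(tr) min(tr$generation[tr$p > 0.5])
  expect_gt(cross(t_half), cross(t_full))
})
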