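test_that("random initialisation places an exact count of altruist carriers", {
  g <- lattice_init_random(c(100, 100), 0.05, seed = 1)
  expect_equal(sum(g), 500)
  expect_equal(dim(g), c(100, 100))
  g2 <- lattice_init_random(c(20, 20), 0.05, seed = 2)
  expect_equal(sum(g2), 20)
  expect_equal(sum(lattice_init_random(c(10, 10), 0)), 0)
  expect_equal(sum(lattice_init_random(c(10, 10), 1)), 100)
})

test_that("patch initialisation fills a centred block", {
  g <- lattice_init_patch(c(100, 100), 2)
  expect_equal(sum(g), 4)
  expect_equal(mean(g), 4 / 10000)
  expect_equal(which(g == 1L, arr.ind = TRUE)[, "row"], rep(50:51, 2),
               ignore_attr = TRUE)
  expect_equal(sort(unique(which(g == 1L, arr.ind = TRUE)[, "col"])), 50:51)
  expect_equal(sum(lattice_init_patch(c(10, 10), 0)), 0)
  expect_equal(sum(lattice_init_patch(c(4, 4), 4)), 16)
  expect_error(lattice_init_patch(c(4, 4), 5), "exceeds")
})

test_that("Moore neighbourhoods truncate at the edges", {
  dims <- c(10, 12)
  expect_equal(nrow(lattice_neighbourhood(dims, c(5, 5))), 8)
  expect_equal(nrow(lattice_neighbourhood(dims, c(1, 1))), 3)
  expect_equal(nrow(lattice_neighbourhood(dims, c(10, 12))), 3)
  expect_equal(nrow(lattice_neighbourhood(dims, c(1, 6))), 5)
  expect_equal(nrow(lattice_neighbourhood(dims, c(4, 12))), 5)
  nb <- lattice_neighbourhood(dims, c(1, 1))
  expect_setequal(paste(nb[, 1], nb[, 2]), c("1 2", "2 1", "2 2"))
})

test_that("an all-neutral lattice is absorbing", {
  pars <- equal_T_params(0.3, bc = 10)
  g <- lattice_init_random(c(8, 8), 0)
  set.seed(3)
  res <- run_lattice_generation(g, pars, K = 2)
  expect_equal(sum(res$lattice), 0)
  expect_equal(res$p, 0)
})

test_that("a uniform altruist lattice has exactly fitness b - c everywhere", {
  pars <- altruism_params(b = 3, c = 0.05, T_alpha = 0.1, T_beta = 0.1, VT = 1)
  g <- lattice_init_random(c(3, 3), 1)
  set.seed(4)
  res <- run_lattice_generation(g, pars, K = 1)
  expect_equal(res$fitness, matrix(3 - 0.05, 3, 3))
  expect_true(all(res$lattice == 1L))
  expect_equal(res$p, 1)
})

test_that("interaction bookkeeping counts both participants", {
  pars <- equal_T_params(0.2, bc = 10)
  g <- lattice_init_random(c(12, 12), 0.4, seed = 5)
  for (K in c(1, 3)) {
    set.seed(6)
    res <- run_lattice_generation(g, pars, K = K)
    expect_true(all(res$interaction_count >= K))
    expect_equal(sum(res$interaction_count), 2 * K * 144)
  }
})

test_that("microbe mode without transmission reproduces genetic mode exactly", {
  pars <- altruism_params(b = 1, c = 0.05, T_alpha = 0, T_beta = 0, VT = 1)
  for (seed in c(11, 12)) {
    cfg_m <- lattice_config(pars, dims = c(20, 20), mode = "microbe",
                            max_generation = 30, seed = seed)
    cfg_g <- lattice_config(pars, dims = c(20, 20), mode = "genetic",
                            max_generation = 30, seed = seed)
    rm_ <- run_lattice_sim(cfg_m)
    rg_ <- run_lattice_sim(cfg_g)
    expect_identical(rm_$p_trajectory, rg_$p_trajectory)
    expect_identical(rm_$final_state, rg_$final_state)
    expect_identical(rm_$outcome, rg_$outcome)
  }
})

test_that("neutral parameters leave the mean proportion at its start (drift only)", {
  pars <- altruism_params(b = 0, c = 0, T_alpha = 0.2, T_beta = 0.2, VT = 1)
  finals <- sapply(1:40, function(s) {
    cfg <- lattice_config(pars, dims = c(15, 15), max_generation = 15,
                          init = list(random_fraction = 0.4), seed = 1000 + s)
    run_lattice_sim(cfg, record_trajectory = FALSE)$final_p
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.4), 4 * se)
})

test_that("runs stop on the configured absorbing targets", {
  pars <- equal_T_params(0.5, bc = 10)
  cfg <- lattice_config(pars, dims = c(40, 40),
                        init = list(central_patch = 2),
                        upper_target = 0.05, seed = 23)
  res <- run_lattice_sim(cfg)
  expect_true(res$outcome %in% c("reached_target", "extinct"))
  if (res$outcome == "reached_target") expect_gte(res$final_p, 0.05)
  all_alpha <- lattice_config(pars, dims = c(10, 10),
                              init = list(random_fraction = 1), seed = 2)
  expect_equal(run_lattice_sim(all_alpha)$outcome, "fixed")
})

test_that("the stabilisation rule smooths fluctuations and flags ramps", {
  expect_true(is_stable(rep(0.4, 401)))
  expect_false(is_stable(rep(0.4, 400)))             # not yet eligible
  ramp <- 0.001 * seq_len(800)
  expect_false(is_stable(ramp))                      # window means differ by 0.2
  osc <- rep(c(0.4, 0.6), 300)
  expect_true(is_stable(osc))                        # period-2 mean is constant
  expect_error(is_stable(rep(0.5, 10), current_generation = 20),
               "insufficient")
})
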