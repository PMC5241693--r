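#' Critical b/c threshold table
#'
#' Evaluates [critical_bc_ratio()] over a grid of horizontal- and
#' vertical-transmission settings, producing the data behind critical-curve
#' plots: the minimal benefit-cost ratio allowing the altruism-inducing
#' microbe to invade from rarity, as a function of its transmission
#' probability. The threshold is non-increasing in `T_alpha` and diverges
#' at `T_alpha = 0`.
#'
#' @param T_alpha numeric vector of alpha transmission probabilities.
#' @param T_beta numeric vector of beta transmission probabilities.
#' @param c numeric vector of altruism costs.
#' @param VT numeric vector of vertical-transmission fidelities.
#' @param b_g,c_g baseline genetic benefit and cost (scalars).
#' @return A data frame with columns `T_alpha`, `T_beta`, `c`, `VT`, `b_g`,
#'   `c_g`, `critical_bc` (one row per grid combination).
#' @export
threshold_table <- function(T_alpha, T_beta = T_alpha, c = 0.05, VT = 1,
                            b_g = 0, c_g = 0) {
  grid <- expand.grid(T_alpha = T_alpha, T_beta = T_beta, c = c, VT = VT,
                      KEEP.OUT.ATTRS = FALSE)
  grid$b_g <- b_g
  grid$c_g <- c_g
  grid$critical_bc <- mapply(
    critical_bc_ratio,
    T_alpha = grid$T_alpha, T_beta = grid$T_beta, c = grid$c, VT = grid$VT,
    MoreArgs = list(b_g = b_g, c_g = c_g)
  )
  grid
}

# deterministic per-replicate seed from (base seed, cell, replicate);
# kept below 2^31
cell_seed <- function(base_seed, cell_index, replicate) {
  (as.double(base_seed) * 2654435761 + cell_index * 97003 + replicate * 101) %%
    2147483647 + 1
}

#' Lattice parameter sweep over transmission and benefit-cost values
#'
#' Runs [run_lattice_sim()] for every combination of equal horizontal
#' transmission `T` (= `T_alpha` = `T_beta`) and `b/c` value, from a random
#' initial occupancy of altruist carriers, and tabulates the mean final
#' proportion and the outcome tallies per cell. Setting
#' `include_genetic = TRUE` adds the genetic-allele control column (no
#' microbes, perfect vertical transmission), run at the same `b/c` values.
#' Per-replicate seeds derive deterministically from `base_seed`, the cell
#' index and the replicate index, so any cell can be reproduced in
#' isolation.
#'
#' @param T_values equal horizontal-transmission probabilities to sweep
#'   (microbe mode).
#' @param bc_values benefit-cost ratios to sweep.
#' @param c cost of the altruistic act (benefit is `bc * c`).
#' @param K interactions initiated per host per generation.
#' @param VT vertical-transmission fidelity (microbe mode).
#' @param dims lattice dimensions.
#' @param init_fraction initial altruist occupancy.
#' @param replicates runs per cell.
#' @param base_seed base seed for the deterministic per-replicate seeds.
#' @param include_genetic add genetic-mode cells (reported with `T = NA`).
#' @param max_generation generation cap per run.
#' @return A data frame of class `altruism_sweep`: one row per cell with
#'   columns `mode`, `T`, `bc`, `mean_final_p`, `replicates` and outcome
#'   tallies `n_extinct`, `n_fixed`, `n_stabilized`, `n_max_generations`.
#' @export
sweep_lattice <- function(T_values, bc_values, c = 0.05, K = 1, VT = 1,
                          dims = c(100, 100), init_fraction = 0.05,
                          replicates = 30, base_seed = 1,
                          include_genetic = FALSE, max_generation = 10000) {
  cells <- data.frame(
    mode = rep("microbe", length(T_values) * length(bc_values)),
    T = rep(T_values, each = length(bc_values)),
    bc = rep(bc_values, times = length(T_values))
  )
  if (include_genetic) {
    cells <- rbind(data.frame(mode = "genetic", T = NA_real_, bc = bc_values),
                   cells)
  }
  if (nrow(cells) == 0) stop("no cells to sweep", call. = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    mode <- cells$mode[ci]
    Tv <- cells$T[ci]
    bc <- cells$bc[ci]
    pars <- if (mode == "microbe") {
      altruism_params(b = bc * c, c = c, T_alpha = Tv, T_beta = Tv, VT = VT)
    } else {
      altruism_params(b = bc * c, c = c, T_alpha = 0, T_beta = 0, VT = 1)
    }
    finals <- character(replicates)
    ps <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cfg <- lattice_config(
        pars, dims = dims, K = K, mode = mode,
        init = list(random_fraction = init_fraction),
        max_generation = max_generation,
        seed = cell_seed(base_seed, ci, r)
      )
      res <- run_lattice_sim(cfg, record_trajectory = FALSE)
      finals[r] <- res$outcome
      ps[r] <- res$final_p
    }
    data.frame(
      mode = mode, T = Tv, bc = bc,
      mean_final_p = mean(ps), replicates = replicates,
      n_extinct = sum(finals == "extinct"),
      n_fixed = sum(finals == "fixed"),
      n_stabilized = sum(finals == "stabilized"),
      n_max_generations = sum(finals == "max_generations")
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "settings") <- list(c = c, K = K, VT = VT, dims = dims,
                                init_fraction = init_fraction,
                                base_seed = base_seed)
  class(out) <- c("altruism_sweep", "data.frame")
  out
}

#' Invasion probability of a rare central patch
#'
#' Estimates the probability that a central `side x side` patch of
#' altruist carriers increases in proportion (reaches `target` before
#' extinction), by running many independent lattice simulations per
#' parameter combination with absorbing targets 0 and `target`; a run that
#' stabilises strictly between the targets is tallied separately (rare).
#' A Wilson score interval accompanies each estimate.
#'
#' @param T_values equal horizontal-transmission probabilities (microbe
#'   mode); use `mode = "genetic"` for the allele control.
#' @param bc_values benefit-cost ratios.
#' @param c cost of the altruistic act.
#' @param K interactions initiated per host per generation.
#' @param VT vertical-transmission fidelity.
#' @param dims lattice dimensions.
#' @param side patch side length (default 2).
#' @param target upper absorbing proportion (default 0.05).
#' @param replicates runs per combination.
#' @param base_seed base seed for deterministic per-run seeds.
#' @param mode `"microbe"` or `"genetic"`.
#' @param conf confidence level of the Wilson interval.
#' @return A data frame of class `altruism_invasion`: columns `mode`, `T`,
#'   `bc`, `n_invaded`, `n_extinct`, `n_stabilized`, `replicates`,
#'   `probability`, `ci_low`, `ci_high`.
#' @export
invasion_probability <- function(T_values, bc_values, c = 0.05, K = 1,
                                 VT = 1, dims = c(100, 100), side = 2,
                                 target = 0.05, replicates = 1000,
                                 base_seed = 1,
                                 mode = c("microbe", "genetic"),
                                 conf = 0.95) {
  mode <- match.arg(mode)
  if (mode == "genetic") T_values <- NA_real_
  cells <- expand.grid(T = T_values, bc = bc_values, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    Tv <- cells$T[ci]
    bc <- cells$bc[ci]
    pars <- if (mode == "microbe") {
      altruism_params(b = bc * c, c = c, T_alpha = Tv, T_beta = Tv, VT = VT)
    } else {
      altruism_params(b = bc * c, c = c, T_alpha = 0, T_beta = 0, VT = 1)
    }
    tally <- c(reached_target = 0L, extinct = 0L, stabilized = 0L,
               max_generations = 0L, fixed = 0L)
    for (r in seq_len(replicates)) {
      cfg <- lattice_config(
        pars, dims = dims, K = K, mode = mode,
        init = list(central_patch = side),
        upper_target = target,
        seed = cell_seed(base_seed, ci, r)
      )
      res <- run_lattice_sim(cfg, record_trajectory = FALSE)
      tally[res$outcome] <- tally[res$outcome] + 1L
    }
    x <- tally[["reached_target"]]
    ci <- wilson_interval(x, replicates, conf)
    data.frame(
      mode = mode, T = Tv, bc = bc,
      n_invaded = x, n_extinct = tally[["extinct"]],
      n_stabilized = tally[["stabilized"]] + tally[["max_generations"]],
      replicates = replicates,
      probability = x / replicates,
      ci_low = ci[1], ci_high = ci[2]
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("altruism_invasion", "data.frame")
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Compare the recursion with the finite-population simulator
#'
#' For each row of a parameter grid, computes the deterministic
#' one-generation change in the alpha proportion and the Monte-Carlo mean
#' change from [estimate_delta_p()], with its standard error and z-score.
#' Used to validate the recursion against an independent stochastic
#' implementation.
#'
#' @param grid data frame with columns `p0`, `b`, `c`, `T_alpha`, `T_beta`,
#'   `VT` (optional `b_g`, `c_g`).
#' @param N even population size for the finite simulator.
#' @param replicates Monte-Carlo replicates per row.
#' @param seed integer seed.
#' @return The grid with added columns `analytic_dp`, `simulated_dp`, `se`,
#'   `z`.
#' @export
validate_recursion <- function(grid, N = 1e5, replicates = 200, seed = 1) {
  stopifnot(all(c("p0", "b", "c", "T_alpha", "T_beta", "VT") %in% names(grid)))
  if (is.null(grid$b_g)) grid$b_g <- 0
  if (is.null(grid$c_g)) grid$c_g <- 0
  set.seed(seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pars <- altruism_params(b = g$b, c = g$c, b_g = g$b_g, c_g = g$c_g,
                            T_alpha = g$T_alpha, T_beta = g$T_beta,
                            VT = g$VT)
    est <- estimate_delta_p(N, g$p0, pars, replicates = replicates)
    c(analytic_dp = est$analytic_delta_p, simulated_dp = est$mean_delta_p,
      se = est$se)
  })
  res <- as.data.frame(do.call(rbind, res))
  grid$analytic_dp <- res$analytic_dp
  grid$simulated_dp <- res$simulated_dp
  grid$se <- res$se
  grid$z <- ifelse(res$se > 0,
                   (res$simulated_dp - res$analytic_dp) / res$se, 0)
  grid
}
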