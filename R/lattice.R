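#' Initialise a lattice with randomly placed altruist carriers
#'
#' Builds a rows x cols grid in which exactly `round(fraction * rows * cols)`
#' sites carry the altruism-inducing type (microbe alpha, or allele A in
#' genetic mode), placed uniformly at random without replacement; all other
#' sites carry the neutral type. The exact-count convention (rather than
#' per-site Bernoulli draws) keeps the initial proportion fixed across
#' replicates.
#'
#' @param dims integer vector `c(rows, cols)`.
#' @param fraction initial proportion of altruist carriers, in \[0, 1\].
#' @param seed optional integer seed.
#' @return An integer matrix (1 = altruist carrier, 0 = neutral) of class
#'   `altruism_lattice`.
#' @export
lattice_init_random <- function(dims = c(100, 100), fraction = 0.05,
                                seed = NULL) {
  stopifnot(length(dims) == 2, all(dims >= 1))
  check_proportion(fraction)
  if (!is.null(seed)) set.seed(seed)
  n <- prod(dims)
  k <- round(fraction * n)
  state <- integer(n)
  if (k > 0) state[sample.int(n, k)] <- 1L
  structure(matrix(state, nrow = dims[1], ncol = dims[2]),
            class = c("altruism_lattice", "matrix"))
}

#' Initialise a lattice with a central patch of altruist carriers
#'
#' Places a `side x side` block of altruist carriers at the grid centre
#' (rows 50-51, cols 50-51 on the default 100 x 100 grid), neutral carriers
#' elsewhere. Used for invasion-from-extreme-rarity experiments.
#'
#' @param dims integer vector `c(rows, cols)`.
#' @param side patch side length (0 gives an all-neutral grid).
#' @return An integer matrix of class `altruism_lattice`.
#' @export
lattice_init_patch <- function(dims = c(100, 100), side = 2) {
  stopifnot(length(dims) == 2, all(dims >= 1), side >= 0)
  if (side > min(dims)) stop("patch side exceeds the grid", call. = FALSE)
  m <- matrix(0L, nrow = dims[1], ncol = dims[2])
  if (side > 0) {
    r0 <- floor((dims[1] - side) / 2) + 1L
    c0 <- floor((dims[2] - side) / 2) + 1L
    m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
  }
  structure(m, class = c("altruism_lattice", "matrix"))
}

#' Moore neighbourhood of a lattice site
#'
#' The up-to-eight sites orthogonally or diagonally adjacent to a focal
#' site, truncated at the grid edges (the grid is not toroidal): interior
#' sites have 8 neighbours, non-corner edge sites 5, corners 3.
#'
#' @param dims integer vector `c(rows, cols)`.
#' @param site integer vector `c(row, col)`, 1-based.
#' @return A two-column matrix of neighbour coordinates (row, col).
#' @export
lattice_neighbourhood <- function(dims, site) {
  stopifnot(length(dims) == 2, length(site) == 2,
            site[1] >= 1, site[1] <= dims[1],
            site[2] >= 1, site[2] <= dims[2])
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  rr <- site[1] + d$dr
  cc <- site[2] + d$dc
  keep <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
  cbind(row = rr[keep], col = cc[keep])
}

#' Simulation configuration for the lattice model
#'
#' Bundles model parameters and run settings for [run_lattice_sim()].
#' Each generation, every host initiates `K` interactions (one per sweep,
#' in a freshly randomised order) with a uniformly chosen Moore neighbour;
#' payoffs accumulate on current states and, in microbe mode, horizontal
#' transmission is applied immediately after each interaction's payoff.
#' Fitness is the accumulated payoff normalised by the number of
#' interactions the host took part in. Reproduction follows Nowak and May:
#' each site is recolonised by a copy of the fittest host among the site
#' and its neighbours (ties broken uniformly at random), inheriting the
#' parent's end-of-generation carrier; with probability `1 - VT` the
#' offspring instead takes the carrier of a uniformly chosen member of the
#' old neighbourhood (site included). In genetic mode vertical transmission
#' is perfect and no horizontal transmission occurs.
#'
#' @param params an [altruism_params()] object.
#' @param dims lattice dimensions, default `c(100, 100)`.
#' @param K interactions initiated per host per generation.
#' @param mode `"microbe"` or `"genetic"`.
#' @param init either `list(random_fraction = f)` or
#'   `list(central_patch = side)`.
#' @param max_generation generation cap (a run still in progress there
#'   reports the proportion at the cap).
#' @param min_generation earliest generation at which the stabilisation
#'   rule may stop the run.
#' @param window smoothing window (generations) of the stabilisation rule.
#' @param tolerance stabilisation tolerance on the smoothed proportion.
#' @param upper_target upper absorbing proportion: 1 for fixation runs,
#'   0.05 for invasion-from-rarity runs.
#' @param seed integer seed for the run.
#' @return A `lattice_config` object.
#' @export
lattice_config <- function(params, dims = c(100, 100), K = 1,
                           mode = c("microbe", "genetic"),
                           init = list(random_fraction = 0.05),
                           max_generation = 10000, min_generation = 400,
                           window = 200, tolerance = 0.01,
                           upper_target = 1, seed = 1) {
  mode <- match.arg(mode)
  params <- as_params(params)
  stopifnot(K >= 1, window >= 1, tolerance > 0,
            max_generation >= 1, min_generation >= 0,
            upper_target > 0, upper_target <= 1)
  if (!is.list(init) || length(init) != 1 ||
      !names(init) %in% c("random_fraction", "central_patch")) {
    stop("'init' must be list(random_fraction=) or list(central_patch=)",
         call. = FALSE)
  }
  structure(
    list(params = params, dims = as.integer(dims), K = as.integer(K),
         mode = mode, init = init,
         max_generation = as.integer(max_generation),
         min_generation = as.integer(min_generation),
         window = as.integer(window), tolerance = tolerance,
         upper_target = upper_target, seed = as.integer(seed)),
    class = "lattice_config"
  )
}

init_from_config <- function(config) {
  if (names(config$init) == "random_fraction") {
    lattice_init_random(config$dims, config$init$random_fraction)
  } else {
    lattice_init_patch(config$dims, config$init$central_patch)
  }
}

#' Run one lattice generation
#'
#' Executes the interaction, fitness, reproduction and vertical-transmission
#' phases of a single generation (see [lattice_config()] for the schedule)
#' and returns the new grid together with the per-site bookkeeping, which
#' is useful for testing and inspection. Uses R's RNG stream; seed with
#' `set.seed()`.
#'
#' @param lattice an integer state matrix (e.g. from
#'   [lattice_init_random()]).
#' @param params an [altruism_params()] object.
#' @param K interactions initiated per host.
#' @param mode `"microbe"` or `"genetic"`.
#' @return A list: `lattice` (new state matrix), `p` (altruist proportion
#'   after reproduction), `fitness`, `payoff_sum`, `interaction_count`,
#'   `post_interaction` (state matrix after interactions, before
#'   reproduction).
#' @export
run_lattice_generation <- function(lattice, params, K = 1,
                                   mode = c("microbe", "genetic")) {
  mode <- match.arg(mode)
  params <- as_params(params)
  dims <- dim(lattice)
  res <- lattice_generation_cpp(
    as.integer(t(lattice)), dims[1], dims[2],
    params$b, params$c, params$b_g, params$c_g,
    params$T_alpha, params$T_beta, params$VT, as.integer(K),
    mode == "microbe"
  )
  shape <- function(v) matrix(v, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  list(
    lattice = structure(shape(res$state),
                        class = c("altruism_lattice", "matrix")),
    p = res$p,
    fitness = shape(res$fitness),
    payoff_sum = shape(res$payoff_sum),
    interaction_count = shape(res$interaction_count),
    post_interaction = shape(res$post_interaction_state)
  )
}

#' Run a lattice simulation to its stopping point
#'
#' Iterates generations until the altruist proportion reaches an absorbing
#' target (0, or `upper_target`), stabilises (the 200-generation smoothed
#' proportion changing by no more than the tolerance; see [is_stable()]),
#' or hits the generation cap, in which case the reported proportion is the
#' one at the cap.
#'
#' @param config a [lattice_config()] object.
#' @param record_trajectory keep the per-generation proportion trajectory
#'   (default `TRUE`).
#' @return A `lattice_result` object: list with `outcome` (one of
#'   `"extinct"`, `"fixed"`, `"reached_target"`, `"stabilized"`,
#'   `"max_generations"`), `final_p`, `p0`, `generations`, `final_state`,
#'   `p_trajectory` (if recorded) and the `config`.
#' @examples
#' pars <- altruism_params(b = 1, c = 0.05, T_alpha = 0.1, T_beta = 0.1)
#' cfg <- lattice_config(pars, dims = c(20, 20), max_generation = 50,
#'                       seed = 42)
#' run_lattice_sim(cfg)
#' @export
run_lattice_sim <- function(config, record_trajectory = TRUE) {
  stopifnot(inherits(config, "lattice_config"))
  set.seed(config$seed)
  lattice <- init_from_config(config)
  params <- config$params
  res <- lattice_run_cpp(
    as.integer(t(lattice)), config$dims[1], config$dims[2],
    params$b, params$c, params$b_g, params$c_g,
    params$T_alpha, params$T_beta, params$VT, config$K,
    config$mode == "microbe",
    config$max_generation, config$min_generation,
    config$window, config$tolerance, config$upper_target,
    record_trajectory
  )
  outcome <- c("extinct", "fixed", "reached_target", "stabilized",
               "max_generations")[res$outcome + 1L]
  out <- list(
    outcome = outcome,
    final_p = res$final_p,
    p0 = res$p0,
    generations = res$generations,
    final_state = matrix(res$final_state, nrow = config$dims[1],
                         ncol = config$dims[2], byrow = TRUE),
    config = config
  )
  if (record_trajectory) out$p_trajectory <- res$p_trajectory
  structure(out, class = "lattice_result")
}

#' @export
print.lattice_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Lattice simulation (%dx%d, %s mode, K=%d, seed=%d)\n",
              cfg$dims[1], cfg$dims[2], cfg$mode, cfg$K, cfg$seed))
  cat(sprintf("  b/c = %g, T_alpha = %g, T_beta = %g, VT = %g\n",
              cfg$params$b / cfg$params$c, cfg$params$T_alpha,
              cfg$params$T_beta, cfg$params$VT))
  cat(sprintf("  outcome: %s after %d generations; p: %.4g -> %.4g\n",
              x$outcome, x$generations, x$p0, x$final_p))
  invisible(x)
}

#' @export
plot.lattice_result <- function(x, ...) {
  if (is.null(x$p_trajectory)) {
    stop("trajectory was not recorded", call. = FALSE)
  }
  plot(seq_along(x$p_trajectory), x$p_trajectory, type = "l",
       xlab = "generation", ylab = "proportion of altruist carriers",
       ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
summary.lattice_result <- function(object, ...) {
  cat(sprintf("outcome=%s generations=%d p0=%.4g final_p=%.4g\n",
              object$outcome, object$generations, object$p0, object$final_p))
  invisible(object)
}

#' Stabilisation rule for a proportion trajectory
#'
#' The trajectory is considered stable at generation `g` when the smoothed
#' proportion — the mean over the trailing 200-generation window — differs
#' from the smoothed value 200 generations earlier by at most the
#' tolerance: `|pbar(g) - pbar(g - window)| <= tolerance`, evaluated only
#' for `g > min_generation`. Smoothing removes generation-to-generation
#' fluctuation, so e.g. a period-2 oscillation counts as stable while a
#' slow steady ramp does not.
#'
#' @param p_history numeric vector of per-generation proportions
#'   (`p_history[g]` is the proportion at generation `g`).
#' @param window smoothing window length (default 200 generations).
#' @param tolerance maximal allowed change of the smoothed proportion
#'   (default 0.01).
#' @param current_generation generation at which to evaluate the rule;
#'   defaults to `length(p_history)`.
#' @param min_generation earliest eligible generation (default 400).
#' @return Logical.
#' @export
is_stable <- function(p_history, window = 200, tolerance = 0.01,
                      current_generation = length(p_history),
                      min_generation = 400) {
  g <- current_generation
  if (g > length(p_history)) {
    stop("insufficient history for the requested generation", call. = FALSE)
  }
  if (g <= min_generation || g < 2 * window) return(FALSE)
  m1 <- mean(p_history[(g - window + 1):g])
  m2 <- mean(p_history[(g - 2 * window + 1):(g - window)])
  abs(m1 - m2) <= tolerance
}
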