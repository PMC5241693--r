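#' Proportion of alpha-carriers after interactions
#'
#' One round of random pairwise interactions in an infinite fully mixed
#' population changes the proportion of hosts carrying the
#' altruism-inducing microbe from `p` to
#' `p + p(1-p)(T_alpha - T_beta)`: discordant pairs arise with frequency
#' `2p(1-p)` and each contributes an expected `1 + T_alpha - T_beta`
#' alpha-carriers after the transmission lottery.
#'
#' @param p proportion of newborn hosts carrying the alpha microbe, in
#'   \[0, 1\] (vectorised).
#' @param params an [altruism_params()] object.
#' @return The post-interaction proportion, same length as `p`.
#' @export
post_interaction_proportion <- function(p, params) {
  params <- as_params(params)
  check_proportion(p)
  p + p * (1 - p) * (params$T_alpha - params$T_beta)
}

#' Mean population fitness
#'
#' Mean fitness of the fully mixed population at alpha-proportion `p`:
#' `1 + b_g - c_g + p(b - c)`, the pairing-frequency-weighted average of
#' `1 +` payoff over the three pair types.
#'
#' @inheritParams post_interaction_proportion
#' @return Mean fitness (vectorised over `p`).
#' @export
mean_fitness <- function(p, params) {
  params <- as_params(params)
  check_proportion(p)
  1 + params$b_g - params$c_g + p * (params$b - params$c)
}

#' Next-generation proportion of alpha-carriers
#'
#' The deterministic recursion of the fully mixed model. A newborn carries
#' microbe alpha either because its parent carried alpha after the
#' interaction round and transmitted vertically (probability `VT`,
#' fitness-weighted over parents), or because vertical transmission failed
#' (probability `1 - VT`) and the newborn picked up a random microbe from
#' the post-interaction parent population:
#'
#' `p' = VT * W + (1 - VT) * p_tilde`
#'
#' where `p_tilde` is [post_interaction_proportion()] and
#' `W = [p^2 f_aa + p(1-p)(f_ab (1-T_beta) + f_ba T_alpha)] / wbar`
#' with `f_aa = 1 + b_g + b - c_g - c` (alpha paired with alpha),
#' `f_ab = 1 + b_g - c_g - c` (alpha paired with beta, stays alpha with
#' probability `1 - T_beta`) and `f_ba = 1 + b_g + b - c_g` (beta paired
#' with alpha, becomes alpha with probability `T_alpha`).
#'
#' @inheritParams post_interaction_proportion
#' @return Next-generation proportion, same length as `p`.
#' @export
next_generation_proportion <- function(p, params) {
  params <- as_params(params)
  check_proportion(p)
  wbar <- mean_fitness(p, params)
  if (any(wbar <= 0)) {
    stop("mean fitness must be positive", call. = FALSE)
  }
  B <- 1 + params$b_g - params$c_g
  f_aa <- B + params$b - params$c
  f_ab <- B - params$c
  f_ba <- B + params$b
  W <- (p^2 * f_aa +
          p * (1 - p) * (f_ab * (1 - params$T_beta) + f_ba * params$T_alpha)) / wbar
  ptilde <- post_interaction_proportion(p, params)
  pmin(1, pmax(0, params$VT * W + (1 - params$VT) * ptilde))
}

#' Spread condition for the altruism-inducing microbe
#'
#' Whether the proportion of alpha-carriers increases from one generation
#' to the next at the current proportion `p`. Equivalent closed form:
#'
#' `VT * [b T_alpha - c(1 - T_beta) - (1 + b_g - c_g)(T_beta - T_alpha)] / wbar(p)
#'   + (1 - VT)(T_alpha - T_beta) > 0`
#'
#' Special cases: with `VT = 1` the condition is independent of `p`
#' (so when it holds, alpha increases to fixation); with
#' `b_g = c_g = 0` it reduces to
#' `b T_alpha > c(1 - T_beta) + (T_beta - T_alpha)`; with
#' `T_alpha = T_beta = T > 0` and `b_g = c_g = 0` it is
#' `b/c > (1 - T)/T` for any `VT > 0`.
#'
#' @param params an [altruism_params()] object.
#' @param p current proportion in (0, 1) (vectorised).
#' @return Logical: `TRUE` where the proportion increases.
#' @export
spread_condition <- function(params, p) {
  params <- as_params(params)
  check_proportion(p, open = TRUE)
  spread_margin(params, p) > 0
}

# signed margin of the spread condition; positive iff p' > p
spread_margin <- function(params, p) {
  B <- 1 + params$b_g - params$c_g
  core <- params$b * params$T_alpha -
    params$c * (1 - params$T_beta) -
    B * (params$T_beta - params$T_alpha)
  params$VT * core / mean_fitness(p, params) +
    (1 - params$VT) * (params$T_alpha - params$T_beta)
}

#' Critical benefit-cost ratio for invasion
#'
#' The minimal `b/c` allowing the altruism-inducing microbe to invade from
#' rarity, i.e. the infimum of `b/c` over which the spread condition holds
#' in the rare-invader limit `p -> 0` (where the mean fitness tends to
#' `1 + b_g - c_g`). Returns `Inf` when no finite benefit satisfies the
#' condition (e.g. `T_alpha = 0`: altruism cannot evolve without horizontal
#' transmission of the inducing microbe). For `T_alpha = T_beta = T` and
#' `b_g = c_g = 0` the threshold is exactly `(1 - T)/T` for every
#' `VT > 0`.
#'
#' @param T_alpha,T_beta horizontal transmission probabilities.
#' @param c cost of the altruistic act (must be positive; the threshold
#'   ratio depends on `c` only through the baseline terms).
#' @param VT vertical transmission fidelity.
#' @param b_g,c_g baseline genetic benefit and cost.
#' @param method `"closed_form"` solves the rare-invader condition
#'   algebraically; `"bisection"` brackets the threshold numerically on the
#'   recursion itself (used as an internal cross-check).
#' @return The critical `b/c` ratio (possibly 0 when any `b > c` invades),
#'   or `Inf`.
#' @examples
#' critical_bc_ratio(T_alpha = 0.1, T_beta = 0.1, c = 0.05)  # 9
#' critical_bc_ratio(T_alpha = 0, T_beta = 0.1, c = 0.05)    # Inf
#' @export
critical_bc_ratio <- function(T_alpha, T_beta, c, VT = 1, b_g = 0, c_g = 0,
                              method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  stopifnot(c > 0)
  B <- 1 + b_g - c_g
  if (method == "bisection") {
    return(critical_bc_bisect(T_alpha, T_beta, c, VT, b_g, c_g))
  }
  # rare-invader margin as a function of b:
  #   VT * (b*Ta - c*(1-Tb) - B*(Tb-Ta)) / B + (1-VT)*(Ta-Tb) > 0
  slope <- VT * T_alpha / B
  intercept <- VT * (-c * (1 - T_beta) - B * (T_beta - T_alpha)) / B +
    (1 - VT) * (T_alpha - T_beta)
  if (slope <= 0) {
    return(if (intercept > 0) 0 else Inf)
  }
  b_star <- -intercept / slope
  max(b_star / c, 0)
}

# numeric cross-check: bisection on b over the rare-invader spread margin,
# evaluated through the recursion at a small p
critical_bc_bisect <- function(T_alpha, T_beta, c, VT, b_g, c_g,
                               p_small = 1e-9, bc_max = 1e7, tol = 1e-9) {
  holds <- function(bc) {
    # margin is evaluated directly so bc below the PD bound can bracket
    pars <- list(b = bc * c, c = c, b_g = b_g, c_g = c_g,
                 T_alpha = T_alpha, T_beta = T_beta, VT = VT)
    class(pars) <- "altruism_params"
    spread_margin(pars, p_small) > 0
  }
  if (holds(0)) return(0)
  if (!holds(bc_max)) return(Inf)
  lo <- 0
  hi <- bc_max
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (holds(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Allele-frequency recursion for genetically encoded altruism
#'
#' The control model in which altruism is encoded by a host allele `A`
#' (cost `c_g_allele`, partner benefit `b_g_allele`) with perfect vertical
#' inheritance and no horizontal transmission:
#'
#' `p' = p (1 - c_g_allele + p b_g_allele) / (1 + p (b_g_allele - c_g_allele))`
#'
#' For any positive cost, `p' < p` on (0, 1): genetically encoded altruism
#' cannot evolve in a fully mixed population.
#'
#' @param p allele-A proportion in \[0, 1\] (vectorised).
#' @param b_g_allele benefit conferred by an A-carrier (must exceed the cost).
#' @param c_g_allele cost paid by an A-carrier, in (0, 1).
#' @return Next-generation allele-A proportion.
#' @export
genetic_next_generation <- function(p, b_g_allele, c_g_allele) {
  check_proportion(p)
  stopifnot(c_g_allele > 0, c_g_allele < 1, b_g_allele > c_g_allele)
  denom <- 1 + p * (b_g_allele - c_g_allele)
  if (any(denom <= 0)) stop("mean fitness must be positive", call. = FALSE)
  p * (1 - c_g_allele + p * b_g_allele) / denom
}

#' Iterate the fully mixed recursion
#'
#' Repeated application of [next_generation_proportion()] (or, for
#' `mode = "genetic"`, [genetic_next_generation()] with `b_g_allele = b`
#' and `c_g_allele = c`), recording the trajectory. Iteration stops early
#' once successive proportions differ by less than `tol` (fixed point).
#'
#' @param p0 initial proportion in \[0, 1\].
#' @param params an [altruism_params()] object.
#' @param generations maximum number of generations (>= 1).
#' @param mode `"microbe"` or `"genetic"`.
#' @param tol fixed-point tolerance on `|p' - p|`.
#' @return A `mixed_trajectory` object: data frame with columns
#'   `generation` (0-based) and `p`, plus attributes `converged` and
#'   `final_p`.
#' @export
iterate_mixed <- function(p0, params, generations,
                          mode = c("microbe", "genetic"), tol = 1e-12) {
  mode <- match.arg(mode)
  params <- as_params(params)
  check_proportion(p0)
  stopifnot(generations >= 1)
  p <- numeric(generations + 1)
  p[1] <- p0
  converged <- FALSE
  n <- generations
  for (g in seq_len(generations)) {
    p_next <- if (mode == "microbe") {
      next_generation_proportion(p[g], params)
    } else {
      genetic_next_generation(p[g], params$b, params$c)
    }
    p[g + 1] <- p_next
    if (abs(p_next - p[g]) < tol) {
      converged <- TRUE
      n <- g
      break
    }
  }
  out <- data.frame(generation = 0:n, p = p[seq_len(n + 1)])
  structure(out, class = c("mixed_trajectory", "data.frame"),
            converged = converged, final_p = p[n + 1], mode = mode)
}

#' @export
print.mixed_trajectory <- function(x, ...) {
  cat(sprintf("Fully mixed %s-mode trajectory: %d generations, p %.4g -> %.4g%s\n",
              attr(x, "mode"), nrow(x) - 1L, x$p[1], attr(x, "final_p"),
              if (attr(x, "converged")) " (converged)" else ""))
  invisible(x)
}

#' @export
plot.mixed_trajectory <- function(x, ...) {
  plot(x$generation, x$p, type = "l", xlab = "generation",
       ylab = "proportion of alpha-carriers", ylim = c(0, 1), ...)
  invisible(x)
}

check_proportion <- function(p, open = FALSE) {
  if (!is.numeric(p) || anyNA(p)) {
    stop("'p' must be numeric without NAs", call. = FALSE)
  }
  if (open) {
    if (any(p <= 0 | p >= 1)) {
      stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
    }
  } else if (any(p < 0 | p > 1)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}
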