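#' One generation of the finite well-mixed population
#'
#' Stochastic finite-N counterpart of the deterministic recursion, used as
#' an independent check. The population (a logical vector, `TRUE` = carries
#' the alpha microbe) is divided into N/2 pairs by a uniform random perfect
#' matching; each pair interacts once (payoff on current states, then one
#' horizontal-transmission draw); fitness is `1 +` payoff. The next
#' generation of size N is sampled with replacement with probability
#' proportional to fitness (Wright-Fisher style); each offspring inherits
#' its parent's post-interaction microbe with probability `VT`, otherwise
#' the microbe of a uniformly random individual from the post-interaction
#' parent population.
#'
#' @param carriers logical vector of even length: `TRUE` for alpha-carriers.
#' @param params an [altruism_params()] object.
#' @return Logical vector of the same length: the offspring generation.
#' @export
mixed_population_step <- function(carriers, params) {
  params <- as_params(params)
  N <- length(carriers)
  if (N %% 2L != 0L) stop("population size must be even", call. = FALSE)
  ord <- sample.int(N)
  i1 <- ord[seq_len(N / 2L)]
  i2 <- ord[(N / 2L + 1L):N]
  a1 <- carriers[i1]
  a2 <- carriers[i2]

  fit <- numeric(N)
  fit[i1] <- 1 + (params$b_g + params$b * a2) - (params$c_g + params$c * a1)
  fit[i2] <- 1 + (params$b_g + params$b * a1) - (params$c_g + params$c * a2)
  if (any(fit <= 0)) {
    stop("individual fitness must be positive (1 + payoff > 0)", call. = FALSE)
  }

  post <- carriers
  disc <- which(a1 != a2)
  if (length(disc) > 0 && (params$T_alpha > 0 || params$T_beta > 0)) {
    ia <- ifelse(a1[disc], i1[disc], i2[disc])  # alpha host of each pair
    ib <- ifelse(a1[disc], i2[disc], i1[disc])  # beta host of each pair
    ta <- stats::runif(length(disc)) < params$T_alpha
    tb <- stats::runif(length(disc)) < params$T_beta
    post[ib[ta]] <- TRUE   # alpha establishes in the beta host
    post[ia[tb]] <- FALSE  # beta establishes in the alpha host
  }

  parents <- sample.int(N, N, replace = TRUE, prob = fit)
  offspring <- post[parents]
  if (params$VT < 1) {
    miss <- stats::runif(N) >= params$VT
    n_miss <- sum(miss)
    if (n_miss > 0) {
      offspring[miss] <- post[sample.int(N, n_miss, replace = TRUE)]
    }
  }
  offspring
}

#' Monte-Carlo estimate of the one-generation change in p
#'
#' Runs `replicates` independent one-generation steps of the finite
#' well-mixed model from an exact initial count `round(p0 * N)` of
#' alpha-carriers, and returns the mean and standard error of the change in
#' the alpha proportion. Used to validate [next_generation_proportion()]:
#' as N grows the mean change converges to the deterministic recursion.
#'
#' @param N even population size.
#' @param p0 initial proportion of alpha-carriers.
#' @param params an [altruism_params()] object.
#' @param replicates number of independent replicates (>= 2).
#' @param seed optional integer seed.
#' @return A list with `mean_delta_p`, `se`, `replicates`, `N`,
#'   `analytic_delta_p` (the deterministic prediction).
#' @export
estimate_delta_p <- function(N, p0, params, replicates = 200, seed = NULL) {
  params <- as_params(params)
  stopifnot(replicates >= 2, N %% 2L == 0L)
  check_proportion(p0)
  if (!is.null(seed)) set.seed(seed)
  n_alpha <- round(p0 * N)
  if (n_alpha == 0L || n_alpha == N) {
    return(list(mean_delta_p = 0, se = 0, replicates = replicates, N = N,
                analytic_delta_p = 0))
  }
  base <- c(rep(TRUE, n_alpha), rep(FALSE, N - n_alpha))
  dp <- vapply(seq_len(replicates), function(r) {
    mean(mixed_population_step(base, params)) - n_alpha / N
  }, numeric(1))
  list(
    mean_delta_p = mean(dp),
    se = stats::sd(dp) / sqrt(replicates),
    replicates = replicates,
    N = N,
    analytic_delta_p = next_generation_proportion(n_alpha / N, params) - n_alpha / N
  )
}
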