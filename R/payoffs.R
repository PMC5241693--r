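#' Pairwise interaction payoffs
#'
#' Computes the prisoner's-dilemma payoffs of one pairwise interaction.
#' Each participant pays its own cost and receives the benefit generated by
#' its partner: an altruist (microbe-alpha carrier, or allele-A host) pays
#' `c_g + c` and confers `b_g + b`; a non-altruist pays `c_g` and confers
#' `b_g`. The roles of initiator and partner are irrelevant to the payoff.
#' Payoffs are evaluated on the pair's states *before* any horizontal
#' transmission in the same interaction: behaviour is attributed to the
#' resident microbe.
#'
#' @param state_i,state_j [agent_state()] objects in the same mode.
#' @param params an [altruism_params()] object.
#' @return Numeric vector of length 2: the payoffs of `state_i` and
#'   `state_j`.
#' @examples
#' p <- altruism_params(b = 3, c = 0.05)
#' pair_payoffs(agent_state("alpha"), agent_state("beta"), p)  # -c, b
#' @export
pair_payoffs <- function(state_i, state_j, params) {
  params <- as_params(params)
  check_same_mode(state_i, state_j)
  ai <- state_i$altruist
  aj <- state_j$altruist
  c(
    (params$b_g + params$b * aj) - (params$c_g + params$c * ai),
    (params$b_g + params$b * ai) - (params$c_g + params$c * aj)
  )
}

#' Horizontal-transmission outcome distribution
#'
#' The probability distribution over post-interaction microbe states of an
#' interacting pair. Transmission and establishment of one microbe is
#' independent of the other; when both transmit they do so simultaneously,
#' so the pair swaps microbes. Concordant pairs are unchanged with
#' probability 1. Alleles do not transmit horizontally, so genetic-mode
#' states are rejected.
#'
#' @inheritParams pair_payoffs
#' @return A data frame with columns `post_i`, `post_j` (carrier labels) and
#'   `prob`; probabilities sum to 1.
#' @examples
#' p <- altruism_params(b = 3, c = 0.05, T_alpha = 0.5, T_beta = 0.5)
#' transmission_distribution(agent_state("alpha"), agent_state("beta"), p)
#' @export
transmission_distribution <- function(state_i, state_j, params) {
  params <- as_params(params)
  check_same_mode(state_i, state_j)
  if (state_i$mode != "microbe") {
    stop("horizontal transmission applies to microbe-mode states only",
         call. = FALSE)
  }
  ci <- state_i$carrier
  cj <- state_j$carrier
  if (ci == cj) {
    return(data.frame(post_i = ci, post_j = cj, prob = 1,
                      stringsAsFactors = FALSE))
  }
  Ta <- params$T_alpha
  Tb <- params$T_beta
  # orient so host "a" carries alpha, host "b" carries beta
  if (ci == "alpha") {
    out <- data.frame(
      post_i = c("alpha", "beta", "beta",        "alpha"),
      post_j = c("alpha", "beta", "alpha",       "beta"),
      prob   = c(Ta * (1 - Tb), Tb * (1 - Ta), Ta * Tb, (1 - Ta) * (1 - Tb)),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      post_i = c("alpha", "beta", "alpha",       "beta"),
      post_j = c("alpha", "beta", "beta",        "alpha"),
      prob   = c(Ta * (1 - Tb), Tb * (1 - Ta), Ta * Tb, (1 - Ta) * (1 - Tb)),
      stringsAsFactors = FALSE
    )
  }
  out
}
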