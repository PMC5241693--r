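#' Model parameters for microbe-induced altruism
#'
#' Bundles the evolutionary parameters of the model and validates them.
#' Hosts carrying the altruism-inducing microbe (type alpha) pay an extra
#' interaction cost `c` and confer an extra benefit `b` on their partner,
#' on top of a shared genetic baseline (`b_g`, `c_g`) paid and conferred by
#' every host. Microbes transmit horizontally during interactions
#' (`T_alpha`, `T_beta`: per-interaction probability that the microbe
#' transmits to, and establishes in, the partner) and vertically at
#' reproduction with fidelity `VT` (with probability `1 - VT` the offspring
#' picks up a random microbe from the parent population or neighbourhood
#' instead).
#'
#' The model's intended domain is the prisoner's dilemma regime
#' `0 < c < 1`, `b > c`; the constructor also admits the boundary cases
#' (`b = c`, or `b = c = 0` for neutral-drift controls) so that behaviour
#' at and below the invasion threshold can be examined.
#'
#' @param b fitness benefit conferred by the microbe-induced altruistic act
#'   (non-negative; `b > c` in the prisoner's dilemma regime).
#' @param c fitness cost of the act, in \[0, 1).
#' @param b_g baseline genetic benefit conferred by every host (default 0).
#' @param c_g baseline genetic cost paid by every host (default 0); a uniform
#'   cost of microbe carriage folds into `c_g`, a differential one into `c`.
#' @param T_alpha horizontal transmission/establishment probability of the
#'   altruism-inducing microbe, in \[0, 1\].
#' @param T_beta same for the neutral microbe.
#' @param VT vertical transmission fidelity, in \[0, 1\].
#'
#' @return An object of class `altruism_params` (a validated list).
#' @examples
#' altruism_params(b = 0.45, c = 0.05, T_alpha = 0.1, T_beta = 0.1, VT = 1)
#' @export
altruism_params <- function(b, c, b_g = 0, c_g = 0,
                            T_alpha = 0, T_beta = 0, VT = 1) {
  stopifnot(
    is.numeric(b), length(b) == 1L, is.finite(b),
    is.numeric(c), length(c) == 1L, is.finite(c)
  )
  if (c < 0 || c >= 1) {
    stop("'c' must lie in [0, 1)", call. = FALSE)
  }
  if (b < 0) {
    stop("'b' must be non-negative", call. = FALSE)
  }
  for (nm in c("T_alpha", "T_beta", "VT")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  if (!is.numeric(c_g) || c_g < 0) {
    stop("'c_g' must be non-negative", call. = FALSE)
  }
  if (c_g > 0 || b_g != 0) {
    if (!(b_g > c_g)) {
      stop("baseline altruism requires b_g > c_g", call. = FALSE)
    }
    if (!(1 + b_g - c_g > 0)) {
      stop("baseline must keep mean fitness positive (1 + b_g - c_g > 0)",
           call. = FALSE)
    }
  }
  structure(
    list(b = b, c = c, b_g = b_g, c_g = c_g,
         T_alpha = T_alpha, T_beta = T_beta, VT = VT),
    class = "altruism_params"
  )
}

#' @export
print.altruism_params <- function(x, ...) {
  cat("Microbe-induced altruism parameters\n")
  cat(sprintf("  payoff:        b = %g, c = %g (b/c = %g)\n", x$b, x$c, x$b / x$c))
  cat(sprintf("  baseline:      b_g = %g, c_g = %g\n", x$b_g, x$c_g))
  cat(sprintf("  horizontal:    T_alpha = %g, T_beta = %g\n", x$T_alpha, x$T_beta))
  cat(sprintf("  vertical:      VT = %g\n", x$VT))
  invisible(x)
}

is_altruism_params <- function(x) inherits(x, "altruism_params")

as_params <- function(params) {
  if (!is_altruism_params(params)) {
    stop("'params' must be created by altruism_params()", call. = FALSE)
  }
  params
}

# Agent state encoding shared across modules: altruist carriers (microbe
# alpha, or allele A in genetic mode) are 1L; neutral carriers (microbe
# beta / allele E) are 0L.

#' Agent states
#'
#' Constructors for the two agent states used throughout the package.
#' In microbe mode an agent carries microbe `alpha` (manipulates its host
#' into altruistic behaviour) or `beta` (no behavioural effect); in genetic
#' mode the corresponding labels are allele `A` (altruist) and `E` (neutral).
#' States carry their mode so that operations can reject mixed-mode pairs
#' and refuse horizontal transmission of alleles.
#'
#' @param carrier `"alpha"` or `"beta"` (microbe mode); `"A"` or `"E"`
#'   (genetic mode).
#' @return An `agent_state` object.
#' @examples
#' agent_state("alpha")
#' agent_state("E")
#' @export
agent_state <- function(carrier) {
  carrier <- match.arg(carrier, c("alpha", "beta", "A", "E"))
  mode <- if (carrier %in% c("alpha", "beta")) "microbe" else "genetic"
  structure(
    list(carrier = carrier,
         altruist = carrier %in% c("alpha", "A"),
         mode = mode),
    class = "agent_state"
  )
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("<agent: %s (%s mode, %s)>\n", x$carrier, x$mode,
              if (x$altruist) "altruist" else "non-altruist"))
  invisible(x)
}

check_same_mode <- function(state_i, state_j) {
  if (!inherits(state_i, "agent_state") || !inherits(state_j, "agent_state")) {
    stop("states must be created by agent_state()", call. = FALSE)
  }
  if (state_i$mode != state_j$mode) {
    stop("mixed-mode agent pair: both states must be microbe or both genetic",
         call. = FALSE)
  }
  invisible(TRUE)
}
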