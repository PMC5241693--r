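# shared parameter builders for the test suite

base_params <- function(b = 3, c = 0.05, ...) {
  altruism_params(b = b, c = c, ...)
}

equal_T_params <- function(T, bc, c = 0.05, VT = 1) {
  altruism_params(b = bc * c, c = c, T_alpha = T, T_beta = T, VT = VT)
}

# enumeration oracle for the post-interaction proportion: average the
# expected number of alpha carriers over the three pair types directly
enum_post_interaction <- function(p, Ta, Tb) {
  pair_aa <- p^2              # both stay alpha
  pair_ab <- 2 * p * (1 - p)  # discordant: enumerate the transmission lottery
  outcomes <- rbind(
    c(n_alpha = 2, prob = Ta * (1 - Tb)),        # alpha establishes only
    c(n_alpha = 0, prob = Tb * (1 - Ta)),        # beta establishes only
    c(n_alpha = 1, prob = Ta * Tb),              # simultaneous swap
    c(n_alpha = 1, prob = (1 - Ta) * (1 - Tb))   # no transmission
  )
  e_disc <- sum(outcomes[, "n_alpha"] * outcomes[, "prob"])
  (pair_aa * 2 + pair_ab * e_disc) / 2
}
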