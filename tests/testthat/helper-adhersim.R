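# Shared test helpers.

# Noise-free parameters: barrier terms and effect sizes pinned at their
# means, so daily probabilities equal the closed-form compositions.
nf_params <- function(...) model_params(alpha_sd = 0, beta_sd = 0, ...)

# Mean of a Normal(mu, s) draw censored into [0, 1] (closed form).
clipped_normal_mean <- function(mu, s) {
  a <- (0 - mu) / s
  b <- (1 - mu) / s
  mu * (pnorm(b) - pnorm(a)) - s * (dnorm(b) - dnorm(a)) + (1 - pnorm(b))
}

# A small observation with history, for feature tests.
obs_with_history <- function(day = 10, reported = "disease",
                             outcomes = list(disease = integer(),
                                             medicine = integer(),
                                             remember = integer()),
                             flags = c(FALSE, FALSE)) {
  observation(1, day, reported, per_type_send_outcomes = outcomes,
              recent_sent_flags = flags)
}
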