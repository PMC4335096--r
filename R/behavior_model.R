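# Patient behavior model: daily barrier draws, message effects, fatigue,
# and the Bernoulli adherence outcome.

#' Message and barrier type labels
#'
#' The simulator recognises three adherence barriers, each addressable by a
#' matching SMS message type: `"disease"` (doubts that the illness is serious
#' enough to treat), `"medicine"` (concerns about the medication's safety or
#' efficacy) and `"remember"` (forgetfulness). `"none"` denotes the
#' no-message action, which is available only to the bandit arm of the
#' message-fatigue scenario; the comparator policies always send.
#'
#' @return `message_types()` returns the three sendable types;
#'   `message_actions()` appends `"none"`.
#' @export
message_types <- function() c("disease", "medicine", "remember")

#' @rdname message_types
#' @export
message_actions <- function() c(message_types(), "none")

#' Behavioral model parameters
#'
#' Bundles the distributional assumptions of the patient model. Each barrier
#' a patient actually has contributes a multiplicative term
#' `alpha ∈ [0, 1]` to the daily adherence probability; barrier terms are
#' redrawn every day from `Normal(alpha_mean, alpha_sd)` and bounded into
#' `[0, 1]`. A message matching a true barrier moves that term toward 1 by a
#' fraction `beta`, itself drawn daily from `Normal(beta_mean, beta_sd)` and
#' bounded. Under message fatigue the effective fraction is
#' `beta * fatigue_factor`, where the factor shrinks by `1 - fatigue_decay`
#' on each fatigued day (a message sent after messages on each of the
#' previous `fatigue_window` days) and otherwise grows by
#' `fatigue_recovery - 1` up to a cap of 1.
#'
#' @param alpha_mean,alpha_sd Mean and SD of the daily barrier-term draw.
#'   Defaults 0.65 and 0.30.
#' @param beta_mean,beta_sd Mean and SD of the daily matched-message effect
#'   size. Defaults 0.70 and 0.30.
#' @param fatigue_decay Per-day multiplier applied to the fatigue factor on
#'   fatigued days; default 0.95 (a 5% daily loss).
#' @param fatigue_recovery Per-day multiplier on non-fatigued days; default
#'   1.10 (a 10% daily recovery, capped at 1).
#' @param fatigue_window Number of consecutive prior send-days that triggers
#'   fatigue; default 2.
#' @param bound_method How out-of-range Gaussian draws are forced into
#'   `[0, 1]`: `"clip"` (default; values are censored at the bounds, so the
#'   realised mean of a 0.65/0.30 draw is about 0.634) or `"resample"`
#'   (draws from the truncated normal).
#' @return An object of class `adhersim_params`.
#' @examples
#' model_params()
#' model_params(alpha_sd = 0, beta_sd = 0) # noise-free, for analytic checks
#' @export
model_params <- function(alpha_mean = 0.65, alpha_sd = 0.30,
                         beta_mean = 0.70, beta_sd = 0.30,
                         fatigue_decay = 0.95, fatigue_recovery = 1.10,
                         fatigue_window = 2L,
                         bound_method = c("clip", "resample")) {
  bound_method <- match.arg(bound_method)
  stopifnot(alpha_mean >= 0, alpha_sd >= 0, beta_mean >= 0, beta_sd >= 0)
  if (fatigue_decay <= 0 || fatigue_decay > 1)
    stop("`fatigue_decay` must lie in (0, 1]", call. = FALSE)
  if (fatigue_recovery < 1)
    stop("`fatigue_recovery` must be >= 1", call. = FALSE)
  fatigue_window <- as.integer(fatigue_window)
  stopifnot(fatigue_window >= 1)
  structure(
    list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         beta_mean = beta_mean, beta_sd = beta_sd,
         fatigue_decay = fatigue_decay, fatigue_recovery = fatigue_recovery,
         fatigue_window = fatigue_window, bound_method = bound_method),
    class = "adhersim_params")
}

# Draw n values from Normal(mean, sd) forced into [0, 1].
# "clip" censors at the bounds; "resample" is an inverse-CDF truncated draw.
draw_bounded <- function(n, mean, sd, method = "clip") {
  if (sd == 0) return(rep(mean, n))
  if (method == "clip") {
    pmin(1, pmax(0, stats::rnorm(n, mean, sd)))
  } else {
    lo <- stats::pnorm(0, mean, sd)
    hi <- stats::pnorm(1, mean, sd)
    stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  }
}

#' Define a simulated patient
#'
#' A patient is defined by the barriers that truly drive their
#' non-adherence and by the barriers they reported on the baseline survey.
#' The two sets coincide except in the misreporting scenario, where the
#' medication-concern group reports forgetfulness instead.
#'
#' @param id Integer patient identifier.
#' @param true_barriers Non-empty subset of [message_types()].
#' @param reported_barriers Subset of [message_types()]; defaults to the
#'   true barriers.
#' @param group Optional group label (e.g. `"medicine_only"`).
#' @return An object of class `adhersim_patient`.
#' @examples
#' patient_spec(1, "medicine", reported_barriers = "remember")
#' @export
patient_spec <- function(id, true_barriers, reported_barriers = true_barriers,
                         group = NULL) {
  true_barriers <- unique(as.character(true_barriers))
  reported_barriers <- unique(as.character(reported_barriers))
  if (length(true_barriers) == 0)
    stop("every patient needs at least one true barrier", call. = FALSE)
  bad <- setdiff(c(true_barriers, reported_barriers), message_types())
  if (length(bad))
    stop("unknown barrier type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(
    list(id = as.integer(id), true_barriers = true_barriers,
         reported_barriers = reported_barriers, group = group),
    class = "adhersim_patient")
}

#' Draw one day's barrier terms for a patient
#'
#' Each barrier the patient actually has gets an independent
#' `Normal(alpha_mean, alpha_sd)` draw bounded into `[0, 1]`; barriers the
#' patient does not have are fixed at exactly 1 and carry no daily noise,
#' so the group baselines (65% for single-barrier patients, 42.25% for the
#' dual-barrier group) emerge from the product rule at the noise-free means.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param spec An [patient_spec()] object.
#' @param params A [model_params()] object.
#' @return Named numeric vector with components `disease`, `medicine`,
#'   `remember`, each in `[0, 1]`.
#' @export
draw_daily_alphas <- function(spec, params) {
  a <- c(disease = 1, medicine = 1, remember = 1)
  tb <- spec$true_barriers
  a[tb] <- draw_bounded(length(tb), params$alpha_mean, params$alpha_sd,
                        params$bound_method)
  a
}

#' Daily adherence probability from the barrier terms
#'
#' The probability that the patient takes the medication today is the
#' product of the three barrier terms:
#' `P(adherence) = alpha_disease * alpha_medicine * alpha_remember`.
#'
#' @param alphas Named numeric vector as returned by [draw_daily_alphas()];
#'   components outside `[0, 1]` are rejected (they indicate an upstream
#'   bounding bug).
#' @return A probability in `[0, 1]`.
#' @examples
#' adherence_probability(c(disease = 0.80, medicine = 0.70, remember = 0.90))
#' @export
adherence_probability <- function(alphas) {
  a <- unname(alphas[c("disease", "medicine", "remember")])
  if (anyNA(a) || length(a) != 3)
    stop("`alphas` must have components disease, medicine, remember",
         call. = FALSE)
  if (any(a < 0) || any(a > 1))
    stop("alpha components must lie in [0, 1]", call. = FALSE)
  prod(a)
}

#' Apply a message's same-day effect to the barrier terms
#'
#' A message only has an effect when its type matches one of the patient's
#' true barriers; then the matching term `a` moves toward 1 by the effective
#' fraction `beta * fatigue_factor`:
#' `a' = a + beta * fatigue_factor * (1 - a)`.
#' Mismatched messages and the no-message action leave the terms unchanged.
#' The effect is transient: it alters today's probability only and no
#' patient state is mutated (the bandit assumption that a message influences
#' only same-day adherence).
#'
#' @param alphas Named numeric vector of the day's barrier terms.
#' @param message One of [message_actions()].
#' @param true_barriers Character vector of the patient's true barriers.
#' @param beta Effect size in `[0, 1]` (already drawn and bounded).
#' @param fatigue_factor Multiplier in `(0, 1]`; 1 when fatigue is off.
#' @return The updated named vector of barrier terms.
#' @examples
#' a <- c(disease = 1, medicine = 0.65, remember = 1)
#' apply_message_effect(a, "medicine", "medicine", beta = 0.6) # -> 0.86
#' @export
apply_message_effect <- function(alphas, message, true_barriers, beta,
                                 fatigue_factor = 1) {
  stopifnot(message %in% message_actions())
  if (beta < 0 || beta > 1)
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  if (fatigue_factor <= 0 || fatigue_factor > 1)
    stop("`fatigue_factor` must lie in (0, 1]", call. = FALSE)
  if (message != "none" && message %in% true_barriers) {
    a <- alphas[[message]]
    alphas[[message]] <- a + beta * fatigue_factor * (1 - a)
  }
  alphas
}

#' Message-fatigue state
#'
#' Tracks the multiplicative fatigue factor and whether a message was sent
#' on each of the last `window` days. The factor starts at 1 (no fatigue)
#' and never exceeds 1.
#'
#' @param window Length of the recent-send window (default 2 days).
#' @return An object of class `adhersim_fatigue`.
#' @export
fatigue_state <- function(window = 2L) {
  structure(list(factor = 1, sent_history = rep(FALSE, as.integer(window))),
            class = "adhersim_fatigue")
}

#' Advance the fatigue state by one day
#'
#' A day is fatigued when a message is sent today after messages on each of
#' the previous `fatigue_window` days: the factor shrinks by
#' `fatigue_decay`. Otherwise it recovers by `fatigue_recovery`, capped at
#' 1. The update happens before the day's message effect is applied, so the
#' first triggering day is already attenuated. With `fatigue_enabled =
#' FALSE` the factor is pinned at 1.
#'
#' @param state A [fatigue_state()] object.
#' @param sent_today Logical; was any message sent today?
#' @param params A [model_params()] object.
#' @param fatigue_enabled Logical; fatigue is an environment property of the
#'   message-fatigue scenario only.
#' @return The updated state; `state$factor` is the multiplier to apply to
#'   today's message effect.
#' @export
update_fatigue <- function(state, sent_today, params, fatigue_enabled = TRUE) {
  if (!fatigue_enabled) {
    state$factor <- 1
  } else if (sent_today && all(state$sent_history)) {
    state$factor <- state$factor * params$fatigue_decay
  } else {
    state$factor <- min(1, state$factor * params$fatigue_recovery)
  }
  state$sent_history <- c(state$sent_history[-1], sent_today)
  state
}

#' Simulate one patient-day
#'
#' Composes the daily model: advance fatigue, draw the barrier terms, draw
#' the day's effect size, apply the message effect, form the adherence
#' probability, and draw the binary adherence outcome (a perfect daily
#' pill-cap sensor is assumed).
#'
#' @inheritParams update_fatigue
#' @param spec A [patient_spec()] object.
#' @param fstate A [fatigue_state()] object.
#' @param action One of [message_actions()].
#' @return A list with `adhered` (logical), `prob` (the day's adherence
#'   probability) and `fstate` (updated fatigue state).
#' @export
simulate_patient_day <- function(spec, fstate, action, params,
                                 fatigue_enabled = FALSE) {
  fstate <- update_fatigue(fstate, action != "none", params, fatigue_enabled)
  alphas <- draw_daily_alphas(spec, params)
  beta <- draw_bounded(1, params$beta_mean, params$beta_sd,
                       params$bound_method)
  alphas <- apply_message_effect(alphas, action, spec$true_barriers, beta,
                                 fstate$factor)
  p <- adherence_probability(alphas)
  list(adhered = stats::runif(1) < p, prob = p, fstate = fstate)
}

#' Mid-course barrier change
#'
#' In the barrier-change scenario, on and after the change day (day 90 by
#' default) every patient whose only barrier was medication concern has that
#' concern resolve and a disease-severity doubt appear instead:
#' `true_barriers` becomes `"disease"`. The reported barriers are left
#' untouched, so the survey-tailored arm keeps its now-stale targeting.
#' Other groups and other scenarios are unaffected.
#'
#' @param spec A [patient_spec()] object.
#' @param day 1-based day index.
#' @param scenario Scenario id (the change applies in scenario 2 only).
#' @param change_day Day the change takes effect (default 90).
#' @return The (possibly updated) patient spec.
#' @export
apply_barrier_change <- function(spec, day, scenario, change_day = 90L) {
  if (scenario == 2 && day >= change_day &&
      identical(spec$true_barriers, "medicine")) {
    spec$true_barriers <- "disease"
  }
  spec
}

#' @export
print.adhersim_params <- function(x, ...) {
  cat("Adherence model parameters\n")
  cat(sprintf("  barrier term:  Normal(%.2f, %.2f), bounded by '%s'\n",
              x$alpha_mean, x$alpha_sd, x$bound_method))
  cat(sprintf("  effect size:   Normal(%.2f, %.2f)\n", x$beta_mean, x$beta_sd))
  cat(sprintf("  fatigue:       decay %.2f / recovery %.2f, window %d days\n",
              x$fatigue_decay, x$fatigue_recovery, x$fatigue_window))
  invisible(x)
}

#' @export
print.adhersim_patient <- function(x, ...) {
  cat(sprintf("Patient %d%s\n", x$id,
              if (is.null(x$group)) "" else paste0(" (", x$group, ")")))
  cat("  true barriers:    ", paste(x$true_barriers, collapse = ", "), "\n")
  cat("  reported barriers:", paste(x$reported_barriers, collapse = ", "), "\n")
  invisible(x)
}
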