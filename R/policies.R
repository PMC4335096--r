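# Comparator message-selection policies and the feature construction
# shared with the bandit arm.

#' Per-patient daily observation
#'
#' The information a policy may use when choosing today's message for one
#' patient: the baseline-survey report and the recent interaction history.
#' `per_type_send_outcomes` holds, for each message type, the binary
#' adherence outcomes that followed the most recent (up to 5) days that
#' type was sent to this patient; `recent_sent_flags` records whether any
#' message was sent on each of the previous 2 days (oldest first).
#'
#' @param patient_id Integer id.
#' @param day 1-based day index.
#' @param reported_barriers Character vector of barriers reported at
#'   baseline.
#' @param per_type_send_outcomes Named list (`disease`, `medicine`,
#'   `remember`) of 0/1 vectors, each of length at most 5.
#' @param recent_sent_flags Logical vector of length 2.
#' @return An object of class `adhersim_obs`.
#' @export
observation <- function(patient_id, day, reported_barriers,
                        per_type_send_outcomes = list(
                          disease = integer(), medicine = integer(),
                          remember = integer()),
                        recent_sent_flags = c(FALSE, FALSE)) {
  stopifnot(length(recent_sent_flags) == 2)
  per_type_send_outcomes <- per_type_send_outcomes[message_types()]
  if (any(lengths(per_type_send_outcomes) > 5))
    stop("per-type outcome windows hold at most the last 5 sends",
         call. = FALSE)
  structure(
    list(patient_id = as.integer(patient_id), day = as.integer(day),
         reported_barriers = as.character(reported_barriers),
         per_type_send_outcomes = per_type_send_outcomes,
         recent_sent_flags = as.logical(recent_sent_flags)),
    class = "adhersim_obs")
}

#' Comparator policies
#'
#' The three non-adaptive strategies the bandit is compared against. All
#' three send a message every day and never choose the no-message action.
#'
#' * `reminder_policy()` always sends a remembering-strategy message.
#' * `random_policy()` draws uniformly among the three message types.
#' * `tailored_policy()` sends a message matching a barrier the patient
#'   reported at baseline: the single reported barrier every day, or (for
#'   patients reporting several) either a uniform random choice among them
#'   (`rule = "random"`, default) or a deterministic day-indexed rotation
#'   (`rule = "alternate"`). Tailoring never adapts to outcomes.
#'
#' @param obs An [observation()] object.
#' @param rule Multi-barrier tailoring rule, `"random"` or `"alternate"`.
#' @return One of [message_types()].
#' @export
reminder_policy <- function(obs) "remember"

#' @rdname reminder_policy
#' @export
random_policy <- function(obs) {
  message_types()[sample.int(3L, 1L)]
}

#' @rdname reminder_policy
#' @export
tailored_policy <- function(obs, rule = c("random", "alternate")) {
  rule <- match.arg(rule)
  rb <- obs$reported_barriers
  if (length(rb) == 0)
    stop("tailoring requires a non-empty set of reported barriers",
         call. = FALSE)
  if (length(rb) == 1) return(rb)
  if (rule == "random") {
    rb[sample.int(length(rb), 1L)]
  } else {
    sort(rb)[((obs$day - 1L) %% length(rb)) + 1L]
  }
}

#' Build the context feature vector for the bandit
#'
#' Fixed layout, all entries in `[0, 1]`:
#' 1. an intercept (1.0);
#' 2. three indicators for the barriers reported at baseline (the bandit's
#'    initial weighting toward the survey, like the tailored arm);
#' 3. three recent-success fractions: for each message type, the fraction
#'    of adherent days among the outcomes that followed the last (up to 5)
#'    sends of that type, with 0.5 as an uninformative prior before the
#'    type has ever been sent;
#' 4. in the message-fatigue scenario only, the two prior-day sent
#'    indicators.
#'
#' Length 7 in scenarios 1-2 and 9 in scenario 3.
#'
#' @param obs An [observation()] object.
#' @param scenario Scenario id in `1:3`.
#' @return Named numeric feature vector.
#' @examples
#' build_features(observation(1, 1, "disease"), scenario = 1)
#' @export
build_features <- function(obs, scenario = 1) {
  frac <- vapply(message_types(), function(t) {
    o <- obs$per_type_send_outcomes[[t]]
    if (length(o) == 0) 0.5 else mean(o)
  }, numeric(1))
  x <- c(intercept = 1,
         stats::setNames(as.numeric(message_types() %in% obs$reported_barriers),
                         paste0("rep_", message_types())),
         stats::setNames(frac, paste0("succ_", message_types())))
  if (scenario == 3) {
    x <- c(x, sent_lag2 = as.numeric(obs$recent_sent_flags[1]),
           sent_lag1 = as.numeric(obs$recent_sent_flags[2]))
  }
  x
}

# Feature vector length for a scenario.
feature_length <- function(scenario) if (scenario == 3) 9L else 7L
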