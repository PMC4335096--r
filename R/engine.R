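# Scenario construction and the Monte Carlo loop:
# cohort x horizon x replications x policies, with per-day aggregation.

POLICIES <- c("reminder", "random", "tailored", "rl")

#' Configure a simulation scenario
#'
#' The three stress-test scenarios share a cohort of 60 patients followed
#' for 180 days, with results averaged over 100 independent replications:
#'
#' * **Scenario 1 (misreported barriers):** the 20 patients whose true
#'   barrier is medication concern report forgetfulness at baseline.
#' * **Scenario 2 (barrier change):** all reports are accurate, but on day
#'   90 the medication-concern group's true barrier switches to disease
#'   doubt (reports are not refreshed).
#' * **Scenario 3 (message fatigue):** a message sent after messages on
#'   both previous days attenuates the matched-message effect by 5% per
#'   fatigued day (10% capped recovery otherwise). Fatigue applies to every
#'   arm; only the bandit gains the no-message action (and the two
#'   prior-day sent flags in its context) to manage it.
#'
#' @param scenario Scenario id in `1:3`.
#' @param horizon Days of follow-up (default 180).
#' @param n_runs Independent replications (default 100).
#' @param group_sizes Named cohort sizes for the `disease_only`,
#'   `medicine_only` and `disease_and_remember` groups (default 20 each).
#' @param params A [model_params()] object.
#' @param ridge,explore_const LinUCB constants (defaults 1 and 1).
#' @param pooling `"pooled"` (one bandit shared by the cohort, default) or
#'   `"per_patient"` (an independent bandit per patient).
#' @param tailored_rule Multi-barrier tailoring rule, see
#'   [tailored_policy()].
#' @param common_rng If `TRUE`, [compare_policies()] reuses the same run
#'   seeds across policies (common random numbers); default `FALSE`
#'   (independent streams).
#' @param change_day Scenario 2 change point (default day 90).
#' @param master_seed Integer master seed; every run seed is derived from
#'   it deterministically.
#' @param fatigue_enabled Optional override; must agree with the scenario
#'   (fatigue belongs to scenario 3 only).
#' @return An object of class `adhersim_config`.
#' @examples
#' scenario_config(scenario = 1, n_runs = 10)
#' @export
scenario_config <- function(scenario = 1, horizon = 180L, n_runs = 100L,
                            group_sizes = c(disease_only = 20L,
                                            medicine_only = 20L,
                                            disease_and_remember = 20L),
                            params = model_params(),
                            ridge = 1, explore_const = 1,
                            pooling = c("pooled", "per_patient"),
                            tailored_rule = c("random", "alternate"),
                            common_rng = FALSE,
                            change_day = 90L,
                            master_seed = 1L,
                            fatigue_enabled = NULL) {
  pooling <- match.arg(pooling)
  tailored_rule <- match.arg(tailored_rule)
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3)
    stop("`scenario` must be 1, 2 or 3", call. = FALSE)
  horizon <- as.integer(horizon); n_runs <- as.integer(n_runs)
  stopifnot(horizon >= 1, n_runs >= 1)
  need <- c("disease_only", "medicine_only", "disease_and_remember")
  if (!all(need %in% names(group_sizes)))
    stop("`group_sizes` must name the groups: ",
         paste(need, collapse = ", "), call. = FALSE)
  group_sizes <- vapply(group_sizes[need], as.integer, integer(1))
  if (any(group_sizes < 0) || sum(group_sizes) < 1)
    stop("cohort must contain at least one patient", call. = FALSE)
  if (!inherits(params, "adhersim_params"))
    stop("`params` must come from model_params()", call. = FALSE)
  fat <- scenario == 3L
  if (!is.null(fatigue_enabled) && !identical(as.logical(fatigue_enabled), fat))
    stop(sprintf(
      "fatigue_enabled = %s conflicts with scenario %d (fatigue belongs to scenario 3 only)",
      fatigue_enabled, scenario), call. = FALSE)
  structure(
    list(scenario = scenario, horizon = horizon, n_runs = n_runs,
         group_sizes = group_sizes, params = params,
         ridge = ridge, explore_const = explore_const,
         pooling = pooling, tailored_rule = tailored_rule,
         common_rng = isTRUE(common_rng),
         change_day = as.integer(change_day),
         master_seed = as.integer(master_seed),
         fatigue_enabled = fat,
         rl_arms = if (fat) message_actions() else message_types(),
         feature_len = feature_length(scenario)),
    class = "adhersim_config")
}

#' Build the simulated cohort
#'
#' Three groups: patients whose only barrier is a disease-severity doubt,
#' patients whose only barrier is medication concern, and patients with
#' both a disease-severity doubt and forgetfulness. In the misreporting
#' scenario the medication-concern group reports forgetfulness at baseline;
#' otherwise every report matches the truth.
#'
#' @param config An [scenario_config()] object.
#' @return List of [patient_spec()] objects.
#' @export
build_cohort <- function(config) {
  gs <- config$group_sizes
  truth <- list(disease_only = "disease",
                medicine_only = "medicine",
                disease_and_remember = c("disease", "remember"))
  specs <- list(); id <- 0L
  for (g in names(gs)) {
    for (i in seq_len(gs[[g]])) {
      id <- id + 1L
      rep_b <- if (config$scenario == 1L && g == "medicine_only")
        "remember" else truth[[g]]
      specs[[id]] <- patient_spec(id, truth[[g]], rep_b, group = g)
    }
  }
  specs
}

# Deterministic 31-bit seed from the master seed and a string key.
derive_seed <- function(master_seed, key) {
  h <- as.double(master_seed) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

run_seeds <- function(config, policy) {
  pfx <- if (config$common_rng) "run" else paste0(policy, "-run")
  vapply(seq_len(config$n_runs),
         function(k) derive_seed(config$master_seed, paste0(pfx, "-", k)),
         integer(1))
}

# Cohort as column-indexed logical matrices (cols: disease, medicine,
# remember) for the vectorized engine.
cohort_matrices <- function(cohort) {
  n <- length(cohort)
  truth <- matrix(FALSE, n, 3, dimnames = list(NULL, message_types()))
  reported <- truth
  group <- character(n)
  for (i in seq_len(n)) {
    truth[i, cohort[[i]]$true_barriers] <- TRUE
    reported[i, cohort[[i]]$reported_barriers] <- TRUE
    group[i] <- cohort[[i]]$group %||% NA_character_
  }
  list(truth = truth, reported = reported, group = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one replication
#'
#' Runs one seeded pass of the full cohort over the horizon under one
#' message-selection policy. Each day the engine applies the scenario-2
#' barrier change if due, lets the policy choose a message for every
#' patient, advances each patient's fatigue state, draws the day's barrier
#' terms and effect size, forms the adherence probability and draws the
#' binary outcome, then updates the per-patient interaction history (and,
#' for the bandit, the chosen arms' ridge statistics — sufficient
#' statistics are additive, so the day's updates are applied together once
#' the day's pill-cap outcomes are in).
#'
#' @param config An [scenario_config()] object.
#' @param policy One of `"reminder"`, `"random"`, `"tailored"`, `"rl"`.
#' @param seed Integer seed for this replication.
#' @return An object of class `adhersim_run`: list with `outcomes`
#'   (horizon x n 0/1 matrix), `actions` (horizon x n character matrix),
#'   `probs` (the underlying daily adherence probabilities), `policy`,
#'   `seed`.
#' @export
run_single <- function(config, policy = POLICIES, seed) {
  policy <- match.arg(policy)
  set.seed(as.integer(seed))
  cohort <- build_cohort(config)
  cm <- cohort_matrices(cohort)
  truth <- cm$truth; reported <- cm$reported
  n <- nrow(truth); H <- config$horizon
  p <- config$params
  sc <- config$scenario
  fat_on <- config$fatigue_enabled
  d <- config$feature_len

  # per-patient state
  ffac <- rep(1, n)                       # fatigue factor
  hist2 <- matrix(FALSE, n, 2)            # sent flags: [,1] = 2 days ago
  outwin <- lapply(1:3, function(t) matrix(NA_real_, n, 5)) # last-5 outcomes
  names(outwin) <- message_types()

  # tailored: pre-resolve reported-barrier index lists
  rep_idx <- lapply(seq_len(n), function(i) which(reported[i, ]))

  # bandit state: arm code 4 = none
  use_rl <- policy == "rl"
  if (use_rl) {
    arms <- config$rl_arms
    K <- length(arms)
    if (config$pooling == "pooled") {
      bandit <- linucb_init(d, arms, config$ridge, config$explore_const)
    } else {
      bandit <- lapply(seq_len(n), function(i)
        linucb_init(d, arms, config$ridge, config$explore_const))
    }
  }

  outcomes <- matrix(0L, H, n)
  actions <- matrix(NA_integer_, H, n)
  probs <- matrix(NA_real_, H, n)

  single_type <- ifelse(lengths(rep_idx) == 1L,
                        vapply(rep_idx, function(z) z[1] %||% NA_integer_,
                               integer(1)), NA_integer_)

  for (day in seq_len(H)) {
    if (sc == 2L && day == config$change_day) {
      ch <- cm$group == "medicine_only"
      truth[ch, ] <- matrix(rep(c(TRUE, FALSE, FALSE), each = sum(ch)),
                            ncol = 3)
    }

    # features (bandit context), built before today's decision
    if (use_rl) {
      s_cnt <- matrix(0, n, 3); n_cnt <- matrix(0, n, 3)
      for (t in 1:3) {
        s_cnt[, t] <- rowSums(outwin[[t]], na.rm = TRUE)
        n_cnt[, t] <- rowSums(!is.na(outwin[[t]]))
      }
      frac <- matrix(0.5, n, 3)
      has <- n_cnt > 0
      frac[has] <- s_cnt[has] / n_cnt[has]
      X <- cbind(1, reported * 1, frac,
                 if (sc == 3L) hist2 * 1)
      colnames(X) <- NULL
    }

    # action selection (codes 1..3 = message types, 4 = none)
    if (policy == "reminder") {
      act <- rep(3L, n)
    } else if (policy == "random") {
      act <- sample.int(3L, n, replace = TRUE)
    } else if (policy == "tailored") {
      act <- single_type
      multi <- which(is.na(act))
      if (length(multi)) {
        if (config$tailored_rule == "random") {
          for (i in multi) {
            ri <- rep_idx[[i]]
            act[i] <- ri[sample.int(length(ri), 1L)]
          }
        } else {
          for (i in multi) {
            ri <- sort(rep_idx[[i]])
            act[i] <- ri[((day - 1L) %% length(ri)) + 1L]
          }
        }
      }
    } else { # rl
      if (config$pooling == "pooled") {
        # score all patients against each arm at the day-start state
        scores <- matrix(0, n, K)
        for (a in seq_len(K)) {
          m <- bandit$arms[[a]]
          theta <- drop(m$Ainv %*% m$b)
          XA <- X %*% m$Ainv
          scores[, a] <- X %*% theta +
            config$explore_const * sqrt(pmax(rowSums(XA * X), 0))
        }
        act <- integer(n)
        for (i in seq_len(n)) {
          si <- scores[i, ]
          cand <- which(si == max(si))
          act[i] <- if (length(cand) > 1)
            cand[sample.int(length(cand), 1L)] else cand
        }
      } else {
        act <- integer(n)
        for (i in seq_len(n)) {
          a <- linucb_select(bandit[[i]], X[i, ])
          act[i] <- match(a, arms)
        }
      }
      # arm order equals message_actions() order, so code 4 = none
    }

    sent <- act <= 3L

    # fatigue update precedes the day's message effect
    if (fat_on) {
      fatigued <- sent & hist2[, 1] & hist2[, 2]
      ffac <- ifelse(fatigued, ffac * p$fatigue_decay,
                     pmin(1, ffac * p$fatigue_recovery))
    }
    hist2 <- cbind(hist2[, 2], sent)

    # daily draws
    amat <- matrix(draw_bounded(n * 3L, p$alpha_mean, p$alpha_sd,
                                p$bound_method), n, 3)
    amat[!truth] <- 1
    beta <- draw_bounded(n, p$beta_mean, p$beta_sd, p$bound_method)

    # matched messages move the targeted term toward 1
    matched <- sent & truth[cbind(seq_len(n), pmin(act, 3L))]
    if (any(matched)) {
      cells <- cbind(which(matched), act[matched])
      a0 <- amat[cells]
      amat[cells] <- a0 + beta[matched] * ffac[matched] * (1 - a0)
    }

    pr <- amat[, 1] * amat[, 2] * amat[, 3]
    out <- as.integer(stats::runif(n) < pr)

    # per-type outcome windows (last <= 5 sends of each type)
    for (t in 1:3) {
      idx <- which(act == t)
      if (length(idx)) {
        outwin[[t]][idx, ] <- cbind(outwin[[t]][idx, -1, drop = FALSE],
                                    out[idx])
      }
    }

    # bandit learning from the day's rewards
    if (use_rl) {
      if (config$pooling == "pooled") {
        for (a in seq_len(K)) {
          idx <- which(act == a)
          if (length(idx)) {
            Xa <- X[idx, , drop = FALSE]
            m <- bandit$arms[[a]]
            m$A <- m$A + crossprod(Xa)
            m$b <- m$b + drop(crossprod(Xa, out[idx]))
            m$Ainv <- chol2inv(chol(m$A))
            bandit$arms[[a]] <- m
          }
        }
      } else {
        for (i in seq_len(n)) {
          bandit[[i]] <- linucb_update(bandit[[i]], arms[act[i]], X[i, ],
                                       out[i])
        }
      }
    }

    outcomes[day, ] <- out
    actions[day, ] <- act
    probs[day, ] <- pr
  }

  structure(
    list(outcomes = outcomes,
         actions = matrix(message_actions()[actions], H, n),
         probs = probs, policy = policy, seed = as.integer(seed),
         scenario = sc),
    class = "adhersim_run")
}

#' Run replicated simulations for one policy
#'
#' Repeats [run_single()] over `n_runs` independently seeded replications
#' and aggregates: the per-day adherence rate is the fraction of the cohort
#' adherent that day, averaged across replications, with the cross-run
#' standard error as the dispersion measure.
#'
#' @inheritParams run_single
#' @return An object of class `adhersim_result` with `daily_mean`,
#'   `daily_sem` (length-`horizon` vectors), a `day_final` summary (final
#'   day and last-10-day means with SEMs), and the cross-run mean action
#'   frequency per day (`action_freq`).
#' @export
run_replications <- function(config, policy = POLICIES) {
  policy <- match.arg(policy)
  seeds <- run_seeds(config, policy)
  H <- config$horizon
  daily <- matrix(NA_real_, H, config$n_runs)
  afreq <- matrix(0, H, 4, dimnames = list(NULL, message_actions()))
  last10_runs <- numeric(config$n_runs)
  lo <- max(1L, H - 9L)
  for (k in seq_len(config$n_runs)) {
    r <- run_single(config, policy, seeds[k])
    daily[, k] <- rowMeans(r$outcomes)
    last10_runs[k] <- mean(daily[lo:H, k])
    for (a in seq_len(4)) afreq[, a] <- afreq[, a] +
      rowMeans(r$actions == message_actions()[a])
  }
  afreq <- afreq / config$n_runs
  nr <- config$n_runs
  sem <- function(v) if (nr > 1) stats::sd(v) / sqrt(nr) else 0
  daily_sem <- if (nr > 1) apply(daily, 1, stats::sd) / sqrt(nr) else
    rep(0, H)
  structure(
    list(policy = policy, config = config,
         daily_mean = rowMeans(daily), daily_sem = daily_sem,
         daily_by_run = daily,
         day_final = list(
           day = H,
           mean = mean(daily[H, ]), sem = sem(daily[H, ]),
           last10_mean = mean(last10_runs), last10_sem = sem(last10_runs)),
         action_freq = afreq, n_runs = nr, seeds = seeds),
    class = "adhersim_result")
}

#' Compare all message-selection policies on one scenario
#'
#' Runs the reminder, random, tailored and bandit arms on the same scenario
#' (independent seed streams by default; set `common_rng = TRUE` in the
#' config for common random numbers) and collects a final-day summary table
#' alongside the full trajectories.
#'
#' @inheritParams run_single
#' @param policies Policies to run (default all four).
#' @return An object of class `adhersim_comparison`: list with `results`
#'   (named list of [run_replications()] outputs), `summary` (data frame of
#'   final-day means/SEMs) and `config`.
#' @export
compare_policies <- function(config, policies = POLICIES) {
  policies <- match.arg(policies, several.ok = TRUE)
  results <- stats::setNames(
    lapply(policies, function(p) run_replications(config, p)), policies)
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(policy = r$policy, day = r$day_final$day,
               mean = r$day_final$mean, sem = r$day_final$sem,
               last10_mean = r$day_final$last10_mean,
               last10_sem = r$day_final$last10_sem,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, config = config),
            class = "adhersim_comparison")
}
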