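test_that("the cohort has the stated composition and reporting rules", {
  cfg2 <- scenario_config(scenario = 2, n_runs = 2)
  cohort <- build_cohort(cfg2)
  expect_length(cohort, 60)
  groups <- table(vapply(cohort, function(s) s$group, character(1)))
  expect_equal(unname(groups[c("disease_only", "medicine_only",
                               "disease_and_remember")]),
               c(20L, 20L, 20L), ignore_attr = TRUE)
  # outside the misreporting scenario every report is accurate
  expect_true(all(vapply(cohort, function(s)
    identical(sort(s$true_barriers), sort(s$reported_barriers)), logical(1))))

  cfg1 <- scenario_config(scenario = 1, n_runs = 2)
  mis <- Filter(function(s) s$group == "medicine_only", build_cohort(cfg1))
  expect_length(mis, 20)
  expect_true(all(vapply(mis, function(s)
    identical(s$true_barriers, "medicine") &&
      identical(s$reported_barriers, "remember"), logical(1))))
})

test_that("noise-free cohort baseline and reminder-arm composition are exact", {
  cfg <- scenario_config(scenario = 1, n_runs = 1, params = nf_params())
  cohort <- build_cohort(cfg)
  base <- vapply(cohort, function(s)
    adherence_probability(draw_daily_alphas(s, cfg$params)), numeric(1))
  expect_equal(mean(base), (0.65 + 0.65 + 0.4225) / 3) # ~0.574, "57%"

  # reminders only match the dual-barrier group's forgetfulness
  r <- run_single(cfg, "reminder", seed = 1)
  expect_true(all(r$actions == "remember"))
  expected <- (0.65 + 0.65 + 0.65 * (0.65 + 0.7 * 0.35)) / 3
  expect_equal(mean(r$probs), expected, tolerance = 1e-12)
  expect_equal(unique(as.vector(r$probs)),
               c(0.65, 0.65 * (0.65 + 0.7 * 0.35)))
})

test_that("noise-free tailored probabilities equal the closed-form compositions", {
  cfg <- scenario_config(scenario = 2, n_runs = 1, params = nf_params())
  r <- run_single(cfg, "tailored", seed = 3)
  matched <- 0.65 + 0.7 * 0.35 # 0.895
  # before day 90 every tailored message matches a true barrier
  expect_true(all(abs(r$probs[1:89, 1:40] - matched) < 1e-12))
  expect_true(all(abs(r$probs[1:89, 41:60] - 0.65 * matched) < 1e-12))
  # from day 90 the medicine group's tailoring is stale: baseline 0.65
  expect_true(all(abs(r$probs[90:180, 21:40] - 0.65) < 1e-12))
})

test_that("runs are bit-reproducible under a seed", {
  cfg <- scenario_config(scenario = 3, n_runs = 1, horizon = 40)
  for (pol in c("random", "rl")) {
    a <- run_single(cfg, pol, seed = 7)
    b <- run_single(cfg, pol, seed = 7)
    expect_identical(a$outcomes, b$outcomes)
    expect_identical(a$actions, b$actions)
    expect_identical(a$probs, b$probs)
    c2 <- run_single(cfg, pol, seed = 8)
    expect_false(identical(a$outcomes, c2$outcomes))
  }
})

test_that("replication aggregation averages runs and reports dispersion", {
  cfg <- scenario_config(scenario = 1, n_runs = 1, horizon = 30)
  r1 <- run_replications(cfg, "random")
  single <- run_single(cfg, "random", r1$seeds[1])
  expect_equal(r1$daily_mean, rowMeans(single$outcomes))
  expect_equal(r1$daily_sem, rep(0, 30))

  cfg5 <- scenario_config(scenario = 1, n_runs = 5, horizon = 30)
  r5 <- run_replications(cfg5, "random")
  expect_true(all(r5$daily_mean >= 0 & r5$daily_mean <= 1))
  expect_true(all(r5$daily_sem >= 0))
  expect_equal(r5$day_final$mean, mean(r5$daily_by_run[30, ]))
})

test_that("day-1 adherence matches each arm's closed-form expectation", {
  # No arm has outcome feedback yet: reminder/random/fresh-bandit act
  # blindly, tailoring acts on the baseline survey only. Expectations under
  # the censored-normal model (E[alpha] ~ 0.6336, E[beta] ~ 0.6760):
  ea <- clipped_normal_mean(0.65, 0.30)
  eb <- clipped_normal_mean(0.70, 0.30)
  m1 <- ea + eb * (1 - ea)        # matched single-barrier patient
  dual_m <- m1 * ea               # dual patient, one barrier matched
  dual_u <- ea^2
  exp_day1 <- c(
    reminder = (ea + ea + dual_m) / 3,
    random = ((2 / 3 * ea + 1 / 3 * m1) * 2 +
                (1 / 3 * dual_u + 2 / 3 * dual_m)) / 3,
    tailored = (m1 + ea + dual_m) / 3, # medicine group's report mismatches
    rl = ((2 / 3 * ea + 1 / 3 * m1) * 2 +
            (1 / 3 * dual_u + 2 / 3 * dual_m)) / 3) # fresh ties -> uniform
  cfg <- scenario_config(scenario = 1, n_runs = 40, horizon = 2)
  d1 <- vapply(names(exp_day1), function(p)
    run_replications(cfg, p)$daily_mean[1], numeric(1))
  se <- sqrt(0.65 * 0.35 / (60 * 40)) # ~0.01
  expect_true(all(abs(d1 - exp_day1) < 3.5 * se))
})

test_that("cross-run SEM at the final day is Bernoulli-consistent", {
  cfg <- scenario_config(scenario = 1, n_runs = 30)
  r <- run_replications(cfg, "reminder")
  p <- r$day_final$mean
  expected_sem <- sqrt(p * (1 - p) / 60) / sqrt(30)
  expect_gt(r$day_final$sem, expected_sem / 2)
  expect_lt(r$day_final$sem, expected_sem * 2)
})

test_that("the tailored arm drops discontinuously at the barrier change", {
  cfg <- scenario_config(scenario = 2, n_runs = 30, master_seed = 5)
  r <- run_replications(cfg, "tailored")
  before <- colMeans(r$daily_by_run[80:89, ])
  after <- colMeans(r$daily_by_run[91:100, ])
  tt <- t.test(after, before, alternative = "less")
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(after) - mean(before), -0.03)
})

test_that("comparators always send; the no-message action is scenario-3 RL only", {
  cfg3 <- scenario_config(scenario = 3, n_runs = 1, horizon = 60)
  for (pol in c("reminder", "random", "tailored")) {
    r <- run_single(cfg3, pol, seed = 2)
    expect_false(any(r$actions == "none"))
  }
  rl3 <- run_single(cfg3, "rl", seed = 2)
  expect_true(all(rl3$actions %in% message_actions()))
  cfg1 <- scenario_config(scenario = 1, n_runs = 1, horizon = 60)
  rl1 <- run_single(cfg1, "rl", seed = 2)
  expect_false(any(rl1$actions == "none"))
})

test_that("policy comparison collects a final-day summary for each arm", {
  cfg <- scenario_config(scenario = 1, n_runs = 3, horizon = 25)
  cmp <- compare_policies(cfg)
  expect_s3_class(cmp, "adhersim_comparison")
  expect_equal(nrow(cmp$summary), 4)
  expect_setequal(cmp$summary$policy, c("reminder", "random", "tailored", "rl"))
  expect_true(all(cmp$summary$mean >= 0 & cmp$summary$mean <= 1))
  expect_identical(summary(cmp), cmp$summary)
})

test_that("the per-patient bandit option runs and is reproducible", {
  cfg <- scenario_config(scenario = 1, n_runs = 1, horizon = 25,
                         pooling = "per_patient")
  a <- run_single(cfg, "rl", seed = 4)
  b <- run_single(cfg, "rl", seed = 4)
  expect_identical(a$outcomes, b$outcomes)
  expect_true(all(a$actions %in% message_types()))
})

test_that("config validation enforces the scenario invariants", {
  expect_error(scenario_config(scenario = 4), "must be 1, 2 or 3")
  expect_error(scenario_config(scenario = 1, fatigue_enabled = TRUE),
               "scenario 3")
  expect_no_error(scenario_config(scenario = 3, fatigue_enabled = TRUE))
  expect_error(scenario_config(group_sizes = c(a = 20)), "must name")
  cfg3 <- scenario_config(scenario = 3)
  expect_true(cfg3$fatigue_enabled)
  expect_identical(cfg3$rl_arms, message_actions())
  expect_identical(scenario_config(scenario = 2)$rl_arms, message_types())
})
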