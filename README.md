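# adhersim

Monte Carlo simulation of text-message (SMS) support for medication
adherence, for health-services and mHealth researchers who want to study
*adaptive* message selection before running a trial. The package simulates
a cohort of chronically ill patients whose daily medication-taking is
driven by three multiplicative adherence barriers, and compares four
message-selection strategies — fixed reminders, random messages,
baseline-survey tailoring, and a LinUCB contextual bandit that learns each
patient's true barriers from daily pill-cap feedback — under three
stress tests: misreported barriers, a mid-course barrier change, and
message fatigue.

## The model

A patient's probability of taking the medication on day *t* is

    P(adherence) = α_disease × α_medicine × α_remember

where each α ∈ [0, 1] is a barrier term: doubt that the disease is worth
treating, concern about the medication, and forgetfulness. Barriers the
patient has are redrawn daily from N(0.65, 0.30) bounded into [0, 1];
barriers they do not have contribute exactly 1. An SMS message matching a
true barrier moves that term toward 1 by a daily effect size
β ~ N(0.70, 0.30):

    α' = α + β · f · (1 − α)

with f the message-fatigue factor (1 unless fatigue is simulated; under
fatigue it loses 5% on each day a message follows messages on both
previous days and recovers 10% on quieter days, capped at 1). Mismatched
messages do nothing. The bandit arm is disjoint-arm LinUCB: one ridge
reward model per message type, arm score `θ̂ᵀx + c·√(xᵀA⁻¹x)`, with the
binary same-day adherence outcome as reward and a context of
reported-barrier indicators plus recent per-message-type success
fractions (plus prior-day send flags and a no-message action in the
fatigue scenario).

## Worked example

```r
library(adhersim)
cfg <- scenario_config(scenario = 1, n_runs = 25, master_seed = 42)
cmp <- compare_policies(cfg)
cmp
```

```
Policy comparison, scenario 1 (25 runs x 180 days)
   policy day  mean   sem last10_mean last10_sem
 reminder 180 59.6% 1.41%       60.6%      0.39%
   random 180 64.9% 1.16%       64.9%      0.34%
 tailored 180 68.7% 1.16%       68.9%      0.37%
       rl 180 76.3% 0.92%       77.2%      0.28%
```

In this scenario the 20 patients whose true barrier is medication concern
reported forgetfulness at baseline, so the survey-tailored arm sends them
useless reminders all 180 days while the bandit learns the mismatch from
outcome feedback: by day 180 the bandit's cohort adherence (76.3%,
cross-run SEM 0.92%) clearly exceeds tailoring (68.7%), random messaging
(64.9%) and plain reminders (59.6%), against a 57% no-intervention
baseline. `plot(cmp)` draws the daily trajectories and
`write_outputs(cmp, dir)` exports trajectory/summary/action-frequency CSVs
plus a JSON summary and the resolved YAML config.

A shell front end wrapping the same functions lives at
`inst/cli/adhersim.R`:

```sh
Rscript inst/cli/adhersim.R run --scenario 1 --policy all --runs 100 --seed 1 --out results/s1
```

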