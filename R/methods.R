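# print / summary / plot methods for configs and results.

#' @export
print.adhersim_config <- function(x, ...) {
  labels <- c("misreported barriers", "barrier change at day 90",
              "message fatigue")
  cat(sprintf("Scenario %d (%s): %d patients, %d days, %d runs\n",
              x$scenario, labels[x$scenario], sum(x$group_sizes),
              x$horizon, x$n_runs))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  cat(sprintf("  bandit: arms {%s}, ridge %g, explore %g, %s\n",
              paste(x$rl_arms, collapse = ", "), x$ridge, x$explore_const,
              x$pooling))
  cat(sprintf("  master seed: %d\n", x$master_seed))
  invisible(x)
}

#' @export
print.adhersim_run <- function(x, ...) {
  cat(sprintf("One replication: policy '%s', scenario %d, seed %d\n",
              x$policy, x$scenario, x$seed))
  cat(sprintf("  %d days x %d patients; overall adherence %.3f\n",
              nrow(x$outcomes), ncol(x$outcomes), mean(x$outcomes)))
  invisible(x)
}

#' @export
print.adhersim_result <- function(x, ...) {
  f <- x$day_final
  cat(sprintf("Policy '%s': %d runs of %d days\n", x$policy, x$n_runs,
              length(x$daily_mean)))
  cat(sprintf("  day %d adherence: %.1f%% (SEM %.2f%%)\n",
              f$day, 100 * f$mean, 100 * f$sem))
  cat(sprintf("  last-10-day mean: %.1f%% (SEM %.2f%%)\n",
              100 * f$last10_mean, 100 * f$last10_sem))
  invisible(x)
}

#' @export
summary.adhersim_result <- function(object, ...) {
  f <- object$day_final
  data.frame(policy = object$policy, day = f$day, mean = f$mean,
             sem = f$sem, last10_mean = f$last10_mean,
             last10_sem = f$last10_sem, stringsAsFactors = FALSE)
}

#' @export
print.adhersim_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison, scenario %d (%d runs x %d days)\n",
              x$config$scenario, x$config$n_runs, x$config$horizon))
  s <- x$summary
  s$mean <- sprintf("%.1f%%", 100 * s$mean)
  s$sem <- sprintf("%.2f%%", 100 * s$sem)
  s$last10_mean <- sprintf("%.1f%%", 100 * s$last10_mean)
  s$last10_sem <- sprintf("%.2f%%", 100 * s$last10_sem)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.adhersim_comparison <- function(object, ...) object$summary

#' Plot daily adherence trajectories
#'
#' One line per policy: the per-day cohort adherence rate averaged across
#' replications.
#'
#' @param x An `adhersim_comparison` or `adhersim_result`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.adhersim_comparison <- function(x, ...) {
  M <- vapply(x$results, function(r) r$daily_mean,
              numeric(x$config$horizon))
  graphics::matplot(M, type = "l", lty = 1, lwd = 2,
                    col = seq_len(ncol(M)),
                    xlab = "day", ylab = "adherence rate", ylim = c(0, 1),
                    main = sprintf("Scenario %d", x$config$scenario), ...)
  graphics::legend("bottomright", legend = colnames(M),
                   col = seq_len(ncol(M)), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' @rdname plot.adhersim_comparison
#' @export
plot.adhersim_result <- function(x, ...) {
  graphics::plot(seq_along(x$daily_mean), x$daily_mean, type = "l", lwd = 2,
                 xlab = "day", ylab = "adherence rate", ylim = c(0, 1),
                 main = sprintf("Policy '%s'", x$policy), ...)
  invisible(x)
}
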