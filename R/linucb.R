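# Disjoint-arm LinUCB: a per-arm ridge-regression reward model with an
# upper-confidence-bound action rule. Sufficient statistics are kept per
# arm as A = ridge*I + sum(x x') and b = sum(r x); the arm score is
# theta'x + c * sqrt(x' A^-1 x) with theta = A^-1 b.

#' Initialise a LinUCB bandit
#'
#' Each arm keeps ridge-regression sufficient statistics: a Gram matrix
#' initialised to `ridge * I` (so it is positive-definite from the start)
#' and a zero reward-moment vector. One model is typically shared across
#' all patients ("pooled" mode); patient identity then enters only through
#' the context features.
#'
#' @param d Feature-vector length (>= 1).
#' @param arms Character vector of arm names (a subset of
#'   [message_actions()]).
#' @param ridge Positive ridge-regularisation constant (default 1).
#' @param explore_const Non-negative UCB width multiplier (default 1).
#' @return An object of class `adhersim_linucb`.
#' @examples
#' linucb_init(7, message_types())
#' @export
linucb_init <- function(d, arms = message_types(), ridge = 1,
                        explore_const = 1) {
  d <- as.integer(d)
  stopifnot(d >= 1, length(arms) >= 1)
  if (ridge <= 0) stop("`ridge` must be positive", call. = FALSE)
  if (explore_const < 0) stop("`explore_const` must be >= 0", call. = FALSE)
  one <- function() list(A = diag(ridge, d), b = numeric(d),
                         Ainv = diag(1 / ridge, d))
  structure(
    list(arms = stats::setNames(lapply(arms, function(a) one()), arms),
         d = d, ridge = ridge, explore_const = explore_const,
         arm_names = arms),
    class = "adhersim_linucb")
}

check_context <- function(state, x) {
  x <- as.numeric(x)
  if (length(x) != state$d)
    stop(sprintf("context has length %d but the bandit was built for d = %d",
                 length(x), state$d), call. = FALSE)
  x
}

#' Upper confidence bound for one arm
#'
#' `theta_hat' x + explore_const * sqrt(x' A^-1 x)` with
#' `theta_hat = A^-1 b`.
#'
#' @param state An [linucb_init()] object.
#' @param arm Arm name.
#' @param x Context feature vector of length `d`.
#' @return Scalar score.
#' @export
linucb_ucb <- function(state, arm, x) {
  x <- check_context(state, x)
  m <- state$arms[[arm]]
  if (is.null(m)) stop("unknown arm: ", arm, call. = FALSE)
  theta <- drop(m$Ainv %*% m$b)
  sum(theta * x) + state$explore_const * sqrt(drop(crossprod(x, m$Ainv %*% x)))
}

#' Choose an arm by UCB
#'
#' Returns the arm with the largest upper confidence bound; exact ties are
#' broken uniformly at random (at initialisation every arm ties, so the
#' bandit begins by sending messages at random).
#'
#' @inheritParams linucb_ucb
#' @return The chosen arm name.
#' @export
linucb_select <- function(state, x) {
  scores <- vapply(state$arm_names, function(a) linucb_ucb(state, a, x),
                   numeric(1))
  cand <- which(scores == max(scores))
  if (length(cand) > 1) cand <- cand[sample.int(length(cand), 1L)]
  state$arm_names[cand]
}

#' Record an observed reward
#'
#' Rank-one update of the chosen arm's sufficient statistics:
#' `A <- A + x x'`, `b <- b + reward * x`. Arms are disjoint, so only the
#' chosen arm's model changes. The reward here is the binary same-day
#' adherence outcome.
#'
#' @inheritParams linucb_ucb
#' @param reward 0 or 1.
#' @return The updated bandit state.
#' @export
linucb_update <- function(state, arm, x, reward) {
  x <- check_context(state, x)
  if (!(isTRUE(reward == 0) || isTRUE(reward == 1)))
    stop("`reward` must be 0 or 1", call. = FALSE)
  m <- state$arms[[arm]]
  if (is.null(m)) stop("unknown arm: ", arm, call. = FALSE)
  m$A <- m$A + tcrossprod(x)
  m$b <- m$b + reward * x
  # Sherman-Morrison rank-one update of the inverse
  Ax <- m$Ainv %*% x
  m$Ainv <- m$Ainv - tcrossprod(Ax) / drop(1 + crossprod(x, Ax))
  state$arms[[arm]] <- m
  state
}

#' Ridge coefficient estimate for one arm
#'
#' @inheritParams linucb_ucb
#' @return Numeric vector `theta_hat = A^-1 b`.
#' @export
linucb_coef <- function(state, arm) {
  m <- state$arms[[arm]]
  if (is.null(m)) stop("unknown arm: ", arm, call. = FALSE)
  drop(m$Ainv %*% m$b)
}

#' @export
print.adhersim_linucb <- function(x, ...) {
  cat(sprintf("LinUCB bandit: %d arms, d = %d, ridge = %g, explore = %g\n",
              length(x$arms), x$d, x$ridge, x$explore_const))
  cat("  arms:", paste(x$arm_names, collapse = ", "), "\n")
  invisible(x)
}
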