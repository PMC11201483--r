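# The high-level selection strategy of the hyper-heuristic.
#
# Each candidate heuristic H_i is scored F(H_i) = phi*f1(H_i) +
# phi*f2(H_j, H_i) + delta*f3(H_i): f1 tracks the heuristic's own recent
# improvement rate, f2 the rate achieved when it followed the previously
# selected heuristic H_j, and f3 the time elapsed since it was last chosen.
# Improvement pins phi at 0.99 (intensification); every deterioration
# bleeds 0.01 from phi into delta (floor 0.01), so sustained failure
# shifts selection pressure towards the longest-idle operator.
#
# Raw improvement rates I/T can dwarf the f3 clock by orders of magnitude,
# so every recorded rate is linearly rescaled into
# [a*tbar, b*tbar] (a = 0.1, b = 0.2, tbar = mean call duration) before it
# enters f1/f2, keeping intensification and diversification commensurate.

#' Choice-function state
#'
#' One state per subgroup; operator utilities, weights and the recorded
#' improvement rates used by the rescaling.
#'
#' @param n_ops Number of low-level heuristics (13 in the full registry).
#' @param a,b Rescaling interval coefficients.
#' @return An environment of class `cf_state` with fields `f1` (per
#'   operator), `f2` (ordered operator pairs), `f3` (idle time), `phi`,
#'   `delta`, `last_op`, `last_duration`, `recorded_rates`, `tbar`,
#'   `n_calls`.
#' @export
cf_state <- function(n_ops, a = 0.1, b = 0.2) {
  st <- new.env(parent = emptyenv())
  st$n_ops <- as.integer(n_ops)
  st$f1 <- numeric(n_ops)
  st$f2 <- matrix(0, n_ops, n_ops) # [prev, current]
  st$f3 <- numeric(n_ops)
  st$phi <- 0.5
  st$delta <- 0.5
  st$last_op <- NA_integer_
  st$last_duration <- 0
  st$recorded_rates <- numeric(0)
  st$tbar <- 0
  st$n_calls <- 0L
  st$a <- a
  st$b <- b
  class(st) <- "cf_state"
  st
}

#' Select the next low-level heuristic
#'
#' Argmax of F = phi*f1 + phi*f2\[last_op, \] + delta*f3, ties broken
#' uniformly at random (a fresh state therefore picks uniformly).
#'
#' @param state A `cf_state`.
#' @return The selected operator index.
#' @export
cf_select <- function(state) {
  f2col <- if (is.na(state$last_op)) numeric(state$n_ops) else
    state$f2[state$last_op, ]
  f <- state$phi * state$f1 + state$phi * f2col + state$delta * state$f3
  top <- which(f == max(f))
  if (length(top) == 1L) top else sample1(top)
}

#' Rescale a raw improvement rate
#'
#' Linear map of the recorded-rate range onto \[a*tbar, b*tbar\]; with a
#' single (or degenerate) recorded range everything maps to the upper end.
#'
#' @param state A `cf_state` with at least one recorded rate.
#' @param raw A raw I/T value.
#' @return The rescaled rate.
#' @export
cf_rescale <- function(state, raw) {
  stopifnot(length(state$recorded_rates) > 0L)
  lo <- min(state$recorded_rates)
  hi <- max(state$recorded_rates)
  if (hi == lo) {
    return(state$b * state$tbar)
  }
  (state$a + (raw - lo) / (hi - lo) * (state$b - state$a)) * state$tbar
}

#' Record an operator call
#'
#' Updates f1 for the operator, f2 for the (previous, current) pair, resets
#' the operator's f3 clock while advancing all others, and maintains the
#' running mean call duration. Non-improving calls contribute I = 0, so the
#' utilities only decay (by factor phi).
#'
#' @param state A `cf_state`.
#' @param op Operator index just applied.
#' @param delta_fitness Change in the subgroup's best fitness.
#' @param duration Call duration (seconds, or 1 in iteration mode); clamped
#'   to machine epsilon if non-positive.
#' @export
cf_record <- function(state, op, delta_fitness, duration) {
  if (duration <= 0) {
    warning("non-positive duration clamped to machine epsilon",
            call. = FALSE)
    duration <- .Machine$double.eps
  }
  state$n_calls <- state$n_calls + 1L
  state$tbar <- state$tbar + (duration - state$tbar) / state$n_calls
  i <- max(delta_fitness, 0)
  prev <- state$last_op
  if (i > 0) {
    r1 <- i / duration
    pair_dur <- duration + state$last_duration
    r2 <- if (!is.na(prev)) i / max(pair_dur, .Machine$double.eps) else NA
    state$recorded_rates <- c(state$recorded_rates, r1,
                              if (!is.na(prev)) r2)
    state$f1[op] <- cf_rescale(state, r1) + state$phi * state$f1[op]
    if (!is.na(prev)) {
      state$f2[prev, op] <- cf_rescale(state, r2) +
        state$phi * state$f2[prev, op]
    }
  } else {
    state$f1[op] <- state$phi * state$f1[op]
    if (!is.na(prev)) {
      state$f2[prev, op] <- state$phi * state$f2[prev, op]
    }
  }
  state$f3 <- state$f3 + duration
  state$f3[op] <- 0
  state$last_op <- op
  state$last_duration <- duration
  invisible(state)
}

#' Update the intensification/diversification weights
#'
#' Improvement rewards phi with 0.99; deterioration decays it linearly by
#' 0.01 down to a floor of 0.01. delta is always 1 - phi.
#'
#' @param state A `cf_state`.
#' @param improved Did the subgroup's best fitness strictly increase?
#' @export
cf_update_weights <- function(state, improved) {
  state$phi <- if (isTRUE(improved)) 0.99 else max(state$phi - 0.01, 0.01)
  state$delta <- 1 - state$phi
  invisible(state)
}
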