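#' Effective local fields of a transition
#'
#' For a transition `prev -> next`, the forward field on spin `i` is
#' `h_i = theta_i + sum_j J_ij prev_j`; the time-reversed field is computed
#' from the arrival state, `h_rev_i = theta_i + sum_j J_ij next_j`, and is
#' what the reverse transition probability is evaluated with.
#'
#' @param realization An [sk_realization()].
#' @param prev_state Length-N spin vector with entries -1/+1.
#' @param next_state Optional candidate next state; when supplied, `h_rev`
#'   is returned as well.
#' @return List with numeric vectors `h` and (optionally) `h_rev`.
#' @export
local_fields <- function(realization, prev_state, next_state = NULL) {
  check_state(prev_state, realization)
  h <- drop(realization$J %*% prev_state) + realization$theta
  out <- list(h = h)
  if (!is.null(next_state)) {
    check_state(next_state, realization)
    out$h_rev <- drop(realization$J %*% next_state) + realization$theta
  }
  out
}

check_state <- function(state, realization) {
  n <- realization$model$n_spins
  if (length(state) != n) {
    stop(sprintf("state must have length %d", n), call. = FALSE)
  }
  if (!all(state %in% c(-1, 1))) {
    stop("state entries must be -1 or +1", call. = FALSE)
  }
  invisible(state)
}

#' Transition probability of the parallel-update kernel
#'
#' `p(next | prev) = prod_i exp(beta next_i h_i) / (2 cosh(beta h_i))` with
#' `h_i` the forward local field. At `beta = 0` every next state has
#' probability `2^-N`.
#'
#' @inheritParams local_fields
#' @param next_state Arrival spin vector.
#' @param log Return the log-probability.
#' @return A probability in `(0, 1]` (or its log).
#' @export
transition_probability <- function(realization, next_state, prev_state,
                                   log = FALSE) {
  beta <- realization$model$beta
  h <- local_fields(realization, prev_state)$h
  check_state(next_state, realization)
  lp <- sum(beta * next_state * h - log2cosh(beta * h))
  if (log) lp else exp(lp)
}

# log(2 cosh(x)) without overflow
log2cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x)))

#' Negative-log transition energies
#'
#' `epsilon_forward()` is `-log p(next | prev)`. `epsilon_reverse()` is
#' `-log p(prev | next)` with the forward kernel applied to the reverse
#' transition, i.e. evaluated with the reversed field
#' `h_rev_i = theta_i + sum_j J_ij next_j`. Their stationary averages give
#' the entropy rate and the time-reversed conditional entropy; the
#' difference of the averages is the steady-state entropy production.
#' All values are in nats.
#'
#' @inheritParams transition_probability
#' @return A scalar in nats.
#' @export
epsilon_forward <- function(realization, next_state, prev_state) {
  -transition_probability(realization, next_state, prev_state, log = TRUE)
}

#' @rdname epsilon_forward
#' @export
epsilon_reverse <- function(realization, next_state, prev_state) {
  beta <- realization$model$beta
  hr <- local_fields(realization, prev_state, next_state)$h_rev
  check_state(prev_state, realization)
  -sum(beta * prev_state * hr - log2cosh(beta * hr))
}
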