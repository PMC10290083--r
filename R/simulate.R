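#' One parallel (synchronous) update of all spins
#'
#' Every spin is redrawn simultaneously: spin `i` becomes `+1` with
#' probability `exp(beta h_i) / (2 cosh(beta h_i))`, `h_i` the local field
#' of the current state. Uses R's RNG stream.
#'
#' @param state Length-N spin vector (-1/+1).
#' @param realization An [sk_realization()].
#' @return The next state.
#' @export
step_synchronous <- function(state, realization) {
  beta <- realization$model$beta
  h <- local_fields(realization, state)$h
  p_up <- stats::plogis(2 * beta * h)
  ifelse(runif(length(state)) < p_up, 1, -1)
}

#' One single-spin (asynchronous) micro-update
#'
#' A uniformly chosen spin is redrawn with the Glauber rate of the current
#' local field; all other spins are copied. N micro-updates advance time by
#' one unit (one sweep).
#'
#' @inheritParams step_synchronous
#' @return List with the new `state` and the `updated` spin index.
#' @export
step_asynchronous <- function(state, realization) {
  beta <- realization$model$beta
  n <- length(state)
  i <- sample.int(n, 1)
  h_i <- sum(realization$J[i, ] * state) + realization$theta[i]
  state[i] <- if (runif(1) < stats::plogis(2 * beta * h_i)) 1 else -1
  list(state = state, updated = i)
}

# Vectorized synchronous engine over replicate chains. S is reps x N.
# Returns the stored (reps, t+1, N) array or just the last transition.
sim_sync_core <- function(J, theta, beta, t_steps, S, store = TRUE) {
  reps <- nrow(S); n <- ncol(S)
  Jt <- t(J)
  states <- if (store) array(NA_integer_, c(reps, t_steps + 1, n))
  if (store) states[, 1, ] <- S
  S_prev <- S
  for (u in seq_len(t_steps)) {
    H <- S %*% Jt
    if (any(theta != 0)) H <- sweep(H, 2, theta, "+")
    P <- stats::plogis(2 * beta * H)
    S_prev <- S
    S <- matrix(-1, reps, n)
    S[matrix(runif(reps * n), reps, n) < P] <- 1
    if (store) states[, u + 1, ] <- S
  }
  list(states = states, final = S, prev = S_prev)
}

#' Simulate trajectories of the kinetic SK model
#'
#' Draws `n_reps` independent chains of `t_steps` time units from a fixed
#' (delta) initial state, reproducibly under `seed`. Synchronous runs store
#' every step; asynchronous runs store either one state per sweep
#' (`record = "sweep"`, N micro-updates each) or every micro-state with the
#' updated-spin record (`record = "micro"`, small systems only).
#' Asynchronous runs also carry streaming steady-state estimates (final
#' sweeps) used by [estimate_entropy_production()].
#'
#' @param realization An [sk_realization()]; the update mode and `beta`
#'   come from its model.
#' @param t_steps Number of time units (steps or sweeps).
#' @param n_reps Number of independent chains.
#' @param seed Seed for the trajectory stream.
#' @param init Initial spin vector; default all `+1` (a fixed determinate
#'   start keeps replicate chains on one ordered branch).
#' @param record For asynchronous runs: `"sweep"` or `"micro"`.
#' @param lag Delayed-correlation lag (native units: steps, or sweeps for
#'   asynchronous runs) tracked by the streaming estimators.
#' @param measure_sweeps Asynchronous only: number of final sweeps entering
#'   the streaming steady-state averages.
#' @return An object of class `"sk_trajectory"`: `states` is a
#'   `(n_reps, time + 1, N)` array in the recorded resolution;
#'   `time_unit` is `"step"`, `"sweep"` or `"micro"`; asynchronous
#'   micro-recording adds `update_mask`.
#' @examples
#' r <- sk_realization(sk_model(8, beta = 1, dj = 0.5), seed = 1)
#' traj <- simulate_sk(r, t_steps = 20, n_reps = 4, seed = 2)
#' dim(traj$states)
#' @export
simulate_sk <- function(realization, t_steps = 128, n_reps = 1, seed = 1,
                        init = NULL, record = c("sweep", "micro"),
                        lag = NULL, measure_sweeps = 1) {
  model <- realization$model
  n <- model$n_spins
  if (t_steps < 1) stop("`t_steps` must be >= 1", call. = FALSE)
  if (is.null(init)) init <- rep(1, n)
  check_state(init, realization)
  withr_seed(seed)
  if (model$update == "synchronous") {
    S0 <- matrix(rep(init, each = n_reps), n_reps, n)
    res <- sim_sync_core(realization$J, realization$theta, model$beta,
                         t_steps, S0, store = TRUE)
    out <- list(states = res$states, time_unit = "step",
                model = model, init = init, seed = seed)
  } else {
    record <- match.arg(record)
    lag_micro <- if (is.null(lag)) 10L * n else as.integer(lag * n)
    reps <- vector("list", n_reps)
    tlen <- if (record == "sweep") t_steps + 1 else t_steps * n + 1
    states <- array(NA_integer_, c(n_reps, tlen, n))
    mask <- if (record == "micro") matrix(NA_integer_, n_reps, t_steps * n)
    stats <- matrix(NA_real_, n_reps, 3,
                    dimnames = list(NULL, c("m_hat", "q_hat", "ep_rate")))
    for (r in seq_len(n_reps)) {
      ch <- cpp_async_chain(realization$J, realization$theta, model$beta,
                            as.integer(t_steps), as.integer(init),
                            if (record == "sweep") 1L else 2L,
                            lag_micro, as.integer(measure_sweeps))
      states[r, , ] <- ch$states
      if (record == "micro") mask[r, ] <- ch$updated
      stats[r, ] <- c(ch$m_hat, ch$q_hat, ch$ep_rate)
    }
    out <- list(states = states,
                time_unit = if (record == "sweep") "sweep" else "micro",
                update_mask = mask, async_stats = tibble::as_tibble(stats),
                lag_micro = lag_micro, model = model, init = init,
                seed = seed)
  }
  structure(out, class = "sk_trajectory")
}

#' @export
print.sk_trajectory <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<sk_trajectory> %d rep(s) x %d %ss x %d spins (%s updates)\n",
              d[1], d[2] - 1, x$time_unit, d[3], x$model$update))
  invisible(x)
}

#' Trajectory estimates of the order parameters
#'
#' `m_hat` is the mean activation at the final recorded time, averaged over
#' spins and replicates; `q_hat(lag)` the delayed self-correlation between
#' the final time and `lag` recorded units earlier; `c_hat = q_hat - m_hat^2`
#' the covariance form. Standard errors are across replicates.
#'
#' @param traj An [simulate_sk()] trajectory.
#' @param lag Lag in the trajectory's recorded time unit.
#' @return One-row tibble with estimates and standard errors.
#' @export
estimate_order_parameters <- function(traj, lag = 1) {
  st <- traj$states
  tl <- dim(st)[2]
  if (lag >= tl) stop("lag exceeds trajectory length", call. = FALSE)
  s_end <- st[, tl, , drop = FALSE]
  s_lag <- st[, tl - lag, , drop = FALSE]
  m_rep <- apply(s_end, 1, mean)
  q_rep <- apply(s_end * s_lag, 1, mean)
  nr <- length(m_rep)
  se <- function(v) if (nr > 1) sd(v) / sqrt(nr) else NA_real_
  tibble::tibble(
    m_hat = mean(m_rep), m_se = se(m_rep),
    q_hat = mean(q_rep), q_se = se(q_rep),
    c_hat = mean(q_rep) - mean(m_rep)^2,
    lag = lag, n_reps = nr, time_unit = traj$time_unit
  )
}

#' Trajectory estimate of the entropy production
#'
#' Synchronous runs: per-spin `sigma_hat` is the replicate average of
#' `epsilon_reverse - epsilon_forward` over the final transition (the
#' steady-state segment after the full burn-in horizon), in nats per step.
#' Asynchronous runs return the per-spin entropy production *rate* in nats
#' per unit time, from the streaming per-micro-step differences collected
#' during simulation.
#'
#' @inheritParams estimate_order_parameters
#' @param realization The realization the trajectory was simulated from.
#' @return One-row tibble with `sigma_hat`, `sigma_se`, `n_reps`, `unit`.
#' @export
estimate_entropy_production <- function(traj, realization) {
  if (traj$model$update == "asynchronous") {
    v <- traj$async_stats$ep_rate
    return(tibble::tibble(
      sigma_hat = mean(v),
      sigma_se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
      n_reps = length(v), unit = "nats/time"))
  }
  st <- traj$states
  tl <- dim(st)[2]
  n <- dim(st)[3]
  beta <- traj$model$beta
  S_end <- matrix(st[, tl, ], dim(st)[1], n)
  S_prev <- matrix(st[, tl - 1, ], dim(st)[1], n)
  sig <- sigma_rep_sync(S_end, S_prev, realization, beta)
  tibble::tibble(
    sigma_hat = mean(sig),
    sigma_se = if (length(sig) > 1) sd(sig) / sqrt(length(sig)) else NA_real_,
    n_reps = length(sig), unit = "nats/step")
}

# per-replicate (eps_rev - eps_fwd)/N for a batch of final transitions
sigma_rep_sync <- function(S_end, S_prev, realization, beta) {
  n <- ncol(S_end)
  Jt <- t(realization$J)
  add_theta <- function(H) {
    if (any(realization$theta != 0)) sweep(H, 2, realization$theta, "+") else H
  }
  H <- add_theta(S_prev %*% Jt)
  Hr <- add_theta(S_end %*% Jt)
  ef <- rowSums(log2cosh(beta * H) - beta * S_end * H)
  er <- rowSums(log2cosh(beta * Hr) - beta * S_prev * Hr)
  (er - ef) / n
}
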