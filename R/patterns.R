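#' Expected pattern length before recurrence
#'
#' In the disordered (`m = 0`) and deep ordered (`m ~ 1`) regimes the
#' first-return probability of a population state is approximately
#' geometric with per-step rate `lambda = ((1 + m)/2)^N`, giving an
#' expected repeat length `(2 / (1 + m))^N`: 1 in the fully ordered limit,
#' `2^N` for disordered dynamics.
#'
#' @param m Magnetization in `[-1, 1]` (used for `m in [0, 1]`).
#' @param n_spins System size N.
#' @return Expected recurrence length, `>= 1` for `m >= 0`.
#' @examples
#' expected_pattern_length(1, 32)  # 1
#' expected_pattern_length(0, 4)   # 16
#' @export
expected_pattern_length <- function(m, n_spins) {
  if (any(abs(m) > 1)) stop("|m| must be <= 1", call. = FALSE)
  (2 / (1 + m))^n_spins
}

#' Geometric approximation of the first-return distribution
#'
#' Comparison curve `Omega(n) ~ lambda exp[(1 - n) lambda]` with
#' `lambda = ((1 + m)/2)^N`; valid in the disordered and deep ordered
#' regimes, where cross-time correlations of the configurational average
#' vanish.
#'
#' @inheritParams expected_pattern_length
#' @param n Vector of return lags (positive integers).
#' @return Tibble with columns `n`, `omega`.
#' @export
first_return_curve <- function(n, m, n_spins) {
  lambda <- ((1 + m) / 2)^n_spins
  tibble::tibble(n = n, omega = lambda * exp((1 - n) * lambda))
}

#' Empirical first-return statistics of simulated trajectories
#'
#' For each replicate of a synchronous trajectory, finds the first lag `n`
#' at which the state at the reference time recurs exactly
#' (`s_(u0+n) = s_u0`). Runs without a recurrence inside the horizon are
#' censored and reported as such.
#'
#' @param traj A synchronous [simulate_sk()] trajectory.
#' @param reference Reference time index (0-based step; default the first
#'   post-burn-in step).
#' @param burn_in Steps discarded before the reference.
#' @return An object of class `"sk_recurrence"`: tibble with columns `n`,
#'   `omega` (empirical first-return frequency) plus attributes
#'   `censored_fraction`, `mean_length` (over uncensored runs) and
#'   `horizon`.
#' @export
empirical_first_return <- function(traj, reference = NULL, burn_in = 0) {
  if (traj$time_unit != "step") {
    stop("first-return analysis expects a synchronous trajectory",
         call. = FALSE)
  }
  st <- traj$states
  tl <- dim(st)[2]
  u0 <- if (is.null(reference)) burn_in + 1 else reference + 1
  if (u0 >= tl) stop("reference time beyond trajectory", call. = FALSE)
  horizon <- tl - u0
  lags <- vapply(seq_len(dim(st)[1]), function(r) {
    ref <- st[r, u0, ]
    for (d in seq_len(horizon)) {
      if (all(st[r, u0 + d, ] == ref)) return(d)
    }
    NA_integer_
  }, 1L)
  obs <- lags[!is.na(lags)]
  tab <- if (length(obs)) table(obs) else table(integer())
  out <- tibble::tibble(n = as.integer(names(tab)),
                        omega = as.vector(tab) / length(lags))
  structure(out, class = c("sk_recurrence", class(out)),
            censored_fraction = mean(is.na(lags)),
            mean_length = if (length(obs)) mean(obs) else NA_real_,
            horizon = horizon)
}
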