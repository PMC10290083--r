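#' Steady-state magnetization of the infinite asymmetric SK model
#'
#' Solves the self-consistency `m = < Int Dz tanh[beta (theta + J0 m + dJ z)] >_theta`
#' by damped fixed-point iteration (damping 0.5, tolerance 1e-10) from the
#' ordered start `m0 = 1` and the disordered start `m0 = 0`. The converged
#' branch with larger `|m|` is reported together with a linear-stability
#' flag (magnitude of the map's slope at the fixed point below one).
#'
#' @param beta Inverse temperature.
#' @param j0 Mean coupling scale.
#' @param dj Coupling heterogeneity.
#' @param dh Field heterogeneity (uniform fields on `[-dh, dh]`).
#' @param theta Optional explicit field values averaged with equal weight
#'   (overrides `dh`).
#' @param scheme A [quad_scheme()].
#' @param damping Damping factor of the iteration.
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap.
#' @param full Return the full branch information instead of the scalar.
#' @return The steady-state `m` (scalar), or with `full = TRUE` a list with
#'   `m`, `stable`, `branches`, `iterations`, `converged`.
#' @examples
#' solve_steady_m(beta = 2, j0 = 1, dj = 0) # Curie-Weiss: tanh(2 m) = m
#' @export
solve_steady_m <- function(beta, j0 = 1, dj = 0.5, dh = 0, theta = NULL,
                           scheme = quad_scheme(), damping = 0.5,
                           tol = 1e-10, max_iter = 10000, full = FALSE) {
  fld <- field_nodes(dh, theta, scheme)
  Fmap <- function(m) {
    vals <- vapply(fld$theta, function(th) {
      gauss_mean_tanh(beta * dj, beta * (th + j0 * m), scheme)
    }, 0)
    sum(fld$w * vals)
  }
  run <- function(m0) {
    m <- m0; it <- 0L; conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      m_new <- m + damping * (Fmap(m) - m)
      if (abs(m_new - m) < tol) { m <- m_new; conv <- TRUE; break }
      m <- m_new
    }
    slope <- (Fmap(m + 1e-6) - Fmap(m - 1e-6)) / 2e-6
    list(m = m, iterations = it, converged = conv, stable = abs(slope) < 1)
  }
  ordered <- run(1)
  disordered <- run(0)
  pick <- if (abs(ordered$m) >= abs(disordered$m)) ordered else disordered
  if (!pick$converged) {
    warning("magnetization fixed point did not converge within max_iter")
  }
  if (full) {
    list(m = pick$m, stable = pick$stable,
         branches = c(ordered = ordered$m, disordered = disordered$m),
         iterations = pick$iterations, converged = pick$converged)
  } else {
    pick$m
  }
}

# G(q): delayed-correlation self-consistency map at fixed steady m,
# averaged over the field distribution. Shared by the synchronous q solver
# and the asynchronous two-time integrator.
q_map <- function(beta, j0, dj, m, dh = 0, theta = NULL,
                  scheme = quad_scheme()) {
  fld <- field_nodes(dh, theta, scheme)
  a <- beta * dj
  b <- beta * (fld$theta + j0 * m)
  function(q) {
    vals <- vapply(b, function(bb) biv_tanh_corr(a, bb, q, scheme), 0)
    sum(fld$w * vals)
  }
}

#' Steady-state delayed self-correlation
#'
#' Solves `q = < Int Dxy^(q) tanh[beta h(x)] tanh[beta h(y)] >_theta` at the
#' steady magnetization `m`. The root of `G(q) - q` on `[0, 1]` is located
#' by bracketed root finding; `G(0) >= 0` and `G(1) < 1` for any `beta < Inf`,
#' so a root always exists, and for the fully asymmetric ensemble it is
#' unique (no spin-glass branch).
#'
#' @inheritParams solve_steady_m
#' @param m Steady-state magnetization from [solve_steady_m()].
#' @param tol Root tolerance.
#' @return The steady-state `q` in `[0, 1]`.
#' @export
solve_steady_q <- function(beta, j0 = 1, dj = 0.5, m, dh = 0, theta = NULL,
                           scheme = quad_scheme(), tol = 1e-12) {
  if (missing(m)) m <- solve_steady_m(beta, j0, dj, dh, theta, scheme)
  G <- q_map(beta, j0, dj, m, dh, theta, scheme)
  f0 <- G(0)
  if (f0 <= tol) return(0)            # disordered, zero-field case
  f1 <- G(1) - 1
  if (f1 >= 0) return(1)              # deterministic limit
  uniroot(function(q) G(q) - q, c(0, 1), f.lower = f0, f.upper = f1,
          tol = tol)$root
}

# Field-averaged ingredients of the entropy formulas at steady state:
# t1 = <Int Dz tanh>, t2m = <Int Dz (1 - tanh^2)>, lc = <Int Dz log 2cosh>,
# drive = <beta (theta + j0 m) Int Dz tanh>.
entropy_ingredients <- function(beta, j0, dj, m, dh = 0, theta = NULL,
                                scheme = quad_scheme()) {
  fld <- field_nodes(dh, theta, scheme)
  per <- vapply(fld$theta, function(th) {
    a <- beta * dj; b <- beta * (th + j0 * m)
    t1 <- gauss_mean_tanh(a, b, scheme)
    t2m <- gauss_mean_sech2(a, b, scheme)
    lc <- gauss_mean_log2cosh(a, b, scheme)
    c(t1 = t1, t2m = t2m, lc = lc, drive = b * t1)
  }, c(t1 = 0, t2m = 0, lc = 0, drive = 0))
  drop(per %*% fld$w)
}

#' Mean-field entropy rate, its time reversal, and entropy production
#'
#' Per-spin steady-state path quantities of the infinite synchronous model,
#' in nats per step. The conditional entropy (entropy rate) is
#' `S = -beta (theta + J0 m) <tanh> - beta^2 dJ^2 <sech^2> + <log 2cosh>`,
#' the time-reversed conditional entropy replaces the `sech^2` weight by
#' `q` times it, and their difference is the steady-state entropy
#' production `sigma = beta^2 dJ^2 (1 - q) <sech^2> >= 0` (clipped at zero
#' for round-off).
#'
#' @inheritParams solve_steady_q
#' @param q Steady-state delayed self-correlation from [solve_steady_q()].
#' @return A scalar, nats per step per spin.
#' @export
conditional_entropy_rate <- function(beta, j0 = 1, dj = 0.5, m, q, dh = 0,
                                     theta = NULL, scheme = quad_scheme()) {
  ing <- entropy_ingredients(beta, j0, dj, m, dh, theta, scheme)
  -ing[["drive"]] - beta^2 * dj^2 * ing[["t2m"]] + ing[["lc"]]
}

#' @rdname conditional_entropy_rate
#' @export
reversed_conditional_entropy_rate <- function(beta, j0 = 1, dj = 0.5, m, q,
                                              dh = 0, theta = NULL,
                                              scheme = quad_scheme()) {
  ing <- entropy_ingredients(beta, j0, dj, m, dh, theta, scheme)
  -ing[["drive"]] - beta^2 * dj^2 * q * ing[["t2m"]] + ing[["lc"]]
}

#' @rdname conditional_entropy_rate
#' @export
entropy_production_sync <- function(beta, j0 = 1, dj = 0.5, m, q, dh = 0,
                                    theta = NULL, scheme = quad_scheme()) {
  ing <- entropy_ingredients(beta, j0, dj, m, dh, theta, scheme)
  max(0, beta^2 * dj^2 * (1 - q) * ing[["t2m"]])
}

#' Solve the full mean-field steady state
#'
#' Convenience wrapper: solves the order parameters and evaluates the
#' per-spin thermodynamic quantities for one parameter point. For
#' asynchronous updates the steady `m` and `q` coincide with the
#' synchronous ones, and the entropy production becomes a rate per unit
#' time computed from the two-time correlation gap (see
#' [async_gap_correlation()]).
#'
#' @inheritParams solve_steady_m
#' @param update `"synchronous"` or `"asynchronous"`.
#' @return An object of class `"sk_meanfield"`; use [tidy()] for a
#'   one-row tibble.
#' @examples
#' fit <- sk_meanfield(beta = 2, dj = 0.5)
#' tidy(fit)
#' @export
sk_meanfield <- function(beta, j0 = 1, dj = 0.5, dh = 0, theta = NULL,
                         update = c("synchronous", "asynchronous"),
                         scheme = quad_scheme()) {
  update <- match.arg(update)
  msol <- solve_steady_m(beta, j0, dj, dh, theta, scheme, full = TRUE)
  m <- msol$m
  q <- solve_steady_q(beta, j0, dj, m, dh, theta, scheme)
  ing <- entropy_ingredients(beta, j0, dj, m, dh, theta, scheme)
  s_cond <- -ing[["drive"]] - beta^2 * dj^2 * ing[["t2m"]] + ing[["lc"]]
  s_rev <- -ing[["drive"]] - beta^2 * dj^2 * q * ing[["t2m"]] + ing[["lc"]]
  out <- list(beta = beta, j0 = j0, dj = dj, dh = dh, theta = theta,
              update = update, m = m, q = q, s_cond = s_cond, s_rev = s_rev,
              sigma = max(0, s_rev - s_cond), q_gap = NA_real_,
              stable = msol$stable, converged = msol$converged,
              branches = msol$branches, scheme = scheme)
  if (update == "asynchronous") {
    gap <- async_gap_correlation(beta, j0, dj, dh, theta, m = m, q = q,
                                 scheme = scheme)
    out$q_gap <- gap$q_gap
    out$sigma <- entropy_production_rate_async(beta, j0, dj,
                                               q_gap = gap$q_gap, m = m,
                                               dh = dh, theta = theta,
                                               scheme = scheme)
  }
  structure(out, class = "sk_meanfield")
}

#' @export
print.sk_meanfield <- function(x, ...) {
  unit <- if (x$update == "synchronous") "nats/step" else "nats/time"
  cat(sprintf(
    "<sk_meanfield> %s: beta = %.4g, J0 = %.4g, dJ = %.4g, dH = %.4g\n",
    x$update, x$beta, x$j0, x$dj, x$dh))
  cat(sprintf("  m = %.6f, q = %.6f%s\n", x$m, x$q,
              if (is.na(x$q_gap)) "" else sprintf(", q_gap = %.6f", x$q_gap)))
  cat(sprintf("  entropy rate = %.6f, reversed = %.6f, production = %.6f %s (per spin)\n",
              x$s_cond, x$s_rev, x$sigma, unit))
  invisible(x)
}

#' @method tidy sk_meanfield
#' @export
tidy.sk_meanfield <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, j0 = x$j0, dj = x$dj, dh = x$dh, update = x$update,
    m = x$m, q = x$q, q_gap = x$q_gap, s_cond = x$s_cond, s_rev = x$s_rev,
    sigma = x$sigma
  )
}

#' @method glance sk_meanfield
#' @export
glance.sk_meanfield <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, stable = x$stable,
    m_ordered = x$branches[["ordered"]],
    m_disordered = x$branches[["disordered"]],
    n_hermite = x$scheme$n_hermite, n_bivariate = x$scheme$n_bivariate
  )
}
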