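# Lean single-cell mean-field evaluation shared by the sweep drivers.
mf_cell <- function(beta, j0, dj, dh = 0, theta = NULL,
                    scheme = quad_scheme()) {
  # non-convergence is reported through the `converged` flag, not as a
  # per-cell warning
  msol <- suppressWarnings(
    solve_steady_m(beta, j0, dj, dh, theta, scheme, full = TRUE))
  q <- solve_steady_q(beta, j0, dj, msol$m, dh, theta, scheme)
  ing <- entropy_ingredients(beta, j0, dj, msol$m, dh, theta, scheme)
  s_cond <- -ing[["drive"]] - beta^2 * dj^2 * ing[["t2m"]] + ing[["lc"]]
  s_rev <- -ing[["drive"]] - beta^2 * dj^2 * q * ing[["t2m"]] + ing[["lc"]]
  c(m = msol$m, q = q, s_cond = s_cond, s_rev = s_rev,
    sigma = max(0, beta^2 * dj^2 * (1 - q) * ing[["t2m"]]),
    converged = as.numeric(msol$converged))
}

#' Mean-field phase-diagram sweep
#'
#' Evaluates the steady-state order parameters and per-spin thermodynamic
#' quantities over a 2-d parameter grid: the `"beta-dJ"` plane at fixed
#' `dh`, or the `"beta-dH"` plane at fixed `dj`. Cells where the
#' magnetization iteration hit its cap are flagged (`converged = FALSE`),
#' not fatal. The result carries the matching critical line for overlay in
#' [autoplot()].
#'
#' @param plane `"beta-dJ"` or `"beta-dH"`.
#' @param beta,dj,dh Grid axes (vectors) or fixed values, per `plane`.
#' @param j0 Mean coupling scale.
#' @param scheme A [quad_scheme()].
#' @param verbose Print progress every 25 cells.
#' @return A tibble of class `"sk_phase_grid"` with one row per cell:
#'   `beta`, `dj`, `dh`, `m`, `q`, `s_cond`, `s_rev`, `sigma`, `converged`.
#' @examples
#' \donttest{
#' grid <- phase_diagram_sweep("beta-dJ", beta = seq(0, 3, 0.5),
#'                             dj = seq(0.1, 1.1, 0.5))
#' }
#' @export
phase_diagram_sweep <- function(plane = c("beta-dJ", "beta-dH"),
                                beta = seq(0, 4, 0.05),
                                dj = seq(0, 3, 0.05),
                                dh = seq(0, 2, 0.05),
                                j0 = 1, scheme = quad_scheme(),
                                verbose = FALSE) {
  plane <- match.arg(plane)
  if (plane == "beta-dJ") {
    if (length(dh) > 1) stop("`dh` must be fixed in the beta-dJ plane",
                             call. = FALSE)
    cells <- tidyr::expand_grid(beta = beta, dj = dj, dh = dh)
  } else {
    if (length(dj) > 1) stop("`dj` must be fixed in the beta-dH plane",
                             call. = FALSE)
    cells <- tidyr::expand_grid(beta = beta, dh = dh, dj = dj)
  }
  vals <- matrix(NA_real_, nrow(cells), 6)
  for (k in seq_len(nrow(cells))) {
    vals[k, ] <- mf_cell(cells$beta[k], j0, cells$dj[k], cells$dh[k],
                         scheme = scheme)
    if (verbose && k %% 25 == 0) {
      message(sprintf("cell %d / %d", k, nrow(cells)))
    }
  }
  colnames(vals) <- c("m", "q", "s_cond", "s_rev", "sigma", "converged")
  out <- dplyr::bind_cols(cells, tibble::as_tibble(vals))
  out$converged <- as.logical(out$converged)
  out$j0 <- j0
  crit <- if (plane == "beta-dJ") {
    critical_line(beta[beta * j0 > 1], j0 = j0, what = "dj", scheme = scheme)
  } else {
    critical_line(beta[beta * j0 > 1], j0 = j0, dj = dj[1], what = "dh",
                  scheme = scheme)
  }
  structure(out, class = c("sk_phase_grid", class(out)),
            plane = plane, critical = crit)
}

#' Finite-size convergence study against the mean-field theory
#'
#' Simulates the model at a series of system sizes and compares the
#' trajectory estimators (mean activation, delayed self-covariance,
#' entropy production) at the final time with the thermodynamic-limit
#' values, as a function of `beta`. Synchronous mode uses the vectorized
#' batch simulator; asynchronous mode runs streaming single-spin chains.
#'
#' @param n_values System sizes, e.g. `c(32, 128, 512)`.
#' @param beta Vector of inverse temperatures.
#' @param j0,dj Coupling ensemble parameters (zero fields).
#' @param t_steps Time units per run.
#' @param n_reps Replicate chains per (N, beta) for synchronous runs;
#'   asynchronous runs use `n_reps` chains with time-averaged estimators.
#' @param mode `"synchronous"` or `"asynchronous"`.
#' @param seed Master seed; each (N, beta) cell derives its own stream.
#' @param scheme A [quad_scheme()].
#' @return Tibble with one row per (N, beta): estimator values, standard
#'   errors, mean-field values and absolute gaps.
#' @export
convergence_study <- function(n_values = c(32, 128, 512),
                              beta = c(0.5, 2), j0 = 1, dj = 0.5,
                              t_steps = 128, n_reps = 1000,
                              mode = c("synchronous", "asynchronous"),
                              seed = 1, scheme = quad_scheme()) {
  mode <- match.arg(mode)
  rows <- list()
  k <- 0
  for (b in beta) {
    mf <- mf_cell(b, j0, dj, scheme = scheme)
    sigma_th <- if (mode == "synchronous") {
      mf[["sigma"]]
    } else {
      entropy_production_rate_async(b, j0, dj, m = mf[["m"]], scheme = scheme)
    }
    for (n in n_values) {
      k <- k + 1
      cell_seed <- split_seed(seed + 7919L * k)
      model <- sk_model(n, beta = b, j0 = j0, dj = dj, update = mode)
      real <- sk_realization(model, seed = cell_seed[["couplings"]])
      if (mode == "synchronous") {
        withr_seed(cell_seed[["trajectory"]])
        S0 <- matrix(1, n_reps, n)
        res <- sim_sync_core(real$J, real$theta, b, t_steps, S0,
                             store = FALSE)
        m_rep <- rowMeans(res$final)
        q_rep <- rowMeans(res$final * res$prev)
        sig_rep <- sigma_rep_sync(res$final, res$prev, real, b)
        est <- c(mean(m_rep), sd(m_rep) / sqrt(n_reps),
                 mean(q_rep), sd(q_rep) / sqrt(n_reps),
                 mean(sig_rep), sd(sig_rep) / sqrt(n_reps))
      } else {
        withr_seed(cell_seed[["trajectory"]])
        ch <- lapply(seq_len(n_reps), function(r) {
          cpp_async_chain(real$J, real$theta, b, as.integer(t_steps),
                          rep(1L, n), 0L, 10L * n,
                          as.integer(max(1, t_steps %/% 4)))
        })
        g <- function(f) vapply(ch, function(x) x[[f]], 0)
        mh <- g("m_hat"); qh <- g("q_hat"); eh <- g("ep_rate")
        est <- c(mean(mh), sd(mh) / sqrt(n_reps),
                 mean(qh), sd(qh) / sqrt(n_reps),
                 mean(eh), sd(eh) / sqrt(n_reps))
      }
      rows[[k]] <- tibble::tibble(
        n_spins = n, beta = b, dj = dj, j0 = j0, mode = mode,
        n_reps = n_reps, t_steps = t_steps, seed = seed,
        m_hat = est[1], m_se = est[2], q_hat = est[3], q_se = est[4],
        sigma_hat = est[5], sigma_se = est[6],
        m_theory = mf[["m"]], q_theory = mf[["q"]], sigma_theory = sigma_th,
        m_gap = abs(est[1] - mf[["m"]]),
        sigma_gap = abs(est[5] - sigma_th)
      )
    }
  }
  dplyr::bind_rows(rows)
}
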