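test_that("synchronous step follows the sign of the field at large beta", {
  r <- make_real(8, beta = 1000, dj = 0, j0 = 1, seed = 1)
  set.seed(1)
  nxt <- step_synchronous(rep(1, 8), r)   # h_i = 1 > 0 for all i
  expect_identical(nxt, rep(1, 8))
})

test_that("infinite-temperature kernel is uniform over states", {
  r <- make_real(4, beta = 0, dj = 0.7, seed = 2)
  traj <- simulate_sk(r, t_steps = 1, n_reps = 1e5, seed = 3)
  idx <- drop((traj$states[, 2, ] + 1) %/% 2 %*% 2^(0:3))
  tab <- tabulate(idx + 1, nbins = 16)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 1e-3)
})

test_that("one-step frequencies match the exact kernel", {
  r <- make_real(3, beta = 1.2, dj = 0.8, seed = 4)
  prev <- c(1, -1, 1)
  traj <- simulate_sk(r, t_steps = 1, n_reps = 1e5, seed = 6, init = prev)
  idx <- drop((traj$states[, 2, ] + 1) %/% 2 %*% 2^(0:2))
  freq <- tabulate(idx + 1, nbins = 8) / 1e5
  p_exact <- apply(enumerate_states(3), 1, transition_probability,
                   prev_state = prev, realization = r)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_true(all(abs(freq - p_exact) < 3 * se + 1e-4))
})

test_that("asynchronous micro-steps flip at most one spin", {
  model <- sk_model(6, beta = 1, dj = 0.5, update = "asynchronous")
  r <- sk_realization(model, seed = 8)
  traj <- simulate_sk(r, t_steps = 10, n_reps = 2, seed = 9, record = "micro")
  st <- traj$states
  for (rep in 1:2) {
    d <- abs(diff(st[rep, , ]))
    expect_true(all(rowSums(d != 0) <= 1))
  }
  expect_equal(dim(traj$update_mask), c(2, 60))
  # beta = 0: the redrawn spin is +-1 with equal probability
  model0 <- sk_model(4, beta = 0, dj = 0.5, update = "asynchronous")
  r0 <- sk_realization(model0, seed = 10)
  tr0 <- simulate_sk(r0, t_steps = 500, n_reps = 1, seed = 11,
                     record = "micro")
  flips <- tr0$states[1, -1, ][cbind(seq_len(2000), tr0$update_mask[1, ])]
  expect_lt(abs(mean(flips)), 3 / sqrt(2000))
})

test_that("trajectories have the documented shape and are reproducible", {
  r <- make_real(5, beta = 1, dj = 0.5, seed = 12)
  t1 <- simulate_sk(r, t_steps = 7, n_reps = 3, seed = 13)
  expect_equal(dim(t1$states), c(3, 8, 5))
  expect_true(all(t1$states %in% c(-1L, 1L)))
  t2 <- simulate_sk(r, t_steps = 7, n_reps = 3, seed = 13)
  expect_identical(t1$states, t2$states)
})

test_that("homogeneous-coupling simulation hits the Curie-Weiss fixed point", {
  cw <- uniroot(function(m) tanh(2 * m) - m, c(0.1, 1), tol = 1e-12)$root
  r <- make_real(512, beta = 2, dj = 0, j0 = 1, seed = 14)
  traj <- simulate_sk(r, t_steps = 30, n_reps = 300, seed = 15)
  est <- estimate_order_parameters(traj)
  expect_lt(abs(est$m_hat - cw), 2 * est$m_se + 5e-3)
})

test_that("order-parameter estimators handle degenerate trajectories", {
  const <- structure(list(states = array(1L, c(4, 6, 3)),
                          time_unit = "step",
                          model = sk_model(3, beta = 1, dj = 0.5)),
                     class = "sk_trajectory")
  est <- estimate_order_parameters(const)
  expect_equal(est$m_hat, 1)
  expect_equal(est$q_hat, 1)
  # two replicates alternating in opposite phase: zero mean, q(1) = -1
  alt <- array(0L, c(2, 6, 2))
  for (u in 1:6) { alt[1, u, ] <- (-1L)^u; alt[2, u, ] <- -(-1L)^u }
  alternating <- structure(list(states = alt, time_unit = "step",
                                model = sk_model(2, beta = 1, dj = 0.5)),
                           class = "sk_trajectory")
  est2 <- estimate_order_parameters(alternating)
  expect_equal(est2$q_hat, -1)
  expect_equal(est2$m_hat, 0)
  expect_error(estimate_order_parameters(const, lag = 10), "lag exceeds")
})

test_that("entropy production estimator is consistent with the enumeration oracle", {
  r <- make_real(5, beta = 1, dj = 0.6, seed = 16)
  exact <- exact_thermo(exact_chain(r), per_spin = TRUE)$sigma
  sds <- numeric(2)
  for (k in 1:2) {
    reps <- c(1000, 10000)[k]
    traj <- simulate_sk(r, t_steps = 25, n_reps = reps, seed = 17 + k)
    est <- estimate_entropy_production(traj, r)
    expect_lt(abs(est$sigma_hat - exact), 3 * est$sigma_se)
    sds[k] <- est$sigma_se
  }
  # standard error shrinks roughly as 1/sqrt(reps)
  expect_equal(sds[1] / sds[2], sqrt(10), tolerance = 0.35)
})

test_that("symmetrized couplings yield statistically zero entropy production", {
  r <- symmetrize(make_real(6, beta = 1, dj = 0.6, seed = 19))
  traj <- simulate_sk(r, t_steps = 40, n_reps = 5000, seed = 20)
  est <- estimate_entropy_production(traj, r)
  expect_lt(abs(est$sigma_hat), 3 * est$sigma_se)
})
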