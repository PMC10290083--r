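test_that("coupling draws have the prescribed ensemble moments", {
  # zero heterogeneity: every entry is exactly j0/N
  m0 <- sk_model(4, beta = 1, j0 = 1, dj = 0)
  expect_equal(sample_couplings(m0, seed = 1),
               matrix(0.25, 4, 4))

  # dj = 0.5, j0 = 1 at N = 1024: sample moments within 3 SE of J0/N and
  # dJ^2/N
  m1 <- sk_model(1024, beta = 1, j0 = 1, dj = 0.5)
  J <- sample_couplings(m1, seed = 7)
  n_entries <- length(J)
  mu <- 1 / 1024
  v <- 0.25 / 1024
  expect_lt(abs(mean(J) - mu), 3 * sqrt(v / n_entries))
  expect_lt(abs(var(as.vector(J)) - v), 3 * v * sqrt(2 / (n_entries - 1)))

  # reproducible under seed; diagonal flag zeroes self-couplings
  expect_identical(J, sample_couplings(m1, seed = 7))
  Jz <- sample_couplings(m1, seed = 7, zero_diagonal = TRUE)
  expect_true(all(diag(Jz) == 0))
  expect_error(sk_model(0, beta = 1), "positive integer")
})

test_that("coupling variance scales as 1/N", {
  v <- vapply(c(64, 256, 1024), function(n) {
    var(as.vector(sample_couplings(sk_model(n, beta = 1, dj = 0.5), seed = 3)))
  }, 0)
  slope <- coef(lm(log(v) ~ log(c(64, 256, 1024))))[2]
  expect_equal(unname(slope), -1, tolerance = 0.05)
})

test_that("uniform field draws match their moments", {
  expect_identical(sample_fields(sk_model(16, beta = 1, dh = 0), seed = 1),
                   numeric(16))
  m <- sk_model(20000, beta = 1, dh = 0.5)
  th <- sample_fields(m, seed = 5)
  n <- length(th)
  v <- 0.5^2 / 3
  expect_lt(abs(mean(th)), 3 * sqrt(v / n))
  expect_lt(abs(var(th) - v), 3 * v * sqrt(2 / (n - 1)))
  expect_error(sk_model(4, beta = 1, dh = -0.1), "non-negative")
})

test_that("local fields agree with the explicit double loop", {
  r <- make_real(5, beta = 1, dj = 0.8, seed = 2)
  r$theta <- c(-0.2, 0.1, 0, 0.3, -0.1)
  s_prev <- c(1, -1, 1, 1, -1)
  s_next <- c(-1, -1, 1, -1, 1)
  lf <- local_fields(r, s_prev, s_next)
  h_loop <- vapply(1:5, function(i) {
    r$theta[i] + sum(vapply(1:5, function(j) r$J[i, j] * s_prev[j], 0))
  }, 0)
  hr_loop <- vapply(1:5, function(i) {
    r$theta[i] + sum(vapply(1:5, function(j) r$J[i, j] * s_next[j], 0))
  }, 0)
  expect_equal(lf$h, h_loop, tolerance = 1e-14)
  expect_equal(lf$h_rev, hr_loop, tolerance = 1e-14)

  # J = 0 leaves only the external field
  r0 <- r; r0$J <- matrix(0, 5, 5)
  expect_equal(local_fields(r0, s_prev)$h, r0$theta)

  # two mutually coupled spins
  r2 <- make_real(2, beta = 1, dj = 0, seed = 1)
  r2$J <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(local_fields(r2, c(1, 1))$h, c(1, 1))
  expect_error(local_fields(r, c(1, -1)), "length")
  expect_error(local_fields(r, c(1, 2, 1, 1, 1)), "-1 or \\+1")
})

test_that("transition kernel is correctly normalized and reduces at beta = 0", {
  r0 <- make_real(4, beta = 0, dj = 0.7, seed = 4)
  states <- enumerate_states(4)
  p <- apply(states, 1, function(s) {
    transition_probability(r0, s, c(1, 1, -1, 1))
  })
  expect_equal(p, rep(2^-4, 16))

  # one spin, closed form
  r1 <- make_real(1, beta = 1.3, dj = 0, j0 = 0, seed = 1)
  r1$theta <- 0.6
  expect_equal(transition_probability(r1, 1, 1),
               exp(1.3 * 0.6) / (2 * cosh(1.3 * 0.6)))

  # normalization over all 2^N arrival states at finite beta
  r <- make_real(8, beta = 1.5, dj = 0.8, seed = 9)
  states <- enumerate_states(8)
  prev <- states[101, ]
  tot <- sum(apply(states, 1, transition_probability, prev_state = prev,
                   realization = r))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("transition energies are negative log kernel probabilities", {
  r <- make_real(6, beta = 1.2, dj = 0.6, seed = 5)
  s1 <- c(1, -1, 1, 1, -1, -1)
  s2 <- c(-1, -1, 1, -1, 1, 1)
  expect_equal(epsilon_forward(r, s2, s1),
               -log(transition_probability(r, s2, s1)), tolerance = 1e-12)
  expect_gte(epsilon_forward(r, s2, s1), 0)

  r0 <- make_real(6, beta = 0, dj = 0.6, seed = 5)
  expect_equal(epsilon_forward(r0, s2, s1), 6 * log(2))
  expect_equal(epsilon_reverse(r0, s2, s1), 6 * log(2))
})

test_that("symmetric couplings make the stationary energy flow vanish", {
  # <eps_reverse - eps_forward> under the exact stationary chain is the
  # bath entropy flow; detailed balance (symmetric J, zero diagonal) kills it
  r <- symmetrize(make_real(5, beta = 1.1, dj = 0.7, seed = 8))
  ch <- exact_chain(r)
  flow <- exact_thermo(ch)$sigma_bath
  expect_lt(abs(flow), 1e-10)
})

test_that("realizations round-trip through TSV", {
  r <- make_real(6, beta = 1.7, dj = 0.4, seed = 21)
  path <- tempfile(fileext = ".tsv")
  write_realization_tsv(r, path)
  r2 <- read_realization_tsv(path)
  expect_equal(r2$J, r$J, tolerance = 1e-15)
  expect_equal(r2$theta, r$theta)
  expect_equal(r2$model$beta, r$model$beta)
  expect_equal(r2$seed, r$seed)
  unlink(path)
})
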