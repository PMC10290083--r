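test_that("magnetization solver recovers scalar fixed points", {
  # dJ = 0 reduces to the Curie-Weiss equation m = tanh(beta J0 m);
  # independent oracle by bisection on the scalar equation
  cw <- uniroot(function(m) tanh(2 * m) - m, c(0.1, 1), tol = 1e-12)$root
  expect_equal(solve_steady_m(beta = 2, j0 = 1, dj = 0), cw,
               tolerance = 1e-8)
  expect_equal(solve_steady_m(beta = 0, j0 = 1, dj = 0.5), 0,
               tolerance = 1e-10)
  # coupling width beyond the zero-temperature critical value: disordered
  # at every temperature
  expect_equal(solve_steady_m(beta = 2, j0 = 1, dj = 1.0), 0,
               tolerance = 1e-8)
  full <- solve_steady_m(beta = 2, j0 = 1, dj = 0.5, full = TRUE)
  expect_true(full$converged)
  expect_true(full$stable)
  expect_gt(full$branches[["ordered"]], 0.7)
})

test_that("delayed self-correlation solves its self-consistency", {
  expect_equal(solve_steady_q(beta = 0, dj = 0.5, m = 0), 0)
  # disordered zero-field phase: m = 0 forces q = 0
  m <- solve_steady_m(beta = 0.5, dj = 0.5)
  expect_equal(solve_steady_q(beta = 0.5, dj = 0.5, m = m), 0)
  # the solution satisfies q = G(q) away from trivial points
  m2 <- solve_steady_m(beta = 2, dj = 0.5)
  q2 <- solve_steady_q(beta = 2, dj = 0.5, m = m2)
  G <- kineticSK:::q_map(2, 1, 0.5, m2)
  expect_equal(G(q2), q2, tolerance = 1e-9)
  # heterogeneous fields sustain q > 0 in the m = 0 region
  m3 <- solve_steady_m(beta = 2, dj = 1.2, dh = 0.5)
  q3 <- solve_steady_q(beta = 2, dj = 1.2, m = m3, dh = 0.5)
  expect_lt(abs(m3), 1e-8)
  expect_gt(q3, 0.01)
})

test_that("entropy formulas obey their limits and the production identity", {
  expect_equal(conditional_entropy_rate(0, 1, 0.5, 0, 0), log(2),
               tolerance = 1e-12)
  expect_equal(reversed_conditional_entropy_rate(0, 1, 0.5, 0, 0), log(2),
               tolerance = 1e-12)
  expect_equal(entropy_production_sync(0, 1, 0.5, 0, 0), 0)
  # no coupling heterogeneity, no irreversibility
  m <- solve_steady_m(2, 1, 0)
  expect_equal(entropy_production_sync(2, 1, 0, m, solve_steady_q(2, 1, 0, m)),
               0, tolerance = 1e-12)
  # quasi-deterministic ordered branch: vanishing entropy rate
  m4 <- solve_steady_m(100, 1, 0.2)
  q4 <- solve_steady_q(100, 1, 0.2, m4)
  expect_lt(abs(conditional_entropy_rate(100, 1, 0.2, m4, q4)), 0.01)
  # sigma = S_rev - S across a parameter grid, to 1e-10
  for (beta in c(0, 0.5, 1, 1.5, 2, 3, 4)) {
    for (dj in c(0.1, 0.5, 1, 2, 3)) {
      m <- suppressWarnings(solve_steady_m(beta, 1, dj))
      q <- solve_steady_q(beta, 1, dj, m)
      s <- conditional_entropy_rate(beta, 1, dj, m, q)
      sr <- reversed_conditional_entropy_rate(beta, 1, dj, m, q)
      sig <- entropy_production_sync(beta, 1, dj, m, q)
      expect_lt(abs(sig - (sr - s)), 1e-10)
      expect_gte(sig, 0)
    }
  }
})

test_that("sk_meanfield wrapper and tidiers are coherent", {
  fit <- sk_meanfield(beta = 2, dj = 0.5)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$sigma, fit$s_rev - fit$s_cond, tolerance = 1e-10)
  expect_true(all(abs(c(td$m, td$q)) <= 1))
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("critical coupling line behaves across temperature", {
  # Curie-Weiss limit: dJ_c -> 0 as beta -> 1/J0 from above
  expect_lt(critical_dj(1.01), 0.11)
  expect_true(is.na(critical_dj(0.9)))
  # deterministic limit of the self-consistency
  expect_equal(critical_dj(1000), sqrt(2 / pi), tolerance = 1e-4)
  expect_equal(critical_dj(Inf), sqrt(2 / pi), tolerance = 1e-12)
  # stable across quadrature resolutions
  d1 <- critical_dj(2, scheme = quad_scheme(n_hermite = 100))
  d2 <- critical_dj(2, scheme = quad_scheme(n_hermite = 400))
  expect_lt(abs(d1 - d2), 1e-8)
})

test_that("critical field line requires dH below J0", {
  expect_equal(critical_dh(Inf, j0 = 1, dj = 0.2), 1, tolerance = 1e-4)
  # rhs <= 1 always: no root at or above J0, and none at beta = 0
  expect_true(is.na(critical_dh(0, j0 = 1, dj = 0.2)))
  expect_true(is.na(critical_dh(0.5, j0 = 1, dj = 0.2)))
  dhc <- critical_dh(4, j0 = 1, dj = 0.2)
  expect_true(dhc > 0 && dhc < 1)
  tab <- critical_line(c(2, 4), dj = 0.2)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$quantity), c("dj_c", "dh_c"))
})

test_that("ordered branch bifurcates exactly at the critical line", {
  # fixed dJ = 0.5: m = 0 below the critical beta, m > 0 above, resolved
  # at 0.01 in beta
  bc <- uniroot(function(b) critical_dj(b) - 0.5, c(1.05, 3), tol = 1e-10)$root
  for (db in c(-0.05, -0.02, -0.01)) {
    expect_lt(suppressWarnings(solve_steady_m(bc + db, 1, 0.5)), 2e-3)
  }
  for (db in c(0.01, 0.02, 0.05)) {
    expect_gt(suppressWarnings(solve_steady_m(bc + db, 1, 0.5)), 0.05)
  }
})
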