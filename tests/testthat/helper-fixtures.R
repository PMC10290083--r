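# Small quenched systems used across tests; built fresh each run.
make_real <- function(n = 5, beta = 1, dj = 0.5, j0 = 1, seed = 11,
                      update = "synchronous", ...) {
  sk_realization(sk_model(n, beta = beta, j0 = j0, dj = dj, update = update),
                 seed = seed, ...)
}

# Same realization with symmetrized couplings and zero diagonal: an
# equilibrium chain obeying detailed balance.
symmetrize <- function(realization) {
  J <- (realization$J + t(realization$J)) / 2
  diag(J) <- 0
  realization$J <- J
  realization
}

# Light quadrature for tests where 1e-6 accuracy suffices.
fast_scheme <- quad_scheme(n_hermite = 80, n_bivariate = 60, n_field = 32)
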