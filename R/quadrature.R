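#' Quadrature scheme for Gaussian and field averages
#'
#' The mean-field solutions average smooth bounded integrands against the
#' standard normal measure `Dz` (Gauss--Hermite nodes with the change of
#' variable `z = sqrt(2) x`), a correlated bivariate normal measure
#' `Dxy^(q)` (realized as `y = q x + sqrt(1-q^2) z` over a product grid),
#' and -- for heterogeneous fields -- a uniform measure on `[-dh, dh]`
#' (Gauss--Legendre nodes). Weights sum to one within 1e-12.
#'
#' @param n_hermite Univariate Hermite node count (default 200).
#' @param n_bivariate Nodes per axis of the bivariate product rule
#'   (default 100).
#' @param n_field Legendre node count for the uniform field average
#'   (default 64).
#' @return An object of class `"sk_quadrature"` with node/weight arrays.
#' @examples
#' s <- quad_scheme()
#' expect_Dz(function(z) z^2, s) # 1
#' @export
quad_scheme <- function(n_hermite = 200, n_bivariate = 100, n_field = 64) {
  gh <- pracma::gaussHermite(n_hermite)
  gh2 <- pracma::gaussHermite(n_bivariate)
  structure(
    list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi),
         z2 = sqrt(2) * gh2$x, w2 = gh2$w / sqrt(pi),
         n_hermite = n_hermite, n_bivariate = n_bivariate,
         n_field = n_field),
    class = "sk_quadrature"
  )
}

#' Expectation against the standard normal measure
#'
#' @param f Vectorized function of one argument.
#' @param scheme A [quad_scheme()].
#' @return `E[f(Z)]`, `Z ~ N(0, 1)`.
#' @export
expect_Dz <- function(f, scheme = quad_scheme()) {
  v <- f(scheme$z)
  if (any(!is.finite(v))) stop("integrand is non-finite at quadrature nodes",
                               call. = FALSE)
  sum(scheme$w * v)
}

#' Expectation against correlated standard normals
#'
#' `E[f(X) g(Y)]` for standard normal `X`, `Y` with correlation `q`,
#' via the substitution `Y = q X + sqrt(1-q^2) Z`.
#'
#' @param f,g Vectorized functions.
#' @param q Correlation, `|q| <= 1`.
#' @inheritParams expect_Dz
#' @export
expect_Dxy <- function(f, g, q, scheme = quad_scheme()) {
  if (abs(q) > 1) stop("|q| must be <= 1", call. = FALSE)
  x <- scheme$z2; w <- scheme$w2
  s <- sqrt(max(0, 1 - q^2))
  # y-grid: rows index x, cols index z
  Y <- outer(q * x, s * x, "+")
  gy <- matrix(g(as.vector(Y)), length(x), length(x))
  inner <- drop(gy %*% w)
  sum(w * f(x) * inner)
}

# Scale-aware Gaussian expectations of the tanh family.
#
# E_z[f(a z + b)] for z ~ N(0,1). Hermite nodes resolve the transition
# region of tanh/sech^2 only while its width 1/a is comparable to the node
# spacing; beyond a = 1 the expectation is rewritten on the kernel's own
# scale. sech^2 and the residuals tanh(u) - sign(u), log2cosh(u) - |u|
# decay exponentially, so a fixed Legendre rule on u in [-30, 30] with the
# slowly varying factor phi((u - b)/a)/a is exact to machine precision,
# and the |.|/sign parts have closed forms under the normal law.
u_kernel_nodes <- function() {
  gl <- pracma::gaussLegendre(400, -30, 30)
  list(u = gl$x, w = gl$w)
}
.quad_cache <- new.env(parent = emptyenv())
get_u_nodes <- function() {
  if (is.null(.quad_cache$u_nodes)) .quad_cache$u_nodes <- u_kernel_nodes()
  .quad_cache$u_nodes
}

gauss_mean_tanh <- function(a, b, scheme = quad_scheme()) {
  if (a == 0) return(tanh(b))
  if (a <= 1) return(sum(scheme$w * tanh(a * scheme$z + b)))
  un <- get_u_nodes()
  sign_part <- 1 - 2 * stats::pnorm(-b / a)       # E[sign(a z + b)]
  resid <- sum(un$w * (tanh(un$u) - sign(un$u)) *
                 stats::dnorm((un$u - b) / a)) / a
  sign_part + resid
}

gauss_mean_sech2 <- function(a, b, scheme = quad_scheme()) {
  if (a == 0) return(1 - tanh(b)^2)
  if (a <= 1) return(sum(scheme$w * (1 - tanh(a * scheme$z + b)^2)))
  un <- get_u_nodes()
  sum(un$w * (1 - tanh(un$u)^2) * stats::dnorm((un$u - b) / a)) / a
}

gauss_mean_log2cosh <- function(a, b, scheme = quad_scheme()) {
  if (a == 0) return(log2cosh(b))
  if (a <= 1) return(sum(scheme$w * log2cosh(a * scheme$z + b)))
  un <- get_u_nodes()
  # E|X| for X ~ N(b, a^2), plus the exponentially decaying remainder
  abs_part <- b * (1 - 2 * stats::pnorm(-b / a)) + 2 * a * stats::dnorm(b / a)
  resid <- sum(un$w * log1p(exp(-2 * abs(un$u))) *
                 stats::dnorm((un$u - b) / a)) / a
  abs_part + resid
}

# Vectorized-in-b version of gauss_mean_tanh (same switching rule).
gauss_mean_tanh_vec <- function(a, b, scheme = quad_scheme()) {
  if (a == 0) return(tanh(b))
  if (a <= 1) {
    TY <- tanh(outer(b, a * scheme$z, "+"))
    return(drop(TY %*% scheme$w))
  }
  un <- get_u_nodes()
  sign_part <- 1 - 2 * stats::pnorm(-b / a)
  ker <- un$w * (tanh(un$u) - sign(un$u))
  resid <- drop(stats::dnorm(outer(b, un$u, function(bb, uu) (uu - bb) / a)) %*%
                  ker) / a
  sign_part + resid
}

# E[tanh(a X + b) tanh(a Y + b)] for standard normals with corr q,
# accurate at any scale a: the inner conditional average
# M(x) = E_z[tanh(a(qx + sz) + b)] is evaluated exactly by the
# scale-aware rule, and the outer integral splits tanh(a x + b) into its
# sign part (half-line integrals of the smooth M(x) phi(x)) and the
# exponentially localized kink part on the kernel scale.
biv_tanh_corr <- function(a, b, q, scheme = quad_scheme()) {
  s <- sqrt(max(0, 1 - q^2))
  M <- function(x) gauss_mean_tanh_vec(a * s, a * q * x + b, scheme)
  if (a <= 1) {
    x <- scheme$z2; w <- scheme$w2
    Y <- outer(q * x, s * x, "+")
    TY <- tanh(matrix(a * Y + b, length(x), length(x)))
    return(sum(w * tanh(a * x + b) * drop(TY %*% w)))
  }
  x0 <- max(-10, min(10, -b / a))
  half <- function(lo, hi) {
    if (hi - lo < 1e-14) return(0)
    gl <- pracma::gaussLegendre(200, lo, hi)
    sum(gl$w * stats::dnorm(gl$x) * M(gl$x))
  }
  sign_part <- half(x0, 10) - half(-10, x0)
  un <- get_u_nodes()
  xs <- (un$u - b) / a
  kink_part <- sum(un$w * (tanh(un$u) - sign(un$u)) * stats::dnorm(xs) *
                     M(xs)) / a
  sign_part + kink_part
}

# Field-average nodes: explicit theta list, or Legendre rule on [-dh, dh].
# Returns list(theta = nodes, w = weights summing to 1).
field_nodes <- function(dh = 0, theta = NULL, scheme = quad_scheme()) {
  if (!is.null(theta)) {
    return(list(theta = as.numeric(theta),
                w = rep(1 / length(theta), length(theta))))
  }
  if (dh == 0) return(list(theta = 0, w = 1))
  gl <- pracma::gaussLegendre(scheme$n_field, -dh, dh)
  list(theta = gl$x, w = gl$w / (2 * dh))
}
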