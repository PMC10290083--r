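#' Critical coupling heterogeneity of the order-disorder transition
#'
#' The ordered branch bifurcates where
#' `1 / (beta J0) = Int Dz (1 - tanh^2[beta dJ z])`. For `beta <= 1/J0` the
#' right-hand side cannot reach `1/(beta J0)` and no transition exists
#' (`NA` returned). `beta = Inf` gives the deterministic (sign-function)
#' limit `dJ_c = sqrt(2/pi) * J0`.
#'
#' @param beta Inverse temperature (may be `Inf`).
#' @param j0 Mean coupling scale.
#' @param scheme A [quad_scheme()].
#' @return Critical `dJ`, or `NA` when the transition does not exist.
#' @examples
#' critical_dj(Inf) # sqrt(2/pi)
#' @export
critical_dj <- function(beta, j0 = 1, scheme = quad_scheme()) {
  if (beta * j0 <= 1) return(NA_real_)
  if (is.infinite(beta)) return(sqrt(2 / pi) * j0)
  rhs <- function(dj) gauss_mean_sech2(beta * dj, 0, scheme)
  target <- 1 / (beta * j0)
  hi <- 1
  while (rhs(hi) > target && hi < 1e6) hi <- hi * 2
  uniroot(function(dj) rhs(dj) - target, c(1e-12, hi), tol = 1e-12)$root
}

#' Critical field heterogeneity with uniformly distributed fields
#'
#' Positive root of `dH / J0 = Int Dz tanh[beta (dH + dJ z)]`; the
#' right-hand side never exceeds 1, so the transition requires `dH < J0`.
#' The zero-temperature variant (`beta = Inf`) replaces `tanh` by the sign
#' function, `Int Dz sign(dH + dJ z) = erf(dH / (dJ sqrt(2)))`.
#'
#' @inheritParams critical_dj
#' @param dj Coupling heterogeneity.
#' @return Critical `dH`, or `NA` when no positive root exists.
#' @examples
#' critical_dh(Inf, dj = 0.2) # ~= 1
#' @export
critical_dh <- function(beta, j0 = 1, dj = 0.5, scheme = quad_scheme()) {
  rhs <- if (is.infinite(beta)) {
    function(dh) pracma::erf(dh / (dj * sqrt(2)))
  } else {
    function(dh) gauss_mean_tanh(beta * dj, beta * dh, scheme)
  }
  f <- function(dh) rhs(dh) - dh / j0
  # f(0) = 0 always; a positive root needs slope > 0 at 0
  eps <- 1e-6 * j0
  if (f(eps) <= 0) return(NA_real_)
  uniroot(f, c(eps, j0 * (1 - 1e-12)), tol = 1e-12)$root
}

#' Critical lines as a tidy table
#'
#' Evaluates [critical_dj()] and/or [critical_dh()] over a vector of
#' inverse temperatures.
#'
#' @inheritParams critical_dh
#' @param beta Vector of inverse temperatures.
#' @param what `"dj"`, `"dh"`, or both.
#' @return Tibble with columns `beta`, `quantity`, `value`.
#' @export
critical_line <- function(beta, j0 = 1, dj = 0.5, what = c("dj", "dh"),
                          scheme = quad_scheme()) {
  what <- match.arg(what, several.ok = TRUE)
  rows <- list()
  if ("dj" %in% what) {
    rows$dj <- tibble::tibble(
      beta = beta, quantity = "dj_c",
      value = vapply(beta, critical_dj, 0, j0 = j0, scheme = scheme))
  }
  if ("dh" %in% what) {
    rows$dh <- tibble::tibble(
      beta = beta, quantity = "dh_c",
      value = vapply(beta, critical_dh, 0, j0 = j0, dj = dj, scheme = scheme))
  }
  dplyr::bind_rows(rows)
}
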