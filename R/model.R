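#' Specify an asymmetric kinetic SK model
#'
#' Defines the disorder ensemble and dynamics of a kinetic Ising chain with
#' quenched Gaussian couplings: `N` spins `s_i = -1/+1`, inverse temperature
#' `beta`, couplings drawn independently with mean `j0/N` and variance
#' `dj^2/N`, and external fields that are either a fixed vector `theta` or
#' drawn uniformly on `[-dh, dh]`. Updates are parallel ("synchronous", all
#' spins redrawn each step) or single-spin ("asynchronous", N micro-updates
#' per unit time).
#'
#' @param n_spins Number of spins N (positive integer).
#' @param beta Inverse temperature, `beta >= 0`.
#' @param j0 Mean coupling scale J0; the coupling mean is `j0/N`.
#' @param dj Coupling heterogeneity (standard-deviation scale) `dj >= 0`;
#'   the coupling variance is `dj^2/N`.
#' @param dh Field heterogeneity: fields are i.i.d. uniform on `[-dh, dh]`.
#'   Ignored when `theta` is given.
#' @param theta Optional explicit field vector (length `n_spins` or scalar,
#'   recycled). Overrides `dh`.
#' @param update `"synchronous"` or `"asynchronous"`.
#'
#' @return An object of class `"sk_model"`.
#' @examples
#' sk_model(64, beta = 2, dj = 0.5)
#' @export
sk_model <- function(n_spins, beta, j0 = 1, dj = 0.5, dh = 0, theta = NULL,
                     update = c("synchronous", "asynchronous")) {
  update <- match.arg(update)
  if (length(n_spins) != 1L || !is.finite(n_spins) || n_spins < 1 ||
      n_spins != round(n_spins)) {
    stop("`n_spins` must be a positive integer", call. = FALSE)
  }
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  if (dj < 0) stop("`dj` must be non-negative", call. = FALSE)
  if (dh < 0) stop("`dh` must be non-negative", call. = FALSE)
  if (!is.null(theta)) {
    theta <- rep_len(as.numeric(theta), n_spins)
    if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  }
  structure(
    list(n_spins = as.integer(n_spins), beta = as.numeric(beta),
         j0 = as.numeric(j0), dj = as.numeric(dj), dh = as.numeric(dh),
         theta = theta, update = update),
    class = "sk_model"
  )
}

#' @export
print.sk_model <- function(x, ...) {
  field <- if (is.null(x$theta)) {
    sprintf("uniform(-%.3g, %.3g)", x$dh, x$dh)
  } else {
    "fixed vector"
  }
  cat(sprintf(
    "<sk_model> N = %d, beta = %.4g, J0 = %.4g, dJ = %.4g, fields: %s, %s updates\n",
    x$n_spins, x$beta, x$j0, x$dj, field, x$update))
  invisible(x)
}

# Split one master seed into named independent sub-seeds (kept < 2^31).
split_seed <- function(seed, streams = c("couplings", "fields", "trajectory")) {
  stopifnot(is.finite(seed))
  seed <- as.integer(seed)
  sub <- (as.double(seed) * 48271 + 11 * seq_along(streams)) %% 2147483647
  setNames(as.integer(sub), streams)
}
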