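#' Draw a quenched coupling matrix
#'
#' Each ordered pair `(i, j)` -- including the diagonal by default -- is an
#' independent Gaussian with mean `j0/N` and variance `dj^2/N`. The diagonal
#' can be zeroed to remove lagged self-couplings; the `O(1/sqrt(N))`
#' self-terms vanish in the thermodynamic limit, and a zero diagonal is
#' required for the symmetric-coupling equilibrium (detailed-balance) check.
#'
#' @param model An [sk_model()].
#' @param seed Integer seed for the coupling stream.
#' @param zero_diagonal Set `J_ii = 0` after sampling.
#' @return An `N x N` numeric matrix.
#' @export
sample_couplings <- function(model, seed, zero_diagonal = FALSE) {
  stopifnot(inherits(model, "sk_model"))
  n <- model$n_spins
  withr_seed(seed)
  J <- matrix(rnorm(n * n, mean = model$j0 / n, sd = model$dj / sqrt(n)), n, n)
  if (zero_diagonal) diag(J) <- 0
  J
}

#' Draw external fields
#'
#' Fields are i.i.d. uniform on `[-dh, dh]`; with `dh = 0` (or an explicit
#' `theta` in the model) the stored constant vector is returned.
#'
#' @inheritParams sample_couplings
#' @return Length-N numeric vector of fields.
#' @export
sample_fields <- function(model, seed) {
  stopifnot(inherits(model, "sk_model"))
  n <- model$n_spins
  if (!is.null(model$theta)) return(model$theta)
  if (model$dh == 0) return(numeric(n))
  withr_seed(seed)
  runif(n, -model$dh, model$dh)
}

# set.seed without leaking: R has no light-weight local RNG here, so we just
# set it; callers own the RNG stream policy (see split_seed()).
withr_seed <- function(seed) set.seed(as.integer(seed %% 2147483647))

#' Realize quenched disorder for a model
#'
#' Draws the coupling matrix and field vector from one master seed, split
#' into independent streams (recorded in the result).
#'
#' @inheritParams sample_couplings
#' @return An object of class `"sk_realization"`: list with elements `J`
#'   (matrix), `theta` (vector), `model`, `seed`, `sub_seeds`.
#' @examples
#' r <- sk_realization(sk_model(8, beta = 1, dj = 0.5), seed = 1)
#' dim(r$J)
#' @export
sk_realization <- function(model, seed, zero_diagonal = FALSE) {
  seeds <- split_seed(seed)
  J <- sample_couplings(model, seeds[["couplings"]], zero_diagonal)
  theta <- sample_fields(model, seeds[["fields"]])
  structure(
    list(J = J, theta = theta, model = model, seed = as.integer(seed),
         sub_seeds = seeds, zero_diagonal = zero_diagonal),
    class = "sk_realization"
  )
}

#' @export
print.sk_realization <- function(x, ...) {
  cat(sprintf("<sk_realization> N = %d, seed = %d, J in [%.3g, %.3g]\n",
              x$model$n_spins, x$seed, min(x$J), max(x$J)))
  invisible(x)
}

#' Write or read a realization as tab-separated text
#'
#' The coupling matrix is stored as an N x N TSV block preceded by `#`
#' header lines carrying the model parameters and the field vector, so a
#' realization round-trips through plain text.
#'
#' @param realization An [sk_realization()].
#' @param path File path.
#' @return `write_realization_tsv()` returns `path` invisibly;
#'   `read_realization_tsv()` returns an `sk_realization`.
#' @export
write_realization_tsv <- function(realization, path) {
  m <- realization$model
  hdr <- c(
    sprintf("# n_spins\t%d", m$n_spins),
    sprintf("# beta\t%.17g", m$beta),
    sprintf("# j0\t%.17g", m$j0),
    sprintf("# dj\t%.17g", m$dj),
    sprintf("# dh\t%.17g", m$dh),
    sprintf("# update\t%s", m$update),
    sprintf("# seed\t%d", realization$seed),
    sprintf("# zero_diagonal\t%d", as.integer(realization$zero_diagonal)),
    paste0("# theta\t", paste(sprintf("%.17g", realization$theta), collapse = "\t"))
  )
  writeLines(hdr, path)
  rows <- apply(realization$J, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  cat(rows, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @rdname write_realization_tsv
#' @export
read_realization_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  val <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t")[[1]]
  }
  model <- sk_model(
    n_spins = as.integer(val("n_spins")), beta = as.numeric(val("beta")),
    j0 = as.numeric(val("j0")), dj = as.numeric(val("dj")),
    dh = as.numeric(val("dh")), update = val("update")
  )
  J <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(J) <- NULL
  structure(
    list(J = J, theta = as.numeric(val("theta")), model = model,
         seed = as.integer(val("seed")),
         sub_seeds = split_seed(as.integer(val("seed"))),
         zero_diagonal = as.logical(as.integer(val("zero_diagonal")))),
    class = "sk_realization"
  )
}
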