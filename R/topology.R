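#' Build a sparse random reservoir topology
#'
#' Draws the fixed recurrent weight matrix `J_fast` of an `n_res`-neuron
#' reservoir: each off-diagonal entry is nonzero with probability `p_conn`
#' (no self-connections) and nonzero weights are i.i.d.
#' Normal(0, `weight_scale^2 / (p_conn * n_res)`), the classic scaling that
#' keeps the spectral radius near `weight_scale` as the network grows.
#' Membrane units here are millivolts with a 20 mV rest-to-threshold gap, so
#' the default `weight_scale = 30` (1.5 x that gap) places the reservoir in
#' the rich, near-chaotic regime; `J_fast` is fixed for ever after.
#'
#' @param n_res Number of reservoir neurons `N`.
#' @param n_in Number of input channels `X`.
#' @param n_out Number of output neurons `Y`.
#' @param p_conn Connection probability in (0, 1].
#' @param weight_scale Scale `g` of the recurrent weights (mV per unit trace).
#' @param seed RNG seed; the draw is deterministic given the seed.
#'
#' @return An object of class `topology` with fields `n_res`, `n_in`,
#'   `n_out`, `p_conn`, `weight_scale`, `j_fast` (a sparse
#'   [Matrix::dgCMatrix-class]) and `seed`.
#' @examples
#' top <- build_topology(n_res = 50, n_in = 2, n_out = 1, p_conn = 0.1, seed = 1)
#' mean(top$j_fast != 0)  # ~ 0.1
#' @export
build_topology <- function(n_res, n_in, n_out, p_conn = 0.1,
                           weight_scale = 30, seed = 1L) {
  n_res <- check_count(n_res, "n_res")
  n_in <- check_count(n_in, "n_in")
  n_out <- check_count(n_out, "n_out")
  check_scalar_num(p_conn, "p_conn", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_num(weight_scale, "weight_scale", lower = 0)

  j_fast <- with_seed(seed, {
    mask <- matrix(stats::runif(n_res * n_res) < p_conn, n_res, n_res)
    diag(mask) <- FALSE
    w <- matrix(0, n_res, n_res)
    n_nz <- sum(mask)
    w[mask] <- stats::rnorm(n_nz, mean = 0,
                            sd = weight_scale / sqrt(p_conn * n_res))
    methods::as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix")
  })

  structure(list(n_res = n_res, n_in = n_in, n_out = n_out,
                 p_conn = p_conn, weight_scale = weight_scale,
                 j_fast = j_fast, seed = as.integer(seed)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  nnz <- Matrix::nnzero(x$j_fast)
  cat(sprintf("Reservoir topology: %d x %d -> %d (N=%d), p=%g, %d nonzero J_fast entries (%.1f%%)\n",
              x$n_in, x$n_res, x$n_out, x$n_res, x$p_conn, nnz,
              100 * nnz / (x$n_res^2)))
  invisible(x)
}
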