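#' Orthonormal discrete cosine basis
#'
#' Returns the first `p` columns of the orthonormal type-II DCT basis over
#' `N` points: column `k` (counting from 0) has entries
#' \eqn{\cos(\pi k (2n + 1) / (2N))}, `n = 0..N-1`, scaled to unit norm.
#' The first column is constant.  Columns are mutually orthogonal, the
#' convention used for drift/regressor bases in neuroimaging software.
#'
#' @param N Number of rows (time points).
#' @param p Number of basis columns, `p <= N`.
#' @return An `N` x `p` matrix with orthonormal columns.
#' @examples
#' X <- dct_basis(20, 7)
#' crossprod(X)  # identity
#' @export
dct_basis <- function(N, p) {
  if (p > N) stop("p must not exceed N")
  n <- seq_len(N) - 1
  X <- vapply(seq_len(p) - 1, function(k) {
    col <- cos(pi * k * (2 * n + 1) / (2 * N))
    if (k == 0) col / sqrt(N) else col * sqrt(2 / N)
  }, numeric(N))
  matrix(X, nrow = N, ncol = p)
}
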