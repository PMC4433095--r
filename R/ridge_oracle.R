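#' Closed-form ridge / BLUP marker solution
#'
#' Fixed-variance mixed-model oracle: `u_hat = (Z'Z + lambda I)^{-1} Z'y`
#' with `lambda = sigma2_e / sigma2_u`. This is the conditional posterior
#' mean of the marker effects under the equal-variance model with all loci
#' included, so a BayesC chain with `pi = 0` and frozen variances must
#' reproduce it up to Monte Carlo error. Dense direct solve; intended for
#' verification at test sizes, not production-scale prediction.
#'
#' @param y response vector.
#' @param Z coded genotype matrix (centered-ten scale).
#' @param lambda positive variance ratio `sigma2_e / sigma2_u`.
#' @return list with `u_hat` (marker effects) and `fitted` (`Z u_hat`,
#'   the BLUP of genomic values).
#' @export
solve_ridge <- function(y, Z, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  Z <- as.matrix(Z)
  if (length(y) != nrow(Z)) stop("dimensions not conformable")
  k <- ncol(Z)
  A <- crossprod(Z) + diag(lambda, k)
  if (lambda == 0 && k > nrow(Z))
    stop("singular system: lambda = 0 with more markers than records")
  u_hat <- as.vector(solve(A, crossprod(Z, y)))
  list(u_hat = u_hat, fitted = as.vector(Z %*% u_hat))
}
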