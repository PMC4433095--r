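#' Run a Bayesian-alphabet MCMC chain
#'
#' Single-site Gibbs sampler with, per model: locus-specific effect
#' variances (BayesA), Metropolis-Hastings variable inclusion with
#' locus-specific variances (BayesB), Gibbs variable inclusion with a
#' common effect variance (BayesC), and additionally a Beta-updated pi
#' (BayesCpi). Update order per sweep: fixed effects (block draw), each
#' locus in storage order (indicator, then effect, then locus variance),
#' common SNP variance, pi, residual variance, genomic-variance sample.
#' Posterior means accumulate every post-burn-in sweep with excluded-locus
#' effects counted as zero, which shrinks each SNP's posterior-mean effect
#' in proportion to its inclusion frequency.
#'
#' @param y numeric response (phenotypes pre-adjusted for fixed effects,
#'   unless `fixed_effects` is supplied).
#' @param genotypes a [genotype_matrix()] in centered-ten coding, or a
#'   plain numeric matrix already on that scale.
#' @param config a [model_config()].
#' @param fixed_effects optional design matrix (full rank; see
#'   [cg_design_matrix()]) sampled with a flat prior.
#' @param check_bookkeeping verify the residual bookkeeping identity
#'   `e = y - X b - Z(u * delta)` every 100 sweeps and report the maximum
#'   deviation.
#' @return A `PosteriorSummary`: posterior-mean effects `u_mean` (zeros
#'   included while excluded), per-SNP `inclusion` frequency, fixed-effect
#'   means, posterior means and post-burn-in samples of Va, Ve, h2 and pi,
#'   and the MH acceptance rate (BayesB).
#' @export
run_chain <- function(y, genotypes, config, fixed_effects = NULL,
                      check_bookkeeping = FALSE) {
  stopifnot(inherits(config, "ModelConfig"))
  if (inherits(genotypes, "GenotypeMatrix")) {
    if (genotypes$coding != "centered")
      stop("genotypes must be in centered-ten coding (encode_centered_ten)")
    Z <- genotypes$dosage
    snp_id <- genotypes$snp_id
  } else {
    Z <- as.matrix(genotypes)
    snp_id <- colnames(Z)
    if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(ncol(Z)))
  }
  if (length(y) != nrow(Z)) stop("length(y) must equal the animal count")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains NaN/NA")
  X <- if (is.null(fixed_effects)) matrix(0, nrow(Z), 0)
       else as.matrix(fixed_effects)
  if (ncol(X) > 0) {
    if (nrow(X) != nrow(Z)) stop("fixed-effect design has wrong row count")
    qd <- qr(X)
    if (qd$rank < ncol(X)) {
      bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
      stop("fixed-effect design is rank deficient; confounded columns: ",
           paste(bad, collapse = ", "))
    }
  }
  v <- apply(Z, 2, stats::var)
  if (any(v == 0))
    warning(sum(v == 0), " monomorphic SNP column(s); effects forced to 0")
  cfg_sc <- config
  # BayesB with pi = 1 is a legal degenerate chain (nothing ever enters);
  # clamp only for the prior-scale arithmetic
  if (cfg_sc$pi >= 1) cfg_sc$pi <- 1 - 1e-8
  sc <- prior_scales(cfg_sc, v)
  model_code <- match(config$model, c("A", "B", "C", "Cpi")) - 1L
  set.seed(config$seed)
  res <- .chain_cpp(y, Z, X, model_code, config$pi, config$Ve_start,
                    config$chain_length, config$burn_in, config$mh_cycles,
                    config$nu_a, config$nu_e, config$update_variances,
                    sc$S_a, sc$S_e,
                    if (check_bookkeeping) 100L else 0L)
  structure(list(
    u_mean = stats::setNames(as.vector(res$u_mean), snp_id),
    inclusion = stats::setNames(as.vector(res$inclusion), snp_id),
    b_mean = as.vector(res$b_mean),
    Va_mean = mean(res$Va_samples), Ve_mean = mean(res$Ve_samples),
    h2_mean = mean(res$h2_samples), pi_mean = mean(res$pi_samples),
    Va_realized_mean = mean(res$Va_realized_samples),
    Va_samples = as.vector(res$Va_samples),
    Va_realized_samples = as.vector(res$Va_realized_samples),
    Ve_samples = as.vector(res$Ve_samples),
    h2_samples = as.vector(res$h2_samples),
    pi_samples = as.vector(res$pi_samples),
    mh_acceptance = res$mh_acceptance,
    bookkeeping_max_err = res$bookkeeping_max_err,
    config = config), class = "PosteriorSummary")
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf("PosteriorSummary (Bayes%s, %d SNPs)\n",
              x$config$model, length(x$u_mean)))
  cat(sprintf("  Va = %.4g  Ve = %.4g  h2 = %.3f  pi = %.4f\n",
              x$Va_mean, x$Ve_mean, x$h2_mean, x$pi_mean))
  if (!is.na(x$mh_acceptance))
    cat(sprintf("  MH acceptance = %.3f\n", x$mh_acceptance))
  invisible(x)
}

#' Genomic variance of current marker effects
#'
#' The per-iteration genomic variance used for heritability reporting:
#' the variance across animals of their genomic values `Z u`, with
#' `h2 = Va / (Va + sigma2_e)` when a residual variance is supplied.
#'
#' @param genotypes centered-ten [genotype_matrix()] or matrix.
#' @param effects per-SNP effect vector (zeros for excluded loci).
#' @param sigma2_e optional residual variance.
#' @return list with `Va`, `g`, and `h2` (when `sigma2_e` given).
#' @export
genomic_variance <- function(genotypes, effects, sigma2_e = NULL) {
  Z <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$dosage
       else as.matrix(genotypes)
  if (nrow(Z) < 2) stop("genomic variance undefined for fewer than 2 animals")
  g <- as.vector(Z %*% effects)
  Va <- stats::var(g)
  out <- list(Va = Va, g = g)
  if (!is.null(sigma2_e)) out$h2 <- Va / (Va + sigma2_e)
  out
}
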