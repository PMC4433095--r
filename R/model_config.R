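#' Configuration for a Bayesian-alphabet analysis
#'
#' @param model one of `"A"`, `"B"`, `"C"`, `"Cpi"`. BayesA forces
#'   `pi = 0`; for BayesCpi, `pi` is the chain's starting value and is then
#'   estimated with a uniform (0,1) prior.
#' @param pi proportion of SNPs with zero effect.
#' @param Va_start,Ve_start starting additive-genetic and residual
#'   variances, trait units squared.
#' @param chain_length,burn_in MCMC iterations (defaults 160000 / 10000, the
#'   full-study scale; scale down for desk runs).
#' @param mh_cycles Metropolis-Hastings proposals per locus per sweep
#'   (BayesB only).
#' @param nu_a,nu_e prior degrees of freedom of the scaled-inverse-chi2
#'   priors on SNP and residual variances.
#' @param update_variances sample variance components (`FALSE` freezes them
#'   at their starting values; used by the ridge/enumeration oracles).
#' @param seed integer RNG seed.
#' @return A `ModelConfig` object.
#' @export
model_config <- function(model = c("Cpi", "A", "B", "C"), pi = 0,
                         Va_start = 1, Ve_start = 1,
                         chain_length = 160000, burn_in = 10000,
                         mh_cycles = 2, nu_a = 4, nu_e = 4,
                         update_variances = TRUE, seed = 1) {
  model <- match.arg(model)
  if (model == "A") pi <- 0
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  if (Va_start <= 0 || Ve_start <= 0) stop("starting variances must be > 0")
  if (nu_a <= 2 || nu_e <= 2)
    stop("prior df must exceed 2 for a finite prior mean")
  structure(list(model = model, pi = pi, Va_start = Va_start,
                 Ve_start = Ve_start, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 mh_cycles = as.integer(mh_cycles),
                 nu_a = nu_a, nu_e = nu_e,
                 update_variances = update_variances,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

#' Shipped per-trait starting values
#'
#' Starting values for the six carcass traits as used in the study
#' (weighted within-breed REML variance components; BayesA/B95 rows carry
#' the uninformed starts that [informed_start()] later replaces).
#' Rows: trait, analysis, pi, Va, Ve.
#'
#' @return data.frame of starting values.
#' @export
default_start_values <- function() {
  tab <- rbind(
    c("WBSF", "Cpi", 0.99, 0.416,   0.624),
    c("WBSF", "C0",  0,    0.416,   0.624),
    c("WBSF", "A",   0,    0.16,    0.55),
    c("WBSF", "B95", 0.95, 0.16,    0.55),
    c("REA",  "Cpi", 0.95, 25.629,  40.170),
    c("REA",  "C0",  0,    25.629,  40.170),
    c("REA",  "A",   0,    21,      44),
    c("REA",  "B95", 0.95, 21,      44),
    c("MARB", "Cpi", 0.9,  3500,    2600),
    c("MARB", "C0",  0,    3500,    2600),
    c("MARB", "A",   0,    3500,    2600),
    c("MARB", "B95", 0.95, 3500,    2600),
    c("FT",   "Cpi", 0.95, 0.092,   0.063),
    c("FT",   "C0",  0,    0.092,   0.063),
    c("FT",   "A",   0,    0.011,   0.136),
    c("FT",   "B95", 0.95, 0.011,   0.136),
    c("HCW",  "Cpi", 0.9,  373.06,  571.19),
    c("HCW",  "C0",  0,    373.06,  571.19),
    c("HCW",  "A",   0,    610,     615),
    c("HCW",  "B95", 0.95, 610,     615),
    c("YG",   "Cpi", 0.9,  0.2049,  0.2049),
    c("YG",   "C0",  0,    0.2049,  0.2049),
    c("YG",   "A",   0,    0.035,   0.358),
    c("YG",   "B95", 0.95, 0.035,   0.358))
  data.frame(trait = tab[, 1], analysis = tab[, 2],
             pi = as.numeric(tab[, 3]), Va = as.numeric(tab[, 4]),
             Ve = as.numeric(tab[, 5]), stringsAsFactors = FALSE)
}

#' Model configuration from the shipped per-trait defaults
#'
#' @param trait one of WBSF, REA, MARB, FT, HCW, YG.
#' @param analysis one of Cpi, C0, A, B95.
#' @param ... overrides passed to [model_config()].
#' @return A `ModelConfig`.
#' @export
default_config <- function(trait, analysis = c("Cpi", "C0", "A", "B95"),
                           ...) {
  analysis <- match.arg(analysis)
  tab <- default_start_values()
  row <- tab[tab$trait == trait & tab$analysis == analysis, ]
  if (nrow(row) != 1) stop("unknown trait: ", trait)
  model <- switch(analysis, Cpi = "Cpi", C0 = "C", A = "A", B95 = "B")
  model_config(model = model, pi = row$pi, Va_start = row$Va,
               Ve_start = row$Ve, ...)
}

#' Prior scales from starting variances
#'
#' Partitions the starting additive variance over the expected number of
#' included loci and their genotype column variances: the per-locus
#' effect-variance prior mean is `Va_start / ((1 - pi) * sum(v_j))`, and the
#' scaled-inverse-chi2 scale follows as `S = mean (nu - 2) / nu` (so the
#' prior mean `nu S / (nu - 2)` equals the partitioned value). The residual
#' scale is derived the same way from `Ve_start`.
#'
#' @param config a [model_config()].
#' @param column_variances per-SNP variances of the centered-ten genotype
#'   columns.
#' @return list with `S_a`, `S_e`, and the per-locus prior mean
#'   `prior_mean_a`.
#' @export
prior_scales <- function(config, column_variances) {
  sv <- sum(column_variances)
  if (sv <= 0) stop("column variances sum to zero")
  if (config$pi >= 1) stop("pi = 1 leaves no loci in the model")
  mean_a <- config$Va_start / ((1 - config$pi) * sv)
  list(S_a = mean_a * (config$nu_a - 2) / config$nu_a,
       S_e = config$Ve_start * (config$nu_e - 2) / config$nu_e,
       prior_mean_a = mean_a)
}

#' Draw from a scaled inverse chi-squared distribution
#'
#' `X = nu * S / chi2(nu)`; mean `nu S / (nu - 2)` for `nu > 2`.
#'
#' @param n number of draws.
#' @param nu degrees of freedom.
#' @param S scale.
#' @return numeric vector of positive draws.
#' @export
rscinvchisq <- function(n, nu, S) nu * S / stats::rchisq(n, df = nu)

#' Gibbs draw for pi (BayesCpi)
#'
#' With `m` of `k` loci currently in the model and a uniform (0,1) prior,
#' `pi | m ~ Beta(k - m + 1, m + 1)`.
#'
#' @param k SNP count.
#' @param m number of included loci.
#' @param n number of draws.
#' @return draws of pi.
#' @export
sample_pi <- function(k, m, n = 1) stats::rbeta(n, k - m + 1, m + 1)

#' Copy posterior-mean variances into a config's starting values
#'
#' The two-stage protocol for starting-value-sensitive models: run BayesCpi
#' first, then restart the target model (typically BayesA) from the BayesCpi
#' posterior means of Va and Ve.
#'
#' @param target_config the [model_config()] to update.
#' @param source_summary a `PosteriorSummary` from [run_chain()].
#' @return the config with `Va_start`, `Ve_start` replaced; all else
#'   unchanged.
#' @export
informed_start <- function(target_config, source_summary) {
  stopifnot(inherits(target_config, "ModelConfig"),
            inherits(source_summary, "PosteriorSummary"))
  target_config$Va_start <- source_summary$Va_mean
  target_config$Ve_start <- source_summary$Ve_mean
  target_config
}

#' Sample-size-weighted starting variances
#'
#' Weighted arithmetic mean of within-group variance estimates, the
#' convention used to pool within-breed REML components into across-breed
#' starting values.
#'
#' @param Va,Ve per-group variance estimates.
#' @param n per-group sample sizes (the weights).
#' @return list with `Va_start`, `Ve_start`.
#' @export
weighted_start <- function(Va, Ve, n) {
  if (!length(Va) || length(Va) != length(Ve) || length(Va) != length(n))
    stop("Va, Ve and n must be equal-length, nonempty")
  if (any(n <= 0)) stop("weights must be positive")
  list(Va_start = sum(Va * n) / sum(n), Ve_start = sum(Ve * n) / sum(n))
}
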