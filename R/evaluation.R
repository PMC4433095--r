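#' Random training/validation allocation
#'
#' Uniform sampling without replacement, breed-blind. Training size is
#' `round(n * fraction)` (half away from zero).
#'
#' @param n_animals total animal count.
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with integer index vectors `training` and `validation`
#'   (disjoint, exhaustive).
#' @export
allocate <- function(n_animals, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_t <- round(n_animals * fraction)
  if (n_t < 2 || n_animals - n_t < 1) stop("allocation leaves too few animals")
  set.seed(seed)
  tr <- sort(sample.int(n_animals, n_t))
  list(training = tr, validation = setdiff(seq_len(n_animals), tr))
}

#' Direct genomic values from posterior-mean SNP effects
#'
#' `DGV_i = sum_j z_ij u_hat_j` on the centered-ten coding. SNP sets are
#' aligned by id between the summary and the genotypes.
#'
#' @param genotypes centered-ten [genotype_matrix()] (or matrix whose
#'   columns match the summary's SNPs in order).
#' @param summary a `PosteriorSummary` from [run_chain()], or a named
#'   effect vector.
#' @return named numeric vector of DGV.
#' @export
predict_dgv <- function(genotypes, summary) {
  u <- if (inherits(summary, "PosteriorSummary")) summary$u_mean else summary
  if (inherits(genotypes, "GenotypeMatrix")) {
    if (genotypes$coding != "centered")
      stop("genotypes must be in centered-ten coding")
    Z <- genotypes$dosage
    ids <- genotypes$snp_id
    if (!is.null(names(u))) {
      missing_snp <- setdiff(names(u), ids)
      if (length(missing_snp))
        stop("SNPs in summary absent from genotypes: ",
             paste(utils::head(missing_snp, 5), collapse = ", "))
      Z <- genotypes$dosage[, match(names(u), ids), drop = FALSE]
    } else if (length(u) != ncol(Z)) stop("SNP count mismatch")
    dgv <- as.vector(Z %*% u)
    names(dgv) <- genotypes$animal_id
  } else {
    Z <- as.matrix(genotypes)
    if (length(u) != ncol(Z)) stop("SNP count mismatch")
    dgv <- as.vector(Z %*% u)
  }
  dgv
}

#' Correlation between DGV and adjusted phenotype in validation
#'
#' @param dgv,y_adj equal-length vectors, at least 3 animals.
#' @return Pearson correlation.
#' @export
validation_correlation <- function(dgv, y_adj) {
  if (length(dgv) != length(y_adj)) stop("length mismatch")
  if (length(dgv) < 3) stop("need at least 3 validation animals")
  if (stats::sd(dgv) == 0 || stats::sd(y_adj) == 0)
    stop("zero variance in DGV or phenotype; correlation undefined")
  stats::cor(dgv, y_adj)
}

#' Realized accuracy r / sqrt(h2)
#'
#' Standardizes the validation correlation by its theoretical ceiling
#' `sqrt(h2)`. Values above 1 are reported as-is with a warning (they
#' indicate an underestimated h2), never clamped.
#'
#' @param r validation correlation.
#' @param h2 heritability in (0, 1].
#' @return realized accuracy.
#' @export
realized_accuracy <- function(r, h2) {
  if (any(h2 <= 0)) stop("h2 must be > 0")
  if (any(h2 > 1)) stop("h2 must be <= 1")
  acc <- r / sqrt(h2)
  if (any(abs(acc) > 1))
    warning("realized accuracy outside the parameter space [0-1]; ",
            "h2 is likely underestimated")
  acc
}

#' Mean, SD and coefficient of variation across replicates
#'
#' @param values per-replicate accuracies or correlations (>= 2).
#' @return list with `mean`, `sd`, `cv` (`sd/mean`; `NA` with a warning
#'   when the mean is 0).
#' @export
replicate_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates")
  m <- mean(values); s <- stats::sd(values)
  cv <- if (m == 0) { warning("mean is 0; CV undefined"); NA_real_ } else s / m
  list(mean = m, sd = s, cv = cv)
}

#' Best-fit training fraction
#'
#' Chooses the fraction with the smallest coefficient of variation of the
#' replicate accuracies, restricted to fractions above 0.5 (smaller
#' training shares inflate the sampling variance of h2 and accuracy); ties
#' break toward the larger training fraction.
#'
#' @param cv_by_fraction named numeric vector, names are training
#'   fractions, values the replicate CV at each.
#' @return the chosen fraction (numeric).
#' @export
select_best_fit <- function(cv_by_fraction) {
  fr <- as.numeric(names(cv_by_fraction))
  if (anyNA(fr)) stop("names of cv_by_fraction must be fractions")
  eligible <- which(fr > 0.5 & !is.na(cv_by_fraction))
  if (!length(eligible)) stop("no eligible fraction above 0.5")
  cvs <- cv_by_fraction[eligible]
  best <- eligible[cvs == min(cvs)]
  max(fr[best])
}

#' Per-breed realized accuracies within the validation set
#'
#' Correlation computed within each sire-breed subset of the validation
#' animals, standardized by that breed's h2. Breeds with fewer than 3
#' validation animals are skipped with a notice.
#'
#' @param dgv,y_adj validation vectors.
#' @param breed breed label per validation animal.
#' @param h2_by_breed named numeric vector of per-breed heritabilities.
#' @return data.frame: breed, n, r, accuracy (NA rows for skipped breeds).
#' @export
per_breed_accuracy <- function(dgv, y_adj, breed, h2_by_breed) {
  stopifnot(length(dgv) == length(y_adj), length(dgv) == length(breed))
  breeds <- unique(breed)
  miss <- setdiff(breeds, names(h2_by_breed))
  if (length(miss))
    stop("missing h2 entry for breed(s): ", paste(miss, collapse = ", "))
  out <- lapply(breeds, function(b) {
    i <- which(breed == b)
    if (length(i) < 3) {
      message("breed ", b, " has ", length(i),
              " validation animals; skipped")
      return(data.frame(breed = b, n = length(i), r = NA_real_,
                        accuracy = NA_real_))
    }
    r <- validation_correlation(dgv[i], y_adj[i])
    data.frame(breed = b, n = length(i), r = r,
               accuracy = suppressWarnings(
                 realized_accuracy(r, h2_by_breed[[b]])))
  })
  do.call(rbind, out)
}

#' Paired t-test of per-replicate validation correlations
#'
#' Classical paired t on the replicate-wise differences (models share
#' identical splits), df = n - 1, two-sided p, with the Bonferroni
#' threshold for the requested family size attached.
#'
#' @param r1,r2 equal-length per-replicate correlation vectors for the two
#'   models, computed on identical splits.
#' @param family_size number of pairwise tests in the comparison family
#'   (default 36: six model pairs by six traits, giving the corrected
#'   threshold 0.05/36 = 0.0014).
#' @return list: mean_difference, t, df, p, bonferroni_alpha, significant.
#' @export
paired_model_ttest <- function(r1, r2, family_size = 36) {
  if (length(r1) != length(r2)) stop("paired vectors must have equal length")
  n <- length(r1)
  if (n < 2) stop("need at least 2 replicates")
  d <- r1 - r2
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    warning("zero-variance differences; t undefined")
    return(list(mean_difference = mean(d), t = NA_real_, df = n - 1,
                p = NA_real_, bonferroni_alpha = 0.05 / family_size,
                significant = NA))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  alpha <- 0.05 / family_size
  list(mean_difference = mean(d), t = tstat, df = n - 1, p = p,
       bonferroni_alpha = alpha, significant = p < alpha)
}

#' Bootstrap-replicate evaluation over a training-fraction grid
#'
#' For every fraction and replicate, allocates a training/validation split
#' (identical across models), trains each model on the training subset and
#' scores the validation subset. Heritability for the realized accuracy is
#' taken per-analysis (each model's own posterior-mean h2) and, when
#' `h2_fixed` is given, also under that fixed (e.g. best-fit BayesC0) h2.
#'
#' @param y_adj pre-adjusted phenotypes.
#' @param genotypes centered-ten [genotype_matrix()].
#' @param configs named list of [model_config()]s.
#' @param fractions training-fraction grid (default the study grid
#'   10%-95%).
#' @param n_replicates splits per fraction (default 20).
#' @param seed master seed; per-replicate split seeds and per-chain seeds
#'   are derived deterministically from it.
#' @param h2_fixed optional fixed h2 for standardization.
#' @return data.frame with one row per fraction x replicate x model:
#'   fraction, replicate, model, n_t, n_v, r, h2, accuracy, accuracy_fixed.
#' @export
evaluate_grid <- function(y_adj, genotypes, configs,
                          fractions = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                                        0.7, 0.8, 0.9, 0.95),
                          n_replicates = 20, seed = 1, h2_fixed = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            genotypes$coding == "centered")
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, function(cf) cf$model, "")
  n <- nrow(genotypes$dosage)
  rows <- list(); ri <- 0
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (rep in seq_len(n_replicates)) {
      split_seed <- as.integer((as.numeric(seed) * 997 + fi * 131 + rep) %%
                                 2147483647)
      sp <- allocate(n, f, seed = split_seed)
      gt <- subset_genotypes(genotypes, animals = sp$training)
      gv <- subset_genotypes(genotypes, animals = sp$validation)
      for (mi in seq_along(configs)) {
        cf <- configs[[mi]]
        cf$seed <- as.integer((as.numeric(split_seed) + mi * 7919) %%
                                2147483647)
        fit <- run_chain(y_adj[sp$training], gt, cf)
        dgv <- predict_dgv(gv, fit)
        r <- validation_correlation(dgv, y_adj[sp$validation])
        h2 <- fit$h2_mean
        ri <- ri + 1
        rows[[ri]] <- data.frame(
          fraction = f, replicate = rep, model = names(configs)[mi],
          n_t = length(sp$training), n_v = length(sp$validation),
          r = r, h2 = h2,
          accuracy = suppressWarnings(realized_accuracy(r, h2)),
          accuracy_fixed = if (is.null(h2_fixed)) NA_real_ else
            suppressWarnings(realized_accuracy(r, h2_fixed)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize an evaluation grid per fraction and model
#'
#' @param grid output of [evaluate_grid()].
#' @param measure column to summarize (`"accuracy"`, `"accuracy_fixed"` or
#'   `"r"`).
#' @return data.frame: fraction, model, mean, sd, cv.
#' @export
summarize_grid <- function(grid, measure = c("accuracy", "accuracy_fixed",
                                             "r")) {
  measure <- match.arg(measure)
  sp <- split(grid, list(grid$fraction, grid$model), drop = TRUE)
  out <- lapply(sp, function(d) {
    s <- replicate_summary(d[[measure]])
    data.frame(fraction = d$fraction[1], model = d$model[1],
               mean = s$mean, sd = s$sd, cv = s$cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$model, out$fraction), ]
}
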