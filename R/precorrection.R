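#' Build contemporary groups from factor labels
#'
#' A contemporary group is the interaction of herd of origin, breed, sex
#' and harvest date; only realized (nonempty) combinations become groups.
#' Group ids are the sorted label combinations, so they are stable under
#' row permutation of the input.
#'
#' @param factors data.frame with columns `herd`, `breed`, `sex`, `date`,
#'   one row per animal.
#' @return A `ContemporaryGroupDesign`: factor `group` per animal plus the
#'   level table.
#' @export
build_groups <- function(factors) {
  need <- c("herd", "breed", "sex", "date")
  miss <- setdiff(need, names(factors))
  if (length(miss))
    stop("missing factor columns: ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(factors[need]) |
                 Reduce(`|`, lapply(factors[need], function(x) x == "")))
  if (length(bad))
    stop("missing factor labels for animal row(s): ",
         paste(bad, collapse = ", "))
  group <- interaction(factors$herd, factors$breed, factors$sex,
                       factors$date, drop = TRUE, sep = ":", lex.order = TRUE)
  structure(list(group = group, levels = levels(group),
                 n_groups = nlevels(group)),
            class = "ContemporaryGroupDesign")
}

#' @export
print.ContemporaryGroupDesign <- function(x, ...) {
  cat(sprintf("ContemporaryGroupDesign: %d animals in %d groups\n",
              length(x$group), x$n_groups))
  invisible(x)
}

#' Full-rank fixed-effect design for contemporary groups
#'
#' Explicit intercept plus dummy columns for all but the first group
#' (drop-one-level identifiability constraint).
#'
#' @param design a [build_groups()] result.
#' @return numeric design matrix, `n x n_groups`.
#' @export
cg_design_matrix <- function(design) {
  stopifnot(inherits(design, "ContemporaryGroupDesign"))
  g <- design$group
  X <- stats::model.matrix(~g)
  colnames(X) <- c("(Intercept)", paste0("cg:", levels(g)[-1]))
  X
}

#' Pre-correct phenotypes for mean and contemporary-group effects
#'
#' Runs a single all-animal BayesCpi fit with the contemporary groups as
#' fixed effects (markers stay in the model so genetic signal is not
#' absorbed into the group means) and subtracts the posterior-mean
#' intercept-plus-group effect from each record. Pre-correcting once,
#' rather than refitting group effects inside every training subset, lets
#' the same adjusted phenotypes be reused across all training/validation
#' partitions.
#'
#' @param y raw phenotypes.
#' @param genotypes centered-ten [genotype_matrix()] (or matrix).
#' @param design a [build_groups()] result.
#' @param config a [model_config()] with `model = "Cpi"`.
#' @return list with `y_adj` (named by animal id when available),
#'   `group_effects` (posterior-mean fitted value per group, intercept
#'   included), `fit` (the `PosteriorSummary`).
#' @export
precorrect <- function(y, genotypes, design, config) {
  stopifnot(inherits(design, "ContemporaryGroupDesign"),
            inherits(config, "ModelConfig"))
  if (config$model != "Cpi")
    stop("pre-correction is defined as a BayesCpi fit (config$model = 'Cpi')")
  X <- cg_design_matrix(design)
  fit <- run_chain(y, genotypes, config, fixed_effects = X)
  adj <- as.vector(X %*% fit$b_mean)
  y_adj <- y - adj
  if (inherits(genotypes, "GenotypeMatrix"))
    names(y_adj) <- genotypes$animal_id
  ge <- vapply(seq_along(design$levels), function(i) {
    row <- which(as.integer(design$group) == i)[1]
    adj[row]
  }, 0)
  names(ge) <- design$levels
  list(y_adj = y_adj, group_effects = ge, fit = fit)
}
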