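#' Quality-control thresholds
#'
#' Defaults follow the standard 50K-chip pipeline for this population:
#' animals with overall call rate < 0.95 are dropped, then SNPs with call
#' rate < 0.89, then SNPs with minor allele frequency < 0.01 (recomputed on
#' surviving animals). Removal uses strict "less than"; values exactly at a
#' threshold are kept.
#'
#' @param animal_call_rate_min,snp_call_rate_min,maf_min proportions in
#'   `[0, 1]`.
#' @return A `QCThresholds` object.
#' @export
qc_thresholds <- function(animal_call_rate_min = 0.95,
                          snp_call_rate_min = 0.89, maf_min = 0.01) {
  v <- c(animal_call_rate_min, snp_call_rate_min, maf_min)
  if (any(v < 0 | v > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(animal_call_rate_min = animal_call_rate_min,
                 snp_call_rate_min = snp_call_rate_min,
                 maf_min = maf_min), class = "QCThresholds")
}

#' Per-animal and per-SNP call rates
#'
#' @param genotypes a [genotype_matrix()].
#' @return list with `animal` and `snp` call-rate vectors (called entries /
#'   total along the axis).
#' @export
call_rates <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  m <- genotypes$mask
  if (!length(m)) stop("empty genotype matrix")
  list(animal = stats::setNames(1 - rowMeans(m), genotypes$animal_id),
       snp = stats::setNames(1 - colMeans(m), genotypes$snp_id))
}

#' Per-SNP minor allele frequency
#'
#' `MAF = min(p, 1 - p)` with `p` the reference-allele frequency over called
#' entries only. SNPs with no called animals get `NA` (flagged for removal).
#'
#' @param genotypes a [genotype_matrix()] in dosage coding.
#' @return named numeric vector of MAFs.
#' @export
minor_allele_frequency <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (genotypes$coding != "dosage")
    stop("MAF requires dosage coding")
  d <- called_dosage(genotypes)
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  p[!is.finite(p)] <- NA_real_
  stats::setNames(pmin(p, 1 - p), genotypes$snp_id)
}

#' Filter animals and SNPs
#'
#' Filter order: animals by call rate first, then SNP call rate, then MAF
#' recomputed on the surviving animals, so that the MAF reflects the
#' analyzed animal set. Strict "less than" removal throughout.
#'
#' @param genotypes a [genotype_matrix()] in dosage coding.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered) and `report` (data.frame id,
#'   type, reason, value for every removal).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            inherits(thresholds, "QCThresholds"))
  if (genotypes$coding != "dosage") stop("qc_filter requires dosage coding")
  report <- data.frame(id = character(0), type = character(0),
                       reason = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  cr <- call_rates(genotypes)
  bad_an <- which(cr$animal < thresholds$animal_call_rate_min)
  if (length(bad_an)) {
    report <- rbind(report, data.frame(
      id = genotypes$animal_id[bad_an], type = "animal",
      reason = "animal_call_rate", value = unname(cr$animal[bad_an])))
    if (length(bad_an) == nrow(genotypes$dosage))
      stop("all animals removed by call-rate filter")
    genotypes <- subset_genotypes(genotypes, animals = -bad_an)
  }
  cr <- call_rates(genotypes)
  bad_snp <- which(cr$snp < thresholds$snp_call_rate_min)
  if (length(bad_snp)) {
    report <- rbind(report, data.frame(
      id = genotypes$snp_id[bad_snp], type = "snp",
      reason = "snp_call_rate", value = unname(cr$snp[bad_snp])))
    if (length(bad_snp) == ncol(genotypes$dosage))
      stop("all SNPs removed by call-rate filter")
    genotypes <- subset_genotypes(genotypes, snps = -bad_snp)
  }
  maf <- minor_allele_frequency(genotypes)
  bad_maf <- which(is.na(maf) | maf < thresholds$maf_min)
  if (length(bad_maf)) {
    if (length(bad_maf) == ncol(genotypes$dosage))
      stop("all SNPs removed by MAF filter")
    report <- rbind(report, data.frame(
      id = genotypes$snp_id[bad_maf], type = "snp", reason = "maf",
      value = unname(maf[bad_maf])))
    genotypes <- subset_genotypes(genotypes, snps = -bad_maf)
  }
  rownames(report) <- NULL
  list(genotypes = genotypes, report = report)
}

#' Mean-impute missing genotypes
#'
#' Each missing entry is set to the within-SNP mean dosage of called
#' animals (fractional values allowed); called entries are untouched and
#' the mask is cleared. Haplotype-based imputation is a non-goal: at the
#' sub-percent missingness this pipeline targets, the within-SNP mean
#' preserves allele frequencies, which is all the downstream regression
#' uses.
#'
#' @param genotypes a [genotype_matrix()] in dosage coding, every SNP with
#'   at least one called animal.
#' @return the genotype matrix with mask cleared.
#' @export
impute_missing <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (genotypes$coding != "dosage") stop("imputation requires dosage coding")
  if (!any(genotypes$mask)) return(genotypes)
  d <- called_dosage(genotypes)
  ncalled <- colSums(!is.na(d))
  if (any(ncalled == 0))
    stop("SNPs with zero called animals (run qc_filter first): ",
         paste(genotypes$snp_id[ncalled == 0], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(genotypes$mask, arr.ind = TRUE)
  genotypes$dosage[idx] <- mu[idx[, 2]]
  genotypes$mask[] <- FALSE
  genotypes
}

#' Encode genotypes on the centered-ten scale
#'
#' Maps dosage to the allelic-state coding used by the regression models:
#' AA (dosage 2) = 10, AB (1) = 0, BB (0) = -10, i.e.
#' `value = 10 (dosage - 1)`; fractional imputed dosages map linearly.
#' Applying twice is rejected via the coding-state guard.
#'
#' @param genotypes an imputed [genotype_matrix()] (empty mask).
#' @return the genotype matrix in centered-ten coding.
#' @export
encode_centered_ten <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (genotypes$coding == "centered")
    stop("genotypes are already in centered-ten coding")
  if (any(genotypes$mask))
    stop("impute missing genotypes before encoding")
  genotypes$dosage <- 10 * (genotypes$dosage - 1)
  genotypes$coding <- "centered"
  genotypes
}

#' Decode centered-ten genotypes back to dosages
#'
#' Inverse of [encode_centered_ten()]; exact on `{0, 1, 2}`.
#'
#' @param genotypes a [genotype_matrix()] in centered-ten coding.
#' @return the genotype matrix in dosage coding.
#' @export
decode_centered_ten <- function(genotypes) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (genotypes$coding != "centered")
    stop("genotypes are not in centered-ten coding")
  genotypes$dosage <- genotypes$dosage / 10 + 1
  genotypes$coding <- "dosage"
  genotypes
}
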