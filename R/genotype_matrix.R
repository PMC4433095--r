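#' Genotype matrix container
#'
#' An animals-by-SNPs dosage store with a missingness mask and per-animal
#' breed/sire labels. The dosage store holds counts of the reference allele
#' (0/1/2, fractional after mean imputation) and is never altered by masking:
#' missing entries are flagged in `mask` and excluded from all frequency
#' computations. `coding` records whether the store is on the raw dosage
#' scale or on the centered-ten scale used by the regression models
#' (AA = 10, AB = 0, BB = -10).
#'
#' @param dosage numeric matrix, animals in rows, SNPs in columns.
#' @param animal_id,snp_id unique identifier vectors (defaults generated).
#' @param breed character vector of sire-breed labels per animal.
#' @param sire_id sire identifier per animal.
#' @param mask logical matrix, `TRUE` where the genotype is missing.
#' @param coding `"dosage"` or `"centered"`.
#'
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, animal_id = NULL, snp_id = NULL,
                            breed = NULL, sire_id = NULL,
                            mask = NULL, coding = c("dosage", "centered")) {
  dosage <- as.matrix(dosage)
  coding <- match.arg(coding)
  n <- nrow(dosage); k <- ncol(dosage)
  if (is.null(animal_id)) animal_id <- paste0("an", seq_len(n))
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(k))
  if (is.null(breed)) breed <- rep(NA_character_, n)
  if (is.null(sire_id)) sire_id <- rep(NA_character_, n)
  if (is.null(mask)) mask <- matrix(FALSE, n, k)
  stopifnot(length(animal_id) == n, length(snp_id) == k,
            length(breed) == n, length(sire_id) == n,
            all(dim(mask) == dim(dosage)))
  if (anyDuplicated(animal_id)) stop("animal ids must be unique")
  if (anyDuplicated(snp_id)) stop("SNP ids must be unique")
  if (coding == "dosage") {
    called <- dosage[!mask]
    if (length(called) && any(called < 0 | called > 2, na.rm = TRUE))
      stop("dosages must lie in [0, 2]")
  }
  structure(list(dosage = dosage, mask = mask, coding = coding,
                 animal_id = as.character(animal_id),
                 snp_id = as.character(snp_id),
                 breed = as.character(breed),
                 sire_id = as.character(sire_id)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d animals x %d SNPs (%s coding)\n",
              nrow(x$dosage), ncol(x$dosage), x$coding))
  nm <- sum(x$mask)
  cat(sprintf("  missing: %d entries (%.2f%%)\n", nm,
              100 * nm / length(x$mask)))
  brs <- table(x$breed, useNA = "no")
  if (length(brs))
    cat("  breeds:", paste(names(brs), brs, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by animals and/or SNPs
#'
#' @param x a [genotype_matrix()].
#' @param animals,snps integer or logical indices (default: keep all).
#' @return A `GenotypeMatrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, animals = NULL, snps = NULL) {
  stopifnot(inherits(x, "GenotypeMatrix"))
  if (is.null(animals)) animals <- seq_len(nrow(x$dosage))
  if (is.null(snps)) snps <- seq_len(ncol(x$dosage))
  genotype_matrix(x$dosage[animals, snps, drop = FALSE],
                  animal_id = x$animal_id[animals],
                  snp_id = x$snp_id[snps],
                  breed = x$breed[animals],
                  sire_id = x$sire_id[animals],
                  mask = x$mask[animals, snps, drop = FALSE],
                  coding = x$coding)
}

# dosage matrix with masked entries set NA (frequency computations)
called_dosage <- function(x) {
  d <- x$dosage
  d[x$mask] <- NA_real_
  d
}
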