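#' Writers and readers for the tab-delimited data dialect
#'
#' Genotypes are written as an animals x SNPs dosage table with a header
#' row of SNP ids plus a sidecar SNP info file (id, chrom, pos);
#' phenotypes/pedigree as columns animal_id, sire_id, breed, herd, sex,
#' date, y; the simulation truth (per-SNP effects, per-animal g, group
#' effects, variances) as tab-delimited tables. Every file starts with a
#' one-line `#` metadata header carrying the seed and package version.
#'
#' @param genotypes a [genotype_matrix()] (dosage coding; missing entries
#'   written as NA).
#' @param path output file.
#' @param seed seed recorded in the metadata header.
#' @name io
NULL

meta_header <- function(seed) {
  sprintf("# dgvbayes v%s seed=%s",
          as.character(utils::packageVersion("dgvbayes")),
          if (is.null(seed)) "NA" else seed)
}

#' @rdname io
#' @export
write_genotypes <- function(genotypes, path, seed = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  d <- called_dosage(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed), con)
  writeLines(paste(c("animal_id", genotypes$snp_id), collapse = "\t"), con)
  utils::write.table(data.frame(animal_id = genotypes$animal_id, d),
                     con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = FALSE)
  info <- file.path(dirname(path),
                    sub("(\\.[^.]*)?$", ".snpinfo\\1", basename(path)))
  con2 <- file(info, "w")
  writeLines(meta_header(seed), con2)
  utils::write.table(data.frame(id = genotypes$snp_id, chrom = 1L,
                                pos = seq_along(genotypes$snp_id)),
                     con2, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con2)
  invisible(path)
}

#' @rdname io
#' @param breed_sire data.frame with animal_id, sire_id, breed (used when
#'   reading back into a [genotype_matrix()]).
#' @export
read_genotypes <- function(path, breed_sire = NULL) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "#")) stop("missing metadata header line")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  snp_id <- colnames(d)
  dimnames(d) <- NULL
  mask <- is.na(d)
  d[mask] <- 0
  breed <- sire <- NULL
  if (!is.null(breed_sire)) {
    i <- match(tab$animal_id, breed_sire$animal_id)
    breed <- breed_sire$breed[i]
    sire <- breed_sire$sire_id[i]
  }
  genotype_matrix(d, animal_id = tab$animal_id, snp_id = snp_id,
                  breed = breed, sire_id = sire, mask = mask)
}

#' @rdname io
#' @param phenotypes data.frame from [simulate_phenotypes()] (or any table
#'   with the phenotype columns).
#' @param pedigree data.frame with animal_id, sire_id, breed.
#' @export
write_phenotypes <- function(phenotypes, pedigree, path, seed = NULL) {
  out <- data.frame(animal_id = pedigree$animal_id,
                    sire_id = pedigree$sire_id,
                    breed = pedigree$breed,
                    herd = phenotypes$herd, sex = phenotypes$sex,
                    date = phenotypes$date, y = phenotypes$y,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_phenotypes <- function(path) {
  if (!startsWith(readLines(path, n = 1), "#"))
    stop("missing metadata header line")
  utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                    stringsAsFactors = FALSE)
}

#' @rdname io
#' @param truth the `truth` element of [simulate_dataset()].
#' @param animal_id animal ids matching `truth$g`.
#' @param snp_id SNP ids matching `truth$effects`.
#' @export
write_truth <- function(truth, animal_id, snp_id, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed), con)
  writeLines(sprintf("# Ve=%.10g", truth$Ve), con)
  writeLines("table\tid\tvalue", con)
  utils::write.table(
    rbind(data.frame(table = "effect", id = snp_id, value = truth$effects),
          data.frame(table = "g", id = animal_id, value = truth$g),
          data.frame(table = "cg", id = names(truth$cg_effects),
                     value = unname(truth$cg_effects))),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a PLINK additive-dosage text export
#'
#' Reads the `--recode A` dialect (header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one 0/1/2 dosage column per SNP, `NA` for missing) onto the
#' same store as [read_genotypes()]: `NA`s become masked entries.
#'
#' @param path a PLINK `.raw` file.
#' @return A [genotype_matrix()] in dosage coding (animal ids from the IID
#'   column).
#' @export
read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  miss <- setdiff(meta, names(tab))
  if (length(miss))
    stop("not a PLINK additive export; missing columns: ",
         paste(miss, collapse = ", "))
  d <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  snp_id <- colnames(d)
  dimnames(d) <- NULL
  mask <- is.na(d)
  d[mask] <- 0
  genotype_matrix(d, animal_id = tab$IID, snp_id = snp_id, mask = mask)
}

#' Write a chain log and posterior SNP summary
#'
#' The chain log holds the post-burn-in samples (iteration, Va, Ve, h2,
#' pi); the SNP table holds id, posterior-mean effect and inclusion
#' frequency.
#'
#' @param fit a `PosteriorSummary`.
#' @param log_path,snp_path output files (either may be `NULL` to skip).
#' @param seed seed recorded in the metadata header.
#' @export
write_chain_summary <- function(fit, log_path = NULL, snp_path = NULL,
                                seed = NULL) {
  stopifnot(inherits(fit, "PosteriorSummary"))
  if (!is.null(log_path)) {
    con <- file(log_path, "w")
    writeLines(meta_header(seed), con)
    utils::write.table(
      data.frame(iteration = seq_along(fit$Va_samples) + fit$config$burn_in,
                 Va = fit$Va_samples, Ve = fit$Ve_samples,
                 h2 = fit$h2_samples, pi = fit$pi_samples),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(snp_path)) {
    con <- file(snp_path, "w")
    writeLines(meta_header(seed), con)
    utils::write.table(
      data.frame(id = names(fit$u_mean), u = unname(fit$u_mean),
                 inclusion = unname(fit$inclusion)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(fit)
}
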