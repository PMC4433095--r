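#' Breed specification for the multi-breed simulator
#'
#' Describes one sire breed: how many progeny it contributes, the ancestry
#' mixture of the commercial dams its sires are mated to, and the drift
#' divergence `F` of the breed from the common ancestral population under
#' the Balding-Nichols model.
#'
#' @param name breed label.
#' @param n_progeny number of progeny carrying this sire-breed label.
#' @param dam_ancestry named numeric vector of mixture weights over breed
#'   names (must sum to 1); dam gametes are drawn from the mixture-weighted
#'   breed allele frequencies. Defaults to 100% the sire breed.
#' @param divergence Balding-Nichols drift parameter `F` in `[0, 1)`.
#' @param n_sires optional sire count; used only when no
#'   [family_structure()] drives family-size sampling.
#'
#' @return A `BreedSpec` object.
#' @export
breed_spec <- function(name, n_progeny, dam_ancestry = NULL,
                       divergence = 0.1, n_sires = NA_integer_) {
  if (is.null(dam_ancestry)) dam_ancestry <- stats::setNames(1, name)
  if (abs(sum(dam_ancestry) - 1) > 1e-9)
    stop("dam_ancestry weights must sum to 1")
  if (divergence < 0 || divergence >= 1)
    stop("divergence F must lie in [0, 1)")
  if (n_progeny < 0) stop("n_progeny must be >= 0")
  structure(list(name = name, n_progeny = as.integer(n_progeny),
                 dam_ancestry = dam_ancestry, divergence = divergence,
                 n_sires = n_sires),
            class = "BreedSpec")
}

#' Default five-breed study population
#'
#' Breed sample sizes proportional to the multi-breed carcass-merit design:
#' Angus 651, Charolais 695, Hereford 1095, Limousin 283, Simmental 516
#' (total 3240), scaled by `scale`. British-breed sires (Angus, Hereford)
#' are mated to dams of their own ancestry; Continental sires (Charolais,
#' Limousin, Simmental) to commercial dams with a high percentage of Angus
#' ancestry (default 50/50).
#'
#' @param scale multiplier on the per-breed progeny counts.
#' @param divergence drift parameter `F` shared by all breeds.
#' @param continental_angus_fraction Angus weight in Continental dam ancestry.
#' @return list of [breed_spec()] objects.
#' @export
cmp_breeds <- function(scale = 1, divergence = 0.1,
                       continental_angus_fraction = 0.5) {
  sizes <- c(Angus = 651, Charolais = 695, Hereford = 1095,
             Limousin = 283, Simmental = 516)
  sizes[] <- pmax(0, round(sizes * scale))
  a <- continental_angus_fraction
  mk <- function(nm) {
    anc <- if (nm %in% c("Angus", "Hereford")) stats::setNames(1, nm)
           else stats::setNames(c(1 - a, a), c(nm, "Angus"))
    breed_spec(nm, sizes[[nm]], dam_ancestry = anc, divergence = divergence)
  }
  lapply(names(sizes), mk)
}

#' Half-sib family structure targets
#'
#' The study population is dominated by singleton sire groups (>37% of
#' animals) with 45% of animals in families of at most 10 progeny; the
#' remainder sit in large half-sib families. `singleton_fraction` and
#' `small_family_fraction` are animal-weighted (fractions of the data, with
#' singletons counted inside the small-family fraction).
#'
#' @param singleton_fraction fraction of animals that are their sire's only
#'   progeny.
#' @param small_family_fraction fraction of animals in sire families of
#'   `<= 10` progeny (includes singletons).
#' @param max_family_size largest half-sib family drawn.
#' @return A `FamilyStructure` object.
#' @export
family_structure <- function(singleton_fraction = 0.37,
                             small_family_fraction = 0.45,
                             max_family_size = 150) {
  if (singleton_fraction < 0 || singleton_fraction > 1 ||
      small_family_fraction < 0 || small_family_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (small_family_fraction < singleton_fraction)
    stop("small_family_fraction must be >= singleton_fraction ",
         "(singletons are families of size 1)")
  if (max_family_size < 11 && small_family_fraction < 1)
    stop("max_family_size < 11 forces all animals into small families")
  structure(list(singleton_fraction = singleton_fraction,
                 small_family_fraction = small_family_fraction,
                 max_family_size = as.integer(max_family_size)),
            class = "FamilyStructure")
}

#' Trait architecture for phenotype simulation
#'
#' @param n_qtl number of loci with nonzero effects.
#' @param effect_dist `"gaussian"` (all effects normal) or `"mixture"`
#'   (one large-effect QTL carrying `large_effect_fraction_of_Vg` of the
#'   genetic variance plus gaussian background QTL).
#' @param large_effect_fraction_of_Vg share of the genetic variance assigned
#'   to the large-effect QTL under `effect_dist = "mixture"`.
#' @param breed_specific_qtl list of `list(locus =, breed =)` entries (locus
#'   index optional, `NA` to auto-select) declaring QTL that segregate in one
#'   breed and are fixed in all others.
#' @param target_h2 narrow-sense heritability; effects are rescaled so the
#'   empirical genetic variance equals `target_h2`, putting the phenotypic
#'   variance at ~1 trait unit squared.
#' @param cg_effect_sd standard deviation of contemporary-group effects, in
#'   trait units.
#' @return A `TraitArchitecture` object.
#' @export
trait_architecture <- function(n_qtl, effect_dist = c("gaussian", "mixture"),
                               large_effect_fraction_of_Vg = 0,
                               breed_specific_qtl = list(),
                               target_h2 = 0.4, cg_effect_sd = 0) {
  effect_dist <- match.arg(effect_dist)
  if (target_h2 < 0 || target_h2 > 1) stop("target_h2 must lie in [0, 1]")
  if (large_effect_fraction_of_Vg < 0 || large_effect_fraction_of_Vg > 1)
    stop("large_effect_fraction_of_Vg must lie in [0, 1]")
  structure(list(n_qtl = as.integer(n_qtl), effect_dist = effect_dist,
                 large_effect_fraction_of_Vg = large_effect_fraction_of_Vg,
                 breed_specific_qtl = breed_specific_qtl,
                 target_h2 = target_h2, cg_effect_sd = cg_effect_sd),
            class = "TraitArchitecture")
}

#' Simulate breed-divergent allele frequencies
#'
#' Ancestral frequencies are drawn `p0 ~ Uniform(0.05, 0.95)` per SNP; each
#' breed's frequency is a Balding-Nichols draw
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` around the ancestral value. `F = 0`
#' reproduces `p0` exactly (no drift).
#'
#' @param n_snps number of loci.
#' @param breeds list of [breed_spec()] objects.
#' @param seed integer RNG seed.
#' @return list with `p0` (ancestral frequencies) and `freq` (SNPs x breeds
#'   matrix, columns named by breed).
#' @export
simulate_breed_frequencies <- function(n_snps, breeds, seed = 1) {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  freq <- matrix(NA_real_, n_snps, length(breeds),
                 dimnames = list(NULL, vapply(breeds, `[[`, "", "name")))
  for (b in seq_along(breeds)) {
    F <- breeds[[b]]$divergence
    if (F == 0) {
      freq[, b] <- p0
    } else {
      a <- p0 * (1 - F) / F
      freq[, b] <- stats::rbeta(n_snps, a, (1 - p0) * (1 - F) / F)
    }
  }
  # keep frequencies strictly inside (0,1) so loci remain usable
  freq[] <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
  list(p0 = p0, freq = freq)
}

# half-sib family sizes for n progeny: singleton hurdle plus a
# zero-truncated negative binomial tail on sizes 2..max, with the tail mean
# tuned so the small-family (<=10) animal fraction is met
draw_family_sizes <- function(n, family) {
  f1 <- family$singleton_fraction
  f10 <- family$small_family_fraction
  smax <- family$max_family_size
  n1 <- round(f1 * n)
  n_rest <- n - n1
  sizes <- rep(1L, n1)
  if (n_rest > 0) {
    if (n_rest == 1) return(c(sizes, 1L))
    tail_target <- if (f1 < 1) (f10 - f1) / (1 - f1) else 0
    s <- 2:smax
    frac_small <- function(mu) {
      p <- stats::dnbinom(s, size = 0.8, mu = mu)
      p <- p / sum(p)
      sum(s[s <= 10] * p[s <= 10]) / sum(s * p)
    }
    if (tail_target <= frac_small(smax) || smax <= 11) {
      mu <- smax
    } else if (tail_target >= frac_small(2.001)) {
      mu <- 2.001
    } else {
      mu <- stats::uniroot(function(m) frac_small(m) - tail_target,
                           c(2.001, smax))$root
    }
    p <- stats::dnbinom(s, size = 0.8, mu = mu)
    p <- p / sum(p)
    draws <- integer(0)
    while (sum(draws) < n_rest)
      draws <- c(draws, sample(s, size = max(8, ceiling(n_rest / mu)),
                               replace = TRUE, prob = p))
    cum <- cumsum(draws)
    keep <- which(cum <= n_rest)
    draws <- draws[keep]
    left <- n_rest - sum(draws)
    if (left > 0) draws <- c(draws, left)  # remainder family
    sizes <- c(sizes, draws)
  }
  if (sum(sizes) != n) stop("internal: family sizes do not sum to n")
  sizes
}

#' Simulate a multi-breed half-sib population
#'
#' Sire genotypes are drawn from their breed's allele frequencies under HWE;
#' each progeny receives one sire gamete (Mendelian sampling from the sire's
#' genotype) and one dam gamete drawn from the dam-ancestry mixture of breed
#' frequencies (gamete-level grading-up, no explicit dam pedigree). Half-sib
#' family sizes follow the [family_structure()] targets.
#'
#' @param breeds list of [breed_spec()] objects.
#' @param freqs output of [simulate_breed_frequencies()] covering all breeds
#'   referenced by any `dam_ancestry`.
#' @param family a [family_structure()], or `NULL` for `n_sires` equal
#'   families per breed.
#' @param seed integer RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()], dosage coding) and
#'   `pedigree` (data.frame: animal_id, sire_id, breed).
#' @export
simulate_population <- function(breeds, freqs, family = family_structure(),
                                seed = 1) {
  freq <- freqs$freq
  refd <- unique(unlist(lapply(breeds, function(b) names(b$dam_ancestry))))
  miss <- setdiff(refd, colnames(freq))
  if (length(miss))
    stop("frequency table lacks breeds referenced by dam_ancestry: ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  k <- nrow(freq)
  dos <- list(); ped <- list()
  for (b in breeds) {
    n <- b$n_progeny
    if (n == 0) next
    sizes <- if (is.null(family)) {
      ns <- if (is.na(b$n_sires)) max(1L, round(n / 20)) else b$n_sires
      base <- rep(n %/% ns, ns)
      if (n %% ns > 0) base[seq_len(n %% ns)] <- base[seq_len(n %% ns)] + 1L
      base[base > 0]
    } else draw_family_sizes(n, family)
    pb <- freq[, b$name]
    pdam <- as.vector(freq[, names(b$dam_ancestry), drop = FALSE] %*%
                        b$dam_ancestry)
    geno <- matrix(NA_real_, n, k)
    sire_of <- rep(seq_along(sizes), sizes)
    sire_geno <- matrix(stats::rbinom(length(sizes) * k, 2, rep(pb, each = length(sizes))),
                        length(sizes), k)
    for (i in seq_len(n)) {
      sg <- sire_geno[sire_of[i], ]
      sire_gam <- stats::rbinom(k, 1, sg / 2)
      dam_gam <- stats::rbinom(k, 1, pdam)
      geno[i, ] <- sire_gam + dam_gam
    }
    sid <- sprintf("%s_s%03d", b$name, sire_of)
    dos[[b$name]] <- geno
    ped[[b$name]] <- data.frame(
      animal_id = sprintf("%s_%04d", b$name, seq_len(n)),
      sire_id = sid, breed = b$name, stringsAsFactors = FALSE)
  }
  if (!length(dos)) stop("no progeny requested in any breed")
  ped <- do.call(rbind, ped); rownames(ped) <- NULL
  gm <- genotype_matrix(do.call(rbind, dos),
                        animal_id = ped$animal_id,
                        snp_id = paste0("snp", seq_len(k)),
                        breed = ped$breed, sire_id = ped$sire_id)
  list(genotypes = gm, pedigree = ped)
}

#' Assign QTL effects and compute true genetic values
#'
#' Samples `n_qtl` loci, assigns effects per the architecture, and rescales
#' them so the empirical variance of the true genetic values
#' `g_i = sum_j z_ij alpha_j` (centered-ten coding) equals `target_h2`,
#' placing the phenotypic variance at ~1. Declared breed-specific QTL are
#' forced to segregate (within-breed MAF >= 0.05) in the named breed and are
#' fixed at dosage 0 in every other breed before effects are assigned, so
#' the genotype matrix is returned (possibly edited at those loci).
#'
#' @param arch a [trait_architecture()].
#' @param genotypes a [genotype_matrix()] in dosage coding, no missingness.
#' @param seed integer RNG seed.
#' @return list with `effects` (per-SNP alpha, zeros off-QTL), `g` (true
#'   genetic values), `qtl` (locus indices), `genotypes` (possibly modified).
#' @export
assign_qtl_effects <- function(arch, genotypes, seed = 1) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            genotypes$coding == "dosage")
  k <- ncol(genotypes$dosage)
  if (arch$n_qtl > k) stop("n_qtl exceeds SNP count")
  set.seed(seed)
  alpha <- numeric(k)
  if (arch$n_qtl == 0)
    return(list(effects = alpha, g = numeric(nrow(genotypes$dosage)),
                qtl = integer(0), genotypes = genotypes))
  dos <- genotypes$dosage
  breed <- genotypes$breed

  # breed-specific loci: pick candidates polymorphic in the target breed,
  # then fix all other breeds at dosage 0
  bs_loci <- integer(0)
  for (bsq in arch$breed_specific_qtl) {
    tb <- bsq$breed
    if (!tb %in% breed) stop("breed-specific QTL breed not present: ", tb)
    in_b <- breed == tb
    locus <- bsq$locus
    if (is.null(locus) || is.na(locus)) {
      p_b <- colMeans(dos[in_b, , drop = FALSE]) / 2
      cand <- setdiff(which(pmin(p_b, 1 - p_b) >= 0.05), bs_loci)
      if (!length(cand))
        stop("no candidate locus with MAF >= 0.05 in breed ", tb)
      locus <- sample(cand, 1)
    } else {
      p_b <- mean(dos[in_b, locus]) / 2
      if (min(p_b, 1 - p_b) < 0.05)
        stop("requested breed-specific locus ", locus,
             " is not polymorphic (MAF >= 0.05) in breed ", tb)
    }
    dos[!in_b, locus] <- 0
    bs_loci <- c(bs_loci, locus)
  }
  genotypes$dosage <- dos

  qtl <- c(bs_loci, sample(setdiff(seq_len(k), bs_loci),
                           arch$n_qtl - length(bs_loci)))
  Zq <- 10 * (dos[, qtl, drop = FALSE] - 1)
  a_q <- stats::rnorm(length(qtl))
  if (arch$effect_dist == "mixture" && arch$large_effect_fraction_of_Vg > 0 &&
      length(qtl) > 1) {
    # first QTL (breed-specific one if declared) carries the stated share
    # of Vg; background QTL share the remainder
    big <- 1L
    g_small <- Zq[, -big, drop = FALSE] %*% a_q[-big]
    v_small <- stats::var(as.vector(g_small))
    v_big <- stats::var(Zq[, big] * a_q[big])
    fr <- arch$large_effect_fraction_of_Vg
    if (v_big > 0 && v_small > 0)
      a_q[big] <- a_q[big] * sqrt(fr / (1 - fr) * v_small / v_big)
  }
  g <- as.vector(Zq %*% a_q)
  vg <- stats::var(g)
  if (vg > 0 && arch$target_h2 > 0) {
    sc <- sqrt(arch$target_h2 / vg)
    a_q <- a_q * sc
    g <- g * sc
  }
  alpha[qtl] <- a_q
  list(effects = alpha, g = g, qtl = qtl, genotypes = genotypes)
}

#' Default contemporary-group design
#'
#' Assigns each animal to the cross of herd x breed x sex x harvest-date
#' labels (4 herds, 2 sexes, 2 dates by default); empty cells never occur in
#' the output because group ids are taken from realized combinations only.
#'
#' @param breed breed label per animal.
#' @param n_herds,n_sexes,n_dates factor level counts.
#' @param seed integer RNG seed.
#' @return data.frame with columns herd, breed, sex, date.
#' @export
make_cg_design <- function(breed, n_herds = 4, n_sexes = 2, n_dates = 2,
                           seed = 1) {
  set.seed(seed)
  n <- length(breed)
  data.frame(
    herd = paste0("h", sample.int(n_herds, n, replace = TRUE)),
    breed = breed,
    sex = c("S", "H")[sample.int(n_sexes, n, replace = TRUE)],
    date = paste0("d", sample.int(n_dates, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}

#' Simulate phenotypes on top of true genetic values
#'
#' `y_i = mu + cg(i) + g_i + e_i` with `e ~ N(0, Ve)`,
#' `Ve = var(g) (1 - h2) / h2`, and contemporary-group effects
#' `~ N(0, cg_effect_sd^2)` shared by all animals in a group.
#'
#' @param g true genetic values from [assign_qtl_effects()].
#' @param arch the [trait_architecture()] (supplies `target_h2`,
#'   `cg_effect_sd`).
#' @param cg_design data.frame from [make_cg_design()] (or any herd/breed/
#'   sex/date table), one row per animal.
#' @param mu overall mean.
#' @param seed integer RNG seed.
#' @return data.frame with y, g_true, cg_true, group labels, and attributes
#'   `Ve`, `cg_effects`.
#' @export
simulate_phenotypes <- function(g, arch, cg_design, mu = 0, seed = 1) {
  n <- length(g)
  stopifnot(nrow(cg_design) == n)
  h2 <- arch$target_h2
  vg <- stats::var(g)
  if (h2 == 0 && vg > 0)
    stop("h2 = 0 with nonzero genetic values leaves Ve undefined")
  set.seed(seed)
  group <- interaction(cg_design$herd, cg_design$breed, cg_design$sex,
                       cg_design$date, drop = TRUE, sep = ":")
  cg_eff <- stats::rnorm(nlevels(group), 0, arch$cg_effect_sd)
  names(cg_eff) <- levels(group)
  cg_i <- cg_eff[as.integer(group)]
  Ve <- if (h2 >= 1 || vg == 0) 0 else vg * (1 - h2) / h2
  e <- if (Ve > 0) stats::rnorm(n, 0, sqrt(Ve)) else numeric(n)
  out <- data.frame(cg_design, group = as.character(group),
                    y = mu + cg_i + g + e, g_true = g, cg_true = cg_i,
                    stringsAsFactors = FALSE)
  attr(out, "Ve") <- Ve
  attr(out, "cg_effects") <- cg_eff
  out
}

#' Flag genotype entries as missing
#'
#' Two independent Bernoulli mechanisms: every entry of a "bad" draw for an
#' animal is masked with probability `animal_rate`, and independently with
#' probability `snp_rate` per SNP; the union is the mask. The dosage store
#' is never altered. Overall expected missingness is
#' `1 - (1 - animal_rate)(1 - snp_rate)`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param animal_rate,snp_rate per-entry masking rates in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the genotype matrix with an updated mask.
#' @export
inject_missingness <- function(genotypes, animal_rate = 0, snp_rate = 0,
                               seed = 1) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            animal_rate >= 0, animal_rate < 1,
            snp_rate >= 0, snp_rate < 1)
  set.seed(seed)
  d <- dim(genotypes$dosage)
  rate <- 1 - (1 - animal_rate) * (1 - snp_rate)
  if (rate > 0)
    genotypes$mask <- genotypes$mask |
      matrix(stats::runif(prod(d)) < rate, d[1], d[2])
  genotypes
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [simulate_breed_frequencies()],
#' [simulate_population()], [assign_qtl_effects()], [make_cg_design()] and
#' [simulate_phenotypes()]; optionally injects missingness.
#'
#' @param n_snps SNP count.
#' @param breeds list of [breed_spec()]s (default [cmp_breeds()] at
#'   `scale = 0.2`).
#' @param arch a [trait_architecture()].
#' @param family a [family_structure()] or `NULL`.
#' @param missing_rate overall missingness rate.
#' @param seed integer RNG seed (sub-seeds derived deterministically).
#' @return list: genotypes, pedigree, phenotypes, truth
#'   (effects/g/qtl/Ve/cg), freqs.
#' @export
simulate_dataset <- function(n_snps = 1000, breeds = cmp_breeds(scale = 0.2),
                             arch = trait_architecture(n_qtl = 50),
                             family = family_structure(),
                             missing_rate = 0, seed = 1) {
  freqs <- simulate_breed_frequencies(n_snps, breeds, seed = seed)
  pop <- simulate_population(breeds, freqs, family = family, seed = seed + 1)
  qt <- assign_qtl_effects(arch, pop$genotypes, seed = seed + 2)
  cg <- make_cg_design(qt$genotypes$breed, seed = seed + 3)
  ph <- simulate_phenotypes(qt$g, arch, cg, seed = seed + 4)
  geno <- qt$genotypes
  if (missing_rate > 0)
    geno <- inject_missingness(geno, animal_rate = missing_rate,
                               seed = seed + 5)
  list(genotypes = geno, pedigree = pop$pedigree, phenotypes = ph,
       truth = list(effects = qt$effects, g = qt$g, qtl = qt$qtl,
                    Ve = attr(ph, "Ve"), cg_effects = attr(ph, "cg_effects")),
       freqs = freqs)
}
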