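test_that("breed frequencies: no-drift identity, determinism, range", {
  breeds <- list(breed_spec("P", 10, divergence = 0),
                 breed_spec("Q", 10, divergence = 0.2))
  f1 <- simulate_breed_frequencies(200, breeds, seed = 5)
  expect_equal(f1$freq[, "P"], f1$p0)           # F = 0: breed freq = p0
  expect_false(isTRUE(all.equal(f1$freq[, "Q"], f1$p0)))
  expect_true(all(f1$freq > 0 & f1$freq < 1))
  f2 <- simulate_breed_frequencies(200, breeds, seed = 5)
  expect_identical(f1, f2)
  expect_error(breed_spec("R", 5, divergence = 1), "F must lie")
})

test_that("breed divergence matches the Balding-Nichols F on the F_ST scale", {
  # F_ST recomputed from the generated table: across-breed variance of the
  # allele frequency relative to its ancestral maximum p0(1-p0)
  breeds <- lapply(1:5, function(i) breed_spec(paste0("b", i), 10,
                                               divergence = 0.1))
  fr <- simulate_breed_frequencies(1000, breeds, seed = 11)
  fst <- mean(apply(fr$freq, 1, stats::var) / (fr$p0 * (1 - fr$p0)))
  expect_lt(abs(fst - 0.1), 0.03)
})

test_that("half-sib family structure hits the singleton/small-family targets", {
  breeds <- cmp_breeds(scale = 1, divergence = 0.05)
  freqs <- simulate_breed_frequencies(5, breeds, seed = 2)
  pop <- simulate_population(breeds, freqs, family = family_structure(),
                             seed = 3)
  expect_equal(nrow(pop$pedigree), 3240)
  fam <- table(pop$pedigree$sire_id)
  sizes <- fam[pop$pedigree$sire_id]      # family size per animal
  singleton <- mean(sizes == 1)
  small <- mean(sizes <= 10)
  expect_lt(abs(singleton - 0.37), 0.05)
  expect_lt(abs(small - 0.45), 0.05)
  # histogram recoverable from the pedigree: sizes sum to the animal count
  expect_equal(sum(fam), 3240)
})

test_that("pure-breed no-drift progeny frequencies match ancestral", {
  # singleton families (n_sires = n) make the 2n sampled alleles independent,
  # so the plain binomial CI applies
  breeds <- list(breed_spec("P", 500, divergence = 0, n_sires = 500))
  freqs <- simulate_breed_frequencies(120, breeds, seed = 7)
  pop <- simulate_population(breeds, freqs, family = NULL, seed = 8)
  phat <- colMeans(pop$genotypes$dosage) / 2
  se <- sqrt(freqs$p0 * (1 - freqs$p0) / (2 * 500))
  expect_true(all(abs(phat - freqs$p0) < 5 * pmax(se, 0.01)))
  expect_lt(mean(abs(phat - freqs$p0)), 0.03)
})

test_that("empty breeds are dropped and infeasible ancestry is caught", {
  breeds <- list(breed_spec("P", 100), breed_spec("Q", 0))
  freqs <- simulate_breed_frequencies(10, breeds, seed = 1)
  pop <- simulate_population(breeds, freqs, seed = 1)
  expect_false("Q" %in% pop$pedigree$breed)
  expect_equal(nrow(pop$pedigree), 100)
  b2 <- list(breed_spec("P", 10, dam_ancestry = c(P = 0.5, Missing = 0.5)))
  expect_error(simulate_population(b2, freqs, seed = 1), "Missing")
})

test_that("population simulation is deterministic and dosages legal", {
  breeds <- list(breed_spec("P", 50, divergence = 0.1))
  freqs <- simulate_breed_frequencies(30, breeds, seed = 4)
  p1 <- simulate_population(breeds, freqs, seed = 9)
  p2 <- simulate_population(breeds, freqs, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$genotypes$dosage %in% 0:2))
})

test_that("QTL effects reproduce the target heritability", {
  breeds <- list(breed_spec("P", 800, divergence = 0.05))
  freqs <- simulate_breed_frequencies(200, breeds, seed = 1)
  pop <- simulate_population(breeds, freqs, seed = 2)
  arch <- trait_architecture(n_qtl = 200, target_h2 = 0.3)
  qt <- assign_qtl_effects(arch, pop$genotypes, seed = 3)
  ph <- simulate_phenotypes(qt$g, arch, make_cg_design(pop$genotypes$breed),
                            seed = 4)
  h2_emp <- var(qt$g) / (var(qt$g) + attr(ph, "Ve"))
  expect_lt(abs(h2_emp - 0.3), 0.02)
})

test_that("large-effect QTL carries its declared variance share", {
  breeds <- list(breed_spec("P", 1000, divergence = 0.05))
  freqs <- simulate_breed_frequencies(300, breeds, seed = 5)
  pop <- simulate_population(breeds, freqs, seed = 6)
  arch <- trait_architecture(n_qtl = 40, effect_dist = "mixture",
                             large_effect_fraction_of_Vg = 0.25,
                             target_h2 = 0.4)
  qt <- assign_qtl_effects(arch, pop$genotypes, seed = 7)
  Z <- 10 * (qt$genotypes$dosage[, qt$qtl] - 1)
  vloc <- apply(Z, 2, var) * qt$effects[qt$qtl]^2   # per-locus 2pq-weighted
  share <- vloc[1] / sum(vloc)
  expect_lt(abs(share - 0.25), 0.05)
})

test_that("null architecture gives zero genetic values", {
  gm <- toy_genotypes()
  qt <- assign_qtl_effects(trait_architecture(n_qtl = 0), gm, seed = 1)
  expect_identical(qt$g, rep(0, 5))
  expect_identical(qt$effects, rep(0, 5))
})

test_that("breed-specific QTL segregate only in the target breed", {
  dat <- breed_qtl_dataset(n_snps = 200, n_per_breed = 150, seed = 21)
  locus <- dat$qtl[1]
  in_b1 <- dat$genotypes$breed == "B1"
  p1 <- mean(dat$genotypes$dosage[in_b1, locus]) / 2
  expect_gte(min(p1, 1 - p1), 0.05)
  expect_true(all(dat$genotypes$dosage[!in_b1, locus] == 0))
  # impossible request reported
  mono <- genotype_matrix(matrix(2, 10, 3), breed = rep(c("X", "Y"), 5))
  arch <- trait_architecture(n_qtl = 1,
                             breed_specific_qtl = list(list(locus = NA,
                                                            breed = "X")))
  expect_error(assign_qtl_effects(arch, mono, seed = 1), "no candidate locus")
})

test_that("phenotype model: noise-free limit, shared cg effects, slope", {
  breeds <- list(breed_spec("P", 2000, divergence = 0.05))
  freqs <- simulate_breed_frequencies(150, breeds, seed = 8)
  pop <- simulate_population(breeds, freqs, seed = 9)
  arch1 <- trait_architecture(n_qtl = 150, target_h2 = 1, cg_effect_sd = 0)
  qt <- assign_qtl_effects(arch1, pop$genotypes, seed = 10)
  cg <- make_cg_design(pop$genotypes$breed, seed = 11)
  ph <- simulate_phenotypes(qt$g, arch1, cg, mu = 3, seed = 12)
  expect_equal(ph$y - 3, qt$g)                       # h2 = 1, cg_sd = 0
  arch2 <- trait_architecture(n_qtl = 150, target_h2 = 0.26,
                              cg_effect_sd = 0.5)
  qt2 <- assign_qtl_effects(arch2, pop$genotypes, seed = 10)
  ph2 <- simulate_phenotypes(qt2$g, arch2, cg, seed = 13)
  # same contemporary group -> identical cg effect
  expect_true(all(tapply(ph2$cg_true, ph2$group,
                         function(v) max(v) - min(v)) == 0))
  slope <- coef(lm((ph2$y - ph2$cg_true) ~ qt2$g))[2]
  expect_lt(abs(slope - 1), 0.1)
  expect_error(simulate_phenotypes(qt2$g,
    trait_architecture(n_qtl = 10, target_h2 = 0), cg, seed = 1),
    "h2 = 0")
})

test_that("missingness mask hits the requested rate and is reproducible", {
  gm <- genotype_matrix(matrix(rbinom(500 * 2000, 2, 0.4), 500, 2000))
  m0 <- inject_missingness(gm, 0, 0, seed = 1)
  expect_false(any(m0$mask))
  m1 <- inject_missingness(gm, animal_rate = 0.0089, seed = 2)
  expect_lt(abs(mean(m1$mask) - 0.0089), 0.002)
  expect_identical(m1$dosage, gm$dosage)             # store untouched
  m2 <- inject_missingness(gm, animal_rate = 0.0089, seed = 2)
  expect_identical(m1$mask, m2$mask)
})

test_that("family structure validates its inputs", {
  expect_error(family_structure(0.5, 0.4), "small_family_fraction")
  expect_error(family_structure(-0.1, 0.4), "fractions")
})
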