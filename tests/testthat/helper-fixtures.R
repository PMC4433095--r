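# in-code fixtures shared across test files

# small hand-checkable genotype matrix (dosage coding)
toy_genotypes <- function() {
  d <- rbind(c(0, 1, 2, 1, 0),
             c(2, 2, 2, 0, 1),
             c(1, 0, 2, 2, 2),
             c(0, 1, 2, 1, 1),
             c(2, 0, 2, 0, 0))
  genotype_matrix(d, animal_id = paste0("A", 1:5),
                  snp_id = paste0("S", 1:5),
                  breed = c("X", "X", "Y", "Y", "Y"))
}

# HWE single-breed genotypes as a centered-ten matrix
hwe_centered <- function(n, k, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(10 * (rbinom(n * k, 2, p) - 1), n, k)
}

# two-breed dataset with one large QTL segregating only in breed "B1"
breed_qtl_dataset <- function(n_snps = 400, n_per_breed = 300, seed = 1,
                              h2 = 0.4, qtl_share = 0.5) {
  breeds <- list(
    breed_spec("B1", n_per_breed, divergence = 0.1),
    breed_spec("B2", n_per_breed, divergence = 0.1))
  freqs <- simulate_breed_frequencies(n_snps, breeds, seed = seed)
  pop <- simulate_population(breeds, freqs, family = NULL, seed = seed + 1)
  arch <- trait_architecture(n_qtl = 12, effect_dist = "mixture",
                             large_effect_fraction_of_Vg = qtl_share,
                             breed_specific_qtl = list(list(locus = NA,
                                                            breed = "B1")),
                             target_h2 = h2)
  qt <- assign_qtl_effects(arch, pop$genotypes, seed = seed + 2)
  cg <- make_cg_design(qt$genotypes$breed, seed = seed + 3)
  ph <- simulate_phenotypes(qt$g, arch, cg, seed = seed + 4)
  list(genotypes = qt$genotypes, arch = arch, phenotypes = ph,
       qtl = qt$qtl, effects = qt$effects)
}

# quick model config for short test chains
quick_config <- function(model = "C", pi = 0, L = 2000, burn = 500,
                         Va = 0.4, Ve = 0.6, seed = 1, ...) {
  model_config(model, pi = pi, Va_start = Va, Ve_start = Ve,
               chain_length = L, burn_in = burn, seed = seed, ...)
}
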