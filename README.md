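# dgvbayes

Bayesian-alphabet whole-genome regression for predicting direct genomic
values (DGV) in crossbred, multi-breed cattle populations.

Commercial beef cattle are mostly crossbred — sired by registered bulls of
several breeds out of commercial dams of mixed ancestry — and usually have
no pedigree. Genomic prediction can still rank such animals for selection
or feedlot sorting, but the best prior on SNP effects depends on the
trait's architecture: meat-tenderness-like traits with large-effect QTL
reward models that allow unequal SNP variances, while near-infinitesimal
traits do not. `dgvbayes` is for quantitative geneticists and animal
breeders who want to run and compare these models, and to study their
behavior on simulated multi-breed data with known truth.

## What is implemented

All models fit, by single-site Gibbs sampling (C++ core, R's RNG, fully
seed-deterministic):

    y_i = sum_j z_ij u_j + e_i,   z_ij in {-10, 0, 10}

with marker effect `u_j ~ N(0, sigma2_u(j))` with probability `1 - pi` and
`u_j = 0` with probability `pi`, scaled inverse-chi-squared priors on all
variances, and optional fixed effects sampled in block:

| model   | pi                        | SNP variance |
|---------|---------------------------|--------------|
| BayesA  | 0                         | per locus    |
| BayesB  | fixed (e.g. 0.95), 2-cycle Metropolis-Hastings inclusion | per locus |
| BayesC0 | 0                         | common       |
| BayesCpi| estimated, uniform prior  | common       |

Around the samplers: a multi-breed synthetic-data generator
(Balding-Nichols breed divergence, purebred-sire x commercial-dam crossing,
singleton-heavy half-sib families, infinitesimal to oligogenic
architectures with breed-specific QTL), genotype QC (call-rate and MAF
filters, mean imputation, centered-ten encoding), contemporary-group
pre-correction via a single all-animal BayesCpi fit, bootstrap
training/validation evaluation with realized accuracy `r / sqrt(h2)`,
best-fit training-fraction selection (minimum CV, > 50% rule), paired
t-tests across models, and a closed-form ridge/BLUP solver used as an
independent oracle in the tests.

## Worked example

Simulate a five-breed population with a moderately oligogenic trait
(h2 = 0.26, one QTL carrying 25% of the genetic variance), run QC,
pre-correct for contemporary groups, fit BayesC0, and validate on a held-out
30%:

```r
library(dgvbayes)

dat <- simulate_dataset(
  n_snps = 500, breeds = cmp_breeds(scale = 0.2),
  arch = trait_architecture(n_qtl = 50, effect_dist = "mixture",
                            large_effect_fraction_of_Vg = 0.25,
                            target_h2 = 0.26, cg_effect_sd = 0.5),
  missing_rate = 0.0089, seed = 1)
dat$genotypes
#> GenotypeMatrix: 648 animals x 500 SNPs (dosage coding)
#>   missing: 2880 entries (0.89%)
#>   breeds: Angus=130, Charolais=139, Hereford=219, Limousin=57, Simmental=103

qc <- qc_filter(dat$genotypes)          # 1 monomorphic SNP removed
Z  <- encode_centered_ten(impute_missing(qc$genotypes))
ph <- dat$phenotypes[match(Z$animal_id, dat$genotypes$animal_id), ]

pc <- precorrect(ph$y, Z, build_groups(ph),
                 model_config("Cpi", pi = 0.9, Va_start = 0.26,
                              Ve_start = 0.74, chain_length = 3000,
                              burn_in = 600, seed = 2))

fit <- run_chain(unname(pc$y_adj), Z,
                 model_config("C", pi = 0, Va_start = 0.26, Ve_start = 0.74,
                              chain_length = 3000, burn_in = 600, seed = 3))
fit
#> PosteriorSummary (BayesC, 499 SNPs)
#>   Va = 0.2121  Ve = 0.7524  h2 = 0.219  pi = 0.0000

sp    <- allocate(nrow(Z$dosage), 0.7, seed = 4)
fit_t <- run_chain(unname(pc$y_adj)[sp$training],
                   subset_genotypes(Z, animals = sp$training),
                   model_config("C", pi = 0, Va_start = 0.26,
                                Ve_start = 0.74, chain_length = 3000,
                                burn_in = 600, seed = 5))
dgv <- predict_dgv(subset_genotypes(Z, animals = sp$validation), fit_t)
r   <- validation_correlation(dgv, unname(pc$y_adj)[sp$validation])
round(r, 3)                                   #> 0.173
round(realized_accuracy(r, fit$h2_mean), 3)   #> 0.37
```

The validation correlation 0.173 is the raw association between DGV and
adjusted phenotype; dividing by `sqrt(h2)` — the ceiling that correlation
can reach — gives the realized accuracy 0.37 of the DGV as a predictor of
genetic merit. Because the data are simulated, the claim can be checked
against truth: `cor(dgv, ph$g_true[sp$validation])` is 0.382 here. At the
full study scale (thousands of animals, tens of thousands of markers,
160 000-iteration chains) accuracies in the 0.4–0.8 range are typical; this
example runs in seconds at desk scale.

The methods vignette (`vignettes/multibreed-genomic-prediction.Rmd`)
documents the model, the generator, all tuning parameters and the design
decisions in detail.

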