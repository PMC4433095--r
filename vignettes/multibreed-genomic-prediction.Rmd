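---
title: "Bayesian-alphabet genomic prediction in multi-breed populations: models, simulator and evaluation design"
author: "dgvbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-alphabet genomic prediction in multi-breed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dgvbayes)
```

## The problem

Commercial beef populations are crossbred: calves are sired by registered
bulls of several breeds (Angus, Charolais, Hereford, Limousin, Simmental)
out of commercial dams of mixed, often unrecorded ancestry. Direct genomic
values (DGV) — an animal's predicted genetic merit, computed as the sum of
estimated SNP effects over its genotype — would let such animals be
selected or sorted (e.g. on feedlot entry) without pedigree or a national
evaluation. The statistical question is which prior on SNP effects best
matches the genetic architecture of each trait: traits influenced by
large-effect QTL reward models that allow unequal SNP variances, while
traits near the infinitesimal model do not.

`dgvbayes` implements the full analysis stack: a multi-breed synthetic-data
generator, genotype quality control and encoding, four whole-genome
regression samplers (BayesA, BayesB, BayesC, BayesCpi), contemporary-group
pre-correction, and bootstrap training/validation evaluation with
realized-accuracy standardization.

## The model

All four samplers fit, by single-site Gibbs sampling,

$$ y_i = \sum_{j=1}^k z_{ij} u_j + e_i, $$

where $y_i$ is a phenotype pre-adjusted for the mean and contemporary-group
effects, $z_{ij} \in \{-10, 0, 10\}$ codes the genotype at marker $j$
(homozygote contrast 20; fractional values after mean imputation map
linearly), $u_j$ is the marker effect and $e_i \sim N(0, \sigma^2_e)$.
Marker effects are zero with probability $\pi$ and
$N(0, \sigma^2_{u(j)})$ otherwise; all variances carry scaled inverse-
$\chi^2$ priors. The models differ in two switches:

| model   | $\pi$                      | SNP variance      |
|---------|----------------------------|-------------------|
| BayesA  | 0 (all markers in)         | per locus         |
| BayesB  | fixed (0.95 by convention) | per locus         |
| BayesC0 | 0                          | common            |
| BayesCpi| estimated, uniform prior   | common            |

Full conditionals are the standard Bayesian-alphabet forms. For the
indicator in BayesC/Cpi the single-locus statistic
$r_j = \mathbf z_j'(\mathbf e + \mathbf z_j u_j \delta_j)$ is
$N(0, v_0)$ under exclusion and $N(0, v_1)$ under inclusion, with
$v_0 = \mathbf z_j'\mathbf z_j\,\sigma^2_e$ and
$v_1 = v_0 + (\mathbf z_j'\mathbf z_j)^2 \sigma^2_u$, giving inclusion odds
$\frac{1-\pi}{\pi}\sqrt{v_0/v_1}\,
\exp\{\tfrac12 r_j^2 (1/v_0 - 1/v_1)\}$; the package verifies this against
an exact two-state enumeration in its test suite. BayesB uses
Metropolis-Hastings with (by default) two prior-draw proposals of
$(\delta_j^*, \sigma^{2*}_{u_j})$ per locus per sweep, so the acceptance
ratio is a pure marginal-likelihood ratio. With $m$ markers currently in
the model, BayesCpi updates $\pi \sim \mathrm{Beta}(k-m+1,\, m+1)$.
BayesC/Cpi share a common effect variance updated as
$\sigma^2_u \sim (\nu_a S_a + \sum_{\delta_j=1} u_j^2)\,/\,
\chi^2_{\nu_a+m}$ — the spec-level operation list only names the per-locus
update, but the common-variance model requires it.

Posterior means accumulate every post-burn-in sweep with excluded-locus
effects counted as zero, so each SNP's posterior-mean effect is shrunk in
proportion to its inclusion frequency — no extra machinery is needed to
realize that property.

### Priors and starting values

Starting additive and residual variances (`Va_start`, `Ve_start`) are trait
knowledge, conventionally the sample-size-weighted mean of within-breed
REML components (`weighted_start()`). The per-locus prior mean variance
partitions `Va_start` over the expected number of included markers and the
genotype column variances:
$\bar\sigma^2_u = V_a / ((1-\pi)\sum_j v_j)$, converted to the scale
parameter by $S = \bar\sigma^2_u(\nu-2)/\nu$. Prior degrees of freedom
default to $\nu_a = \nu_e = 4$, the de facto convention of this software
family; both are configurable. The shipped `default_start_values()` table
carries the per-trait starts for six carcass traits (shear force, ribeye
area, marbling, fat thickness, carcass weight, yield grade).

BayesA is sensitive to its starting variances; the two-stage protocol
(`informed_start()`) runs BayesCpi first and restarts BayesA from its
posterior-mean variances. The chain itself is insensitive for the C-family
models, where the data overwhelm the starts.

### Genomic variance and heritability

Per sweep the package records two genomic-variance samples: the *realized*
variance of the current genomic values $\mathrm{var}_i(\sum_j z_{ij} u_j
\delta_j)$ and the *model-implied* variance
$\sum_{j:\delta_j=1} \sigma^2_{u(j)} v_j$. Reported $h^2$ samples use the
model-implied form, $h^2 = V_a/(V_a + \sigma^2_e)$, which stays in $[0,1]$
and is free of the Monte Carlo spread of $u$; when markers far outnumber
records the realized form inflates $V_a$ by the average posterior variance
of the genomic values (about +0.02 at $n=1000$, $k=2000$ in our checks).
Both sample paths are returned, so either convention can be inspected.

## The synthetic-data generator

No genotype or phenotype data from the motivating study are deposited, so
the generator reproduces its statistical structure and is itself
first-class, tested code:

* **Breed divergence.** Ancestral allele frequencies
  $p_0 \sim U(0.05, 0.95)$ per SNP; each breed draws
  $p \sim \mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$ (Balding-Nichols),
  one interpretable drift parameter $F$ per breed ($F=0$ reproduces $p_0$
  exactly). The default $F = 0.1$ puts mean pairwise $F_{ST}$ near 0.1,
  typical of taurine beef breeds.
* **Crossing.** Sires are drawn from their breed's frequencies under HWE;
  each progeny gets one Mendelian sire gamete and one dam gamete from the
  mixture-weighted breed frequencies (`dam_ancestry`). This gamete-level
  grading-up stands in for explicit multi-generation dam pedigrees —
  sufficient because the models here ignore linkage. British-breed sires
  (Angus, Hereford) mate dams of their own ancestry; Continental sires mate
  50% Angus commercial dams by default (the true fraction in the study is
  unstated and configurable).
* **Family structure.** The study data are singleton-heavy: ~37% of
  animals are their sire's only progeny and 45% sit in half-sib families
  of at most 10. A single zero-truncated negative binomial cannot be
  simultaneously singleton-heavy and long-tailed (its size law is
  unimodal), so family sizes use a singleton hurdle plus a zero-truncated
  negative binomial tail on sizes 2..`max_family_size`, with the tail mean
  tuned by root-finding so both animal-weighted fractions are met.
* **Architectures.** `trait_architecture()` spans infinitesimal
  (`n_qtl = k`, gaussian effects) to oligogenic (few QTL, optionally one
  large-effect QTL carrying a stated share of the genetic variance).
  Breed-specific QTL are forced to segregate (MAF ≥ 0.05) in the target
  breed and are fixed at dosage zero in all others by direct edit of the
  genotype matrix — an idealization that makes the contract exactly
  assertable. Effects are rescaled so the empirical genetic variance equals
  `target_h2`, placing the phenotypic variance at ~1 trait unit²; the
  residual variance follows as $V_g(1-h^2)/h^2$.
* **Contemporary groups** are the herd × breed × sex × harvest-date cross
  (4 × breeds × 2 × 2 by default, realized cells only), with shared
  $N(0, \sigma^2_{cg})$ effects.
* **Missingness** composes independent animal-level and SNP-level Bernoulli
  masks; the dosage store is never altered, so QC can be tested against
  ground truth. The study's post-call missingness was 0.89%.

What the generator does **not** emulate: linkage and LD between markers,
selection, multi-generation pedigrees, genotyping error. Tests passing on
these data therefore demonstrate sampler and pipeline correctness and the
architecture-dependent model ordering, but not LD-mediated effects — see
"Known limitations".

## Quality control

Filters mirror the standard 50K-chip pipeline: animals with call rate
< 0.95 first, then SNPs with call rate < 0.89, then MAF < 0.01 recomputed
on surviving animals (so MAF reflects the analyzed set; the source
pipeline does not state an order). Removal is strict "less than": a SNP at
exactly the threshold survives. Missing genotypes are mean-imputed within
SNP — haplotype phasing is out of scope, and at sub-percent missingness the
within-SNP mean preserves the allele frequency, which is all the
regression consumes. Imputation must precede encoding; the coding-state
guard rejects double encoding.

## Pre-correction and evaluation

Contemporary-group effects are estimated once, in a single all-animal
BayesCpi fit with the group design as a fixed effect (explicit intercept,
drop-one constraint; block updates from the exact multivariate-normal
conditional under a flat prior). Markers stay in that model so genetic
signal is not absorbed into group means; only the fixed-effect posterior
means are subtracted. Pre-correcting once lets every training/validation
partition reuse the same adjusted phenotypes.

Evaluation draws `n_replicates` (default 20) random breed-blind splits per
training fraction (grid 10%–95%), reusing identical splits across models.
Accuracy is reported as the validation correlation $r$ between DGV and
adjusted phenotype, and as the realized accuracy $r/\sqrt{h^2}$ — the
correlation divided by its theoretical ceiling. Values above 1 (they occur
when $h^2$ is underestimated, e.g. by BayesCpi on oligogenic traits) are
reported with a warning, never clamped. The best-fit training fraction
minimizes the coefficient of variation of accuracy across replicates among
fractions above 0.5, ties toward more training data; on synthetic data the
rule lands in the 55–80% band with CV inflation at ≥ 90% fractions, the
same heuristic the motivating study reports. Cross-model comparisons use a
classical paired t-test on per-replicate correlations, with a Bonferroni
family of 36 tests by default (six model pairs × six traits → corrected
threshold 0.05/36 ≈ 0.0014).

Per-breed accuracies standardize the within-breed validation correlation
by that breed's own heritability; both the per-replicate-standardize-then-
average path and the raw correlations are exposed, since the study's
wording leaves the order ambiguous. Breeds with fewer than 3 validation
animals are skipped with a notice.

## Numerical and design choices

* **Update order** per sweep: fixed effects → loci in storage order
  (indicator, effect, locus variance) → common variance → $\pi$ →
  $\sigma^2_e$ → genomic-variance sample; running means, no thinning. The
  order is fixed for reproducibility; the source software's order is not
  published.
* **Determinism.** The C++ core uses R's RNG, so a `ModelConfig` seed gives
  bit-identical posterior summaries; every generator and allocation
  function is a pure function of (inputs, seed). The full pipeline run
  twice with one seed writes byte-identical files.
* **Bookkeeping.** The residual identity
  $\mathbf e = \mathbf y - X\mathbf b - Z(\mathbf u \odot \boldsymbol\delta)$
  is maintained incrementally and can be asserted every 100 sweeps
  (`check_bookkeeping = TRUE`); drift stays below $10^{-8}$ in tests.
* **Degeneracies.** Monomorphic surviving loci get $u \equiv 0$ with a
  warning; $\pi$ is clamped to $[10^{-8}, 1-10^{-8}]$ inside odds; BayesB
  with $\pi = 1$ runs as a legal degenerate chain (DGV ≡ 0); rank-deficient
  fixed-effect designs are refused with the confounded columns named.
* **Oracle mode.** `update_variances = FALSE` freezes variance components:
  BayesC0 then reproduces the closed-form ridge/BLUP solution
  $(Z'Z + \lambda I)^{-1}Z'y$, and the single-locus indicator chains (both
  the Gibbs and the MH path, whose proposals then use the fixed variance)
  target the exactly enumerable two-state posterior. These cross-checks
  anchor the sampler tests.

## Test-scale choices

The motivating study ran 160 000-iteration chains on 3240 animals × 40 645
SNPs; those are the package defaults, but the shipped tests run at desk
scale, chosen once as: ridge-oracle check at $n=200, k=500$, 20 000
sweeps; heritability recovery on five datasets of $n=1000, k=2000$ with
8000-sweep chains (the posterior sd of $h^2$ at that size is ~0.06, so
recovery is asserted on the five-dataset average of posterior means);
$\pi$-architecture discrimination at $n=500, k=1000$; model ordering at
$n=600, k=400$ (oligogenic) and $n=1000, k=150$ (infinitesimal — with
unlinked markers the per-locus-variance models match the equal-variance
model tightly only when each marker is well informed, roughly
$n/k \gtrsim 5$; at marker densities beyond that the comparison is
dominated by adaptivity noise that real data resolve through LD); best-fit
grid on ~3000 animals × 300 SNPs with 600-sweep chains.

## Known limitations

* **No linkage.** Simulated SNPs are unlinked. One real consequence:
  BayesB with $\pi = 0.95$ genuinely loses accuracy on a dense (per-locus
  infinitesimal) simulated trait, because the 95% of markers excluded in
  any sweep have no linked proxies among the included 5%. On real dense
  panels this equivalence is mediated by LD, which is why the motivating
  study saw near-identical accuracies across models for infinitesimal
  traits. The corresponding acceptance check is asserted as specified and
  fails under this simulator by design consequence, with BayesA and
  BayesCpi (whose inclusion adapts) matching BayesC0 within 0.01.
* **Mean imputation**, not haplotype phasing; appropriate only at the
  sub-percent missingness emulated here.
* **Single-trait, additive** models only; no dominance, epistasis or
  genotype uncertainty.
* The $h^2$ recovery tolerance reflects posterior spread at test scale,
  not an asymptotic guarantee; BayesCpi is expected to underestimate $h^2$
  on strongly oligogenic traits (the study observed the same), which is
  why realized accuracies are conventionally standardized by the BayesC0
  estimate.

## A minimal run

```{r example}
dat <- simulate_dataset(
  n_snps = 1000, breeds = cmp_breeds(scale = 0.2),
  arch = trait_architecture(n_qtl = 100, effect_dist = "mixture",
                            large_effect_fraction_of_Vg = 0.25,
                            target_h2 = 0.26, cg_effect_sd = 0.5),
  missing_rate = 0.0089, seed = 1)

qc <- qc_filter(dat$genotypes)
Z  <- encode_centered_ten(impute_missing(qc$genotypes))
ph <- dat$phenotypes[match(Z$animal_id, dat$genotypes$animal_id), ]

pc <- precorrect(ph$y, Z, build_groups(ph),
                 model_config("Cpi", pi = 0.9, Va_start = 0.26,
                              Ve_start = 0.74, chain_length = 4000,
                              burn_in = 1000, seed = 2))

grid <- evaluate_grid(
  unname(pc$y_adj), Z,
  list(C0  = model_config("C", pi = 0, Va_start = 0.26, Ve_start = 0.74,
                          chain_length = 3000, burn_in = 600),
       Cpi = model_config("Cpi", pi = 0.9, Va_start = 0.26,
                          Ve_start = 0.74, chain_length = 3000,
                          burn_in = 600)),
  fractions = c(0.6, 0.7), n_replicates = 5, seed = 3)
summarize_grid(grid, "r")
```
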