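test_that("prior scales partition the starting variance over included loci", {
  v <- runif(1000, 50, 150)
  cfg <- model_config("Cpi", pi = 0.99, Va_start = 0.416, Ve_start = 0.624)
  sc <- prior_scales(cfg, v)
  expect_equal(sc$prior_mean_a, 0.416 / (0.01 * sum(v)))
  expect_equal(sc$S_a * cfg$nu_a / (cfg$nu_a - 2), sc$prior_mean_a)
  expect_equal(sc$S_e * cfg$nu_e / (cfg$nu_e - 2), 0.624)
  # pi = 0, single locus of unit variance: prior mean = Va_start
  cfg0 <- model_config("C", pi = 0, Va_start = 0.3, Ve_start = 1)
  expect_equal(prior_scales(cfg0, 1)$prior_mean_a, 0.3)
  # large df: scale approaches the prior mean
  cfg_inf <- model_config("C", pi = 0, Va_start = 0.3, Ve_start = 1,
                          nu_a = 1e8, nu_e = 1e8)
  expect_equal(prior_scales(cfg_inf, 1)$S_a, 0.3, tolerance = 1e-6)
  expect_error(prior_scales(model_config("C", pi = 1, Va_start = 1,
                                         Ve_start = 1), v), "pi = 1")
})

test_that("scaled inverse chi-squared draws match the analytic moment", {
  set.seed(1)
  x <- rscinvchisq(1e5, nu = 6, S = 2)        # mean = nu S / (nu - 2) = 3
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 3) / 3, 0.01)
  # locus-variance posterior at u_j = 0.2, nu_a = 4: moment of the
  # scInvChi2(nu_a + 1, (nu_a S_a + u^2)/(nu_a + 1)) full conditional
  Sa <- 0.05; u <- 0.2; nu <- 4
  scale_post <- (nu * Sa + u^2) / (nu + 1)
  y <- rscinvchisq(2e5, nu + 1, scale_post)
  expect_lt(abs(mean(y) - (nu + 1) * scale_post / (nu - 1)) /
              ((nu + 1) * scale_post / (nu - 1)), 0.02)
  # u_j = 0: posterior scale collapses to S_a nu/(nu+1)
  expect_equal((nu * Sa + 0) / (nu + 1), Sa * nu / (nu + 1))
})

test_that("pi Gibbs draw is Beta(k - m + 1, m + 1)", {
  # analytic means at the corners
  expect_equal((100 - 0 + 1) / (100 + 2), 101 / 102)
  set.seed(2)
  expect_lt(abs(mean(sample_pi(100, 0, 1e4)) - 101 / 102), 0.002)
  expect_lt(abs(mean(sample_pi(100, 100, 1e4)) - 1 / 102), 0.002)
  expect_lt(abs(mean(sample_pi(100, 10, 1e5)) - 91 / 102), 0.002)
})

test_that("marker-effect conditional mean follows the ridge formula", {
  # one locus: posterior mean with fixed variances = r/(zz + ve/vu)
  z <- c(1, 3, 0, -1, 1); zz <- sum(z^2)   # 12... kept general below
  y <- c(0.5, 1.2, -0.3, 0.1, 0.4)
  r <- sum(z * y)
  ols <- solve_ridge(y, matrix(z), lambda = 0)$u_hat
  expect_equal(ols, r / zz)                          # sigma2_u -> infinity
  shr <- solve_ridge(y, matrix(z), lambda = 10)$u_hat
  expect_equal(shr, r / (zz + 10))                   # ve/vu = 10
})

test_that("chains are seed-deterministic and keep the bookkeeping identity", {
  Z <- hwe_centered(80, 40, seed = 3)
  set.seed(4); y <- rnorm(80)
  for (m in c("A", "B", "C", "Cpi")) {
    cfg <- quick_config(m, pi = if (m %in% c("B", "Cpi")) 0.9 else 0,
                        L = 800, burn = 200, seed = 11)
    f1 <- run_chain(y, Z, cfg, check_bookkeeping = TRUE)
    f2 <- run_chain(y, Z, cfg)
    expect_identical(f1$u_mean, f2$u_mean)
    expect_identical(f1$h2_samples, f2$h2_samples)
    expect_lt(f1$bookkeeping_max_err, 1e-8)
    expect_true(all(f1$Ve_samples > 0))
    expect_true(all(f1$h2_samples >= 0 & f1$h2_samples <= 1))
    expect_true(all(f1$inclusion >= 0 & f1$inclusion <= 1))
  }
})

test_that("degenerate settings: pi forced by model, monomorphic loci", {
  expect_equal(model_config("A", pi = 0.5)$pi, 0)    # BayesA includes all
  Z <- hwe_centered(50, 10, seed = 5)
  Z[, 4] <- 0                                        # monomorphic survivor
  set.seed(6); y <- rnorm(50)
  expect_warning(fit <- run_chain(y, Z, quick_config("C", L = 500,
                                                     burn = 100)),
                 "monomorphic")
  expect_equal(unname(fit$u_mean[4]), 0)
  expect_equal(unname(fit$inclusion[4]), 0)
  # BayesB with pi = 1: nothing enters, DGV identically zero
  fitB <- run_chain(y, Z[, 1:3], quick_config("B", pi = 1, L = 500,
                                              burn = 100))
  expect_true(all(fitB$u_mean == 0))
  expect_equal(unname(predict_dgv(Z[, 1:3], fitB)), rep(0, 50))
  # BayesC with pi = 0 keeps every locus in the model
  fitC <- run_chain(y, Z[, 1:3], quick_config("C", pi = 0, L = 500,
                                              burn = 100))
  expect_true(all(fitC$inclusion == 1))
})

test_that("BayesB MH acceptance rate is a proper diagnostic", {
  Z <- hwe_centered(100, 50, seed = 7)
  set.seed(8); y <- rnorm(100)
  fit <- run_chain(y, Z, quick_config("B", pi = 0.9, L = 1000, burn = 200))
  expect_gt(fit$mh_acceptance, 0)
  expect_lt(fit$mh_acceptance, 1)
  fitC <- run_chain(y, Z, quick_config("C", L = 500, burn = 100))
  expect_true(is.na(fitC$mh_acceptance))
})

test_that("fixed-effect block draw recovers orthogonal group means", {
  n <- 60
  grp <- rep(0:1, each = n / 2)
  X <- cbind(g0 = 1 - grp, g1 = grp)     # orthogonal two-group design
  set.seed(9)
  y <- c(2, -1)[grp + 1] + rnorm(n, 0, 0.5)
  Z <- hwe_centered(n, 5, seed = 10)
  cfg <- quick_config("C", L = 25000, burn = 2000, Va = 1e-6, Ve = 0.25,
                      update_variances = FALSE, seed = 12)
  fit <- run_chain(y, Z, cfg, fixed_effects = X)
  # posterior sd of each group mean is sqrt(0.25/30) ~ 0.09; with ~23k
  # near-independent draws the MC se is ~2e-3, so 0.02 is > 3 MC se
  means <- tapply(y, grp, mean)
  expect_lt(abs(fit$b_mean[1] - means[1]), 0.02)
  expect_lt(abs(fit$b_mean[2] - means[2]), 0.02)
  # rank-deficient design is refused with the offending column named
  Xbad <- cbind(X, both = 1)
  expect_error(run_chain(y, Z, cfg, fixed_effects = Xbad), "rank deficient")
  # no fixed effects: b_mean empty
  expect_length(run_chain(y, Z, quick_config("C", L = 300,
                                             burn = 50))$b_mean, 0)
})

test_that("genomic variance of current effects is the spread of Z u", {
  Z <- hwe_centered(2000, 1, p = 0.3, seed = 13)
  p_hat <- mean(Z[, 1] / 10 + 1) / 2
  gv <- genomic_variance(Z, 0.05, sigma2_e = 1)
  expect_lt(abs(gv$Va - 100 * 2 * p_hat * (1 - p_hat) * 0.05^2) / gv$Va, 0.05)
  expect_true(gv$h2 >= 0 && gv$h2 <= 1)
  expect_equal(genomic_variance(Z, 0)$Va, 0)
  expect_error(genomic_variance(Z[1, , drop = FALSE], 0.05), "fewer than 2")
})

test_that("informed and weighted starting values follow the protocol", {
  ws <- weighted_start(Va = c(0.4, 0.6), Ve = c(1, 2), n = c(100, 300))
  expect_equal(ws$Va_start, 0.55)
  expect_equal(ws$Ve_start, 1.75)
  expect_equal(weighted_start(0.4, 1.1, 50)$Va_start, 0.4)   # single group
  ws3 <- weighted_start(c(1, 2, 3), c(2, 4, 6), c(1, 2, 3))
  expect_equal(ws3$Va_start, (1 + 4 + 9) / 6)
  expect_equal(ws3$Ve_start, (2 + 8 + 18) / 6)
  expect_error(weighted_start(numeric(0), numeric(0), numeric(0)), "nonempty")

  # two-stage starts: the uninformed WBSF BayesA starts (0.16, 0.55) are
  # replaced by the BayesCpi posterior means, nothing else changes
  Z <- hwe_centered(60, 20, seed = 14)
  set.seed(15); y <- rnorm(60)
  src <- run_chain(y, Z, quick_config("Cpi", pi = 0.9, L = 600, burn = 100))
  tgt <- default_config("WBSF", "A", chain_length = 500, burn_in = 100)
  expect_equal(tgt$Va_start, 0.16)
  expect_equal(tgt$Ve_start, 0.55)
  inf <- informed_start(tgt, src)
  expect_equal(inf$Va_start, src$Va_mean)
  expect_equal(inf$Ve_start, src$Ve_mean)
  expect_equal(inf$model, tgt$model)
  expect_equal(inf$pi, tgt$pi)
  expect_identical(informed_start(inf, src), inf)    # idempotent
})

test_that("shipped starting-value table carries the per-trait defaults", {
  tab <- default_start_values()
  expect_equal(nrow(tab), 24)
  wb <- tab[tab$trait == "WBSF" & tab$analysis == "Cpi", ]
  expect_equal(c(wb$pi, wb$Va, wb$Ve), c(0.99, 0.416, 0.624))
  cfg <- default_config("FT", "B95")
  expect_equal(cfg$model, "B")
  expect_equal(cfg$pi, 0.95)
  expect_equal(c(cfg$Va_start, cfg$Ve_start), c(0.011, 0.136))
  expect_equal(cfg$chain_length, 160000L)
  expect_equal(cfg$burn_in, 10000L)
  expect_equal(cfg$mh_cycles, 2L)
  expect_error(default_config("NOPE", "A"), "unknown trait")
})

test_that("config invariants are enforced", {
  expect_error(model_config("C", pi = 1.2), "pi")
  expect_error(model_config("C", chain_length = 100, burn_in = 100),
               "burn_in")
  expect_error(model_config("C", Va_start = 0), "variances")
})
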