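test_that("genotype marginals match Binomial(2, maf) moments", {
  g <- simulate_genotypes(genotype_model(p = 4, maf = 0.25, rho = 0),
                          n = 20000, seed = 1)
  expect_true(all(g %in% 0:2))
  se_mean <- sqrt(0.375 / 20000)
  expect_lt(max(abs(colMeans(g) - 0.5)), 4 * se_mean)
  expect_lt(max(abs(apply(g, 2, var) - 0.375)), 0.01)
  # independence at rho = 0
  cors <- cor(g)[upper.tri(diag(4))]
  expect_lt(max(abs(cors)), 4 / sqrt(20000))
})

test_that("latent copula correlation induces genotype correlation", {
  g <- simulate_genotypes(genotype_model(p = 6, maf = 0.25, rho = 0.1),
                          n = 30000, seed = 2)
  cors <- cor(g)[upper.tri(diag(6))]
  # discretization attenuates the latent 0.1 to roughly 0.07 on the
  # genotype scale; all pairs share the exchangeable structure
  expect_gt(min(cors), 0.05)
  expect_lt(max(cors), 0.095)
  # monotone in rho
  g2 <- simulate_genotypes(genotype_model(p = 6, maf = 0.25, rho = 0.4),
                           n = 30000, seed = 3)
  expect_gt(mean(cor(g2)[upper.tri(diag(6))]), mean(cors))
})

test_that("generators are deterministic under a seed", {
  gm <- genotype_model(p = 5, maf = c(0.25, 0.75), rho = 0.1)
  expect_identical(simulate_genotypes(gm, 50, seed = 9),
                   simulate_genotypes(gm, 50, seed = 9))
  sm <- simulation_model(beta0 = -1, p = 5, marginal_idx = 1:2,
                         marginal_beta = log(1.5))
  g <- simulate_genotypes(gm, 200, seed = 10)
  expect_identical(simulate_phenotype(g, sm, seed = 11),
                   simulate_phenotype(g, sm, seed = 11))
  expect_identical(simulate_case_control(gm, sm, 30, 30, seed = 12),
                   simulate_case_control(gm, sm, 30, 30, seed = 12))
})

test_that("phenotype model hits closed-form prevalences", {
  gm <- genotype_model(p = 3, maf = 0.5)
  g <- simulate_genotypes(gm, 40000, seed = 13)
  y0 <- simulate_phenotype(g, simulation_model(beta0 = 0, p = 3), seed = 14)
  expect_lt(abs(mean(y0) - 0.5), 4 * sqrt(0.25 / 40000))
  y5 <- simulate_phenotype(g, simulation_model(beta0 = -5, p = 3), seed = 15)
  expect_lt(abs(mean(y5) - plogis(-5)), 4 * sqrt(plogis(-5) / 40000) + 1e-3)
})

test_that("interaction terms enter the linear predictor", {
  sm <- simulation_model(beta0 = -1, p = 3,
                         interactions = data.frame(i = 1, j = 2, beta = 2))
  g <- matrix(c(2, 0, 2, 0, 1, 0), 2, 3)  # subject 1: G1=2,G2=2; subject 2: 0
  eta <- epiget:::.linear_predictor(g, sm)
  expect_equal(eta, c(-1 + 2 * 4, -1))
  expect_error(simulation_model(beta0 = 0, p = 3,
                                interactions = data.frame(i = 2, j = 2,
                                                          beta = 1)),
               "distinct")
})

test_that("subsampling respects class counts and errors when short", {
  set.seed(16)
  g <- simulate_genotypes(genotype_model(p = 3, maf = 0.3), 500)
  y <- rbinom(500, 1, 0.3)
  out <- subsample_case_control(g, y, 50, 100, seed = 17)
  expect_equal(sum(out$phenotype), 50)
  expect_equal(length(out$phenotype), 150)
  expect_error(subsample_case_control(g, y, 1e4, 10, seed = 18),
               "insufficient")
})

test_that("pool generator meets requested design or reports prevalence", {
  gm <- genotype_model(p = 4, maf = 0.3)
  sm <- simulation_model(beta0 = -1, p = 4, marginal_idx = 1,
                         marginal_beta = log(2))
  out <- simulate_case_control(gm, sm, 200, 200, seed = 19)
  expect_equal(sum(out$phenotype), 200)
  expect_equal(nrow(out$genotypes), 400)
  # impossible prevalence under the cap: beta0 = -12 gives ~6e-6
  sm_rare <- simulation_model(beta0 = -12, p = 4)
  # the no-effect shortcut bypasses the pool, so force effects in
  sm_rare <- simulation_model(beta0 = -12, p = 4, marginal_idx = 1,
                              marginal_beta = 1e-9)
  expect_error(simulate_case_control(gm, sm_rare, 50, 50, seed = 20,
                                     pool_cap = 20),
               "prevalence")
})

test_that("no-effect shortcut matches the pooled route distributionally", {
  gm <- genotype_model(p = 3, maf = 0.4)
  sm_null <- simulation_model(beta0 = -2, p = 3)
  out <- simulate_case_control(gm, sm_null, 300, 300, seed = 21)
  # genotype law must be unchanged: compare moments against direct draws
  expect_lt(abs(mean(out$genotypes) - 0.8), 4 * sqrt(0.48 / 1800) + 0.02)
  expect_equal(sum(out$phenotype), 300)
  # under marginal effects the case mean must exceed the control mean
  sm_eff <- simulation_model(beta0 = -1, p = 3, marginal_idx = 1,
                             marginal_beta = log(3))
  out2 <- simulate_case_control(gm, sm_eff, 400, 400, seed = 22)
  expect_gt(mean(out2$genotypes[out2$phenotype == 1, 1]),
            mean(out2$genotypes[out2$phenotype == 0, 1]))
})

test_that("disease architecture generator composes risk pieces", {
  arch <- disease_architecture(
    risk_snps = data.frame(maf = c(0.3, 0.2), or = c(1.4, 1.2)),
    exposures = data.frame(prevalence = 0.25, or = 1.5),
    n_null = 5, gxg = data.frame(i = 1, j = 2, beta = log(2)),
    beta0 = -2)
  out <- simulate_disease(arch, 100, 100, seed = 23)
  expect_equal(ncol(out$genotypes), 7)
  expect_equal(sum(out$phenotype), 100)
  expect_equal(ncol(out$covariates), 1)
  expect_true(all(out$covariates %in% 0:1))
  expect_identical(out, simulate_disease(arch, 100, 100, seed = 23))
  # a null architecture reduces to pure noise: risk SNP mean matches HWE
  arch0 <- disease_architecture(
    risk_snps = data.frame(maf = 0.3, or = 1), n_null = 3, beta0 = -1)
  out0 <- simulate_disease(arch0, 300, 300, seed = 24)
  expect_lt(abs(mean(out0$genotypes[, 1]) - 0.6), 0.05)
})

test_that("input validation rejects malformed models", {
  expect_error(genotype_model(p = 5, maf = 0.25, rho = 1), "rho")
  expect_error(genotype_model(p = 5, maf = 1.2), "maf")
  expect_error(simulate_phenotype(matrix(0L, 5, 3),
                                  simulation_model(beta0 = 0, p = 4)),
               "markers")
})
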