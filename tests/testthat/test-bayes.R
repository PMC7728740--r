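test_that("BRR with fixed variances matches the conjugate ridge closed form", {
  set.seed(61)
  n <- 150
  x <- rbinom(n, 2, 0.4)
  a_true <- 0.8
  y <- 1.5 + x * a_true + rnorm(n, sd = 1)
  G <- genotype_matrix(matrix(x, ncol = 1))
  s2e <- 1; s2a <- 0.5
  cfg <- gibbs_config("BRR", n_iter = 30000, burn_in = 5000, thin = 10,
                      seed = 2, fix_sigma2_a = s2a, fix_sigma2_e = s2e,
                      store_effect_samples = TRUE)
  ps <- run_gibbs(y, G, cfg)
  # closed form on the centered design with y centered (mu integrated out)
  xc <- x - mean(x)
  yc <- y - mean(y)
  a_exact <- sum(xc * yc) / (sum(xc^2) + s2e / s2a)
  chain <- ps$effect_samples[, 1]
  r1 <- stats::acf(chain, plot = FALSE, lag.max = 1)$acf[2]
  ess <- length(chain) * (1 - r1) / (1 + r1)
  mcse <- sd(chain) / sqrt(max(ess, 1))
  expect_lt(abs(ps$add_effects[[1]] - a_exact), 3 * mcse)
})

test_that("kept-sample bookkeeping and seeded chain reproducibility", {
  G <- small_panel(40, 15, seed = 62)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.5, seed = 63)
  cfg <- gibbs_config("BayesCpi", n_iter = 10000, burn_in = 1000, thin = 10,
                      seed = 4)
  ps <- run_gibbs(st$phenotypes, G, cfg)
  expect_equal(ps$n_samples_kept, 900L)

  ps2 <- run_gibbs(st$phenotypes, G, cfg)
  expect_identical(ps$chains, ps2$chains)
  expect_identical(ps$add_effects, ps2$add_effects)
})

test_that("Bayes B with all-null prior collapses to the intercept", {
  G <- small_panel(50, 20, seed = 64)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.5, seed = 65)
  cfg <- gibbs_config("BayesB", n_iter = 4000, burn_in = 1000, thin = 5,
                      pi0 = 1, seed = 5)
  ps <- run_gibbs(st$phenotypes, G, cfg)
  expect_true(all(abs(ps$add_effects) < 1e-3 * sd(st$phenotypes$value)))
  fitted <- posterior_predict(ps, G)
  expect_lt(max(abs(fitted - ps$mu)), 1e-3 * sd(st$phenotypes$value))
})

test_that("with n >> p and diffuse priors every model agrees with least squares", {
  set.seed(66)
  n <- 200
  X <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  beta <- c(1, -0.5, 0.25)
  y <- 2 + drop(X %*% beta) + rnorm(n, sd = 0.5)
  G <- genotype_matrix(X)
  Xc <- sweep(X, 2, 2 * G$allele_freq, "-")
  ols <- coef(lm(y ~ Xc))[-1]
  for (m in c("BRR", "BL", "BayesA", "BayesB", "BayesCpi")) {
    cfg <- gibbs_config(m, n_iter = 8000, burn_in = 2000, thin = 5, seed = 6,
                        pi0 = if (m == "BayesB") 0.05 else NULL,
                        store_effect_samples = TRUE)
    ps <- run_gibbs(y, G, cfg)
    mcse <- apply(ps$effect_samples, 2, function(ch) {
      r1 <- stats::acf(ch, plot = FALSE, lag.max = 1)$acf[2]
      sd(ch) / sqrt(max(length(ch) * (1 - r1) / (1 + r1), 1))
    })
    expect_true(all(abs(ps$add_effects - ols) < pmax(3 * mcse, 0.02)),
                label = paste(m, "posterior mean vs OLS"))
  }
})

test_that("sparse-prior models rank true QTL above background by inclusion probability", {
  G <- simulate_genotypes(500, 2000, seed = 67)
  st <- simulate_trait(G, n_qtl = 10, h2a = 0.5, seed = 68)
  qtl <- st$truth$qtl_indices
  for (m in c("BayesB", "BayesCpi")) {
    cfg <- gibbs_config(m, n_iter = 2000, burn_in = 500, thin = 5, seed = 7)
    ps <- run_gibbs(st$phenotypes, G, cfg)
    expect_gt(mean(ps$inclusion_prob[qtl]),
              mean(ps$inclusion_prob[-qtl]),
              label = paste(m, "QTL inclusion"))
  }
})

test_that("posterior prediction contract: consistency, linearity, marker checks", {
  G <- small_panel(40, 12, seed = 69)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.6, seed = 70)
  cfg <- gibbs_config("BRR", n_iter = 3000, burn_in = 500, thin = 5, seed = 8)
  ps <- run_gibbs(st$phenotypes, G, cfg)

  # training-set prediction reproduces fitted genetic values + mu exactly
  expect_equal(unname(posterior_predict(ps, G)),
               unname(ps$fitted_genetic_values + ps$mu))

  # doubling one marker effect doubles its contribution
  ps2 <- ps
  j <- which.max(abs(ps$add_effects))
  ps2$add_effects[j] <- 2 * ps2$add_effects[j]
  W <- sweep(G$dosage, 2, 2 * ps$allele_freq, "-")
  delta <- posterior_predict(ps2, G) - posterior_predict(ps, G)
  expect_equal(unname(delta), unname(W[, j] * ps$add_effects[j]))

  # all-zero effects -> intercept everywhere
  ps0 <- ps
  ps0$add_effects[] <- 0
  expect_equal(unname(posterior_predict(ps0, G)), rep(ps$mu, 40))

  expect_error(posterior_predict(ps, G[, 1:5]), "lack training markers")
})

test_that("additive + dominance model fits and predicts", {
  G <- simulate_genotypes(300, 200, maf_range = c(0.2, 0.5), seed = 71)
  st <- simulate_trait(G, n_qtl = 10, h2a = 0.4, h2d = 0.2, seed = 72)
  cfg <- gibbs_config("BRR", n_iter = 3000, burn_in = 500, thin = 5,
                      seed = 9, use_dominance = TRUE)
  ps <- run_gibbs(st$phenotypes, G, cfg)
  expect_length(ps$dom_effects, 200)
  expect_gt(cor(ps$fitted_genetic_values, st$truth$genotypic_values), 0.5)
  expect_equal(unname(posterior_predict(ps, G)),
               unname(ps$fitted_genetic_values + ps$mu))
})
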