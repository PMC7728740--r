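test_that("predictive ability is the Pearson correlation with a missing-value sentinel", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(predictive_ability(y, y), 1)
  expect_equal(predictive_ability(y, -y), -1)
  expect_true(is.na(predictive_ability(y, rep(2, 5))))
  expect_error(predictive_ability(y, y[1:3]))
})

test_that("90/10 splits round to the protocol sizes and partition the panel", {
  expect_equal(round(0.9 * 322), 290)   # 322 -> 290 training / 32 validation
  expect_equal(round(0.9 * 646), 581)   # 646 -> 581 training / 65 validation

  G <- simulate_genotypes(60, 40, seed = 131)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.5, seed = 132)
  cv <- run_cv(list(GBLUP = kernel_model("GBLUP")), G, st$phenotypes,
               n_cycles = 4, seed = 7)
  expect_equal(unique(cv$train_n), 54)
  expect_equal(unique(cv$valid_n), 6)
  expect_equal(cv$train_n + cv$valid_n, rep(60, nrow(cv)))
})

test_that("identical model specifications receive identical PA vectors and share a letter", {
  G <- simulate_genotypes(80, 60, seed = 133)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.6, seed = 134)
  models <- list(m_one = kernel_model("GBLUP"), m_two = kernel_model("GBLUP"))
  cv <- run_cv(models, G, st$phenotypes, n_cycles = 5, seed = 11)
  pa1 <- cv$pa[cv$model == "m_one"]
  pa2 <- cv$pa[cv$model == "m_two"]
  expect_equal(pa1, pa2)
  cld <- tukey_kramer_cld(cv)
  expect_equal(cld$letters, c("a", "a"))
})

test_that("the full harness is seed-reproducible", {
  G <- simulate_genotypes(60, 50, seed = 135)
  st <- simulate_trait(G, n_qtl = 3, h2a = 0.5, seed = 136)
  models <- list(GBLUP = kernel_model("GBLUP"),
                 BRR = gibbs_config("BRR", n_iter = 800, burn_in = 200,
                                    thin = 2))
  cv1 <- run_cv(models, G, st$phenotypes, n_cycles = 3, seed = 13)
  cv2 <- run_cv(models, G, st$phenotypes, n_cycles = 3, seed = 13)
  expect_identical(cv1, cv2)
})

test_that("a null trait yields near-zero mean PA over 20 cycles", {
  G <- simulate_genotypes(200, 300, seed = 137)
  nul <- simulate_trait(G, n_qtl = 5, h2a = 0, seed = 138)
  cv <- run_cv(list(GBLUP = kernel_model("GBLUP")), G, nul$phenotypes,
               n_cycles = 20, seed = 17)
  expect_lt(abs(mean(cv$pa)), 0.15)
})

test_that("clearly separated models get distinct Tukey-Kramer letters", {
  set.seed(139)
  cv <- data.frame(model = rep(c("good", "bad"), each = 50),
                   trait = "t",
                   pa = c(rnorm(50, 0.7, 0.01), rnorm(50, 0.1, 0.01)))
  cld <- tukey_kramer_cld(cv)
  expect_equal(sort(cld$letters), c("a", "b"))
  expect_equal(cld$model[1], "good")  # ordered by decreasing mean
})

test_that("pairwise significance decisions match the TukeyHSD oracle on random fixtures", {
  set.seed(140)
  for (fix in 1:5) {
    k <- sample(3:5, 1)
    n_per <- sample(c(8, 12, 20), k, replace = TRUE)
    mus <- runif(k, 0, 0.6)
    df <- do.call(rbind, lapply(seq_len(k), function(i)
      data.frame(model = paste0("m", i), trait = "t",
                 pa = rnorm(n_per[i], mus[i], 0.08))))
    # implementation route: studentized-range decisions inside the CLD
    cld <- tukey_kramer_cld(df, alpha = 0.05)
    # oracle route: stats::TukeyHSD on the one-way fit
    tk <- TukeyHSD(aov(pa ~ model, data = df), conf.level = 0.95)$model
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1]]
      sig_oracle <- tk[r, "p adj"] < 0.05
      l1 <- cld$letters[cld$model == pair[1]]
      l2 <- cld$letters[cld$model == pair[2]]
      shares <- any(strsplit(l1, "")[[1]] %in% strsplit(l2, "")[[1]])
      # models share a letter exactly when the oracle finds no difference
      expect_equal(!shares, sig_oracle,
                   label = sprintf("fixture %d pair %s", fix, r))
    }
  }
})

test_that("zero within-group variance is rejected", {
  cv <- data.frame(model = rep(c("a", "b"), each = 5), trait = "t",
                   pa = rep(c(0.5, 0.6), each = 5))
  expect_error(tukey_kramer_cld(cv), "zero within-group variance")
})

test_that("constant predictions are recorded as missing PA with a warning", {
  G <- simulate_genotypes(40, 20, seed = 141)
  st <- simulate_trait(G, n_qtl = 2, h2a = 0.5, seed = 142)
  # an all-null Bayes B predicts the intercept only, i.e. a constant
  models <- list(null_bayesb = gibbs_config("BayesB", n_iter = 400,
                                            burn_in = 100, thin = 2, pi0 = 1))
  expect_warning(cv <- run_cv(models, G, st$phenotypes, n_cycles = 1, seed = 19),
                 "constant predictions")
  expect_true(all(is.na(cv$pa)))
})
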