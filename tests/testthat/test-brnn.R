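test_that("activation functions match their definitions and saturate safely", {
  expect_equal(activation_eval("logsig", 0), 0.5)
  expect_equal(activation_eval("tansig", 0), 0)
  expect_equal(activation_eval("purelin", 2.5), 2.5)
  expect_equal(activation_eval("tansig", 50), 1, tolerance = 1e-12)
  expect_equal(activation_eval("logsig", -1000), 0)
  expect_equal(activation_eval("tansig", -1000), -1)
  x <- seq(-3, 3, by = 0.5)
  expect_equal(activation_eval("tansig", x), tanh(x), tolerance = 1e-12)
})

test_that("the ten named architectures have the documented layer/activation tuples", {
  p <- brnn_presets()
  expect_named(p, paste0("brnn", 1:10))
  tuple <- function(arch) list(n = vapply(arch, `[[`, numeric(1), "neurons"),
                               a = vapply(arch, `[[`, character(1), "activation"))
  expect_equal(tuple(p$brnn1), list(n = 1, a = "purelin"))
  expect_equal(tuple(p$brnn2), list(n = 1, a = "logsig"))
  expect_equal(tuple(p$brnn3), list(n = 1, a = "tansig"))
  expect_equal(tuple(p$brnn4), list(n = c(2, 1), a = c("purelin", "purelin")))
  expect_equal(tuple(p$brnn5), list(n = c(2, 1), a = c("logsig", "logsig")))
  expect_equal(tuple(p$brnn6), list(n = c(2, 1), a = c("tansig", "tansig")))
  expect_equal(tuple(p$brnn7), list(n = c(2, 1), a = c("tansig", "purelin")))
  expect_equal(tuple(p$brnn8), list(n = c(2, 1), a = c("logsig", "purelin")))
  expect_equal(tuple(p$brnn9), list(n = c(2, 2, 1),
                                    a = c("tansig", "logsig", "purelin")))
  expect_equal(tuple(p$brnn10), list(n = c(2, 2, 1),
                                     a = c("logsig", "tansig", "purelin")))
})

test_that("a single purelin unit recovers the least-squares slope of a linear trait", {
  set.seed(92)
  x <- matrix(rnorm(100), 100, 1)
  y <- 2 * x[, 1] + rnorm(100, sd = 0.01)
  net <- train_brnn(x, y, brnn_config("brnn1", max_epochs = 300, seed = 2))
  slope <- coef(lm(predict_net(net, x) ~ x[, 1]))[2]
  ls_slope <- coef(lm(y ~ x[, 1]))[2]
  expect_lt(abs(slope - ls_slope), 0.05)
})

test_that("evidence bookkeeping: gamma in [0, k], objective non-increasing at accepted steps", {
  set.seed(93)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, -1, 0.5, 0)) + rnorm(50, sd = 0.3)
  net <- train_brnn(X, y, brnn_config("brnn4", max_epochs = 100, seed = 3))
  tr <- net$trace
  expect_true(all(tr$gamma >= 0 & tr$gamma <= net$n_weights))
  expect_true(all(tr$objective_after <= tr$objective_before + 1e-10))
})

test_that("pure-noise targets are regularized harder than signal targets", {
  set.seed(94)
  x <- matrix(rnorm(100), 100, 1)
  y_sig <- 2 * x[, 1] + rnorm(100, sd = 0.1)
  y_noise <- rnorm(100)
  for (s in 1:3) {
    net_s <- train_brnn(x, y_sig, brnn_config("brnn1", max_epochs = 300, seed = s))
    net_n <- train_brnn(x, y_noise, brnn_config("brnn1", max_epochs = 300, seed = s))
    g_s <- utils::tail(net_s$trace$gamma, 1)
    g_n <- utils::tail(net_n$trace$gamma, 1)
    expect_lt(g_n, g_s)
    expect_lt(g_n, 0.5 * net_n$n_weights)
  }
})

test_that("prediction contract: zero nets, column checks, permutation symmetry", {
  cfg <- brnn_config("brnn1")
  shapes <- gpdeep:::.brnn_shapes(3, cfg$architecture)
  k <- 3 + 1 + 1 + 1
  net0 <- structure(list(weights = rep(0, k), shapes = shapes, config = cfg,
                         x_center = rep(0, 3), x_scale = rep(1, 3),
                         y_center = 0, y_scale = 1, n_weights = k,
                         trace = NULL),
                    class = "BrnnNetwork")
  expect_equal(predict_net(net0, matrix(rnorm(15), 5, 3)), rep(0, 5))

  set.seed(95)
  X <- matrix(rnorm(120), 30, 4)
  y <- rnorm(30)
  net <- train_brnn(X, y, brnn_config("brnn4", max_epochs = 30, seed = 4))
  expect_error(predict_net(net, X[, 1:3]), "columns")

  # permuting input columns together with first-layer weights and scaling
  perm <- c(3, 1, 4, 2)
  netp <- net
  pw <- gpdeep:::.brnn_unpack(net$weights, net$shapes)
  pw$W[[1]] <- pw$W[[1]][, perm, drop = FALSE]
  netp$weights <- unlist(lapply(seq_along(pw$W), function(l)
    c(as.vector(pw$W[[l]]), pw$b[[l]])))
  netp$x_center <- net$x_center[perm]
  netp$x_scale <- net$x_scale[perm]
  expect_equal(predict_net(netp, X[, perm]), predict_net(net, X))
})

test_that("the weight-count cap refuses quadratic blow-ups", {
  X <- matrix(rnorm(600), 20, 30)
  y <- rnorm(20)
  cfg <- brnn_config("brnn1", max_weights = 10)
  expect_error(train_brnn(X, y, cfg), "reduce p")
})

test_that("brnn1 (purelin) beats the tansig-only brnn3 on a linear trait over CV cycles", {
  G <- simulate_genotypes(150, 60, seed = 96)
  st <- simulate_trait(G, n_qtl = 5, h2a = 0.6, seed = 97)
  models <- list(brnn1 = brnn_config("brnn1", max_epochs = 60),
                 brnn3 = brnn_config("brnn3", max_epochs = 60))
  cv <- run_cv(models, G, st$phenotypes, n_cycles = 10, seed = 5)
  m <- tapply(cv$pa, cv$model, mean)
  expect_gte(m[["brnn1"]], m[["brnn3"]])
})
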