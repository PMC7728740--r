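zero_params <- function(H, C) {
  structure(list(W = matrix(0, 4 * H, C), R = matrix(0, 4 * H, H),
                 b = numeric(4 * H), w_out = matrix(0, 1, H), b_out = 0),
            class = "LstmParameters")
}

test_that("the cell step reproduces hand-evaluated gate equations", {
  p0 <- zero_params(2, 3)
  # tanh variant, zero weights: i = f = o = 1/2, g = 0, C = c/2
  cvec <- c(0.8, -0.4)
  st <- lstm_cell_step(p0, c(1, 2, 3), c(0, 0), cvec, "tanh")
  expect_equal(drop(st$i), c(0.5, 0.5))
  expect_equal(drop(st$f), c(0.5, 0.5))
  expect_equal(drop(st$o), c(0.5, 0.5))
  expect_equal(drop(st$g), c(0, 0))
  expect_equal(drop(st$C), 0.5 * cvec)
  expect_equal(drop(st$h), 0.5 * tanh(0.5 * cvec))

  # relu variant with C_prev = 1: C = 1/2, h = o * relu(C) = 1/4
  st2 <- lstm_cell_step(p0, c(0, 0, 0), c(0, 0), c(1, 1), "relu")
  expect_equal(drop(st2$C), c(0.5, 0.5))
  expect_equal(drop(st2$h), c(0.25, 0.25))

  expect_error(lstm_cell_step(p0, c(1, 2), c(0, 0), c(0, 0), "tanh"),
               "dimension mismatch")
})

test_that("gate outputs stay in (0,1) and tanh hidden states in [-1,1]", {
  set.seed(101)
  params <- lstm_init_params(4, 6, "tanh", seed = 1)
  h <- matrix(0, 4, 5); C <- matrix(0, 4, 5)
  for (t in 1:6) {
    st <- lstm_cell_step(params, matrix(rnorm(30, sd = 2), 6, 5), h, C, "tanh")
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$h) <= 1))
    h <- st$h; C <- st$C
  }
})

test_that("analytic gradients match central finite differences on a tiny net", {
  for (act in c("tanh", "relu")) {
    params <- lstm_init_params(3, 5, act, seed = 42)
    set.seed(43)
    x_seq <- list(matrix(rnorm(20), 5, 4), matrix(rnorm(20), 5, 4))
    y <- rnorm(4)
    lg <- lstm_loss_grad(params, x_seq, y, act)
    eps <- 1e-6
    for (nm in names(params)) {
      P <- params[[nm]]
      for (j in seq_along(P)) {
        pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
        fd <- (lstm_loss_grad(pp, x_seq, y, act)$loss -
                 lstm_loss_grad(pm, x_seq, y, act)$loss) / (2 * eps)
        an <- lg$grads[[nm]][j]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-5)
      }
    }
  }
})

test_that("the lstm1-lstm6 grid crosses {relu, tanh} x {10%, 50%, 100%}", {
  p <- lstm_presets()
  expect_named(p, paste0("lstm", 1:6))
  grid <- t(vapply(p, function(cfg)
    c(cfg$state_activation, as.character(cfg$minibatch_fraction)),
    character(2)))
  expect_equal(unname(grid[, 1]),
               c("relu", "tanh", "relu", "tanh", "relu", "tanh"))
  expect_equal(unname(grid[, 2]),
               c("0.1", "0.1", "0.5", "0.5", "1", "1"))
})

test_that("training is bitwise seed-reproducible and counts update steps by batch size", {
  G <- small_panel(40, 30, seed = 102)
  y <- rnorm(40)
  cfg <- lstm_config(hidden_units = 4, chunk_size = 10, epochs = 3, seed = 9)
  n1 <- train_lstm(G$dosage, y, cfg)
  n2 <- train_lstm(G$dosage, y, cfg)
  expect_identical(n1$loss_trace, n2$loss_trace)
  expect_identical(n1$params, n2$params)

  # fewer update steps as the mini-batch fraction grows (fixed epochs)
  steps <- vapply(c(0.1, 0.5, 1.0), function(f) {
    cfgf <- lstm_config(hidden_units = 4, chunk_size = 10, epochs = 3,
                        minibatch_fraction = f, seed = 9)
    train_lstm(G$dosage, y, cfgf)$n_updates
  }, numeric(1))
  expect_true(all(diff(steps) < 0))
  expect_equal(steps[3], 3)  # full batch: one update per epoch
})

test_that("training fits a noiseless linear trait well below the variance floor", {
  G <- simulate_genotypes(300, 200, seed = 103)
  st <- simulate_trait(G, n_qtl = 5, h2a = 1, h2d = 0, seed = 104)
  net <- train_lstm(G$dosage, st$phenotypes$value,
                    lstm_config(hidden_units = 8, chunk_size = 50,
                                epochs = 60, state_activation = "relu",
                                minibatch_fraction = 0.1, seed = 1))
  mse <- mean((predict_lstm(net, G$dosage) - st$phenotypes$value)^2)
  expect_lt(mse, 0.1 * var(st$phenotypes$value))
})

test_that("prediction contract: duplicates, zero nets, marker checks, batch-free inference", {
  G <- small_panel(30, 25, seed = 105)
  y <- rnorm(30)
  net <- train_lstm(G$dosage, y,
                    lstm_config(hidden_units = 3, chunk_size = 10,
                                epochs = 2, seed = 2))
  Xd <- G$dosage[c(4, 4, 9), ]
  pred <- predict_lstm(net, Xd)
  expect_equal(pred[1], pred[2])
  expect_error(predict_lstm(net, G$dosage[, 1:10]), "markers")

  # inference ignores the mini-batch fraction
  net2 <- net
  net2$config$minibatch_fraction <- 0.1
  expect_identical(predict_lstm(net2, G$dosage), predict_lstm(net, G$dosage))

  # all-zero parameters predict the (rescaled) output bias everywhere
  net0 <- net
  net0$params <- zero_params(net$config$hidden_units, net$config$chunk_size)
  expect_equal(unname(predict_lstm(net0, G$dosage)),
               rep(net$y_center, 30))
})

test_that("the relu variant starts from an identity cell-candidate recurrence", {
  p <- lstm_init_params(5, 8, "relu", seed = 3)
  H <- 5
  expect_equal(p$R[2 * H + seq_len(H), ], diag(H))
  expect_equal(p$b, numeric(4 * H))
  pt <- lstm_init_params(5, 8, "tanh", seed = 3)
  expect_equal(pt$b[H + seq_len(H)], rep(1, H))  # forget-gate bias
})
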