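#' Configuration for LSTM regression on SNP dosages
#'
#' Each sample's SNP vector (genome order) is chunked into a sequence of
#' `ceiling(p / chunk_size)` steps of `chunk_size` features (the last chunk
#' zero-padded), fed through a single LSTM layer, and the final hidden state
#' feeds a linear regression head. Training minimizes mean squared error by
#' mini-batch gradient descent (momentum SGD by default, Adam optional)
#' with gradient-norm clipping; mini-batches of size
#' `ceiling(minibatch_fraction * n_train)` are resampled every epoch.
#'
#' The ReLU state-activation variant replaces tanh in both the cell
#' candidate and the cell-output transform, and initializes the recurrent
#' block of the cell-candidate gate to the identity matrix with zero biases
#' (the IRNN-style strategy); all other weights use Glorot initialization.
#'
#' @param hidden_units LSTM hidden size (default 32).
#' @param state_activation `"tanh"` (default) or `"relu"`.
#' @param minibatch_fraction fraction of the training set per gradient
#'   update, in (0, 1\].
#' @param chunk_size SNPs per sequence step (default 100; `chunk_size = p`
#'   gives a degenerate single-step network).
#' @param epochs training epochs (default 100).
#' @param optimizer `"sgdm"` (stochastic gradient descent with momentum
#'   0.9, the default) or `"adam"`. In the p >> n regime Adam's
#'   per-coordinate step normalization fits sample-specific noise as fast
#'   as shared signal and validation accuracy collapses; plain momentum
#'   SGD from a near-linear initialization follows a ridge-like path that
#'   generalizes.
#' @param learning_rate step size (default 0.01 for sgdm, use ~0.005 for
#'   adam).
#' @param weight_decay decoupled (AdamW-style) L2 weight decay applied to
#'   all weights except biases (default 1e-4, the usual toolbox default);
#'   with p >> n some decay is what keeps the network from interpolating
#'   the training set.
#' @param grad_clip global gradient-norm clip (default 1).
#' @param init_scale multiplier on the Glorot input-weight initialization
#'   (default 0.01). Small input weights start the network in its
#'   near-linear regime (gates at 1/2), so gradient descent fits the
#'   genome-wide linear signal before the nonlinear memorization capacity
#'   kicks in.
#' @param momentum momentum coefficient for sgdm (default 0.9).
#' @param seed RNG seed; fixed seed gives a bitwise-identical loss trace.
#' @return An `LstmConfig` list.
#' @export
lstm_config <- function(hidden_units = 32L,
                        state_activation = c("tanh", "relu"),
                        minibatch_fraction = 1.0, chunk_size = 100L,
                        epochs = 100L, optimizer = c("sgdm", "adam"),
                        learning_rate = 0.01, weight_decay = 1e-4,
                        grad_clip = 1.0, init_scale = 0.01,
                        momentum = 0.9, seed = 1L) {
  state_activation <- match.arg(state_activation)
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_units >= 1, chunk_size >= 1,
            minibatch_fraction > 0, minibatch_fraction <= 1,
            epochs >= 1, learning_rate > 0)
  structure(
    list(name = "custom", hidden_units = as.integer(hidden_units),
         state_activation = state_activation,
         minibatch_fraction = minibatch_fraction,
         chunk_size = as.integer(chunk_size), epochs = as.integer(epochs),
         optimizer = optimizer, learning_rate = learning_rate,
         weight_decay = weight_decay, grad_clip = grad_clip,
         init_scale = init_scale, momentum = momentum,
         seed = as.integer(seed)),
    class = "LstmConfig")
}

#' The six named LSTM architectures
#'
#' The grid crosses the state activation (ReLU for lstm1/lstm3/lstm5, Tanh
#' for lstm2/lstm4/lstm6) with the mini-batch fraction (10% for
#' lstm1/lstm2, 50% for lstm3/lstm4, 100% for lstm5/lstm6).
#'
#' @param ... overrides passed to [lstm_config()] for every preset (e.g.
#'   `epochs`, `hidden_units`, `chunk_size`).
#' @return Named list of `LstmConfig`s.
#' @export
lstm_presets <- function(...) {
  grid <- list(
    lstm1 = list(state_activation = "relu", minibatch_fraction = 0.1),
    lstm2 = list(state_activation = "tanh", minibatch_fraction = 0.1),
    lstm3 = list(state_activation = "relu", minibatch_fraction = 0.5),
    lstm4 = list(state_activation = "tanh", minibatch_fraction = 0.5),
    lstm5 = list(state_activation = "relu", minibatch_fraction = 1.0),
    lstm6 = list(state_activation = "tanh", minibatch_fraction = 1.0))
  out <- lapply(names(grid), function(nm) {
    cfg <- do.call(lstm_config, c(grid[[nm]], list(...)))
    cfg$name <- nm
    cfg
  })
  stats::setNames(out, names(grid))
}

.state_act <- function(kind, x) if (kind == "relu") pmax(x, 0) else tanh(x)
# derivative expressed through the activation value
.state_act_deriv_from_value <- function(kind, a)
  if (kind == "relu") (a > 0) * 1 else 1 - a^2
# derivative at the pre-activation (needed for act(C_t))
.state_act_deriv_at <- function(kind, x)
  if (kind == "relu") (x > 0) * 1 else 1 - tanh(x)^2

#' Initialize LSTM parameters
#'
#' `W` (input weights), `R` (recurrent weights) and `b` (biases) are each
#' the row-concatenation over the four components (input gate i, forget
#' gate f, cell candidate g, output gate o): `W` is `4H x C`, `R` is
#' `4H x H`, `b` has length `4H`, plus a scalar linear head (`w_out`,
#' `b_out`).
#'
#' @param hidden_units hidden size H.
#' @param input_size per-step feature count C.
#' @param state_activation `"tanh"` or `"relu"`; the ReLU variant sets the
#'   cell-candidate recurrent block to the identity and all biases to zero.
#' @param seed RNG seed.
#' @return An `LstmParameters` list with elements `W`, `R`, `b`, `w_out`,
#'   `b_out`.
#' @export
lstm_init_params <- function(hidden_units, input_size,
                             state_activation = "tanh", seed = 1L) {
  set.seed(seed)
  H <- hidden_units; C <- input_size
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  W <- glorot(4 * H, C)
  R <- glorot(4 * H, H)
  b <- numeric(4 * H)
  # unit forget-gate bias so early sequence steps (= upstream chromosome
  # chunks) are not forgotten before the final state is read out
  b[H + seq_len(H)] <- 1
  if (state_activation == "relu") {
    # identity recurrent initialization for the cell-candidate block;
    # biases stay zero in this variant
    R[2 * H + seq_len(H), ] <- diag(H)
    b[] <- 0
  }
  structure(list(W = W, R = R, b = b,
                 w_out = glorot(1, H), b_out = 0),
            class = "LstmParameters")
}

# row index helpers into the 4H-stacked gate order (i, f, g, o)
.gate_rows <- function(H) list(i = seq_len(H), f = H + seq_len(H),
                               g = 2 * H + seq_len(H), o = 3 * H + seq_len(H))

#' One LSTM cell step
#'
#' Gate pre-activations are `z = W x_t + R h_prev + b`; the input, forget
#' and output gates pass through the logistic sigmoid, the cell candidate
#' through the state activation; then `C_t = f * C_prev + i * g` and
#' `h_t = o * act(C_t)`.
#'
#' @param params an `LstmParameters` (see [lstm_init_params()]).
#' @param x_t step input: length-C vector or C x B matrix.
#' @param h_prev,C_prev previous hidden/cell state: length-H or H x B.
#' @param state_activation `"tanh"` or `"relu"`.
#' @return List with `h`, `C` and the gate values `i`, `f`, `g`, `o`.
#' @export
lstm_cell_step <- function(params, x_t, h_prev, C_prev,
                           state_activation = "tanh") {
  H <- length(params$b) / 4
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev); C_prev <- as.matrix(C_prev)
  if (nrow(x_t) != ncol(params$W) || nrow(h_prev) != H || nrow(C_prev) != H)
    stop("dimension mismatch in lstm_cell_step")
  z <- params$W %*% x_t + params$R %*% h_prev + params$b
  g_rows <- .gate_rows(H)
  i <- 1 / (1 + exp(-z[g_rows$i, , drop = FALSE]))
  f <- 1 / (1 + exp(-z[g_rows$f, , drop = FALSE]))
  g <- .state_act(state_activation, z[g_rows$g, , drop = FALSE])
  o <- 1 / (1 + exp(-z[g_rows$o, , drop = FALSE]))
  C <- f * C_prev + i * g
  h <- o * .state_act(state_activation, C)
  list(h = h, C = C, i = i, f = f, g = g, o = o)
}

# chunk an n x p matrix into a list of T matrices (C x n), zero-padded
.lstm_chunk <- function(X, chunk_size) {
  n <- nrow(X); p <- ncol(X)
  T_steps <- ceiling(p / chunk_size)
  lapply(seq_len(T_steps), function(t) {
    cols <- ((t - 1) * chunk_size + 1):min(t * chunk_size, p)
    out <- matrix(0, chunk_size, n)
    out[seq_along(cols), ] <- t(X[, cols, drop = FALSE])
    out
  })
}

#' Loss and analytic gradients of the LSTM regression network
#'
#' Full forward pass and backpropagation through time for the mean
#' squared error of the linear head on the final hidden state. Exposed so
#' the gradients can be verified against finite differences.
#'
#' @param params an `LstmParameters`.
#' @param x_seq list of T step-input matrices, each C x B.
#' @param y numeric targets, length B.
#' @param state_activation `"tanh"` or `"relu"`.
#' @return List with `loss` and `grads` (same shapes as `params`).
#' @export
lstm_loss_grad <- function(params, x_seq, y, state_activation = "tanh") {
  H <- length(params$b) / 4
  B <- ncol(x_seq[[1]])
  T_steps <- length(x_seq)
  gr <- .gate_rows(H)

  h <- matrix(0, H, B); C <- matrix(0, H, B)
  cache <- vector("list", T_steps)
  for (t in seq_len(T_steps)) {
    st <- lstm_cell_step(params, x_seq[[t]], h, C, state_activation)
    cache[[t]] <- c(st, list(h_prev = h, C_prev = C))
    h <- st$h; C <- st$C
  }
  yhat <- drop(params$w_out %*% h) + params$b_out
  r <- yhat - y
  loss <- mean(r^2)

  dW <- params$W * 0; dR <- params$R * 0; db <- params$b * 0
  dyhat <- matrix(2 * r / B, 1, B)
  dw_out <- dyhat %*% t(h)
  db_out <- sum(dyhat)
  dh <- crossprod(params$w_out, dyhat)
  dC <- matrix(0, H, B)
  for (t in rev(seq_len(T_steps))) {
    st <- cache[[t]]
    aC <- .state_act(state_activation, st$C)
    d_o <- dh * aC
    dC <- dC + dh * st$o * .state_act_deriv_at(state_activation, st$C)
    d_i <- dC * st$g
    d_g <- dC * st$i
    d_f <- dC * st$C_prev
    dC_prev <- dC * st$f
    dz <- rbind(d_i * st$i * (1 - st$i),
                d_f * st$f * (1 - st$f),
                d_g * .state_act_deriv_from_value(state_activation, st$g),
                d_o * st$o * (1 - st$o))
    dW <- dW + tcrossprod(dz, x_seq[[t]])
    dR <- dR + tcrossprod(dz, st$h_prev)
    db <- db + rowSums(dz)
    dh <- crossprod(params$R, dz)
    dC <- dC_prev
  }
  list(loss = loss,
       grads = list(W = dW, R = dR, b = db, w_out = dw_out, b_out = db_out))
}

#' Train an LSTM regression network on SNP dosages
#'
#' @param X n x p dosage matrix (columns in genome order).
#' @param y numeric targets, length n.
#' @param cfg an [lstm_config()].
#' @return An `LstmNetwork`: `params`, `config`, scaling constants, the
#'   per-update `loss_trace`, and `n_updates` (total gradient steps).
#' @export
train_lstm <- function(X, y, cfg = lstm_config()) {
  stopifnot(inherits(cfg, "LstmConfig"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd); x_scale[x_scale < 1e-12] <- 1
  Xs <- t((t(X) - x_center) / x_scale)
  y_center <- mean(y)
  y_scale <- stats::sd(y); if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  x_seq <- .lstm_chunk(Xs, cfg$chunk_size)
  C_in <- cfg$chunk_size
  params <- lstm_init_params(cfg$hidden_units, C_in, cfg$state_activation,
                             cfg$seed)
  params$W <- params$W * cfg$init_scale

  # Adam state
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  batch_size <- ceiling(cfg$minibatch_fraction * n)
  loss_trace <- numeric(0)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    n_batches <- ceiling(n / batch_size)
    for (bidx in seq_len(n_batches)) {
      sel <- ord[(((bidx - 1) * batch_size + 1):min(bidx * batch_size, n))]
      xb <- lapply(x_seq, function(m) m[, sel, drop = FALSE])
      lg <- lstm_loss_grad(params, xb, ys[sel], cfg$state_activation)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d (exploding gradients)",
                     epoch))
      g <- lg$grads
      gnorm <- sqrt(sum(vapply(g, function(m) sum(m^2), numeric(1))))
      if (is.finite(gnorm) && gnorm > cfg$grad_clip)
        g <- lapply(g, function(m) m * (cfg$grad_clip / gnorm))
      step <- step + 1L
      for (nm in names(params)) {
        wd <- if (nm %in% c("b", "b_out")) 0 else cfg$weight_decay
        if (cfg$optimizer == "adam") {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * (mhat / (sqrt(vhat) + eps) + wd * params[[nm]])
        } else {
          mom[[nm]] <- cfg$momentum * mom[[nm]] -
            cfg$learning_rate * (g[[nm]] + wd * params[[nm]])
          params[[nm]] <- params[[nm]] + mom[[nm]]
        }
      }
      loss_trace <- c(loss_trace, lg$loss)
    }
  }

  structure(
    list(params = params, config = cfg,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         loss_trace = loss_trace, n_updates = step, p = ncol(X)),
    class = "LstmNetwork")
}

#' @export
print.LstmNetwork <- function(x, ...) {
  cat(sprintf(
    "LstmNetwork [%s]: H=%d, %s, mini-batch %.0f%%, %d updates, loss %.4g\n",
    x$config$name, x$config$hidden_units, x$config$state_activation,
    100 * x$config$minibatch_fraction, x$n_updates,
    utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict from a trained LSTM network
#'
#' Deterministic forward pass with the training scaling and chunking; the
#' mini-batch fraction plays no role at inference.
#'
#' @param net an `LstmNetwork` from [train_lstm()].
#' @param X_new matrix with the training marker count.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict_lstm <- function(net, X_new) {
  stopifnot(inherits(net, "LstmNetwork"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != net$p)
    stop(sprintf("X_new has %d markers; the network was trained on %d",
                 ncol(X_new), net$p))
  Xs <- t((t(X_new) - net$x_center) / net$x_scale)
  x_seq <- .lstm_chunk(Xs, net$config$chunk_size)
  H <- net$config$hidden_units
  B <- nrow(X_new)
  h <- matrix(0, H, B); C <- matrix(0, H, B)
  for (t in seq_along(x_seq)) {
    st <- lstm_cell_step(net$params, x_seq[[t]], h, C,
                         net$config$state_activation)
    h <- st$h; C <- st$C
  }
  yhat_s <- drop(net$params$w_out %*% h) + net$params$b_out
  yhat_s * net$y_scale + net$y_center
}

#' @export
predict.LstmNetwork <- function(object, newdata, ...) predict_lstm(object, newdata)
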