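#' Activation functions for Bayesian-regularized networks
#'
#' `purelin(x) = x`; `logsig(x) = 1 / (1 + exp(-x))`;
#' `tansig(x) = 2 / (1 + exp(-2x)) - 1`. All saturate rather than overflow.
#'
#' @param kind one of `"purelin"`, `"logsig"`, `"tansig"`.
#' @param x numeric input (vector or matrix).
#' @return The activation evaluated elementwise.
#' @export
activation_eval <- function(kind = c("purelin", "logsig", "tansig"), x) {
  kind <- match.arg(kind)
  switch(kind,
         purelin = x,
         logsig = 1 / (1 + exp(-x)),
         tansig = 2 / (1 + exp(-2 * x)) - 1)
}

# derivative in terms of the activation value a = act(z)
.activation_deriv <- function(kind, a) {
  switch(kind,
         purelin = array(1, dim = dim(a) %||% length(a)),
         logsig = a * (1 - a),
         tansig = 1 - a^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for a Bayesian-regularized feed-forward network
#'
#' The architecture is a list of hidden layers, each `(neurons, activation)`,
#' followed by an implicit single linear output unit. Training minimizes
#' `F(w) = beta * E_D + alpha * E_W` (`E_D` the residual sum of squares,
#' `E_W` the sum of squared weights) by Levenberg-Marquardt, with the
#' regularization pair `(alpha, beta)` re-estimated after every accepted
#' step from the evidence framework's effective parameter count.
#'
#' @param architecture list of `list(neurons =, activation =)` hidden
#'   layers, or a preset name `"brnn1"` ... `"brnn10"` (see
#'   [brnn_presets()]).
#' @param alpha,beta initial regularization parameters (weight penalty /
#'   data misfit weight).
#' @param max_epochs maximum accepted LM steps (default 1000).
#' @param lm_damping initial LM damping `mu` (default 0.005).
#' @param seed RNG seed for the Nguyen-Widrow-style initialization.
#' @param input_scaling z-score the input columns internally (default TRUE).
#' @param max_weights cap on the total weight count `k`; exact LM is
#'   quadratic in `k`, so larger problems must reduce `p` or use a marker
#'   subset.
#' @return A `BrnnConfig` list.
#' @export
brnn_config <- function(architecture = "brnn1", alpha = 0.01, beta = 1,
                        max_epochs = 1000L, lm_damping = 0.005, seed = 1L,
                        input_scaling = TRUE, max_weights = 20000L) {
  if (is.character(architecture)) {
    presets <- brnn_presets()
    if (!architecture %in% names(presets))
      stop("unknown BRNN preset '", architecture, "'")
    name <- architecture
    architecture <- presets[[architecture]]
  } else name <- "custom"
  stopifnot(length(architecture) >= 1, alpha > 0, beta > 0)
  for (layer in architecture)
    stopifnot(layer$neurons >= 1,
              layer$activation %in% c("purelin", "logsig", "tansig"))
  structure(
    list(name = name, architecture = architecture, alpha = alpha,
         beta = beta, max_epochs = as.integer(max_epochs),
         lm_damping = lm_damping, seed = as.integer(seed),
         input_scaling = input_scaling, max_weights = as.integer(max_weights)),
    class = "BrnnConfig")
}

#' The ten named BRNN architectures
#'
#' brnn1-brnn3: one layer of one neuron with purelin / logsig / tansig.
#' brnn4-brnn8: two layers of two and one neurons; brnn4-brnn6 repeat
#' purelin / logsig / tansig in both layers, brnn7 uses tansig then purelin,
#' brnn8 logsig then purelin. brnn9-brnn10: three layers of 2, 2, 1 neurons
#' combining all three activations (brnn9: tansig, logsig, purelin; brnn10:
#' logsig, tansig, purelin). Every network ends in a single linear output
#' unit.
#'
#' @return Named list of architectures (lists of `neurons`/`activation`).
#' @export
brnn_presets <- function() {
  L <- function(n, a) list(neurons = n, activation = a)
  list(
    brnn1 = list(L(1, "purelin")),
    brnn2 = list(L(1, "logsig")),
    brnn3 = list(L(1, "tansig")),
    brnn4 = list(L(2, "purelin"), L(1, "purelin")),
    brnn5 = list(L(2, "logsig"), L(1, "logsig")),
    brnn6 = list(L(2, "tansig"), L(1, "tansig")),
    brnn7 = list(L(2, "tansig"), L(1, "purelin")),
    brnn8 = list(L(2, "logsig"), L(1, "purelin")),
    brnn9 = list(L(2, "tansig"), L(2, "logsig"), L(1, "purelin")),
    brnn10 = list(L(2, "logsig"), L(2, "tansig"), L(1, "purelin")))
}

# ---- internal weight bookkeeping -------------------------------------------

# layer sizes: input p -> hidden units... -> 1 linear output
.brnn_shapes <- function(p, architecture) {
  sizes <- c(p, vapply(architecture, function(l) l$neurons, numeric(1)), 1)
  acts <- c(vapply(architecture, function(l) l$activation, character(1)),
            "purelin")
  list(sizes = sizes, acts = acts, n_layers = length(acts))
}

.brnn_unpack <- function(w, shapes) {
  Ws <- vector("list", shapes$n_layers)
  bs <- vector("list", shapes$n_layers)
  off <- 0
  for (l in seq_len(shapes$n_layers)) {
    nin <- shapes$sizes[l]; nout <- shapes$sizes[l + 1]
    Ws[[l]] <- matrix(w[off + seq_len(nin * nout)], nout, nin)
    off <- off + nin * nout
    bs[[l]] <- w[off + seq_len(nout)]
    off <- off + nout
  }
  list(W = Ws, b = bs)
}

.brnn_forward <- function(w, shapes, X) {
  # X: p x n. Returns activations per layer (incl. input) and output vector.
  pw <- .brnn_unpack(w, shapes)
  A <- vector("list", shapes$n_layers + 1)
  A[[1]] <- X
  for (l in seq_len(shapes$n_layers)) {
    Z <- pw$W[[l]] %*% A[[l]] + pw$b[[l]]
    A[[l + 1]] <- activation_eval(shapes$acts[l], Z)
  }
  list(A = A, yhat = drop(A[[shapes$n_layers + 1]]), pw = pw)
}

# Jacobian of the network output w.r.t. every weight: n x k
.brnn_jacobian <- function(fw, shapes) {
  n <- ncol(fw$A[[1]])
  L <- shapes$n_layers
  deltas <- vector("list", L)
  deltas[[L]] <- .activation_deriv(shapes$acts[L], fw$A[[L + 1]])
  for (l in rev(seq_len(L - 1))) {
    deltas[[l]] <- crossprod(fw$pw$W[[l + 1]], deltas[[l + 1]]) *
      .activation_deriv(shapes$acts[l], fw$A[[l + 1]])
  }
  blocks <- vector("list", 2 * L)
  for (l in seq_len(L)) {
    nout <- shapes$sizes[l + 1]; nin <- shapes$sizes[l]
    D <- t(deltas[[l]])                 # n x nout
    Ain <- t(fw$A[[l]])                 # n x nin
    # column (r + (c-1)*nout) corresponds to W[r, c]
    blocks[[2 * l - 1]] <- D[, rep(seq_len(nout), times = nin), drop = FALSE] *
      Ain[, rep(seq_len(nin), each = nout), drop = FALSE]
    blocks[[2 * l]] <- D
  }
  do.call(cbind, blocks)
}

# Nguyen-Widrow-style seeded initialization
.brnn_init <- function(shapes, seed) {
  set.seed(seed)
  w <- numeric(0)
  for (l in seq_len(shapes$n_layers)) {
    nin <- shapes$sizes[l]; nout <- shapes$sizes[l + 1]
    Wl <- matrix(stats::runif(nout * nin, -0.5, 0.5), nout, nin)
    nw <- 0.7 * nout^(1 / nin)
    rn <- sqrt(rowSums(Wl^2))
    Wl <- Wl * nw / pmax(rn, 1e-12)
    bl <- if (nout > 1) nw * seq(-1, 1, length.out = nout) * sign(Wl[, 1])
          else stats::runif(1, -0.5, 0.5)
    w <- c(w, as.vector(Wl), bl)
  }
  w
}

#' Train a Bayesian-regularized feed-forward network
#'
#' Levenberg-Marquardt on the Gauss-Newton approximation of
#' `F(w) = beta * E_D + alpha * E_W`, with MacKay evidence updates after
#' each accepted step: `gamma = k - 2 * alpha * tr(H^{-1})` (the effective
#' number of parameters, always in `[0, k]` since
#' `H = 2 beta J'J + 2 alpha I` has eigenvalues `>= 2 alpha`), then
#' `alpha <- gamma / (2 E_W)` and `beta <- (n - gamma) / (2 E_D)`.
#' Inputs are z-scored and targets standardized internally; predictions are
#' returned on the original scale.
#'
#' @param X n x p numeric matrix of predictors (e.g. SNP dosages).
#' @param y numeric targets, length n (n >= 10).
#' @param cfg a [brnn_config()].
#' @return A `BrnnNetwork`: flattened `weights`, `shapes`, `config`,
#'   scaling constants and a per-epoch `trace` (objective before/after the
#'   accepted step, `E_D`, `E_W`, `alpha`, `beta`, `gamma`).
#' @export
train_brnn <- function(X, y, cfg = brnn_config()) {
  stopifnot(inherits(cfg, "BrnnConfig"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 10)

  x_center <- if (cfg$input_scaling) colMeans(X) else rep(0, ncol(X))
  x_scale <- if (cfg$input_scaling) {
    s <- apply(X, 2, stats::sd); s[s < 1e-12] <- 1; s
  } else rep(1, ncol(X))
  Xs <- t((t(X) - x_center) / x_scale)      # keep n x p, then transpose
  y_center <- mean(y)
  y_scale <- stats::sd(y); if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  shapes <- .brnn_shapes(ncol(X), cfg$architecture)
  k <- sum(shapes$sizes[-length(shapes$sizes)] * shapes$sizes[-1] +
             shapes$sizes[-1])
  if (k > cfg$max_weights)
    stop(sprintf(paste0("network has %d weights (cap %d): exact ",
                        "Levenberg-Marquardt is quadratic in the weight ",
                        "count; reduce p or use a marker subset"),
                 k, cfg$max_weights))

  w <- .brnn_init(shapes, cfg$seed)
  alpha <- cfg$alpha; beta <- cfg$beta
  mu <- cfg$lm_damping
  Xt <- t(Xs)                               # p x n

  objective <- function(w, alpha, beta) {
    fw <- .brnn_forward(w, shapes, Xt)
    r <- ys - fw$yhat
    E_D <- sum(r^2); E_W <- sum(w^2)
    list(F = beta * E_D + alpha * E_W, E_D = E_D, E_W = E_W, r = r, fw = fw)
  }

  st <- objective(w, alpha, beta)
  if (!is.finite(st$F)) stop("non-finite objective at initialization")
  warmup <- min(10L, max(2L, cfg$max_epochs %/% 10L))
  trace <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    J <- .brnn_jacobian(st$fw, shapes)
    H <- 2 * beta * crossprod(J) + diag(2 * alpha, k)
    g <- -2 * beta * crossprod(J, st$r) + 2 * alpha * w
    F_before <- st$F
    accepted <- FALSE
    while (mu <= 1e10) {
      step <- tryCatch(drop(solve(H + diag(mu, k), -g)),
                       error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + step
        st_new <- objective(w_new, alpha, beta)
        # gain ratio: actual vs model-predicted decrease; rejects
        # no-progress jumps (e.g. to a weight-permutation mirror) that a
        # bare F comparison would accept
        pred_dec <- 0.5 * sum(step * (mu * step - g))
        rho <- (st$F - st_new$F) / max(pred_dec, 1e-300)
        if (is.finite(st_new$F) && st_new$F < st$F && rho > 1e-3) {
          w <- w_new; st <- st_new
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break
    # evidence update at the current Gauss-Newton Hessian; held back for a
    # short warm-up so a near-zero initial E_W cannot blow alpha up and
    # collapse the network before it has fit anything
    gamma <- k - 2 * alpha * sum(diag(solve(H)))
    if (epoch > warmup) {
      alpha <- max(gamma, 1e-8) / (2 * max(st$E_W, 1e-8))
      beta <- max(n - gamma, 1e-8) / (2 * max(st$E_D, 1e-12))
    }
    trace <- rbind(trace,
                   data.frame(epoch = epoch, objective_before = F_before,
                              objective_after = st$F, E_D = st$E_D,
                              E_W = st$E_W, alpha = alpha, beta = beta,
                              gamma = gamma))
    st <- objective(w, alpha, beta)  # re-evaluate F under the new (alpha, beta)
    if (sqrt(sum(g^2)) < 1e-10) break
  }
  if (!is.finite(st$F)) stop("non-finite objective during training")

  structure(
    list(weights = w, shapes = shapes, config = cfg,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         n_weights = k, trace = trace),
    class = "BrnnNetwork")
}

#' @export
print.BrnnNetwork <- function(x, ...) {
  cat(sprintf("BrnnNetwork [%s]: %d weights, %d epochs, gamma_eff %.2f/%d\n",
              x$config$name, x$n_weights,
              if (is.null(x$trace)) 0 else nrow(x$trace),
              if (is.null(x$trace)) NA_real_ else utils::tail(x$trace$gamma, 1),
              x$n_weights))
  invisible(x)
}

#' Predict from a trained Bayesian-regularized network
#'
#' Deterministic forward pass using the training scaling constants.
#'
#' @param net a `BrnnNetwork` from [train_brnn()].
#' @param X_new matrix with the training column count.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict_net <- function(net, X_new) {
  stopifnot(inherits(net, "BrnnNetwork"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(net$x_center))
    stop(sprintf("X_new has %d columns; the network was trained on %d",
                 ncol(X_new), length(net$x_center)))
  Xs <- (t(X_new) - net$x_center) / net$x_scale   # p x n
  fw <- .brnn_forward(net$weights, net$shapes, Xs)
  fw$yhat * net$y_scale + net$y_center
}

#' @export
predict.BrnnNetwork <- function(object, newdata, ...) predict_net(object, newdata)
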