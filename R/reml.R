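#' REML variance components on relationship/kernel matrices
#'
#' Fits the mixed model `y = 1*mu + sum_k g_k + e` with
#' `g_k ~ N(0, K_k * sigma2_k)` and `e ~ N(0, I * sigma2_e)` by restricted
#' maximum likelihood: expectation-maximization steps refined by
#' average-information (AI) updates. Components are constrained non-negative
#' (boundary at `1e-6 * var(y)`); standard errors come from the inverse AI
#' matrix at the optimum.
#'
#' @param y a `PhenotypeTable` or numeric vector (no missing values after
#'   alignment).
#' @param kernels one `RelationshipMatrix` or a list of one or two, aligned
#'   to (or alignable by sample id against) `y`.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the restricted log-likelihood change
#'   (default 1e-8).
#' @param method `"ai"` (EM warm-up then AI refinement, the default) or
#'   `"em"` (pure EM, monotone in the restricted likelihood).
#' @param init optional numeric vector of starting values, one per kernel
#'   plus the residual (last).
#' @return A `VarianceComponents` object: `sigma2` (named per-kernel, last
#'   element `sigma2_e`), convenience fields `sigma2_a`, `sigma2_d`,
#'   `sigma2_e`, `se`, the sampling covariance `cov` (inverse AI), `loglik`,
#'   the per-iteration `loglik_trace`, `n_used` and `converged`.
#' @export
fit_reml <- function(y, kernels, max_iter = 100L, tol = 1e-8,
                     method = c("ai", "em"), init = NULL) {
  method <- match.arg(method)
  if (inherits(kernels, "RelationshipMatrix")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1, length(kernels) <= 2)

  if (inherits(y, "PhenotypeTable")) {
    ok <- !is.na(y$value)
    ids <- y$sample_id[ok]
    yv <- y$value[ok]
    kernels <- lapply(kernels, function(K) {
      idx <- match(ids, K$sample_ids)
      if (anyNA(idx)) stop("kernel is missing phenotyped samples")
      .relmat(K$values[idx, idx, drop = FALSE], ids, K$kind, K$bandwidth_h)
    })
  } else {
    yv <- as.numeric(y)
    if (anyNA(yv)) stop("y contains missing values")
  }
  n <- length(yv)
  if (n < 30) stop("REML needs n >= 30 samples (got ", n, ")")
  Ks <- lapply(kernels, function(K) {
    stopifnot(nrow(K$values) == n)
    if (max(abs(K$values - diag(n))) < 1e-8)
      stop("kernel is (numerically) the identity: aliased with the residual")
    K$values
  })
  kinds <- vapply(kernels, function(K) K$kind, character(1))

  vy <- stats::var(yv)
  bound <- 1e-6 * vy
  m <- length(Ks)
  theta <- if (!is.null(init)) as.numeric(init) else rep(vy / (m + 1), m + 1)
  theta <- pmax(theta, bound)

  Klist <- c(Ks, list(diag(n)))
  X <- matrix(1, n, 1)

  eval_state <- function(theta) {
    V <- matrix(0, n, n)
    for (j in seq_len(m)) V <- V + theta[j] * Ks[[j]]
    diag(V) <- diag(V) + theta[m + 1]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      diag(V) <- diag(V) + 1e-8 * mean(diag(V))
      ch <- chol(V)
    }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    Py <- P %*% yv
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(yv * Py))
    list(P = P, Py = Py, loglik = as.numeric(ll))
  }

  st <- eval_state(theta)
  trace <- st$loglik
  converged <- FALSE
  AI <- NULL

  for (it in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    KPy <- lapply(Klist, function(K) K %*% Py)
    score <- numeric(m + 1)
    for (j in seq_len(m + 1))
      score[j] <- -0.5 * (sum(P * Klist[[j]]) - sum(Py * KPy[[j]]))
    AI <- matrix(0, m + 1, m + 1)
    for (j in seq_len(m + 1)) {
      PKPy_j <- P %*% KPy[[j]]
      for (k in j:(m + 1)) {
        AI[j, k] <- AI[k, j] <- 0.5 * sum(KPy[[k]] * PKPy_j)
      }
    }

    em_step <- function() {
      th <- theta
      for (j in seq_len(m + 1)) {
        tr_PK <- sum(P * Klist[[j]])
        th[j] <- theta[j] + (theta[j]^2 / n) * (sum(Py * KPy[[j]]) - tr_PK)
      }
      pmax(th, bound)
    }

    if (method == "em" || it <= 2) {
      theta_new <- em_step()
    } else {
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      theta_new <- if (is.null(step)) em_step() else pmax(theta + step, bound)
    }

    st_new <- eval_state(theta_new)
    if (method == "ai" && it > 2 && st_new$loglik < st$loglik - 1e-10) {
      # AI overshoot: fall back to the monotone EM step
      theta_new <- em_step()
      st_new <- eval_state(theta_new)
    }
    delta_ll <- st_new$loglik - st$loglik
    theta <- theta_new
    st <- st_new
    trace <- c(trace, st$loglik)
    if (abs(delta_ll) < tol && it > 2) { converged <- TRUE; break }
  }
  if (!converged && method == "ai") {
    cond <- structure(
      class = c("reml_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "REML did not converge in %d iterations (last loglik %.6g)",
             max_iter, st$loglik),
           call = sys.call(-1), iterate = theta, loglik = st$loglik))
    stop(cond)
  }

  covm <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, m + 1, m + 1))
  se <- sqrt(pmax(diag(covm), 0))
  nm <- c(vapply(kinds, function(k)
    switch(k, additive = "sigma2_a", dominance = "sigma2_d",
           gaussian = "sigma2_g", paste0("sigma2_", k)), character(1)),
    "sigma2_e")
  names(theta) <- nm; names(se) <- nm
  dimnames(covm) <- list(nm, nm)
  structure(
    list(sigma2 = theta,
         sigma2_a = unname(theta[nm == "sigma2_a"][1]),
         sigma2_d = if ("sigma2_d" %in% nm) unname(theta[["sigma2_d"]]) else NA_real_,
         sigma2_e = unname(theta[["sigma2_e"]]),
         se = se, cov = covm, loglik = st$loglik, loglik_trace = trace,
         n_used = n, converged = converged, kinds = kinds),
    class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("VarianceComponents (REML):\n")
  for (nm in names(x$sigma2))
    cat(sprintf("  %-10s %10.5f (se %.5f)\n", nm, x$sigma2[[nm]], x$se[[nm]]))
  cat(sprintf("  loglik %.4f, n = %d, converged: %s\n",
              x$loglik, x$n_used, x$converged))
  invisible(x)
}

#' Heritability ratios from variance components
#'
#' Narrow mode: `h2 = sigma2_a / (sigma2_a + sigma2_e)`. Broad mode (for an
#' additive + dominance fit): `H2 = (sigma2_a + sigma2_d) / (sigma2_a +
#' sigma2_d + sigma2_e)` with the additive and dominance ratios
#' `ha2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e)` and
#' `hd2 = sigma2_d / (sigma2_a + sigma2_d + sigma2_e)`, so `ha2 + hd2 = H2`
#' by construction. Standard errors by the delta method on the inverse-AI
#' covariance of the components.
#'
#' @param vc a `VarianceComponents` from [fit_reml()] (or a list with fields
#'   `sigma2_a`, `sigma2_d`, `sigma2_e`, optionally `cov`).
#' @param mode `"narrow"` or `"broad_with_ratios"`.
#' @return A data.frame with columns `ratio`, `estimate`, `se`.
#' @export
heritability_ratios <- function(vc, mode = c("narrow", "broad_with_ratios")) {
  mode <- match.arg(mode)
  sa <- vc$sigma2_a
  se2 <- vc$sigma2_e
  covm <- vc$cov
  delta_se <- function(grad, idx) {
    if (is.null(covm) || anyNA(covm)) return(NA_real_)
    C <- covm[idx, idx, drop = FALSE]
    sqrt(max(0, drop(t(grad) %*% C %*% grad)))
  }
  if (mode == "narrow") {
    if (is.na(sa) || is.na(se2)) stop("narrow mode needs sigma2_a and sigma2_e")
    tot <- sa + se2
    if (tot <= 0) stop("zero total variance")
    h2 <- sa / tot
    g <- c(se2, -sa) / tot^2
    idx <- match(c("sigma2_a", "sigma2_e"), rownames(covm))
    return(data.frame(ratio = "h2", estimate = h2, se = delta_se(g, idx)))
  }
  sd2 <- vc$sigma2_d
  if (is.na(sa) || is.na(sd2) || is.na(se2))
    stop("broad mode needs sigma2_a, sigma2_d and sigma2_e")
  tot <- sa + sd2 + se2
  if (tot <= 0) stop("zero total variance")
  idx <- match(c("sigma2_a", "sigma2_d", "sigma2_e"), rownames(covm))
  H2 <- (sa + sd2) / tot
  ha2 <- sa / tot
  hd2 <- sd2 / tot
  gH <- c(se2, se2, -(sa + sd2)) / tot^2
  ga <- c(sd2 + se2, -sa, -sa) / tot^2
  gd <- c(-sd2, sa + se2, -sd2) / tot^2
  data.frame(ratio = c("H2", "ha2", "hd2"),
             estimate = c(H2, ha2, hd2),
             se = c(delta_se(gH, idx), delta_se(ga, idx), delta_se(gd, idx)))
}
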