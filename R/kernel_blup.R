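#' Kernel BLUP: GBLUP and RKHS prediction of genetic values
#'
#' Solves the mixed model `y = 1*mu + sum_k g_k + e`,
#' `g_k ~ N(0, K_k sigma2_k)`, at plugged-in variance components: `mu` by
#' generalized least squares and each `g_k` by its BLUP
#' `sigma2_k K_k V^{-1} (y - mu)` with `V = sum_k sigma2_k K_k + sigma2_e I`
#' (equivalent to Henderson's equations without requiring `K^{-1}`). With the
#' VanRaden additive matrix this is GBLUP; with a Gaussian kernel it is RKHS
#' regression.
#'
#' @param y a `PhenotypeTable` or numeric vector.
#' @param kernels one `RelationshipMatrix` or list of one or two.
#' @param vc optional `VarianceComponents`; when absent, [fit_reml()] is run
#'   internally on the same kernels.
#' @param jitter diagonal jitter added to `V` if its Cholesky fails
#'   (default 1e-8 of the mean diagonal).
#' @return A `GeneticValues` object: `mu`, `values` (summed genetic values
#'   per sample), `components` (per-kernel BLUP matrix, samples x kernels),
#'   `vc_used`, and the training kernels/sample ids needed by
#'   [predict_blup()].
#' @export
fit_kernel_blup <- function(y, kernels, vc = NULL, jitter = 1e-8) {
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
    ids <- kernels[[1]]$sample_ids
  }
  n <- length(yv)
  if (is.null(vc)) vc <- fit_reml(yv, kernels)
  m <- length(kernels)
  sig <- vc$sigma2
  if (length(sig) != m + 1)
    stop("variance components do not match the number of kernels")

  V <- matrix(0, n, n)
  for (j in seq_len(m)) V <- V + sig[j] * kernels[[j]]$values
  diag(V) <- diag(V) + sig[m + 1]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    diag(V) <- diag(V) + jitter * mean(diag(V))
    ch <- tryCatch(chol(V), error = function(e)
      stop("coefficient matrix singular even after jitter"))
  }
  Vi <- chol2inv(ch)
  one <- rep(1, n)
  mu <- sum(Vi %*% yv) / sum(Vi)
  r <- Vi %*% (yv - mu)
  comp <- matrix(0, n, m)
  for (j in seq_len(m)) comp[, j] <- sig[j] * (kernels[[j]]$values %*% r)
  colnames(comp) <- vapply(kernels, function(K) K$kind, character(1))
  structure(
    list(mu = mu, values = rowSums(comp), components = comp,
         vc_used = vc, kernels = kernels, sample_ids = ids),
    class = "GeneticValues")
}

#' @export
print.GeneticValues <- function(x, ...) {
  cat(sprintf("GeneticValues: %d samples, mu = %.4f, kernels: %s\n",
              length(x$values), x$mu, paste(colnames(x$components),
                                            collapse = " + ")))
  invisible(x)
}

#' Predict genetic values for new samples by kernel interpolation
#'
#' `g_new = K_cross K_train^{-1} g_train` per kernel;
#' `y_hat = mu + sum_k g_new_k`. `K_cross` holds kernel values between new
#' (rows) and training (columns) samples, built from the same marker set and
#' training-derived constants (allele frequencies or distance
#' normalization).
#'
#' @param fit a `GeneticValues` from [fit_kernel_blup()].
#' @param K_cross one matrix (single-kernel fit) or a list of matrices in
#'   kernel order, each new x training.
#' @param jitter diagonal jitter for inverting the training kernel.
#' @return Numeric vector of predicted phenotypic values (`mu` + genetic).
#' @export
predict_blup <- function(fit, K_cross, jitter = 1e-8) {
  stopifnot(inherits(fit, "GeneticValues"))
  if (is.matrix(K_cross)) K_cross <- list(K_cross)
  m <- ncol(fit$components)
  if (length(K_cross) != m)
    stop("need one cross-kernel per fitted kernel (got ", length(K_cross),
         ", expected ", m, ")")
  n_tr <- length(fit$values)
  pred <- rep(fit$mu, nrow(K_cross[[1]]))
  for (j in seq_len(m)) {
    Kc <- K_cross[[j]]
    if (ncol(Kc) != n_tr)
      stop("cross-kernel columns must align with the training samples")
    Kt <- fit$kernels[[j]]$values
    Kt_j <- Kt + diag(jitter * max(mean(diag(Kt)), 1), n_tr)
    g_new <- Kc %*% solve(Kt_j, fit$components[, j])
    pred <- pred + drop(g_new)
  }
  pred
}
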