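#' Genomic relationship and kernel matrices
#'
#' Constructors for the three sample-similarity matrices used by the
#' prediction models: the VanRaden additive genomic relationship matrix, the
#' Su-style dominance relationship matrix built from heterozygosity
#' deviations, and the Gaussian kernel for RKHS regression.
#'
#' @name kinship
NULL

.relmat <- function(values, sample_ids, kind, bandwidth_h = NA_real_) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, kind = kind,
                 bandwidth_h = bandwidth_h),
            class = "RelationshipMatrix")
}

#' @export
print.RelationshipMatrix <- function(x, ...) {
  cat(sprintf("RelationshipMatrix (%s): %d x %d, mean diag %.3f\n",
              x$kind, nrow(x$values), ncol(x$values),
              mean(diag(x$values))))
  invisible(x)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' `A = W W' / (2 * sum p_i (1 - p_i))` with `W` the dosage matrix centered
#' by twice the allele frequency per marker. Monomorphic markers contribute
#' zero to both numerator and denominator.
#'
#' @param G a complete `GenotypeMatrix`.
#' @return A `RelationshipMatrix` of kind `"additive"`.
#' @export
additive_relationship <- function(G) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  if (anyNA(G$dosage)) stop("missing dosages; run filter_markers() first")
  p_i <- G$allele_freq
  denom <- 2 * sum(p_i * (1 - p_i))
  if (denom <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  W <- sweep(G$dosage, 2, 2 * p_i, "-")
  .relmat(tcrossprod(W) / denom, G$sample_ids, "additive")
}

#' Dominance genomic relationship matrix (heterozygosity deviations)
#'
#' `W_d` column i is the heterozygote indicator minus `2 p_i q_i`;
#' `D = W_d W_d' / sum (2 p_i q_i)(1 - 2 p_i q_i)`.
#'
#' @param G a complete `GenotypeMatrix`. Imputed (real-valued) dosages are
#'   treated as heterozygous only when exactly 1.
#' @return A `RelationshipMatrix` of kind `"dominance"`.
#' @export
dominance_relationship <- function(G) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  if (anyNA(G$dosage)) stop("missing dosages; run filter_markers() first")
  p_i <- G$allele_freq
  q_i <- 1 - p_i
  tpq <- 2 * p_i * q_i
  denom <- sum(tpq * (1 - tpq))
  if (denom <= 0)
    stop("zero dominance denominator: no expected heterozygosity in the panel")
  Wd <- sweep((G$dosage == 1) * 1, 2, tpq, "-")
  .relmat(tcrossprod(Wd) / denom, G$sample_ids, "dominance")
}

#' Gaussian kernel for RKHS regression
#'
#' `K_ij = exp(-h * d2_ij)` where `d2` is the squared Euclidean distance
#' between the dosage rows of samples i and j, normalized by its maximum
#' over all pairs so that `d2` ranges over \[0, 1\]. The diagonal is exactly
#' 1, and the maximally distant pair attains `exp(-h)`. The bandwidth `h`
#' controls the rate of similarity decay.
#'
#' @param G a complete `GenotypeMatrix` with at least 2 samples.
#' @param h positive bandwidth (default 0.5).
#' @return A `RelationshipMatrix` of kind `"gaussian"`, with the maximum
#'   unnormalized squared distance stored as attribute `"max_d2"` (used to
#'   normalize cross-kernels for held-out samples consistently).
#' @export
gaussian_kernel <- function(G, h = 0.5) {
  stopifnot(inherits(G, "GenotypeMatrix"), h > 0)
  X <- G$dosage
  if (anyNA(X)) stop("missing dosages; run filter_markers() first")
  if (nrow(X) < 2) stop("gaussian kernel needs at least 2 samples")
  d2 <- .pairwise_sqdist(X, X)
  m <- max(d2)
  if (m > 0) d2 <- d2 / m
  K <- exp(-h * d2)
  diag(K) <- 1
  out <- .relmat(K, G$sample_ids, "gaussian", bandwidth_h = h)
  attr(out, "max_d2") <- m
  out
}

# squared Euclidean distances between rows of X and rows of Y, clipped at 0
.pairwise_sqdist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

#' Gaussian cross-kernel between new and training samples
#'
#' Kernel values between held-out samples and the training set, using the
#' training kernel's bandwidth and distance normalization so held-out
#' predictions are on the same scale.
#'
#' @param K a `RelationshipMatrix` of kind `"gaussian"` from
#'   [gaussian_kernel()].
#' @param G_new `GenotypeMatrix` of new samples (same markers as training).
#' @param G_train the training `GenotypeMatrix`.
#' @return Matrix of kernel values, new samples x training samples.
#' @export
gaussian_cross_kernel <- function(K, G_new, G_train) {
  stopifnot(inherits(K, "RelationshipMatrix"), K$kind == "gaussian")
  if (!identical(G_new$marker_ids, G_train$marker_ids))
    stop("marker sets differ between new and training genotypes")
  d2 <- .pairwise_sqdist(G_new$dosage, G_train$dosage)
  m <- attr(K, "max_d2")
  if (m > 0) d2 <- d2 / m
  exp(-K$bandwidth_h * d2)
}

#' Write a relationship matrix as a delimited table with sample-id headers
#'
#' @param K a `RelationshipMatrix`.
#' @param path output path.
#' @export
write_relationship <- function(K, path) {
  df <- data.frame(sample_id = K$sample_ids, K$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
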