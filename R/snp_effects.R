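#' Back-solve per-SNP effects from predicted genetic values
#'
#' Recovers marker effects from any model's genetic values via
#' `u_hat = D Z' [Z D Z']^{-1} a_hat`, where `Z` is the marker design and
#' `D` a diagonal matrix of per-marker weights, re-estimated iteratively:
#' starting from `D = I`, each iteration computes `u_hat`, sets
#' `D*_{i} = u_hat_i^2 * 2 p_i (1 - p_i)`, and renormalizes `D` so its
#' trace stays equal to the marker count. Iterating sharpens the contrast
#' between large- and small-effect markers, which is what makes the
#' trajectory usable for QTL discovery.
#'
#' @param G a complete `GenotypeMatrix` on the same samples as `a_hat`.
#' @param a_hat per-sample genetic values (fitted genetic values of a
#'   Bayesian model, GBLUP/RKHS BLUPs, or network predictions); the mean is
#'   removed internally.
#' @param n_iterations number of weighted iterations (default 3).
#' @param ridge_jitter ridge added to `Z D Z'` before inversion; `NULL`
#'   (default) uses `1e-8 * mean(diag(Z D Z'))`, `0` disables it (exact
#'   interpolation).
#' @param center center `Z` by `2 p_i` per marker (default TRUE); the
#'   uncentered \{0,1,2\} coding is available with `center = FALSE`.
#' @return An `EffectTrajectory`: `marker_ids`, `u_by_iteration` (list of
#'   per-marker effect vectors), `D_diag_by_iteration` (the weights used at
#'   each iteration; iteration 1 is the identity), `a_hat`, `p_i`, `chrom`,
#'   `pos`, and `n_iterations_run` (can be fewer than requested if all
#'   effects collapse to zero).
#' @export
backsolve_effects <- function(G, a_hat, n_iterations = 3L,
                              ridge_jitter = NULL, center = TRUE) {
  stopifnot(inherits(G, "GenotypeMatrix"))
  if (anyNA(G$dosage)) stop("missing dosages; run filter_markers() first")
  a_hat <- as.numeric(a_hat)
  n <- nrow(G$dosage); p <- ncol(G$dosage)
  stopifnot(length(a_hat) == n, n >= 2)
  a <- a_hat - mean(a_hat)
  p_i <- G$allele_freq
  Z <- if (center) sweep(G$dosage, 2, 2 * p_i, "-") else G$dosage
  w2pq <- 2 * p_i * (1 - p_i)

  d_diag <- rep(1, p)                      # D_1 = identity
  u_list <- vector("list", n_iterations)
  d_list <- vector("list", n_iterations)
  ran <- 0L
  for (t in seq_len(n_iterations)) {
    ZD <- sweep(Z, 2, d_diag, "*")         # Z D
    M <- tcrossprod(ZD, Z)                 # Z D Z'
    jit <- if (is.null(ridge_jitter)) 1e-8 * mean(diag(M)) else ridge_jitter
    if (jit > 0) diag(M) <- diag(M) + jit
    # centered Z satisfies 1'Z = 0, so Z D Z' is rank-deficient by one even
    # in the generic case; a thresholded eigen pseudo-solve returns the
    # minimum-norm solution (a_hat is centered, hence orthogonal to the
    # null space and the system stays consistent)
    eg <- eigen(M, symmetric = TRUE)
    keep <- eg$values > 1e-12 * max(eg$values, 0)
    if (!any(keep))
      stop("Z D Z' numerically singular even with jitter (iteration ", t, ")")
    s <- eg$vectors[, keep, drop = FALSE] %*%
      (crossprod(eg$vectors[, keep, drop = FALSE], a) / eg$values[keep])
    u <- d_diag * drop(crossprod(Z, s))
    u_list[[t]] <- u
    d_list[[t]] <- d_diag
    ran <- t
    d_star <- u^2 * w2pq
    if (sum(d_star) <= 0) {
      warning("all back-solved effects zero at iteration ", t,
              "; stopping early")
      break
    }
    d_diag <- d_star * (p / sum(d_star))   # trace renormalization
  }
  structure(
    list(marker_ids = G$marker_ids,
         u_by_iteration = u_list[seq_len(ran)],
         D_diag_by_iteration = d_list[seq_len(ran)],
         a_hat = a, p_i = p_i, chrom = G$chrom, pos = G$pos,
         n_iterations_run = ran, centered = center),
    class = "EffectTrajectory")
}

#' @export
print.EffectTrajectory <- function(x, ...) {
  cat(sprintf("EffectTrajectory: %d markers, %d iterations\n",
              length(x$marker_ids), x$n_iterations_run))
  for (t in seq_len(x$n_iterations_run)) {
    u <- abs(x$u_by_iteration[[t]])
    cat(sprintf("  iter %d: max|u| = %.4g, median|u| = %.4g\n",
                t, max(u), stats::median(u)))
  }
  invisible(x)
}

#' Call QTL from a back-solved effect trajectory
#'
#' Markers whose absolute effect at the chosen iteration exceeds the
#' threshold, sorted by decreasing `|u|`. The threshold is trait-specific
#' and deliberately a required user choice.
#'
#' @param traj an `EffectTrajectory`.
#' @param threshold absolute-effect threshold.
#' @param iteration which iteration's effects to use (default 3, or the
#'   last one run if fewer).
#' @return data.frame with columns `marker_id`, `chrom`, `pos`, `effect`.
#' @export
call_qtl <- function(traj, threshold, iteration = 3L) {
  stopifnot(inherits(traj, "EffectTrajectory"))
  iteration <- min(iteration, traj$n_iterations_run)
  if (iteration < 1) stop("trajectory holds no iterations")
  u <- traj$u_by_iteration[[iteration]]
  hit <- which(abs(u) > threshold)
  hit <- hit[order(abs(u[hit]), decreasing = TRUE)]
  data.frame(marker_id = traj$marker_ids[hit],
             chrom = traj$chrom[hit], pos = traj$pos[hit],
             effect = u[hit], stringsAsFactors = FALSE)
}

#' Write an effect trajectory as a long-format table
#'
#' Columns: marker, iteration, effect, weight.
#'
#' @param traj an `EffectTrajectory`.
#' @param path output path.
#' @export
write_effect_trajectory <- function(traj, path) {
  rows <- do.call(rbind, lapply(seq_len(traj$n_iterations_run), function(t)
    data.frame(marker_id = traj$marker_ids, iteration = t,
               effect = traj$u_by_iteration[[t]],
               weight = traj$D_diag_by_iteration[[t]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write QTL calls as BED-like rows
#'
#' Columns: chrom, pos - 1, pos, marker, effect (0-based half-open).
#'
#' @param qtl data.frame from [call_qtl()].
#' @param path output path.
#' @export
write_qtl_bed <- function(qtl, path) {
  bed <- data.frame(chrom = qtl$chrom, start = qtl$pos - 1L, end = qtl$pos,
                    marker = qtl$marker_id, effect = qtl$effect)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
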