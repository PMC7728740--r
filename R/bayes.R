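#' Configuration for the Bayesian alphabet Gibbs samplers
#'
#' All five models share the linear model
#' `y_i = mu + sum_j A_ij a_j (+ D_ij d_j) + e_i` and differ only in the
#' prior on the marker effects: BRR a common Normal variance, BL a double
#' exponential (Laplace), Bayes A marker-specific scaled-inverse-chi^2
#' variances, Bayes B a point mass at zero with probability `pi0` plus
#' marker-specific variances, Bayes Cpi a point mass with common variance
#' and `pi` sampled under a uniform Beta prior.
#'
#' Hyperparameter defaults follow common practice: `df_a = df_e = 5`; when
#' `S_a`/`S_e` are `NULL` they are set at fit time so the prior *mode* of
#' the marker variance is `0.5 var(y) / sum(2 p_i q_i)` and of the residual
#' variance is `0.5 var(y)`. The desk-scale default chain is 30,000
#' iterations, 5,000 burn-in, thin 10; `chain_preset = "full"` switches to
#' the long-chain preset (1,000,000 / 100,000 / 50) used for production
#' analyses.
#'
#' @param model one of `"BRR"`, `"BL"`, `"BayesA"`, `"BayesB"`, `"BayesCpi"`.
#' @param n_iter,burn_in,thin chain settings (`burn_in < n_iter`, `thin >= 1`).
#' @param seed RNG seed; identical seeds give identical chains.
#' @param df_a,S_a prior degrees of freedom and scale for marker variances.
#' @param df_e,S_e prior for the residual variance.
#' @param pi0 prior proportion of null markers: fixed for Bayes B
#'   (default 0.95), initial value for Bayes Cpi (default 0.5).
#' @param lambda_shape,lambda_rate Gamma prior on the Bayesian LASSO
#'   regularization parameter lambda^2.
#' @param use_dominance also fit dominance effects on the \{0,1,0\} design.
#' @param fix_sigma2_a,fix_sigma2_e optional fixed values for the marker /
#'   residual variance (used for conjugate closed-form checks).
#' @param store_effect_samples keep the per-iteration marker-effect samples
#'   (memory: kept x p doubles).
#' @param chain_preset `"desk"` (default) or `"full"`.
#' @return A `GibbsConfig` list.
#' @export
gibbs_config <- function(model = c("BRR", "BL", "BayesA", "BayesB", "BayesCpi"),
                         n_iter = 30000L, burn_in = 5000L, thin = 10L,
                         seed = 1L, df_a = 5, S_a = NULL, df_e = 5,
                         S_e = NULL, pi0 = NULL,
                         lambda_shape = 1.1, lambda_rate = 1e-4,
                         use_dominance = FALSE,
                         fix_sigma2_a = NULL, fix_sigma2_e = NULL,
                         store_effect_samples = FALSE,
                         chain_preset = c("desk", "full")) {
  model <- match.arg(model)
  chain_preset <- match.arg(chain_preset)
  if (chain_preset == "full") {
    n_iter <- 1000000L; burn_in <- 100000L; thin <- 50L
  }
  stopifnot(burn_in < n_iter, thin >= 1, df_a > 0, df_e > 0)
  if (is.null(pi0)) pi0 <- if (model == "BayesB") 0.95 else 0.5
  stopifnot(pi0 >= 0, pi0 <= 1)
  structure(
    list(model = model, n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), df_a = df_a, S_a = S_a, df_e = df_e,
         S_e = S_e, pi0 = pi0, lambda_shape = lambda_shape,
         lambda_rate = lambda_rate, use_dominance = use_dominance,
         fix_sigma2_a = fix_sigma2_a, fix_sigma2_e = fix_sigma2_e,
         store_effect_samples = store_effect_samples),
    class = "GibbsConfig")
}

.model_code <- c(BRR = 0L, BL = 1L, BayesA = 2L, BayesB = 3L, BayesCpi = 4L)

#' Run a Bayesian alphabet Gibbs sampler
#'
#' Single-site Gibbs sampling with conjugate full conditionals: Normal for
#' the intercept and each marker effect, scaled-inverse-chi^2 for variances,
#' inverse-Gaussian mixing for the Bayesian LASSO, Bernoulli indicators for
#' Bayes B / Cpi and Beta for Cpi's `pi`. The additive design is centered by
#' `2 p_i` inside the sampler (the intercept absorbs the mean; predictions
#' are invariant). Posterior means are taken over the kept samples,
#' `floor((n_iter - burn_in) / thin)` in number.
#'
#' @param y a `PhenotypeTable` or numeric vector.
#' @param G a complete `GenotypeMatrix` (no missing dosages).
#' @param cfg a [gibbs_config()].
#' @return A `PosteriorSummary`: posterior means `mu`, `add_effects`,
#'   `dom_effects`, `marker_var`, `resid_var`, `pi`, `inclusion_prob`,
#'   `fitted_genetic_values` (design at posterior-mean effects),
#'   `n_samples_kept`, scalar chains in `chains`, and the training
#'   constants (`allele_freq`, `marker_ids`, dominance centering) used by
#'   [posterior_predict()].
#' @export
run_gibbs <- function(y, G, cfg) {
  stopifnot(inherits(cfg, "GibbsConfig"), inherits(G, "GenotypeMatrix"))
  if (inherits(y, "PhenotypeTable")) {
    al <- .align_gy(y, G)
    yv <- al$y$value
    G <- al$G
  } else {
    yv <- as.numeric(y)
    stopifnot(length(yv) == nrow(G$dosage))
  }
  if (anyNA(yv) || !all(is.finite(yv))) stop("non-finite phenotype values")
  if (ncol(G$dosage) == 0) stop("no markers (p = 0)")
  if (anyNA(G$dosage)) stop("missing dosages; run filter_markers() first")

  p_i <- G$allele_freq
  X <- sweep(G$dosage, 2, 2 * p_i, "-")
  vy <- stats::var(yv)
  sum2pq <- max(sum(2 * p_i * (1 - p_i)), .Machine$double.eps)
  S_a <- if (is.null(cfg$S_a)) (cfg$df_a + 2) / cfg$df_a * 0.5 * vy / sum2pq
         else cfg$S_a
  S_e <- if (is.null(cfg$S_e)) (cfg$df_e + 2) / cfg$df_e * 0.5 * vy
         else cfg$S_e

  if (cfg$use_dominance) {
    Xd <- (G$dosage == 1) * 1
    dom_center <- colMeans(Xd)
    Xd <- sweep(Xd, 2, dom_center, "-")
  } else {
    Xd <- matrix(0, length(yv), 0)
    dom_center <- numeric(0)
  }

  set.seed(cfg$seed)
  res <- .gibbs_cpp(yv, X, Xd, .model_code[[cfg$model]],
                    cfg$n_iter, cfg$burn_in, cfg$thin,
                    cfg$df_a, S_a, cfg$df_e, S_e, cfg$pi0,
                    cfg$lambda_shape, cfg$lambda_rate,
                    !is.null(cfg$fix_sigma2_a),
                    if (is.null(cfg$fix_sigma2_a)) 0 else cfg$fix_sigma2_a,
                    !is.null(cfg$fix_sigma2_e),
                    if (is.null(cfg$fix_sigma2_e)) 0 else cfg$fix_sigma2_e,
                    cfg$store_effect_samples)

  a_hat <- drop(res$add_effects)
  d_hat <- if (cfg$use_dominance) drop(res$dom_effects) else numeric(0)
  fitted <- drop(X %*% a_hat)
  if (cfg$use_dominance) fitted <- fitted + drop(Xd %*% d_hat)

  structure(
    list(model = cfg$model, mu = res$mu,
         add_effects = stats::setNames(a_hat, G$marker_ids),
         dom_effects = if (cfg$use_dominance)
           stats::setNames(d_hat, G$marker_ids) else NULL,
         marker_var = res$marker_var, dom_var = res$dom_var,
         resid_var = res$resid_var, pi = res$pi,
         inclusion_prob = stats::setNames(drop(res$inclusion_prob),
                                          G$marker_ids),
         fitted_genetic_values = stats::setNames(fitted, G$sample_ids),
         n_samples_kept = res$n_samples_kept,
         chains = list(mu = drop(res$mu_chain),
                       resid_var = drop(res$resid_var_chain),
                       marker_var = drop(res$marker_var_chain),
                       pi = drop(res$pi_chain)),
         effect_samples = res$effect_samples,
         allele_freq = p_i, marker_ids = G$marker_ids,
         dom_center = dom_center, config = cfg),
    class = "PosteriorSummary")
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf("PosteriorSummary [%s]: %d markers, %d kept samples\n",
              x$model, length(x$add_effects), x$n_samples_kept))
  cat(sprintf("  mu = %.4f, marker var = %.5f, resid var = %.5f",
              x$mu, x$marker_var, x$resid_var))
  if (!is.na(x$pi)) cat(sprintf(", pi = %.3f", x$pi))
  cat("\n")
  invisible(x)
}

#' Predict phenotypes for new genotypes from a Gibbs posterior
#'
#' `y_hat = mu + W_new a_hat (+ dominance term)` with `W_new` centered by
#' the *training* allele frequencies (and the training heterozygosity means
#' for the dominance design).
#'
#' @param ps a `PosteriorSummary` from [run_gibbs()].
#' @param G_new a `GenotypeMatrix` with exactly the training marker set.
#' @return Named numeric vector of predictions.
#' @export
posterior_predict <- function(ps, G_new) {
  stopifnot(inherits(ps, "PosteriorSummary"), inherits(G_new, "GenotypeMatrix"))
  missing <- setdiff(ps$marker_ids, G_new$marker_ids)
  if (length(missing) > 0)
    stop("new genotypes lack training markers: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  G_new <- G_new[, ps$marker_ids]
  W <- sweep(G_new$dosage, 2, 2 * ps$allele_freq, "-")
  pred <- ps$mu + drop(W %*% ps$add_effects)
  if (!is.null(ps$dom_effects)) {
    Hd <- sweep((G_new$dosage == 1) * 1, 2, ps$dom_center, "-")
    pred <- pred + drop(Hd %*% ps$dom_effects)
  }
  stats::setNames(pred, G_new$sample_ids)
}
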