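#' Additive cross-relationship between new and training samples
#'
#' VanRaden cross-block: both designs are centered by the *training* allele
#' frequencies and scaled by the training denominator, so held-out
#' predictions use only training-derived constants.
#'
#' @param G_new `GenotypeMatrix` of new samples (training marker set).
#' @param G_train the training `GenotypeMatrix`.
#' @return Matrix of relationship values, new x training.
#' @export
additive_cross_kernel <- function(G_new, G_train) {
  if (!identical(G_new$marker_ids, G_train$marker_ids))
    stop("marker sets differ between new and training genotypes")
  p_i <- G_train$allele_freq
  denom <- 2 * sum(p_i * (1 - p_i))
  W_new <- sweep(G_new$dosage, 2, 2 * p_i, "-")
  W_tr <- sweep(G_train$dosage, 2, 2 * p_i, "-")
  tcrossprod(W_new, W_tr) / denom
}

#' Kernel-model specification for the CV harness
#'
#' @param type `"GBLUP"` or `"RKHS"`.
#' @param h Gaussian bandwidth (RKHS only, default 0.5).
#' @param use_dominance add a dominance kernel (GBLUP only).
#' @return A `KernelModelSpec` list.
#' @export
kernel_model <- function(type = c("GBLUP", "RKHS"), h = 0.5,
                         use_dominance = FALSE) {
  type <- match.arg(type)
  structure(list(type = type, h = h, use_dominance = use_dominance),
            class = "KernelModelSpec")
}

# fit on the training split and predict the validation split; every model
# sees only training-derived scaling/frequencies
.fit_and_predict <- function(spec, G_train, y_train, G_valid, seed) {
  if (inherits(spec, "GibbsConfig")) {
    spec$seed <- seed
    ps <- run_gibbs(y_train, G_train, spec)
    return(posterior_predict(ps, G_valid))
  }
  if (inherits(spec, "KernelModelSpec")) {
    if (spec$type == "GBLUP") {
      kernels <- list(additive_relationship(G_train))
      if (spec$use_dominance)
        kernels <- c(kernels, list(dominance_relationship(G_train)))
      fit <- fit_kernel_blup(y_train, kernels)
      Kc <- list(additive_cross_kernel(G_valid, G_train))
      if (spec$use_dominance) {
        # dominance cross-block from training heterozygosity constants
        p_i <- G_train$allele_freq
        tpq <- 2 * p_i * (1 - p_i)
        Wd_new <- sweep((G_valid$dosage == 1) * 1, 2, tpq, "-")
        Wd_tr <- sweep((G_train$dosage == 1) * 1, 2, tpq, "-")
        Kc <- c(Kc, list(tcrossprod(Wd_new, Wd_tr) / sum(tpq * (1 - tpq))))
      }
      return(predict_blup(fit, Kc))
    }
    K <- gaussian_kernel(G_train, h = spec$h)
    fit <- fit_kernel_blup(y_train, K)
    return(predict_blup(fit, gaussian_cross_kernel(K, G_valid, G_train)))
  }
  if (inherits(spec, "BrnnConfig")) {
    spec$seed <- seed
    net <- train_brnn(G_train$dosage, y_train$value, spec)
    return(predict_net(net, G_valid$dosage))
  }
  if (inherits(spec, "LstmConfig")) {
    spec$seed <- seed
    net <- train_lstm(G_train$dosage, y_train$value, spec)
    return(predict_lstm(net, G_valid$dosage))
  }
  stop("unknown model specification of class ",
       paste(class(spec), collapse = "/"))
}

#' Predictive ability: Pearson correlation of observed and predicted
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return The Pearson correlation, or `NA` if either vector is constant
#'   (missing-value sentinel rather than an error).
#' @export
predictive_ability <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0 ||
      anyNA(observed) || anyNA(predicted))
    return(NA_real_)
  stats::cor(observed, predicted)
}

#' Repeated 90/10 cross-validation across models
#'
#' Per cycle, one seeded random split into training (`train_frac`) and
#' validation groups is shared by all models (a paired design, sharpening
#' model contrasts); each model trains on the training split only and is
#' scored by the Pearson correlation between observed and predicted values
#' on the validation split.
#'
#' @param models named list of model specifications: [gibbs_config()],
#'   [kernel_model()], [brnn_config()] or [lstm_config()] objects.
#' @param G a complete `GenotypeMatrix`.
#' @param y a `PhenotypeTable` (n >= 20 after alignment).
#' @param n_cycles number of cross-validation cycles (default 10 at desk
#'   scale; the production protocol uses 50).
#' @param train_frac training fraction (default 0.9).
#' @param seed master seed; split seeds and per-model chain seeds derive
#'   from it.
#' @return A `CvResultTable`: data.frame with columns `model`, `trait`,
#'   `cycle`, `pa`, `train_n`, `valid_n`, `seed`.
#' @export
run_cv <- function(models, G, y, n_cycles = 10L, train_frac = 0.9,
                   seed = 1L) {
  stopifnot(is.list(models), length(models) >= 1,
            !is.null(names(models)), all(nzchar(names(models))))
  al <- .align_gy(y, G)
  y <- al$y; G <- al$G
  n <- nrow(G$dosage)
  if (n < 20) stop("cross-validation needs n >= 20 samples")
  n_train <- round(train_frac * n)
  if (n_train < 2 || n_train >= n) stop("degenerate training fraction")

  set.seed(seed)
  splits <- lapply(seq_len(n_cycles), function(cc) sample.int(n, n_train))

  rows <- list()
  for (cc in seq_len(n_cycles)) {
    tr <- sort(splits[[cc]])
    va <- setdiff(seq_len(n), tr)
    G_tr <- G[tr, ]; G_va <- G[va, ]
    y_tr <- y[tr, , drop = FALSE]
    y_va <- y$value[va]
    for (mi in seq_along(models)) {
      mseed <- (seed + 7919L * cc + 131L * mi) %% .Machine$integer.max
      pred <- .fit_and_predict(models[[mi]], G_tr, y_tr, G_va, mseed)
      pa <- predictive_ability(y_va, as.numeric(pred))
      if (is.na(pa))
        warning(sprintf("constant predictions for model '%s' in cycle %d; PA recorded as missing",
                        names(models)[mi], cc))
      rows[[length(rows) + 1L]] <- data.frame(
        model = names(models)[mi], trait = y$trait[1], cycle = cc,
        pa = pa, train_n = length(tr), valid_n = length(va), seed = mseed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("CvResultTable", "data.frame")
  out
}

#' Tukey-Kramer comparison of model predictive abilities
#'
#' One-way analysis of variance of per-cycle PA across models (per trait),
#' all pairwise comparisons by the studentized-range statistic with the
#' Tukey-Kramer unequal-n standard error, and compact letter display by the
#' insert-and-absorb algorithm: models sharing a letter are not
#' significantly different at level `alpha`.
#'
#' @param cv a `CvResultTable` from [run_cv()] (or any data.frame with
#'   columns `model`, `trait`, `pa`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per trait x model: `trait`, `model`,
#'   `mean_pa`, `sd_pa`, `n`, `letters`, ordered by decreasing mean PA.
#' @export
tukey_kramer_cld <- function(cv, alpha = 0.05) {
  stopifnot(all(c("model", "trait", "pa") %in% names(cv)))
  out <- lapply(split(as.data.frame(cv), cv$trait), function(df) {
    df <- df[!is.na(df$pa), , drop = FALSE]
    groups <- split(df$pa, df$model)
    k <- length(groups)
    if (k < 2) stop("Tukey-Kramer needs >= 2 models")
    if (any(vapply(groups, length, integer(1)) < 2))
      stop("Tukey-Kramer needs >= 2 cycles per model")
    ni <- vapply(groups, length, numeric(1))
    mi <- vapply(groups, mean, numeric(1))
    si <- vapply(groups, stats::sd, numeric(1))
    N <- sum(ni)
    mse <- sum((ni - 1) * si^2) / (N - k)
    if (mse <= 0) stop("zero within-group variance: studentized range undefined")
    dfree <- N - k
    mods <- names(groups)
    sig <- matrix(FALSE, k, k, dimnames = list(mods, mods))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      q <- abs(mi[a] - mi[b]) /
        sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
      pval <- stats::ptukey(q, k, dfree, lower.tail = FALSE)
      sig[a, b] <- sig[b, a] <- pval < alpha
    }
    letters_by_model <- .insert_absorb_cld(mods[order(mi, decreasing = TRUE)],
                                           sig)
    res <- data.frame(trait = df$trait[1], model = mods, mean_pa = mi,
                      sd_pa = si, n = ni,
                      letters = letters_by_model[mods],
                      stringsAsFactors = FALSE, row.names = NULL)
    res[order(res$mean_pa, decreasing = TRUE), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Piepho insert-and-absorb compact letter display. `mods` ordered by
# decreasing mean; `sig` a symmetric logical significance matrix.
.insert_absorb_cld <- function(mods, sig) {
  groups <- list(mods)
  for (a in seq_along(mods)) {
    for (b in seq_along(mods)) {
      if (b <= a) next
      if (!sig[mods[a], mods[b]]) next
      gnew <- list()
      for (g in groups) {
        if (mods[a] %in% g && mods[b] %in% g) {
          gnew <- c(gnew, list(setdiff(g, mods[a])), list(setdiff(g, mods[b])))
        } else gnew <- c(gnew, list(g))
      }
      # absorb: drop groups contained in another
      keep <- rep(TRUE, length(gnew))
      for (i in seq_along(gnew)) for (j in seq_along(gnew)) {
        if (i != j && keep[j] &&
            all(gnew[[i]] %in% gnew[[j]]) &&
            (length(gnew[[i]]) < length(gnew[[j]]) || i > j))
          keep[i] <- FALSE
      }
      groups <- gnew[keep]
    }
  }
  # order groups by the rank of their best member, assign letters
  best <- vapply(groups, function(g) min(match(g, mods)), numeric(1))
  groups <- groups[order(best)]
  lab <- stats::setNames(rep("", length(mods)), mods)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]])
      lab[m] <- paste0(lab[m], letters[gi])
  }
  lab
}

#' Summarize a CV table the way genomic-prediction studies tabulate it
#'
#' Mean PA per model with the Tukey-Kramer letter as a superscript-style
#' suffix.
#'
#' @param cv a `CvResultTable`.
#' @param alpha significance level for the letters.
#' @return data.frame from [tukey_kramer_cld()] with an extra `display`
#'   column like `"0.531 (a)"`.
#' @export
cv_summary <- function(cv, alpha = 0.05) {
  s <- tukey_kramer_cld(cv, alpha = alpha)
  s$display <- sprintf("%.3f (%s)", s$mean_pa, s$letters)
  s
}
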