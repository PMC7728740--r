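#' Simulate a biallelic SNP panel
#'
#' Generates a samples x markers dosage matrix mimicking a filtered breeding
#' panel: marker allele frequencies drawn uniformly from `maf_range`, markers
#' spread over 10 chromosomes with increasing positions. Without structure,
#' dosages are Binomial(2, p_i) per marker. `ld_rho > 0` induces first-order
#' autocorrelation between adjacent markers on a chromosome through
#' correlated latent Gaussian haplotypes (an AR(1) copula thresholded at the
#' allele frequency). Family mode draws parental diplotypes from the same
#' process and produces offspring by Mendelian gamete sampling, one random
#' parental allele per locus.
#'
#' @param n number of samples. In family mode must equal
#'   `n_families * offspring_per_family`.
#' @param p number of markers.
#' @param maf_range length-2 numeric interval within \[0.05, 0.5\] from which
#'   allele frequencies are drawn (a degenerate interval fixes them).
#' @param n_families number of full-sib families (0 = unrelated panel).
#' @param offspring_per_family full sibs per family.
#' @param ld_rho adjacent-marker latent correlation in \[0, 1).
#' @param seed RNG seed.
#' @param n_chrom number of chromosomes markers are assigned to.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5),
                               n_families = 0L, offspring_per_family = 0L,
                               ld_rho = 0, seed = 1L, n_chrom = 10L) {
  stopifnot(n >= 1, p >= 1, length(maf_range) == 2,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1)
  if (n_families > 0 && n != n_families * offspring_per_family)
    stop(sprintf("n (%d) must equal n_families * offspring_per_family (%d x %d)",
                 n, n_families, offspring_per_family))
  set.seed(seed)
  freq <- stats::runif(p, maf_range[1], maf_range[2])
  chrom <- as.character(sort(rep_len(seq_len(n_chrom), p)))
  pos <- integer(p)
  for (cc in unique(chrom)) {
    k <- which(chrom == cc)
    pos[k] <- cumsum(sample(1000:10000, length(k), replace = TRUE))
  }
  thr <- stats::qnorm(freq)  # latent z < thr => carrying the counted allele

  draw_haplotypes <- function(m) {
    # m haplotypes x p loci of 0/1 alleles via AR(1) latent field per chromosome
    z <- matrix(stats::rnorm(m * p), m, p)
    if (ld_rho > 0) {
      for (j in 2:p) {
        if (chrom[j] == chrom[j - 1])
          z[, j] <- ld_rho * z[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
      }
    }
    sweep(z, 2, thr, "<") * 1L
  }

  if (n_families == 0) {
    h1 <- draw_haplotypes(n)
    h2 <- draw_haplotypes(n)
    dos <- h1 + h2
  } else {
    dos <- matrix(0L, n, p)
    row <- 1L
    parent_haps <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      par_h <- draw_haplotypes(4L)  # sire {1,2}, dam {3,4}
      parent_haps[[f]] <- par_h
      for (o in seq_len(offspring_per_family)) {
        # per-locus independent Mendelian transmission
        pick_s <- sample(1:2, p, replace = TRUE)
        pick_d <- sample(3:4, p, replace = TRUE)
        dos[row, ] <- par_h[cbind(pick_s, seq_len(p))] +
          par_h[cbind(pick_d, seq_len(p))]
        row <- row + 1L
      }
    }
  }
  g <- genotype_matrix(dos, sample_ids = sprintf("S%04d", seq_len(n)),
                       marker_ids = sprintf("snp%05d", seq_len(p)),
                       chrom = chrom, pos = pos)
  if (n_families > 0) {
    attr(g, "family") <- rep(seq_len(n_families), each = offspring_per_family)
    # parental haplotypes (4 x p of 0/1 per family) kept for Mendelian checks
    attr(g, "parent_haplotypes") <- parent_haps
  }
  g
}

#' Simulate a quantitative trait with known genetic architecture
#'
#' A handful of large-effect QTL plus a polygenic background: `n_qtl` markers
#' are chosen as QTL carrying `qtl_share` of the additive variance, all
#' remaining markers carry the rest as a Normal polygenic background.
#' Dominance effects act on the QTL through the heterozygosity \{0,1,0\}
#' design. Effect vectors are rescaled so the *realized* variance components
#' hit the targets exactly: with phenotypic variance standardized to 1,
#' `var(breeding values) = h2a`, `var(dominance deviations) = h2d`, and
#' residual noise is rescaled to variance `1 - h2a - h2d`.
#'
#' @param G a complete (no missing) `GenotypeMatrix`.
#' @param n_qtl number of large-effect QTL (0 = purely polygenic).
#' @param h2a target narrow-sense (additive) heritability in \[0, 1\].
#' @param h2d target dominance ratio; `h2a + h2d` must be < 1 unless
#'   `h2a + h2d == 1` exactly (noiseless trait).
#' @param qtl_share fraction of the additive variance carried by the QTL
#'   (default 0.5).
#' @param seed RNG seed.
#' @param mu trait mean.
#' @param trait trait label for the returned `PhenotypeTable`.
#' @return A list with elements `phenotypes` (a [phenotype_table()]) and
#'   `truth` (class `TruthRecord`): QTL indices, per-marker additive and
#'   dominance effects, per-sample breeding and genotypic values, and the
#'   variance components `sigma2_a`, `sigma2_d`, `sigma2_e`.
#' @export
simulate_trait <- function(G, n_qtl = 10L, h2a = 0.5, h2d = 0,
                           qtl_share = 0.5, seed = 1L, mu = 0,
                           trait = "sim_trait") {
  stopifnot(inherits(G, "GenotypeMatrix"),
            h2a >= 0, h2d >= 0, n_qtl <= ncol(G$dosage),
            qtl_share >= 0, qtl_share <= 1)
  if (h2a + h2d > 1 || (h2a + h2d >= 1 && h2a + h2d != 1))
    stop("h2a + h2d must be < 1 (or exactly 1 for a noiseless trait)")
  if (anyNA(G$dosage)) stop("genotype matrix has missing dosages; filter first")
  set.seed(seed)
  n <- nrow(G$dosage); p <- ncol(G$dosage)
  sigma2_a <- h2a; sigma2_d <- h2d; sigma2_e <- 1 - h2a - h2d

  W <- sweep(G$dosage, 2, 2 * G$allele_freq, "-")   # centered additive design
  qtl <- if (n_qtl > 0) sort(sample.int(p, n_qtl)) else integer(0)

  rescale_to <- function(x, target_var) {
    v <- stats::var(x)
    if (v <= 0) return(x * 0)
    x * sqrt(target_var / v)
  }

  a <- numeric(p)
  if (n_qtl > 0) a[qtl] <- stats::rnorm(n_qtl)
  bg <- setdiff(seq_len(p), qtl)
  if (length(bg) > 0) a[bg] <- stats::rnorm(length(bg), sd = 0.1)

  share_q <- if (n_qtl > 0) qtl_share else 0
  bv_q <- if (n_qtl > 0) drop(W[, qtl, drop = FALSE] %*% a[qtl]) else numeric(n)
  bv_b <- if (length(bg) > 0) drop(W[, bg, drop = FALSE] %*% a[bg]) else numeric(n)
  if (n_qtl > 0 && stats::var(bv_q) > 0) {
    s <- sqrt(share_q * sigma2_a / stats::var(bv_q)); a[qtl] <- a[qtl] * s; bv_q <- bv_q * s
  }
  if (length(bg) > 0 && stats::var(bv_b) > 0) {
    s <- sqrt((1 - share_q) * sigma2_a / stats::var(bv_b)); a[bg] <- a[bg] * s; bv_b <- bv_b * s
  }
  bv <- bv_q + bv_b
  # final exact rescale of the whole additive effect vector
  if (stats::var(bv) > 0) {
    s <- sqrt(sigma2_a / stats::var(bv)); a <- a * s; bv <- bv * s
  } else if (sigma2_a > 0) {
    stop("additive design has zero variance; cannot hit the h2a target")
  }

  d <- numeric(p)
  dv <- numeric(n)
  if (sigma2_d > 0) {
    if (n_qtl == 0) stop("h2d > 0 requires n_qtl > 0 (dominance acts on QTL)")
    H <- (G$dosage[, qtl, drop = FALSE] == 1) * 1  # {0,1,0} design
    H <- sweep(H, 2, colMeans(H), "-")
    d[qtl] <- stats::rnorm(n_qtl)
    dv <- drop(H %*% d[qtl])
    if (stats::var(dv) <= 0) stop("no heterozygosity variance at the QTL")
    s <- sqrt(sigma2_d / stats::var(dv)); d[qtl] <- d[qtl] * s; dv <- dv * s
  }

  e <- stats::rnorm(n)
  e <- if (sigma2_e > 0) rescale_to(e, sigma2_e) else numeric(n) * 0
  gval <- bv + dv
  y <- mu + gval + e

  truth <- structure(
    list(qtl_indices = qtl, qtl_ids = G$marker_ids[qtl],
         add_effects = a, dom_effects = d,
         breeding_values = bv, genotypic_values = gval,
         sigma2_a = sigma2_a, sigma2_d = sigma2_d, sigma2_e = sigma2_e,
         mu = mu),
    class = "TruthRecord")
  list(phenotypes = phenotype_table(G$sample_ids, y, trait = trait),
       truth = truth)
}

#' Write the simulated truth as a delimited marker-effect table
#'
#' @param truth a `TruthRecord` from [simulate_trait()].
#' @param G the `GenotypeMatrix` the trait was simulated on.
#' @param path output path.
#' @export
write_truth <- function(truth, G, path) {
  df <- data.frame(marker_id = G$marker_ids, chrom = G$chrom, pos = G$pos,
                   add_effect = truth$add_effects,
                   dom_effect = truth$dom_effects,
                   is_qtl = seq_along(G$marker_ids) %in% truth$qtl_indices)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
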