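#' Genotype dosage matrix with marker metadata
#'
#' Container for a samples x markers dosage matrix coded 0/1/2 (count of the
#' tracked allele; for VCF input this is the ALT allele). Missing genotypes
#' are `NA`. Allele frequencies are computed from the non-missing entries of
#' each column and are recomputed whenever the dosages change.
#'
#' @param dosage numeric matrix, samples in rows, markers in columns, entries
#'   in \{0, 1, 2, NA\} (real-valued entries are permitted after mean
#'   imputation by [filter_markers()]).
#' @param sample_ids character vector of unique sample identifiers.
#' @param marker_ids character vector of marker identifiers.
#' @param chrom per-marker chromosome label.
#' @param pos per-marker 1-based physical position (bp).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosage`, `sample_ids`, `marker_ids`, `chrom`, `pos`, `allele_freq`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            marker_ids = colnames(dosage),
                            chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage)
  p <- ncol(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(p))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(sample_ids) != n || length(marker_ids) != p)
    stop("sample/marker id lengths do not match the dosage matrix")
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p)
  if (length(chrom) != p || length(pos) != p)
    stop("marker metadata length must equal the number of markers")
  bad <- which(is.finite(dosage) & (dosage < 0 | dosage > 2))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(dosage))
    stop(sprintf("dosage outside [0, 2] at sample '%s', marker '%s' (value %g)",
                 sample_ids[rc[1]], marker_ids[rc[2]], dosage[bad[1]]))
  }
  dimnames(dosage) <- list(sample_ids, marker_ids)
  g <- structure(
    list(dosage = dosage, sample_ids = sample_ids, marker_ids = marker_ids,
         chrom = as.character(chrom), pos = as.integer(pos),
         allele_freq = rep(NA_real_, p)),
    class = "GenotypeMatrix")
  g$allele_freq <- .allele_freq(dosage)
  g
}

# column allele frequency of the counted allele over non-missing samples
.allele_freq <- function(dosage) {
  colMeans(dosage, na.rm = TRUE) / 2
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers\n",
              nrow(x$dosage), ncol(x$dosage)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom)[seq_len(min(10, length(unique(x$chrom))))],
                    collapse = ", ")))
  cat(sprintf("  missing: %.2f%%, mean MAF: %.3f\n", 100 * miss,
              mean(pmin(x$allele_freq, 1 - x$allele_freq), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' Subset a GenotypeMatrix by samples and/or markers
#'
#' @param x a `GenotypeMatrix`.
#' @param i sample index (integer, logical or character).
#' @param j marker index.
#' @param ... ignored.
#' @return A `GenotypeMatrix` restricted to the selected samples and markers;
#'   allele frequencies are recomputed from the retained samples.
#' @export
`[.GenotypeMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$marker_ids)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  sample_ids = x$sample_ids[i],
                  marker_ids = x$marker_ids[j],
                  chrom = x$chrom[j], pos = x$pos[j])
}

#' Read genotypes from a delimited table, PLINK .raw, or VCF
#'
#' Table dialect: samples in rows, first column the sample id, remaining
#' columns one marker each (header = marker ids), entries in \{0,1,2\} or NA.
#' PLINK `.raw` (as written by `plink --recode A`): the first six columns
#' (FID IID PAT MAT SEX PHENOTYPE) are skipped. VCF: biallelic SNPs only;
#' GT fields 0/0, 0/1, 1/1 map to dosage 0, 1, 2 of the ALT allele and
#' `./.` to missing.
#'
#' @param path file path.
#' @param format one of `"table"`, `"plink_raw"`, `"vcf"`.
#' @param sep field separator for the table dialect (default whitespace/tab
#'   autodetected by [utils::read.table()]).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("table", "plink_raw", "vcf"),
                           sep = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         table = .read_genotype_table(path, sep = sep),
         plink_raw = .read_plink_raw(path),
         vcf = .read_vcf(path))
}

.check_dosage_cells <- function(mat, path) {
  bad <- which(!is.na(mat) & !(mat %in% c(0, 1, 2)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(mat))
    stop(sprintf("%s: dosage value %g outside {0,1,2} at row %d, column %d",
                 path, mat[bad[1]], rc[1], rc[2]))
  }
}

.read_genotype_table <- function(path, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "na", "."))
  if (ncol(df) < 2) stop(path, ": expected a sample-id column plus markers")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  .check_dosage_cells(mat, path)
  genotype_matrix(mat, sample_ids = ids, marker_ids = colnames(df)[-1])
}

.read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", "."))
  if (ncol(df) < 7) stop(path, ": PLINK .raw needs 6 metadata columns + markers")
  ids <- as.character(df[["IID"]])
  mat <- as.matrix(df[, -(1:6), drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  .check_dosage_cells(mat, path)
  # .raw marker headers carry the counted allele as suffix, e.g. rs123_A
  genotype_matrix(mat, sample_ids = ids, marker_ids = colnames(mat))
}

.read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1)) {
    k <- which(n_alt != 1)[1]
    stop(sprintf("%s: non-biallelic record '%s' (%d ALT alleles)",
                 path, rownames(vcf)[k], n_alt[k]))
  }
  gt <- VariantAnnotation::geno(vcf)$GT          # markers x samples
  if (is.null(gt)) stop(path, ": VCF has no GT field")
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA, "." = NA)
  known <- gt %in% names(map) | is.na(gt)
  if (!all(known)) {
    k <- which(!known)[1]
    rc <- arrayInd(k, dim(gt))
    stop(sprintf("%s: unsupported GT '%s' in record '%s'",
                 path, gt[k], rownames(gt)[rc[1]]))
  }
  dos <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  genotype_matrix(t(dos),
                  sample_ids = colnames(gt),
                  marker_ids = rownames(gt),
                  chrom = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr))
}

#' Write a GenotypeMatrix in the delimited table dialect
#'
#' The written file round-trips exactly through
#' `read_genotypes(format = "table")` when dosages are integer-coded.
#'
#' @param G a `GenotypeMatrix`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  df <- data.frame(sample_id = G$sample_ids, G$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker quality control: MAF and missingness filters, subsampling, imputation
#'
#' Removes markers with minor allele frequency below `maf_min` or missing
#' fraction above `missing_max`, optionally retains a seeded uniform random
#' subset of the survivors, and mean-imputes any remaining missing dosages so
#' every downstream model sees a complete matrix. MAF is
#' `min(p, 1 - p)` over non-missing samples.
#'
#' @param G a `GenotypeMatrix`.
#' @param maf_min minimum minor allele frequency retained (default 0.05, the
#'   panel-filtering convention for SNP chip data).
#' @param missing_max maximum tolerated missing fraction per marker
#'   (default 0.10).
#' @param subsample optional integer: retain this many markers, drawn
#'   uniformly at random (seeded) from the survivors.
#' @param seed RNG seed used only when `subsample` is given.
#' @return A `GenotypeMatrix` with filtered markers, no missing entries
#'   (column-mean imputed), and recomputed allele frequencies.
#' @export
filter_markers <- function(G, maf_min = 0.05, missing_max = 0.10,
                           subsample = NULL, seed = 1L) {
  stopifnot(inherits(G, "GenotypeMatrix"),
            maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1)
  p_i <- .allele_freq(G$dosage)
  maf <- pmin(p_i, 1 - p_i)
  maf[is.na(maf)] <- 0                      # all-missing column: drop
  miss <- colMeans(is.na(G$dosage))
  keep <- which(maf >= maf_min & miss <= missing_max)
  if (!is.null(subsample)) {
    if (subsample > length(keep))
      stop(sprintf("subsample (%d) exceeds surviving marker count (%d)",
                   subsample, length(keep)))
    set.seed(seed)
    keep <- sort(sample(keep, subsample))
  }
  dos <- G$dosage[, keep, drop = FALSE]
  # column-mean imputation of remaining missing cells
  nas <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    cm <- colMeans(dos, na.rm = TRUE)
    dos[nas] <- cm[nas[, 2]]
  }
  genotype_matrix(dos, sample_ids = G$sample_ids,
                  marker_ids = G$marker_ids[keep],
                  chrom = G$chrom[keep], pos = G$pos[keep])
}
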