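#' Per-sample pre-corrected trait values
#'
#' Phenotypes are assumed pre-corrected for non-genetic effects (experimental
#' design, block effects): each record is one sample's adjusted value for one
#' trait in one (optional) environment.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param value numeric vector of trait values (NA = missing).
#' @param trait trait label.
#' @param environment optional environment label.
#' @return A `PhenotypeTable`: a data.frame with columns `sample_id`,
#'   `trait`, `environment`, `value`.
#' @export
phenotype_table <- function(sample_ids, value, trait = "trait",
                            environment = NA_character_) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(sample_ids) != length(value))
    stop("sample_ids and value lengths differ")
  structure(
    data.frame(sample_id = sample_ids, trait = trait,
               environment = environment, value = as.numeric(value),
               stringsAsFactors = FALSE),
    class = c("PhenotypeTable", "data.frame"))
}

#' Read phenotypes from a delimited table
#'
#' Expects a header naming a sample-id column (first column) and one or more
#' trait columns. Non-numeric cells become missing. Returns one
#' `PhenotypeTable` per trait column.
#'
#' @param path file path.
#' @param sep field separator (autodetected whitespace by default).
#' @param environment optional environment label stored on every table.
#' @return A named list of `PhenotypeTable`s, one per trait column.
#' @export
read_phenotypes <- function(path, sep = "", environment = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop(path, ": expected a sample-id column plus >= 1 trait")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(path, ": duplicated sample id '", ids[duplicated(ids)][1], "'")
  out <- lapply(names(df)[-1], function(tr) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    phenotype_table(ids, v, trait = tr, environment = environment)
  })
  names(out) <- names(df)[-1]
  out
}

#' Write one or more PhenotypeTables as a delimited file
#'
#' @param y a `PhenotypeTable` or list of them sharing sample ids.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_phenotypes <- function(y, path, sep = "\t") {
  if (inherits(y, "PhenotypeTable")) y <- list(y)
  ids <- y[[1]]$sample_id
  df <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (tab in y) {
    stopifnot(identical(tab$sample_id, ids))
    df[[tab$trait[1]]] <- tab$value
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a PhenotypeTable against a GenotypeMatrix; returns list(y, G) with
# matching sample order and missing-phenotype samples dropped
.align_gy <- function(y, G) {
  stopifnot(inherits(y, "PhenotypeTable"), inherits(G, "GenotypeMatrix"))
  idx <- match(y$sample_id, G$sample_ids)
  if (anyNA(idx))
    stop("phenotype samples absent from genotypes: ",
         paste(y$sample_id[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  ok <- !is.na(y$value)
  list(y = y[ok, , drop = FALSE], G = G[idx[ok], ])
}
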