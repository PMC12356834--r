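#' Construct a genotype matrix
#'
#' The central genotype container: diploid alternate-allele dosages for a set
#' of samples (rows) and decomposed bi-allelic variants (columns), together
#' with the per-call sequencing depth and alternate-read fraction used by the
#' quality-control filters. Missing genotypes are `NA`.
#'
#' @param dosage integer matrix (samples x variants) with values 0/1/2 or `NA`.
#'   Row names are sample ids, column names variant ids.
#' @param depth integer matrix of total reads per call, same shape, or `NULL`.
#' @param alt_frac numeric matrix of alternate-read fractions in `[0, 1]`,
#'   defined only for non-missing calls with depth > 0; `NA` elsewhere.
#'   May be `NULL` when allelic depths were unavailable.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, depth = NULL, alt_frac = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must carry sample ids as rownames and variant ids as colnames")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  for (m in list(depth, alt_frac)) {
    if (!is.null(m) && !identical(dim(m), dim(dosage)))
      stop("depth/alt_frac must have the same shape as dosage")
  }
  structure(list(dosage = dosage, depth = depth, alt_frac = alt_frac),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants index vectors (ids, positions or logical).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosage)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$dosage)) else variants
  take <- function(m) if (is.null(m)) NULL else m[si, vi, drop = FALSE]
  genotype_matrix(x$dosage[si, vi, drop = FALSE], take(x$depth), take(x$alt_frac))
}

sample_ids <- function(x) rownames(x$dosage)
variant_ids <- function(x) colnames(x$dosage)

#' Per-sample genotype call rate
#'
#' @param genotypes a `genotype_matrix`.
#' @return Named numeric vector, fraction of non-missing calls per sample.
#' @export
sample_call_rate <- function(genotypes) {
  1 - rowMeans(is.na(genotypes$dosage))
}

#' Per-variant genotype call rate
#'
#' @param genotypes a `genotype_matrix`.
#' @return Named numeric vector, fraction of non-missing calls per variant.
#' @export
variant_call_rate <- function(genotypes) {
  1 - colMeans(is.na(genotypes$dosage))
}
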