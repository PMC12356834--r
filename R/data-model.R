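## Readers and writers for the three pipeline inputs (VCF, sample sheet,
## annotation table) and the per-gene burden results.

PHENOTYPE_LEVELS <- c("control", "PACG_chronic", "APAC")
SEX_LEVELS <- c("female", "male", "unknown")
CONSEQUENCE_LEVELS <- c("stop_gained", "start_lost", "frameshift",
                        "splice_canonical", "missense", "synonymous", "other")

#' Read a multi-sample VCF into variant records and a genotype matrix
#'
#' Multi-allelic sites are decomposed into independent bi-allelic records,
#' one per alternate allele; sibling records share a `parent_site_id`
#' (`chrom:pos:ref`) so that downstream QC can apply the rule that a failure
#' of any allele fails the whole site. Genotypes are read unphased: `0/1`
#' and `1|0` both give dosage 1; any genotype containing `.` (including
#' half-missing calls such as `./1`) is treated as missing. Per-call depth
#' is taken from `DP`, falling back to the sum of `AD`; the alternate-read
#' fraction is computed from `AD` and left undefined when `AD` is absent.
#'
#' @param path path to a VCF 4.x file (plain or gzip-compressed) with `GT`
#'   and, when available, `DP` and `AD` per call.
#' @return A list with `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `parent_site_id`, `vqslod`) and `genotypes`
#'   (a [genotype_matrix], samples x variants, sample order as in the VCF).
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  if (n_site == 0) stop("VCF contains no variant records")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)
  samples <- colnames(gt)
  n_smp <- length(samples)
  # VQSLOD pass-through from INFO, if annotated upstream
  info <- vcf@fix[, "INFO"]
  vq <- suppressWarnings(as.numeric(sub(".*VQSLOD=([^;]+).*", "\\1",
                                        ifelse(grepl("VQSLOD=", info), info, NA))))

  alts_by_site <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts_by_site)
  rec_site <- rep.int(seq_len(n_site), n_alt)
  rec_allele <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  n_rec <- length(rec_site)

  parent <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], sep = ":")
  alt_alleles <- unlist(alts_by_site, use.names = FALSE)
  # stable id: the VCF ID for named bi-allelic sites, chrom:pos:ref:alt otherwise
  ids <- fix[, "ID"]
  has_id <- !is.na(ids) & ids != "."
  vid <- ifelse(has_id[rec_site] & n_alt[rec_site] == 1L,
                ids[rec_site],
                paste(parent[rec_site], alt_alleles, sep = ":"))
  if (anyDuplicated(vid))
    vid <- make.unique(vid, sep = "#")

  variants <- data.frame(
    variant_id = vid,
    chrom = fix[rec_site, "CHROM"],
    pos = as.integer(fix[rec_site, "POS"]),
    ref = fix[rec_site, "REF"],
    alt = alt_alleles,
    parent_site_id = parent[rec_site],
    vqslod = vq[rec_site],
    stringsAsFactors = FALSE
  )
  if (any(variants$pos < 1)) stop("VCF positions must be >= 1")
  if (any(variants$ref == variants$alt))
    stop("reference and alternate alleles must differ")

  # split diploid genotype strings once; bare "." also counts as missing
  a1 <- sub("[/|].*", "", gt)
  a2 <- sub(".*[/|]", "", gt)
  missing <- is.na(gt) | a1 == "." | a2 == "."

  dosage <- matrix(NA_integer_, n_smp, n_rec,
                   dimnames = list(samples, vid))
  depth <- matrix(NA_integer_, n_smp, n_rec, dimnames = list(samples, vid))
  altf <- matrix(NA_real_, n_smp, n_rec, dimnames = list(samples, vid))

  ad_split <- if (!is.null(ad)) {
    array(NA_real_, dim = c(n_site, n_smp, max(n_alt) + 1L))
  } else NULL
  if (!is.null(ad)) {
    for (i in seq_len(n_site)) {
      parts <- strsplit(ad[i, ], ",", fixed = TRUE)
      for (s in seq_len(n_smp)) {
        v <- suppressWarnings(as.numeric(parts[[s]]))
        if (length(v)) ad_split[i, s, seq_along(v)] <- v
      }
    }
  }

  for (r in seq_len(n_rec)) {
    i <- rec_site[r]
    j <- rec_allele[r]
    tgt <- as.character(j)
    d <- (a1[i, ] == tgt) + (a2[i, ] == tgt)
    d[missing[i, ]] <- NA_integer_
    dosage[, r] <- as.integer(d)
    if (!is.null(ad_split)) {
      ad_i <- matrix(ad_split[i, , ], nrow = n_smp)
      ad_tot <- rowSums(ad_i, na.rm = TRUE)
      ad_tot[rowSums(!is.na(ad_i)) == 0] <- NA
    } else {
      ad_tot <- rep(NA_real_, n_smp)
    }
    dpt <- dp[i, ]
    dpt[is.na(dpt)] <- ad_tot[is.na(dpt)]
    depth[, r] <- as.integer(round(dpt))
    if (!is.null(ad_split)) {
      f <- ad_split[i, , j + 1L] / ad_tot
      f[!is.finite(f)] <- NA_real_
      f[missing[i, ] | is.na(d)] <- NA_real_
      altf[, r] <- f
    }
  }

  list(variants = variants,
       genotypes = genotype_matrix(dosage, depth,
                                   if (is.null(ad)) NULL else altf))
}

#' Read the sample sheet
#'
#' @param path tab-separated file with header; required columns `sample_id`,
#'   `stratum`, `sex`, `phenotype`; optional `frac_bases_20x`.
#' @return Data frame of sample records with a derived logical `is_case`
#'   (`TRUE` for chronic PACG and APAC phenotypes).
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "stratum", "sex", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet is missing required columns: ", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  bad <- !(df$phenotype %in% PHENOTYPE_LEVELS)
  if (any(bad))
    stop("unknown phenotype label(s) in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$phenotype[bad]), collapse = ", "),
         " (expected ", paste(PHENOTYPE_LEVELS, collapse = "/"), ")")
  badsex <- !(df$sex %in% SEX_LEVELS)
  if (any(badsex))
    stop("unknown sex label(s): ", paste(unique(df$sex[badsex]), collapse = ", "))
  df$is_case <- df$phenotype %in% c("PACG_chronic", "APAC")
  if ("frac_bases_20x" %in% names(df)) {
    df$frac_bases_20x <- as.numeric(df$frac_bases_20x)
    ok <- is.na(df$frac_bases_20x) |
      (df$frac_bases_20x >= 0 & df$frac_bases_20x <= 1)
    if (!all(ok)) stop("frac_bases_20x must lie in [0, 1]")
  }
  df
}

#' Read the variant annotation table
#'
#' One record per (variant, gene) pair with a consequence class, a CADD
#' scaled score where applicable, and optional external per-population
#' allele-frequency columns (any column named `ext_af_*`). Missense records
#' lacking a CADD score are kept but flagged unusable for qualifying-variant
#' selection, with a warning.
#'
#' @param path tab-separated file with header; required columns `variant_id`,
#'   `gene`, `consequence`; optional `cadd_scaled` and `ext_af_*` columns.
#' @param known_variants optional character vector of variant ids present in
#'   the genotype data; records referencing other ids are flagged
#'   (`known = FALSE`) but retained.
#' @return Data frame of annotation records with logical columns `known` and
#'   `usable` (FALSE for missense records without a CADD score).
#' @export
read_annotations <- function(path, known_variants = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  req <- c("variant_id", "gene", "consequence")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation table is missing required columns: ",
         paste(miss, collapse = ", "))
  bad <- !(df$consequence %in% CONSEQUENCE_LEVELS)
  if (any(bad))
    stop("unknown consequence label(s): ",
         paste(unique(df$consequence[bad]), collapse = ", "),
         " (expected ", paste(CONSEQUENCE_LEVELS, collapse = "/"), ")")
  if (anyDuplicated(df[c("variant_id", "gene")]))
    stop("duplicate (variant_id, gene) annotation records")
  if (!"cadd_scaled" %in% names(df)) df$cadd_scaled <- NA_real_
  df$cadd_scaled <- as.numeric(df$cadd_scaled)
  if (any(df$cadd_scaled < 0, na.rm = TRUE))
    stop("cadd_scaled must be non-negative")
  df$usable <- !(df$consequence == "missense" & is.na(df$cadd_scaled))
  if (any(!df$usable))
    warning(sum(!df$usable),
            " missense record(s) lack a CADD score and are excluded from",
            " qualifying-variant selection")
  df$known <- if (is.null(known_variants)) TRUE else
    df$variant_id %in% known_variants
  df
}

#' Write per-gene burden results to TSV
#'
#' One row per gene; P values and odds ratios at full precision; the
#' per-stratum 2x2 cells are packed into a single `strata` column as
#' `label=a/b/c/d` entries separated by `;` so a result file round-trips
#' losslessly through [read_burden_results()].
#'
#' @param results a data frame from [gene_burden_scan()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_burden_results <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  pack <- vapply(results$strata, function(st) {
    paste(sprintf("%s=%d/%d/%d/%d", st$stratum, st$a, st$b, st$c, st$d),
          collapse = ";")
  }, character(1))
  num <- function(x) vapply(x, function(v)
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE),
    character(1))
  out <- data.frame(
    gene = results$gene,
    or_mh = num(results$or_mh),
    ci_low = num(results$ci_low),
    ci_high = num(results$ci_high),
    chisq = num(results$chisq),
    p_cmh = num(results$p_cmh),
    p_adjusted = num(results$p_adjusted),
    exome_wide_significant = results$exome_wide_significant,
    strata = pack,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene burden results written by [write_burden_results()]
#'
#' @param path path to a results TSV.
#' @return Data frame in the layout produced by [gene_burden_scan()].
#' @export
read_burden_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  strata <- lapply(strsplit(df$strata, ";", fixed = TRUE), function(entries) {
    parts <- strsplit(entries, "[=/]")
    data.frame(
      stratum = vapply(parts, `[`, character(1), 1),
      a = as.integer(vapply(parts, `[`, character(1), 2)),
      b = as.integer(vapply(parts, `[`, character(1), 3)),
      c = as.integer(vapply(parts, `[`, character(1), 4)),
      d = as.integer(vapply(parts, `[`, character(1), 5)),
      stringsAsFactors = FALSE
    )
  })
  out <- data.frame(
    gene = df$gene,
    or_mh = as.numeric(df$or_mh),
    ci_low = as.numeric(df$ci_low),
    ci_high = as.numeric(df$ci_high),
    chisq = as.numeric(df$chisq),
    p_cmh = as.numeric(df$p_cmh),
    p_adjusted = as.numeric(df$p_adjusted),
    exome_wide_significant = as.logical(df$exome_wide_significant),
    stringsAsFactors = FALSE
  )
  out$strata <- strata
  out
}
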