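## Qualifying-variant selection and dominant carrier collapsing.

PTV_CLASSES <- c("stop_gained", "start_lost", "frameshift", "splice_canonical")

#' Qualifying-variant rule
#'
#' A variant qualifies when its minor allele frequency is below `maf_max`
#' in every ancestry group and it is either protein-truncating
#' (stop-gained, start-lost, frameshift, canonical splice-site) or a
#' missense with CADD scaled score strictly greater than `cadd_min`.
#'
#' @param maf_max strict MAF upper bound (default 0.01).
#' @param ptv_classes consequence classes counted as protein-truncating.
#' @param cadd_min strict CADD lower bound for missense variants
#'   (default 10).
#' @return A `qualifying_rule` list.
#' @export
qualifying_rule <- function(maf_max = 0.01, ptv_classes = PTV_CLASSES,
                            cadd_min = 10) {
  stopifnot(maf_max > 0, maf_max < 1, cadd_min >= 0,
            all(ptv_classes %in% CONSEQUENCE_LEVELS))
  structure(list(maf_max = maf_max, ptv_classes = ptv_classes,
                 cadd_min = cadd_min), class = "qualifying_rule")
}

#' Per-group minor allele frequency
#'
#' For every variant and ancestry group, the alternate-allele frequency is
#' the alternate-allele count divided by twice the number of non-missing
#' diploid calls; the minor allele frequency folds it as `min(af, 1 - af)`.
#' Groups with no non-missing calls give `NA`.
#'
#' @param genotypes a [genotype_matrix].
#' @param samples sample sheet aligned with the genotype rows.
#' @param groups grouping vector per sample (default: the country stratum).
#' @return Numeric matrix, variants x groups, of minor allele frequencies.
#' @export
group_maf <- function(genotypes, samples, groups = samples$stratum) {
  stopifnot(identical(sample_ids(genotypes), samples$sample_id))
  dos <- genotypes$dosage
  lev <- unique(groups)
  out <- matrix(NA_real_, ncol(dos), length(lev),
                dimnames = list(colnames(dos), lev))
  for (g in lev) {
    d <- dos[groups == g, , drop = FALSE]
    called <- colSums(!is.na(d))
    af <- colSums(d, na.rm = TRUE) / (2 * called)
    af[called == 0] <- NA
    out[, g] <- pmin(af, 1 - af)
  }
  out
}

#' Select qualifying variants
#'
#' @param annotations annotation table from [read_annotations()].
#' @param group_mafs matrix from [group_maf()] (rows indexed by variant
#'   id). External per-population allele-frequency columns in the
#'   annotation table (`ext_af_*`), when present, are folded to minor
#'   allele frequencies and subjected to the same MAF bound.
#' @param rule a [qualifying_rule()].
#' @return Character vector of qualifying variant ids.
#' @export
select_qualifying <- function(annotations, group_mafs,
                              rule = qualifying_rule()) {
  ann <- annotations[annotations$usable & annotations$known, , drop = FALSE]
  idx <- match(ann$variant_id, rownames(group_mafs))
  maf <- group_mafs[idx, , drop = FALSE]
  ext_cols <- grep("^ext_af_", names(ann), value = TRUE)
  if (length(ext_cols)) {
    ext <- as.matrix(ann[ext_cols])
    maf <- cbind(maf, pmin(ext, 1 - ext))
  }
  # rare in every group where frequency is defined; a variant with no
  # defined frequency anywhere conservatively fails
  defined <- rowSums(!is.na(maf)) > 0
  rare <- defined & apply(maf < rule$maf_max, 1, all, na.rm = TRUE)
  damaging <- ann$consequence %in% rule$ptv_classes |
    (ann$consequence == "missense" & !is.na(ann$cadd_scaled) &
       ann$cadd_scaled > rule$cadd_min)
  unique(ann$variant_id[rare & damaging])
}

#' Collapse qualifying variants to per-gene carrier indicators
#'
#' Dominant collapsing: a sample is a carrier for a gene when it has
#' dosage >= 1 at any qualifying variant of that gene. Samples whose calls
#' are missing at every qualifying variant of a gene are `NA` (carrier
#' status unknown) and are excluded from that gene's tables. Genes with no
#' qualifying variants are omitted.
#'
#' @param genotypes a QC-passing [genotype_matrix].
#' @param qualifying_ids character vector of qualifying variant ids.
#' @param gene_map data frame with columns `variant_id` and `gene` (the
#'   annotation table works as-is).
#' @return A `carrier_matrix`: list with `carrier` (logical genes x
#'   samples matrix, `NA` = unknown) and `variants` (named list of
#'   contributing variant ids per gene).
#' @export
collapse_carriers <- function(genotypes, qualifying_ids, gene_map) {
  qual <- gene_map[gene_map$variant_id %in% qualifying_ids &
                     gene_map$variant_id %in% variant_ids(genotypes), ,
                   drop = FALSE]
  genes <- sort(unique(qual$gene))
  dos <- genotypes$dosage
  carrier <- matrix(NA, length(genes), nrow(dos),
                    dimnames = list(genes, rownames(dos)))
  vars <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    vg <- qual$variant_id[qual$gene == g]
    vars[[g]] <- vg
    d <- dos[, vg, drop = FALSE]
    any_alt <- rowSums(d >= 1L, na.rm = TRUE) > 0
    all_missing <- rowSums(!is.na(d)) == 0
    status <- any_alt
    status[all_missing & !any_alt] <- NA
    carrier[g, ] <- status
  }
  structure(list(carrier = carrier, variants = vars),
            class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("carrier_matrix: %d genes x %d samples\n",
              nrow(x$carrier), ncol(x$carrier)))
  invisible(x)
}

#' Build per-gene, per-stratum 2x2 carrier tables
#'
#' For every gene, counts case carriers (`a`), case non-carriers (`b`),
#' control carriers (`c`) and control non-carriers (`d`) within each
#' stratum. Samples with unknown carrier status for a gene are excluded
#' from that gene's tables; strata without both cases and controls are
#' dropped (recorded in the `dropped_strata` attribute).
#'
#' @param carriers a [collapse_carriers()] result, or a logical genes x
#'   samples matrix.
#' @param samples sample sheet aligned with the carrier columns.
#' @param stratify_by `"cohort"` (country strata), `"cohort_sex"`
#'   (country x sex; samples of unknown sex are dropped), or `"apac"`
#'   (country strata with cases restricted to the acute subtype; controls
#'   unchanged).
#' @return Named list (per gene) of data frames with columns `stratum`,
#'   `a`, `b`, `c`, `d`.
#' @export
stratum_tables <- function(carriers, samples,
                           stratify_by = c("cohort", "cohort_sex", "apac")) {
  stratify_by <- match.arg(stratify_by)
  cm <- if (inherits(carriers, "carrier_matrix")) carriers$carrier else carriers
  stopifnot(is.matrix(cm), identical(colnames(cm), samples$sample_id))
  keep <- rep(TRUE, nrow(samples))
  strata <- samples$stratum
  if (stratify_by == "cohort_sex") {
    keep <- samples$sex %in% c("female", "male")
    strata <- paste(samples$stratum, samples$sex, sep = ":")
  } else if (stratify_by == "apac") {
    keep <- !samples$is_case | samples$phenotype == "APAC"
  }
  if (!any(keep)) stop("empty stratification")
  dropped <- character(0)
  out <- stats::setNames(vector("list", nrow(cm)), rownames(cm))
  for (g in rownames(cm)) {
    st <- cm[g, ]
    use <- keep & !is.na(st)
    tb <- NULL
    for (s in unique(strata[use])) {
      in_s <- use & strata == s
      case <- samples$is_case[in_s]
      if (!any(case) || all(case)) {
        dropped <- unique(c(dropped, s))
        next
      }
      carr <- st[in_s]
      tb <- rbind(tb, data.frame(
        stratum = s,
        a = sum(carr & case), b = sum(!carr & case),
        c = sum(carr & !case), d = sum(!carr & !case),
        stringsAsFactors = FALSE))
    }
    out[[g]] <- tb
  }
  attr(out, "dropped_strata") <- dropped
  out
}

#' Per-sample exome-wide variant count
#'
#' Number of variants at which the sample carries at least one alternate
#' allele; the covariate used alongside the ancestry principal components
#' in the adjusted burden model.
#'
#' @param genotypes a QC-passing [genotype_matrix].
#' @return Named integer vector per sample.
#' @export
exome_variant_count <- function(genotypes) {
  stats::setNames(as.integer(rowSums(genotypes$dosage >= 1L, na.rm = TRUE)),
                  sample_ids(genotypes))
}

#' Carrier-frequency summary for a 2x2 table set
#'
#' Pools the per-stratum tables of one gene and reports carrier counts and
#' percentages among cases and controls, as printed in study reports.
#'
#' @param strata data frame of per-stratum tables (columns `a`, `b`, `c`,
#'   `d`).
#' @param digits digits for the rounded percentages (default 2 significant
#'   figures as typically printed).
#' @return List with `case_carriers`, `cases`, `case_pct`,
#'   `control_carriers`, `controls`, `control_pct`, and
#'   `case_prevalence_pct` (cases as a fraction of all analyzable samples).
#' @export
carrier_frequency <- function(strata, digits = 2) {
  a <- sum(strata$a); b <- sum(strata$b)
  c <- sum(strata$c); d <- sum(strata$d)
  list(case_carriers = a, cases = a + b,
       case_pct = signif(100 * a / (a + b), digits),
       control_carriers = c, controls = c + d,
       control_pct = signif(100 * c / (c + d), digits),
       case_prevalence_pct = signif(100 * (a + b) / (a + b + c + d), digits))
}
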