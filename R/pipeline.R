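## End-to-end orchestration: simulate (optional) -> variant QC -> sample QC
## -> ancestry PCA -> qualifying selection -> collapsing -> association ->
## secondary analyses -> reports. Every stage logs its input/output counts.

#' Pipeline configuration
#'
#' @param vcf,annotations,samples paths to the three pipeline inputs
#'   (ignored when `simulate` is supplied).
#' @param simulate optional [sim_config()]; when given, the study is
#'   simulated into `out_dir/sim/` first and its outputs are used as
#'   inputs.
#' @param thresholds a [qc_thresholds()].
#' @param rule a [qualifying_rule()].
#' @param stratify_by stratification for the primary analysis.
#' @param model_spec an [adjusted_model_spec()] for the covariate-adjusted
#'   burden model (fit for the top-ranked genes).
#' @param alpha_exome exome-wide significance threshold.
#' @param adjust_top number of top-ranked genes to refit with the
#'   adjusted model.
#' @param run_secondary run the sex/subtype-restricted secondary analyses.
#' @param out_dir output directory.
#' @param seed integer seed recorded and used for any stage randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, annotations = NULL, samples = NULL,
                            simulate = NULL,
                            thresholds = qc_thresholds(),
                            rule = qualifying_rule(),
                            stratify_by = "cohort",
                            model_spec = adjusted_model_spec(),
                            alpha_exome = ALPHA_EXOME,
                            adjust_top = 5L,
                            run_secondary = TRUE,
                            out_dir = tempfile("cmhburden_run_"),
                            seed = 1L) {
  if (is.null(simulate) &&
      (is.null(vcf) || is.null(annotations) || is.null(samples)))
    stop("either the three input paths or a simulation config is required")
  structure(as.list(environment()), class = "pipeline_config")
}

serialize_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(config), path)
}

#' Run the full collapsing-analysis pipeline
#'
#' Executes the stages in fixed order, writing each stage's artifact and a
#' machine-readable log line (JSON) with input/output counts to
#' `out_dir/pipeline_log.jsonl`. The configuration is copied verbatim
#' (YAML) into the output directory; reruns with an identical config and
#' seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the main in-memory artifacts (`results`,
#'   `secondary`, `qc_variants`, `qc_samples`, `pcs`, `coverage_report`,
#'   paths) and the output directory in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "pipeline_log.jsonl")
  if (file.exists(logfile)) unlink(logfile)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE, sep = "")
  }
  serialize_config(config, file.path(out, "config.yaml"))

  paths <- list(vcf = config$vcf, annotations = config$annotations,
                samples = config$samples)
  if (!is.null(config$simulate)) {
    paths <- simulate_study(config$simulate, file.path(out, "sim"))
    log_stage("simulate", seed = config$simulate$seed)
  }

  vc <- read_vcf(paths$vcf)
  smp <- read_samples(paths$samples)
  if (!identical(sample_ids(vc$genotypes), smp$sample_id)) {
    missing <- setdiff(sample_ids(vc$genotypes), smp$sample_id)
    if (length(missing))
      stop("VCF samples absent from the sample sheet: ",
           paste(utils::head(missing, 5), collapse = ", "))
    smp <- smp[match(sample_ids(vc$genotypes), smp$sample_id), , drop = FALSE]
  }
  ann <- read_annotations(paths$annotations,
                          known_variants = vc$variants$variant_id)
  log_stage("read", n_variants = nrow(vc$variants), n_samples = nrow(smp),
            n_annotations = nrow(ann))

  # variant QC
  vqc <- variant_qc(vc$variants, vc$genotypes, smp, config$thresholds)
  keep_v <- names(vqc$pass)[vqc$pass]
  geno_v <- subset_genotypes(vqc$genotypes, variants = keep_v)
  log_stage("variant_qc", n_in = nrow(vc$variants), n_pass = length(keep_v))
  utils::write.table(
    data.frame(variant_id = names(vqc$pass), pass = vqc$pass,
               reasons = vapply(vqc$reasons, paste, character(1),
                                collapse = ";")),
    file.path(out, "variant_qc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # ancestry PCA + kinship on LD-pruned common variants (MAF >= 5%)
  af <- colMeans(geno_v$dosage, na.rm = TRUE) / 2
  common <- pmin(af, 1 - af) >= 0.05 & !is.na(af)
  pcs <- NULL; kin <- NULL
  if (sum(common) >= config$thresholds$n_pcs) {
    dos_c <- geno_v$dosage[, common, drop = FALSE]
    pruned <- ld_prune(dos_c, config$thresholds$ld_r2_max)
    log_stage("ld_prune", n_common = sum(common), n_retained = length(pruned))
    if (length(pruned) >= config$thresholds$n_pcs) {
      pcs <- compute_pca(dos_c[, pruned, drop = FALSE],
                         config$thresholds$n_pcs)
      kin <- king_kinship(dos_c[, pruned, drop = FALSE])
    }
  }

  # sample QC
  sqc <- sample_qc(smp, geno_v, config$thresholds, pcs = pcs, kinship = kin)
  keep_s <- names(sqc$pass)[sqc$pass]
  log_stage("sample_qc", n_in = nrow(smp), n_pass = length(keep_s))
  smp2 <- smp[match(keep_s, smp$sample_id), , drop = FALSE]
  geno2 <- subset_genotypes(geno_v, samples = keep_s)
  pcs2 <- if (!is.null(pcs)) pcs[keep_s, , drop = FALSE] else NULL

  # qualifying selection and collapsing
  mafs <- group_maf(geno2, smp2)
  qual <- select_qualifying(ann, mafs, config$rule)
  carriers <- collapse_carriers(geno2, qual, ann)
  log_stage("collapse", n_qualifying = length(qual),
            n_genes = nrow(carriers$carrier))

  # association
  tables <- stratum_tables(carriers, smp2, config$stratify_by)
  results <- gene_burden_scan(tables, config$alpha_exome)
  evc <- exome_variant_count(geno2)
  if (!is.null(pcs2) && config$adjust_top > 0) {
    covar <- data.frame(pcs2, exome_variant_count = evc[keep_s],
                        check.names = FALSE)
    top <- utils::head(results$gene[!is.na(results$p_cmh)],
                       config$adjust_top)
    for (g in top) {
      fit <- adjusted_burden_model(carriers$carrier[g, keep_s],
                                   smp2$is_case, covar, config$model_spec)
      results$p_adjusted[results$gene == g] <- fit$p
    }
  }
  write_burden_results(results, file.path(out, "burden_results.tsv"))
  log_stage("association", n_genes = nrow(results),
            n_significant = sum(results$exome_wide_significant, na.rm = TRUE))

  secondary <- NULL
  if (isTRUE(config$run_secondary)) {
    secondary <- secondary_analyses(carriers, smp2, config$alpha_exome)
    for (nm in names(secondary))
      write_burden_results(secondary[[nm]],
                           file.path(out, paste0("secondary_", nm, ".tsv")))
    log_stage("secondary", analyses = names(secondary))
  }

  covrep <- coverage_profile_report(geno2, smp2)
  utils::write.table(covrep, file.path(out, "coverage_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("report", done = TRUE)

  invisible(list(out_dir = out, results = results, secondary = secondary,
                 qc_variants = vqc, qc_samples = sqc, pcs = pcs2,
                 carriers = carriers, samples = smp2, genotypes = geno2,
                 coverage_report = covrep, paths = paths))
}

#' Exome-wide variant-count profile by phenotype group
#'
#' Report-only diagnostic for case-control coverage bias: per phenotype
#' group, quantiles of the per-sample exome-wide variant count, plus a
#' two-sample Wilcoxon location test comparing cases with controls (in the
#' `location_p` attribute).
#'
#' @param genotypes QC-passing [genotype_matrix].
#' @param samples sample sheet aligned with the genotype rows.
#' @return Data frame, one row per phenotype group, with count quantiles.
#' @export
coverage_profile_report <- function(genotypes, samples) {
  evc <- exome_variant_count(genotypes)
  groups <- split(evc, samples$phenotype)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    qs <- stats::quantile(groups[[g]], c(0.05, 0.25, 0.5, 0.75, 0.95))
    data.frame(group = g, n = length(groups[[g]]),
               q05 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4],
               q95 = qs[5], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  p <- if (any(samples$is_case) && any(!samples$is_case)) {
    stats::wilcox.test(evc[samples$is_case], evc[!samples$is_case],
                       exact = FALSE)$p.value
  } else NA_real_
  attr(out, "location_p") <- p
  out
}
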