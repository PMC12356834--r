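## Synthetic multi-cohort case-control exome generator.
##
## Emulates the statistical structure the collapsing analysis assumes:
## country-stratified case/control cohorts, a rare-skewed site frequency
## spectrum, consequence and CADD annotations with non-qualifying decoys,
## spiked risk genes with a configurable control carrier frequency and
## carrier odds ratio, a separate block of common variants carrying an
## ancestry gradient and induced LD for the pruning/PCA steps, and
## sequencing artifacts (per-call depth, binomial allelic-balance noise,
## base and batch-differential missingness).

#' Specification of a spiked risk gene
#'
#' @param gene gene symbol to spike.
#' @param control_carrier_freq cumulative qualifying-variant carrier
#'   frequency among controls (probability in (0, 1)).
#' @param odds_ratio target carrier odds ratio for case status; case carrier
#'   probability follows the exact odds transform
#'   `p = OR * q / (1 - q + OR * q)`.
#' @param per_stratum_or optional named numeric vector of stratum-specific
#'   odds-ratio overrides.
#' @return A `risk_gene_spec` list.
#' @export
risk_gene_spec <- function(gene, control_carrier_freq = 0.01,
                           odds_ratio = 2.0, per_stratum_or = NULL) {
  stopifnot(control_carrier_freq > 0, control_carrier_freq < 1,
            odds_ratio > 0)
  structure(list(gene = gene, control_carrier_freq = control_carrier_freq,
                 odds_ratio = odds_ratio, per_stratum_or = per_stratum_or),
            class = "risk_gene_spec")
}

#' Simulation configuration
#'
#' Defaults describe a four-country case-control exome study scaled to desk
#' size: the case:control ratio, female-dominated case series (62% female,
#' matching the reported 38% male fraction), APAC subtype fraction (~31% of
#' cases), one spiked risk gene at 1% control carrier frequency with carrier
#' odds ratio 2.14, and a rare-skewed Beta(0.2, 200) allele-frequency law
#' truncated at 5%. A separate common-variant block (allele frequencies
#' Uniform(0.05, 0.5) with stratum-specific shifts) feeds the LD-pruning and
#' ancestry-PCA steps; 10% of common variants are emitted as near-duplicates
#' to induce LD.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of `(seed, config)`.
#' @param strata_spec data frame with columns `label`, `n_cases`,
#'   `n_controls`.
#' @param n_genes number of genes in the rare-variant block.
#' @param variants_per_gene mean of the (zero-truncated Poisson) per-gene
#'   variant count.
#' @param af_beta shape parameters of the Beta allele-frequency law for rare
#'   variants.
#' @param af_max truncation point of the rare allele-frequency law.
#' @param consequence_probs named probability vector over consequence
#'   classes; must sum to 1.
#' @param risk_genes list of [risk_gene_spec()] objects; gene symbols must
#'   be among the simulated genes (`GENE0001` ... ).
#' @param mean_depth mean of the Poisson per-call depth law.
#' @param ab_noise extra allelic-balance noise: heterozygous alternate-read
#'   counts are drawn Binomial(depth, p) with p ~ Beta centred at 0.5 and
#'   precision decreasing in `ab_noise`; 0 gives p = 0.5 exactly.
#' @param base_missingness per-call missing probability applied to all
#'   samples.
#' @param stratum_missingness named numeric vector of additional per-call
#'   missing probability by stratum (batch effects).
#' @param ancestry_shift magnitude of the per-stratum common-variant
#'   allele-frequency gradient (0 = no population structure).
#' @param n_common number of common variants in the ancestry block.
#' @param ld_dup_frac fraction of common variants re-emitted as noisy copies
#'   (induces LD for the pruning step).
#' @param sex_case_fraction fraction of cases that are female.
#' @param apac_fraction fraction of cases with the acute (APAC) subtype.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       strata_spec = data.frame(
                         label = c("Singapore", "HongKong", "Japan", "Vietnam"),
                         n_cases = c(30L, 25L, 25L, 20L),
                         n_controls = c(35L, 30L, 30L, 25L)),
                       n_genes = 100L,
                       variants_per_gene = 8,
                       af_beta = c(0.2, 200),
                       af_max = 0.05,
                       consequence_probs = c(synonymous = 0.35, missense = 0.45,
                                             stop_gained = 0.05, frameshift = 0.05,
                                             splice_canonical = 0.03,
                                             start_lost = 0.02, other = 0.05),
                       risk_genes = list(risk_gene_spec("GENE0001",
                                                        control_carrier_freq = 0.01,
                                                        odds_ratio = 2.14)),
                       mean_depth = 60,
                       ab_noise = 0,
                       base_missingness = 0.005,
                       stratum_missingness = NULL,
                       ancestry_shift = 0.02,
                       n_common = 2000L,
                       ld_dup_frac = 0.1,
                       sex_case_fraction = 0.62,
                       apac_fraction = 0.31) {
  stopifnot(all(c("label", "n_cases", "n_controls") %in% names(strata_spec)),
            all(strata_spec$n_cases >= 0), all(strata_spec$n_controls >= 0),
            abs(sum(consequence_probs) - 1) < 1e-8,
            all(names(consequence_probs) %in% CONSEQUENCE_LEVELS),
            base_missingness >= 0, base_missingness < 1,
            mean_depth > 0, ab_noise >= 0,
            sex_case_fraction >= 0, sex_case_fraction <= 1,
            apac_fraction >= 0, apac_fraction <= 1)
  cfg <- structure(as.list(environment()), class = "sim_config")
  for (rg in risk_genes) {
    stopifnot(inherits(rg, "risk_gene_spec"))
    ors <- c(rg$odds_ratio, rg$per_stratum_or)
    q <- rg$control_carrier_freq
    if (any(ors * q / (1 - q + ors * q) >= 1 - 1e-6))
      stop("risk gene ", rg$gene,
           ": implied case carrier probability is numerically 1")
  }
  cfg
}

#' Gene-level carrier frequency implied by per-variant allele frequencies
#'
#' Under Hardy-Weinberg genotype frequencies and mutual independence of the
#' variants, the probability that a diploid individual carries at least one
#' alternate allele across the set is `1 - prod((1 - af)^2)`.
#'
#' @param afs numeric vector of allele frequencies, each in `[0, 1]`.
#' @return Carrier probability in `[0, 1]`; 0 for an empty set.
#' @export
carrier_freq_from_afs <- function(afs) {
  if (length(afs) == 0) return(0)
  if (any(afs < 0 | afs > 1)) stop("allele frequencies must lie in [0, 1]")
  1 - prod((1 - afs)^2)
}

case_carrier_prob <- function(q, or) or * q / (1 - q + or * q)

#' Inject batch-differential missingness into a genotype matrix
#'
#' Sets calls to missing with an extra per-call probability that depends on
#' the sample's stratum or phenotype, emulating batch effects that the
#' differential-missingness filter is designed to catch.
#'
#' @param genotypes a [genotype_matrix].
#' @param samples sample sheet data frame aligned with the genotype rows.
#' @param offsets named numeric vector: names are stratum labels, `"case"`
#'   or `"control"`; values are extra missing probabilities in `[0, 1]`.
#' @param variant_ids optional subset of variant ids to perturb (default:
#'   all).
#' @return A perturbed copy of `genotypes`.
#' @export
inject_batch_missingness <- function(genotypes, samples, offsets,
                                     variant_ids = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(offsets >= 0), all(offsets <= 1))
  ids <- sample_ids(genotypes)
  stopifnot(identical(ids, samples$sample_id))
  p <- rep(0, length(ids))
  for (key in names(offsets)) {
    hit <- if (key %in% c("case", "control")) {
      samples$is_case == (key == "case")
    } else samples$stratum == key
    p[hit] <- p[hit] + offsets[[key]]
  }
  if (any(p > 1)) stop("resulting missing probability exceeds 1")
  cols <- if (is.null(variant_ids)) seq_len(ncol(genotypes$dosage)) else
    match(variant_ids, variant_ids(genotypes))
  dos <- genotypes$dosage
  for (j in cols) {
    drop <- stats::runif(length(p)) < p
    dos[drop, j] <- NA_integer_
  }
  genotype_matrix(dos, genotypes$depth, genotypes$alt_frac)
}

#' Simulate a stratified case-control exome study
#'
#' Writes the three pipeline inputs (VCF with GT:DP:AD, annotation TSV,
#' sample sheet TSV) plus a truth table recording, per gene and stratum, the
#' generative control carrier frequency and odds ratio. Risk-gene carrier
#' status is drawn per sample with control carrier probability `q` and case
#' carrier probability from the exact odds transform; each carrier receives
#' one qualifying heterozygous variant in the gene. All other gene-variant
#' genotypes are drawn independently of phenotype under Hardy-Weinberg.
#' Sequencing artifacts (depth, allelic-balance noise on heterozygotes,
#' missingness) are applied afterwards.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Named list of paths: `vcf`, `annotations`, `samples`, `truth`.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  ## ---- samples --------------------------------------------------------
  ss <- config$strata_spec
  mk <- function(label, n, case) {
    if (n == 0) return(NULL)
    data.frame(stratum = label, is_case = case, stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  rows <- do.call(rbind, unlist(lapply(seq_len(nrow(ss)), function(i) {
    list(mk(ss$label[i], ss$n_cases[i], TRUE),
         mk(ss$label[i], ss$n_controls[i], FALSE))
  }), recursive = FALSE))
  n <- nrow(rows)
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    stratum = rows$stratum,
    sex = ifelse(rows$is_case,
                 ifelse(stats::runif(n) < config$sex_case_fraction, "female", "male"),
                 ifelse(stats::runif(n) < 0.5, "female", "male")),
    phenotype = ifelse(rows$is_case,
                       ifelse(stats::runif(n) < config$apac_fraction,
                              "APAC", "PACG_chronic"),
                       "control"),
    frac_bases_20x = round(pmin(1, stats::rbeta(n, 90, 6)), 4),
    stringsAsFactors = FALSE
  )
  is_case <- rows$is_case

  ## ---- rare-variant block ---------------------------------------------
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  risk_idx <- vapply(config$risk_genes, function(r) match(r$gene, genes), 1L)
  if (anyNA(risk_idx)) stop("risk gene symbol not among simulated genes")
  nv <- pmax(1L, stats::rpois(config$n_genes, config$variants_per_gene))
  gene_of <- rep(genes, nv)
  m_rare <- length(gene_of)
  af <- stats::rbeta(m_rare, config$af_beta[1], config$af_beta[2])
  af <- pmin(af, config$af_max)
  cons <- sample(names(config$consequence_probs), m_rare, replace = TRUE,
                 prob = config$consequence_probs)
  cadd <- rep(NA_real_, m_rare)
  mis <- cons == "missense"
  cadd[mis] <- pmax(0, stats::rnorm(sum(mis), 15, 8))
  syn <- cons == "synonymous"
  cadd[syn] <- pmax(0, stats::rnorm(sum(syn), 5, 3))
  ptv <- cons %in% c("stop_gained", "start_lost", "frameshift", "splice_canonical")
  cadd[ptv] <- pmax(0, stats::rnorm(sum(ptv), 35, 5))

  ## force risk-gene variants to be qualifying (rare + missense CADD >= 15
  ## or PTV), with one low-CADD decoy per risk gene to exercise the selector
  qual_variant <- logical(m_rare)
  for (k in seq_along(config$risk_genes)) {
    idx <- which(gene_of == genes[risk_idx[k]])
    qidx <- idx
    if (length(idx) > 1) {
      decoy <- idx[length(idx)]
      cons[decoy] <- "missense"
      cadd[decoy] <- stats::runif(1, 0, 8)
      qidx <- idx[-length(idx)]
    }
    cons[qidx] <- ifelse(stats::runif(length(qidx)) < 0.8, "missense",
                         "stop_gained")
    cadd[qidx][cons[qidx] == "missense"] <-
      stats::runif(sum(cons[qidx] == "missense"), 15, 35)
    cadd[qidx][cons[qidx] == "stop_gained"] <- NA_real_
    af[idx] <- pmin(af[idx], 0.004)
    qual_variant[qidx] <- TRUE
  }

  dosage <- matrix(0L, n, m_rare)
  # non-risk genotypes: HWE draws, independent of phenotype
  nonrisk_cols <- !(gene_of %in% genes[risk_idx])
  dosage[, nonrisk_cols] <- stats::rbinom(n * sum(nonrisk_cols), 2,
                                          rep(af[nonrisk_cols], each = n))

  truth <- NULL
  strat_levels <- ss$label
  for (k in seq_along(config$risk_genes)) {
    rg <- config$risk_genes[[k]]
    idx <- which(gene_of == genes[risk_idx[k]])
    qidx <- idx[qual_variant[idx]]
    for (s in strat_levels) {
      or_s <- if (!is.null(rg$per_stratum_or) && s %in% names(rg$per_stratum_or))
        rg$per_stratum_or[[s]] else rg$odds_ratio
      q <- rg$control_carrier_freq
      p1 <- case_carrier_prob(q, or_s)
      in_s <- samples$stratum == s
      pr <- ifelse(is_case[in_s], p1, q)
      carrier <- stats::runif(sum(in_s)) < pr
      # carriers spread uniformly over the gene's qualifying variants so no
      # single spiked variant drifts above the rare-MAF bound
      pick <- qidx[sample.int(length(qidx), sum(carrier), replace = TRUE)]
      rows_s <- which(in_s)[carrier]
      for (i in seq_along(rows_s)) dosage[rows_s[i], pick[i]] <- 1L
      truth <- rbind(truth, data.frame(gene = rg$gene, stratum = s,
                                       q_control = q, odds_ratio = or_s,
                                       stringsAsFactors = FALSE))
    }
    # decoy variants in the risk gene segregate independently of phenotype
    didx <- idx[!qual_variant[idx]]
    if (length(didx))
      dosage[, didx] <- stats::rbinom(n * length(didx), 2,
                                      rep(af[didx], each = n))
  }
  # truth rows for non-risk genes: null OR
  null_truth <- expand.grid(gene = setdiff(genes, genes[risk_idx]),
                            stratum = strat_levels, stringsAsFactors = FALSE)
  if (nrow(null_truth)) {
    null_truth$q_control <- NA_real_
    null_truth$odds_ratio <- 1
    truth <- rbind(truth, null_truth)
  }

  ## ---- common-variant ancestry block ----------------------------------
  m_common <- config$n_common
  af_c <- stats::runif(m_common, 0.05, 0.5)
  shift_grid <- seq(-1, 1, length.out = nrow(ss)) * config$ancestry_shift
  names(shift_grid) <- ss$label
  dos_c <- matrix(0L, n, m_common)
  for (s in strat_levels) {
    in_s <- samples$stratum == s
    af_s <- pmin(0.95, pmax(0.01, af_c + shift_grid[[s]]))
    dos_c[in_s, ] <- stats::rbinom(sum(in_s) * m_common, 2,
                                   rep(af_s, each = sum(in_s)))
  }
  # LD: noisy duplicates of a fraction of common variants
  n_dup <- floor(m_common * config$ld_dup_frac)
  if (n_dup > 0) {
    src <- sample.int(m_common, n_dup)
    dup <- dos_c[, src, drop = FALSE]
    flip <- matrix(stats::runif(n * n_dup) < 0.02, n, n_dup)
    dup[flip] <- stats::rbinom(sum(flip), 2, rep(af_c[src], each = n)[flip])
    dos_c <- cbind(dos_c, dup)
    m_common <- m_common + n_dup
  }

  ## ---- assemble site table --------------------------------------------
  m <- m_rare + m_common
  dosage <- cbind(dosage, dos_c)
  vid <- sprintf("v%06d", seq_len(m))
  chrom <- c(rep("1", m_rare), rep("2", m_common))
  pos <- c(seq_len(m_rare) * 100L, seq_len(m_common) * 100L)
  refs <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 character(1))

  ## ---- sequencing artifacts -------------------------------------------
  depth <- matrix(stats::rpois(n * m, config$mean_depth), n, m)
  alt_reads <- matrix(0L, n, m)
  het <- which(dosage == 1L)
  p_het <- if (config$ab_noise > 0) {
    prec <- 1 / config$ab_noise
    stats::rbeta(length(het), prec / 2, prec / 2)
  } else rep(0.5, length(het))
  alt_reads[het] <- stats::rbinom(length(het), depth[het], p_het)
  hom <- which(dosage == 2L)
  alt_reads[hom] <- depth[hom] - stats::rbinom(length(hom), depth[hom], 0.01)
  homref <- which(dosage == 0L)
  alt_reads[homref] <- stats::rbinom(length(homref), depth[homref], 0.005)

  miss_p <- rep(config$base_missingness, n)
  if (!is.null(config$stratum_missingness)) {
    for (s in names(config$stratum_missingness))
      miss_p[samples$stratum == s] <- miss_p[samples$stratum == s] +
        config$stratum_missingness[[s]]
  }
  if (any(miss_p > 1)) stop("total missingness probability exceeds 1")
  drop <- matrix(stats::runif(n * m) < miss_p, n, m)
  gt_dos <- dosage
  gt_dos[drop] <- NA_integer_

  ## ---- write outputs ---------------------------------------------------
  paths <- list(vcf = file.path(out_dir, "study.vcf"),
                annotations = file.path(out_dir, "annotations.tsv"),
                samples = file.path(out_dir, "samples.tsv"),
                truth = file.path(out_dir, "truth.tsv"))

  write_sim_vcf(paths$vcf, samples$sample_id, vid, chrom, pos, refs, alts,
                gt_dos, depth, alt_reads)

  ann <- data.frame(variant_id = vid[seq_len(m_rare)],
                    gene = gene_of,
                    consequence = cons,
                    cadd_scaled = ifelse(is.na(cadd), NA, round(cadd, 2)),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  utils::write.table(samples, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# Plain-text VCF 4.2 writer for the simulator output (GT:DP:AD per call).
write_sim_vcf <- function(path, sample_names, vid, chrom, pos, ref, alt,
                          dosage, depth, alt_reads) {
  n <- nrow(dosage); m <- ncol(dosage)
  gt_str <- matrix("./.", n, m)
  gt_str[dosage == 0L] <- "0/0"
  gt_str[dosage == 1L] <- "0/1"
  gt_str[dosage == 2L] <- "1/1"
  ref_reads <- depth - alt_reads
  cell <- matrix(paste0(gt_str, ":", depth, ":", ref_reads, ",", alt_reads),
                 n, m)
  header <- c("##fileformat=VCFv4.2",
              "##source=cmhburden-simulate",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c(chrom[j], pos[j], vid[j], ref[j], alt[j], ".", "PASS", ".",
            "GT:DP:AD", cell[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
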