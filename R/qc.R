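## Variant- and sample-level quality control, ancestry PCA and relatedness.

#' Quality-control thresholds
#'
#' Defaults follow the standard stringent exome QC cascade: per-call depth
#' >= 10 reads, variant call rate > 95%, Hardy-Weinberg exact P >= 1e-4
#' within every country stratum, case-control differential-missingness
#' Fisher P >= 1e-3, heterozygous allelic balance strictly inside
#' (0.20, 0.80), sample call rate >= 95%, >= 80% of target bases at 20x,
#' LD pruning at pairwise r^2 < 0.1, top 5 ancestry principal components,
#' and robust-z outlier cutoffs of 4 median absolute deviations.
#'
#' @param min_depth minimum per-call read depth.
#' @param min_variant_call_rate variant-level call-rate threshold
#'   (strictly greater than).
#' @param hwe_alpha Hardy-Weinberg exact-test exclusion alpha.
#' @param diff_missing_alpha differential-missingness exclusion alpha.
#' @param ab_low,ab_high allelic-balance window (strict inequalities).
#' @param min_sample_call_rate sample completion-rate threshold (at least).
#' @param min_frac_bases_20x coverage threshold (strictly greater than).
#' @param ld_r2_max maximum pairwise r^2 among retained common variants.
#' @param n_pcs number of ancestry principal components.
#' @param het_outlier_k,singleton_outlier_k,pca_outlier_k robust-z (MAD)
#'   cutoffs for the sample outlier screens.
#' @param kinship_dup,kinship_related KING-robust kinship thresholds for
#'   duplicates and first-degree relatives.
#' @param ab_action `"mask"` (set failing heterozygous calls missing,
#'   default) or `"drop"` (fail the whole variant if any het call falls
#'   outside the window).
#' @param vqslod_min optional VQSLOD pass-through threshold for real data;
#'   `NULL` disables the check.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_depth = 10,
                          min_variant_call_rate = 0.95,
                          hwe_alpha = 1e-4,
                          diff_missing_alpha = 1e-3,
                          ab_low = 0.20, ab_high = 0.80,
                          min_sample_call_rate = 0.95,
                          min_frac_bases_20x = 0.80,
                          ld_r2_max = 0.10,
                          n_pcs = 5,
                          het_outlier_k = 4,
                          singleton_outlier_k = 4,
                          pca_outlier_k = 4,
                          kinship_dup = 0.354,
                          kinship_related = 0.0884,
                          ab_action = c("mask", "drop"),
                          vqslod_min = NULL) {
  stopifnot(ab_low > 0, ab_low < ab_high, ab_high < 1,
            hwe_alpha > 0, hwe_alpha < 1,
            diff_missing_alpha > 0, diff_missing_alpha < 1)
  ab_action <- match.arg(ab_action)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the diploid sample size and the minor
#' allele count, the two-sided P value is the sum of the conditional
#' probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed count.
#'
#' @param n_homref,n_het,n_homalt genotype counts (non-negative integers,
#'   positive total).
#' @return Two-sided exact P value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n == 0) stop("total genotype count must be positive")
  n_alt <- 2 * n_homalt + n_het
  n1 <- min(n_alt, 2 * n - n_alt)          # minor allele count
  if (n1 == 0) return(1)
  hets <- seq(n1 %% 2, n1, by = 2)         # feasible het counts (parity)
  logp <- lfactorial(n) - lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n1 + hets) / 2) + hets * log(2) +
    lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n)
  p <- exp(logp)
  p_obs <- p[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele count")
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

#' Mask heterozygous calls with extreme allelic balance
#'
#' Heterozygous calls whose alternate-read fraction falls outside the open
#' interval `(ab_low, ab_high)` are set to missing (boundary values fail:
#' the window is strict). Homozygous calls are untouched. Heterozygous
#' calls with no allelic-depth information are skipped and counted.
#'
#' @param genotypes a [genotype_matrix].
#' @param thresholds a [qc_thresholds()].
#' @return List: `genotypes` (masked copy), `n_masked`, `n_skipped` (hets
#'   lacking an alternate-read fraction).
#' @export
apply_allelic_balance <- function(genotypes, thresholds = qc_thresholds()) {
  dos <- genotypes$dosage
  af <- genotypes$alt_frac
  if (is.null(af)) {
    return(list(genotypes = genotypes, n_masked = 0L,
                n_skipped = sum(dos == 1L, na.rm = TRUE)))
  }
  het <- !is.na(dos) & dos == 1L
  no_af <- het & is.na(af)
  bad <- het & !is.na(af) & (af <= thresholds$ab_low | af >= thresholds$ab_high)
  dos[bad] <- NA_integer_
  list(genotypes = genotype_matrix(dos, genotypes$depth, genotypes$alt_frac),
       n_masked = sum(bad), n_skipped = sum(no_af))
}

#' Case-control differential-missingness test
#'
#' Two-sided Fisher exact test on the called/missing by case/control 2x2
#' table for one variant.
#'
#' @param called_cases,missing_cases,called_controls,missing_controls
#'   non-negative counts; both row totals (cases, controls) must be
#'   positive.
#' @return Two-sided P value; 1 by convention when a column total is zero.
#' @export
differential_missingness_test <- function(called_cases, missing_cases,
                                          called_controls, missing_controls) {
  stopifnot(called_cases + missing_cases > 0,
            called_controls + missing_controls > 0)
  if (called_cases + called_controls == 0 ||
      missing_cases + missing_controls == 0) return(1)
  m <- matrix(c(called_cases, missing_cases, called_controls, missing_controls),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Variant-level quality control cascade
#'
#' Applies, in fixed order: (1) per-call depth masking (< `min_depth` reads
#' set missing); (2) allelic-balance masking of heterozygotes; (3) variant
#' call rate (> `min_variant_call_rate` required, evaluated after masking);
#' (4) Hardy-Weinberg exact test within every country stratum on all
#' samples of the stratum (fail if P < `hwe_alpha` in any stratum);
#' (5) case-control differential missingness (fail if
#' P < `diff_missing_alpha`); (6) the multi-allelic sibling rule: if any
#' decomposed record of a site fails, all records of that site fail. Every
#' step is blind to phenotype except differential missingness.
#'
#' @param variants variant table from [read_vcf()].
#' @param genotypes matching [genotype_matrix].
#' @param samples sample sheet aligned with the genotype rows.
#' @param thresholds a [qc_thresholds()].
#' @return A `variant_qc_report`: list with `genotypes` (masked matrix),
#'   `pass` (named logical per variant), `reasons` (named list of ordered
#'   failure reasons), and `steps` (data frame of per-step counts).
#' @export
variant_qc <- function(variants, genotypes, samples,
                       thresholds = qc_thresholds()) {
  stopifnot(identical(variant_ids(genotypes), variants$variant_id),
            identical(sample_ids(genotypes), samples$sample_id))
  vids <- variants$variant_id
  reasons <- stats::setNames(vector("list", length(vids)), vids)
  add_reason <- function(fail, why) {
    for (v in vids[fail]) reasons[[v]] <<- c(reasons[[v]], why)
    reasons
  }
  steps <- list()

  # (0) optional VQSLOD pass-through for real data
  if (!is.null(thresholds$vqslod_min)) {
    fail_vq <- !is.na(variants$vqslod) & variants$vqslod < thresholds$vqslod_min
    reasons <- add_reason(fail_vq, "vqslod")
    steps$vqslod <- sum(fail_vq)
  }

  # (1) depth mask
  dos <- genotypes$dosage
  n_depth_masked <- 0L
  if (!is.null(genotypes$depth)) {
    low <- !is.na(dos) & !is.na(genotypes$depth) &
      genotypes$depth < thresholds$min_depth
    n_depth_masked <- sum(low)
    dos[low] <- NA_integer_
  }
  geno <- genotype_matrix(dos, genotypes$depth, genotypes$alt_frac)
  steps$depth_masked_calls <- n_depth_masked

  # (2) allelic balance
  ab <- apply_allelic_balance(geno, thresholds)
  geno <- ab$genotypes
  steps$ab_masked_calls <- ab$n_masked
  if (ab$n_skipped > 0)
    steps$ab_skipped_calls <- ab$n_skipped
  if (thresholds$ab_action == "drop") {
    had_bad <- colSums(is.na(geno$dosage) & !is.na(dos)) > 0  # masked here
    reasons <- add_reason(had_bad, "allelic_balance")
  }

  # (3) call rate
  cr <- variant_call_rate(geno)
  fail_cr <- !(cr > thresholds$min_variant_call_rate)
  reasons <- add_reason(fail_cr, "call_rate")
  steps$call_rate <- sum(fail_cr)

  # (4) HWE per country stratum, all samples
  fail_hwe <- logical(length(vids))
  for (s in unique(samples$stratum)) {
    in_s <- samples$stratum == s
    if (!any(in_s)) {
      warning("stratum ", s, " has no samples; skipped for HWE")
      next
    }
    d <- geno$dosage[in_s, , drop = FALSE]
    n0 <- colSums(d == 0L, na.rm = TRUE)
    n1 <- colSums(d == 1L, na.rm = TRUE)
    n2 <- colSums(d == 2L, na.rm = TRUE)
    tot <- n0 + n1 + n2
    p <- rep(1, length(vids))
    nz <- tot > 0
    p[nz] <- mapply(hwe_exact_test, n0[nz], n1[nz], n2[nz])
    fail_hwe <- fail_hwe | (p < thresholds$hwe_alpha)
  }
  reasons <- add_reason(fail_hwe, "hwe")
  steps$hwe <- sum(fail_hwe)

  # (5) differential missingness
  case <- samples$is_case
  dmiss <- is.na(geno$dosage)
  ca_called <- colSums(!dmiss[case, , drop = FALSE])
  ca_missing <- colSums(dmiss[case, , drop = FALSE])
  co_called <- colSums(!dmiss[!case, , drop = FALSE])
  co_missing <- colSums(dmiss[!case, , drop = FALSE])
  p_dm <- mapply(differential_missingness_test,
                 ca_called, ca_missing, co_called, co_missing)
  fail_dm <- p_dm < thresholds$diff_missing_alpha
  reasons <- add_reason(fail_dm, "differential_missingness")
  steps$differential_missingness <- sum(fail_dm)

  # (6) sibling rule for decomposed multi-allelic sites
  failed <- lengths(reasons) > 0
  sib_fail <- variants$parent_site_id %in%
    unique(variants$parent_site_id[failed])
  new_fail <- sib_fail & !failed
  reasons <- add_reason(new_fail, "sibling_failed")
  steps$sibling_rule <- sum(new_fail)

  pass <- stats::setNames(lengths(reasons) == 0, vids)
  structure(list(genotypes = geno, pass = pass, reasons = reasons,
                 steps = data.frame(step = names(steps),
                                    count = unlist(steps, use.names = FALSE),
                                    stringsAsFactors = FALSE)),
            class = "variant_qc_report")
}

#' @export
print.variant_qc_report <- function(x, ...) {
  cat(sprintf("variant_qc_report: %d/%d variants pass\n",
              sum(x$pass), length(x$pass)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Greedy LD pruning of common variants
#'
#' Left-to-right scan: a variant is dropped when its squared Pearson
#' correlation of dosages (pairwise-complete) with any already-retained
#' variant exceeds `r2_max`. Zero-variance variants are excluded before
#' pruning. The retained set therefore has all pairwise r^2 <= `r2_max`.
#'
#' @param dosage numeric matrix, samples x variants, `NA` allowed.
#' @param r2_max maximum allowed pairwise r^2 (default 0.1).
#' @return Character vector of retained variant ids (column names).
#' @export
ld_prune <- function(dosage, r2_max = 0.1) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  v <- apply(dosage, 2, stats::var, na.rm = TRUE)
  keep_cols <- which(!is.na(v) & v > 0)
  retained <- integer(0)
  for (j in keep_cols) {
    if (length(retained)) {
      r <- suppressWarnings(
        stats::cor(dosage[, j], dosage[, retained, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      if (any(r^2 > r2_max)) next
    }
    retained <- c(retained, j)
  }
  colnames(dosage)[retained]
}

#' Ancestry principal components from common-variant dosages
#'
#' Dosages are mean-imputed per variant, centred at twice the estimated
#' allele frequency and scaled by `sqrt(2 p (1 - p))` (the binomial
#' standard deviation), then decomposed by SVD. Scores are the projections
#' on the top `n_pcs` axes; each axis sign is fixed by making its
#' largest-magnitude variant loading positive, so results are deterministic.
#'
#' @param dosage numeric matrix, samples x variants, `NA` allowed.
#' @param n_pcs number of components to return.
#' @return Numeric matrix samples x `n_pcs` with columns `PC1`, `PC2`, ...
#' @export
compute_pca <- function(dosage, n_pcs = 5) {
  stopifnot(is.matrix(dosage))
  p_hat <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  dosage <- dosage[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  if (ncol(dosage) < n_pcs)
    stop("need at least n_pcs variants after dropping constant columns")
  x <- sweep(dosage, 2, 2 * p_hat)
  x <- sweep(x, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  x[is.na(x)] <- 0                      # mean imputation after centring
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  for (k in seq_len(n_pcs)) {
    load_k <- sv$v[, k]
    if (load_k[which.max(abs(load_k))] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(rownames(dosage), paste0("PC", seq_len(n_pcs)))
  scores
}

#' KING-robust pairwise kinship
#'
#' Between-family robust kinship estimator from identity counts:
#' `phi = (N_het,het - 2 * N_opposite_hom) / (N_het_i + N_het_j)`, with all
#' counts restricted to sites non-missing in both samples. Duplicates (or
#' monozygotic twins) give phi ~ 0.5, first-degree relatives ~ 0.25.
#'
#' @param dosage numeric matrix, samples x variants, `NA` allowed.
#' @return Symmetric numeric matrix of kinship estimates (diagonal `NA`).
#' @export
king_kinship <- function(dosage) {
  m_ok <- (!is.na(dosage)) * 1
  h <- (dosage == 1L & !is.na(dosage)) * 1
  a0 <- (dosage == 0L & !is.na(dosage)) * 1
  a2 <- (dosage == 2L & !is.na(dosage)) * 1
  n_hethet <- h %*% t(h)
  n_opp <- a0 %*% t(a2) + a2 %*% t(a0)
  het_shared_i <- h %*% t(m_ok)          # hets of i at sites called in j
  denom <- het_shared_i + t(het_shared_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[!is.finite(phi)] <- NA
  diag(phi) <- NA
  dimnames(phi) <- list(rownames(dosage), rownames(dosage))
  phi
}

robust_z <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  madv <- stats::mad(x, na.rm = TRUE)
  if (!is.finite(madv) || madv == 0) return(rep(0, length(x)))
  (x - med) / madv
}

#' Count per-sample singletons
#'
#' A singleton is a variant whose alternate allele is observed in exactly
#' one sample of the dataset; the count per sample is the number of
#' singletons that sample carries.
#'
#' @param genotypes a [genotype_matrix].
#' @return Named integer vector per sample.
#' @export
count_singletons <- function(genotypes) {
  dos <- genotypes$dosage
  carriers <- colSums(dos >= 1L, na.rm = TRUE)
  single <- carriers == 1L
  if (!any(single))
    return(stats::setNames(integer(nrow(dos)), rownames(dos)))
  d <- dos[, single, drop = FALSE]
  d[is.na(d)] <- 0L
  stats::setNames(as.integer(rowSums(d >= 1L)), rownames(dos))
}

#' Sample-level quality control cascade
#'
#' Fails samples with insufficient target coverage
#' (`frac_bases_20x <= min_frac_bases_20x`), low genotype completion rate,
#' outlying heterozygote counts (robust z within country stratum), outlying
#' singleton counts on either tail (both unusually low and unusually high
#' counts fail), ancestry-PCA outliers (any of the top PCs beyond `k` MADs
#' within stratum), and duplicates or first-degree relatives by KING-robust
#' kinship (one of each pair kept, preferring cases, then the higher call
#' rate). Strata with fewer than 10 samples skip the robust outlier screens
#' with a warning.
#'
#' @param samples sample sheet aligned with the genotype rows.
#' @param genotypes post-variant-QC [genotype_matrix] restricted to passing
#'   variants (used for call rate, heterozygosity, singletons).
#' @param thresholds a [qc_thresholds()].
#' @param pcs optional samples x PCs score matrix from [compute_pca()].
#' @param kinship optional kinship matrix from [king_kinship()] (computed
#'   on LD-pruned common variants).
#' @return A `sample_qc_report`: list with `pass` (named logical),
#'   `reasons`, `steps`, and `metrics` (per-sample call rate, het count,
#'   singleton count).
#' @export
sample_qc <- function(samples, genotypes, thresholds = qc_thresholds(),
                      pcs = NULL, kinship = NULL) {
  stopifnot(identical(sample_ids(genotypes), samples$sample_id))
  ids <- samples$sample_id
  reasons <- stats::setNames(vector("list", length(ids)), ids)
  add_reason <- function(fail, why) {
    for (s in ids[fail]) reasons[[s]] <<- c(reasons[[s]], why)
    reasons
  }
  steps <- list()

  # coverage
  if ("frac_bases_20x" %in% names(samples) &&
      any(!is.na(samples$frac_bases_20x))) {
    fail_cov <- !is.na(samples$frac_bases_20x) &
      !(samples$frac_bases_20x > thresholds$min_frac_bases_20x)
    reasons <- add_reason(fail_cov, "coverage")
    steps$coverage <- sum(fail_cov)
  }

  # completion rate
  cr <- sample_call_rate(genotypes)
  fail_cr <- cr < thresholds$min_sample_call_rate
  reasons <- add_reason(fail_cr, "call_rate")
  steps$call_rate <- sum(fail_cr)

  # robust outlier screens within stratum
  n_het <- rowSums(genotypes$dosage == 1L, na.rm = TRUE)
  n_singleton <- count_singletons(genotypes)
  fail_het <- fail_sing <- fail_pca <- logical(length(ids))
  for (s in unique(samples$stratum)) {
    in_s <- samples$stratum == s
    if (sum(in_s) < 10) {
      warning("stratum ", s, " has fewer than 10 samples; ",
              "outlier screens skipped")
      next
    }
    fail_het[in_s] <- abs(robust_z(n_het[in_s])) > thresholds$het_outlier_k
    fail_sing[in_s] <- abs(robust_z(n_singleton[in_s])) >
      thresholds$singleton_outlier_k
    if (!is.null(pcs)) {
      z <- apply(pcs[in_s, , drop = FALSE], 2, robust_z)
      fail_pca[in_s] <- apply(abs(z) > thresholds$pca_outlier_k, 1, any)
    }
  }
  reasons <- add_reason(fail_het, "het_outlier")
  steps$het_outlier <- sum(fail_het)
  reasons <- add_reason(fail_sing, "singleton_outlier")
  steps$singleton_outlier <- sum(fail_sing)
  if (!is.null(pcs)) {
    reasons <- add_reason(fail_pca, "pca_outlier")
    steps$pca_outlier <- sum(fail_pca)
  }

  # duplicates / relatedness
  if (!is.null(kinship)) {
    fail_kin <- logical(length(ids))
    alive <- lengths(reasons) == 0
    phi <- kinship[ids, ids]
    repeat {
      cand <- which(alive & !fail_kin)
      if (length(cand) < 2) break
      sub <- phi[cand, cand, drop = FALSE]
      hit <- which(sub > thresholds$kinship_related, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) == 0) break
      i <- cand[hit[1, 1]]; j <- cand[hit[1, 2]]
      # keep cases over controls, then the higher call rate
      drop <- if (samples$is_case[i] != samples$is_case[j]) {
        if (samples$is_case[i]) j else i
      } else if (cr[i] != cr[j]) {
        if (cr[i] > cr[j]) j else i
      } else j
      fail_kin[drop] <- TRUE
    }
    reasons <- add_reason(fail_kin, "relatedness")
    steps$relatedness <- sum(fail_kin)
  }

  pass <- stats::setNames(lengths(reasons) == 0, ids)
  structure(list(pass = pass, reasons = reasons,
                 steps = data.frame(step = names(steps),
                                    count = unlist(steps, use.names = FALSE),
                                    stringsAsFactors = FALSE),
                 metrics = data.frame(sample_id = ids, call_rate = cr,
                                      n_het = n_het,
                                      n_singletons = n_singleton,
                                      stringsAsFactors = FALSE)),
            class = "sample_qc_report")
}

#' @export
print.sample_qc_report <- function(x, ...) {
  cat(sprintf("sample_qc_report: %d/%d samples pass\n",
              sum(x$pass), length(x$pass)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}
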