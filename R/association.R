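## Stratified association statistics: Cochran-Mantel-Haenszel test,
## Mantel-Haenszel common odds ratio with Robins-Breslow-Greenland CI,
## Haldane-Anscombe zero-cell handling, covariate-adjusted burden model
## with a Firth fallback, exome-wide scan and secondary analyses.

ALPHA_EXOME <- 2.5e-6

as_strata_df <- function(strata) {
  if (is.data.frame(strata)) return(strata)
  do.call(rbind, lapply(strata, as.data.frame))
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Chi-square statistic `(sum_k (a_k - E_k))^2 / sum_k V_k` with
#' `E_k = (a_k + b_k)(a_k + c_k) / n_k` and the hypergeometric variance
#' `V_k = (a_k + b_k)(c_k + d_k)(a_k + c_k)(b_k + d_k) / (n_k^2 (n_k - 1))`.
#' No continuity correction is applied. The two-sided P value comes from
#' the chi-square distribution with 1 degree of freedom.
#'
#' @param strata data frame (or list of rows) of per-stratum 2x2 cells with
#'   columns `a` (case carriers), `b` (case non-carriers), `c` (control
#'   carriers), `d` (control non-carriers).
#' @return List with `chisq` and `p`; both `NA` (flagged by a `degenerate`
#'   element) when every stratum has zero hypergeometric variance.
#' @export
cmh_test <- function(strata) {
  st <- as_strata_df(strata)
  a <- as.numeric(st$a); b <- as.numeric(st$b)
  c <- as.numeric(st$c); d <- as.numeric(st$d)
  n <- a + b + c + d
  ok <- n > 1
  e <- (a + b) * (a + c) / n
  v <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  v[!ok] <- 0
  if (sum(v) == 0)
    return(list(chisq = NA_real_, p = NA_real_, degenerate = TRUE))
  chisq <- sum(a - e)^2 / sum(v)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

rbg_log_or_var <- function(a, b, c, d) {
  n <- a + b + c + d
  r <- a * d / n; s <- b * c / n
  p <- (a + d) / n; q <- (b + c) / n
  sr <- sum(r); ss <- sum(s)
  sum(p * r) / (2 * sr^2) + sum(p * s + q * r) / (2 * sr * ss) +
    sum(q * s) / (2 * ss^2)
}

#' Mantel-Haenszel common odds ratio with 95% confidence interval
#'
#' `OR_MH = sum_k(a_k d_k / n_k) / sum_k(b_k c_k / n_k)`; the confidence
#' interval uses the Robins-Breslow-Greenland variance of `log OR_MH`
#' (+/- 1.96 SE). When either sum is zero the Haldane-Anscombe correction
#' (0.5 added to every cell of each stratum containing a zero) is applied
#' and the result flagged.
#'
#' @param strata per-stratum 2x2 cells as in [cmh_test()].
#' @param conf confidence level (default 0.95).
#' @return List with `or`, `ci` (length-2 vector), and `corrected`
#'   (logical: Haldane-Anscombe applied).
#' @export
mh_common_or <- function(strata, conf = 0.95) {
  st <- as_strata_df(strata)
  a <- as.numeric(st$a); b <- as.numeric(st$b)
  c <- as.numeric(st$c); d <- as.numeric(st$d)
  n <- a + b + c + d
  corrected <- FALSE
  if (sum(a * d / n) == 0 || sum(b * c / n) == 0) {
    corrected <- TRUE
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    n <- a + b + c + d
  }
  or <- sum(a * d / n) / sum(b * c / n)
  v <- rbg_log_or_var(a, b, c, d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * sqrt(v))
  list(or = or, ci = ci, corrected = corrected)
}

#' Single-table odds ratio with Haldane-Anscombe zero-cell correction
#'
#' If any cell of the 2x2 table is zero, 0.5 is added to all four cells;
#' the odds ratio is the cross-product on the (possibly corrected) cells
#' and the confidence interval is the Woolf (log) interval on the same
#' cells. Without a zero cell the result is the plain Woolf estimate.
#'
#' @param a,b,c,d the 2x2 cells (case carriers, case non-carriers, control
#'   carriers, control non-carriers).
#' @param conf confidence level (default 0.95).
#' @return List with `or`, `ci`, and `corrected`.
#' @export
haldane_anscombe_or <- function(a, b, c, d, conf = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), corrected = corrected)
}

#' Exome-wide gene-based burden scan
#'
#' Runs [cmh_test()] and [mh_common_or()] on every gene's stratum tables
#' and flags exome-wide significance at `alpha_exome` (default 2.5e-6, the
#' Bonferroni-style threshold for ~20,000 gene tests). Genes with
#' degenerate tables are reported with `NA` statistics rather than
#' dropped. Results are sorted by ascending P with a stable gene-name
#' tiebreak.
#'
#' @param gene_tables named list (per gene) of per-stratum 2x2 data frames
#'   from [stratum_tables()].
#' @param alpha_exome exome-wide significance threshold.
#' @return Data frame with columns `gene`, `or_mh`, `ci_low`, `ci_high`,
#'   `chisq`, `p_cmh`, `p_adjusted` (`NA` until filled by the adjusted
#'   model), `exome_wide_significant`, and a list-column `strata`.
#' @export
gene_burden_scan <- function(gene_tables, alpha_exome = ALPHA_EXOME) {
  genes <- names(gene_tables)
  rows <- lapply(genes, function(g) {
    st <- gene_tables[[g]]
    if (is.null(st) || nrow(st) == 0) {
      return(data.frame(gene = g, or_mh = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, chisq = NA_real_,
                        p_cmh = NA_real_, p_adjusted = NA_real_,
                        exome_wide_significant = NA,
                        stringsAsFactors = FALSE))
    }
    ct <- cmh_test(st)
    orr <- mh_common_or(st)
    data.frame(gene = g, or_mh = orr$or, ci_low = orr$ci[1],
               ci_high = orr$ci[2], chisq = ct$chisq, p_cmh = ct$p,
               p_adjusted = NA_real_,
               exome_wide_significant = !is.na(ct$p) && ct$p < alpha_exome,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$strata <- unname(gene_tables)
  ord <- order(out$p_cmh, out$gene, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha_exome") <- alpha_exome
  out
}

#' Covariate-adjusted model specification
#'
#' @param covariates ordered covariate names (default: the top 5 ancestry
#'   principal components plus the exome-wide variant count).
#' @param estimation `"ml"` (maximum-likelihood logistic regression) or
#'   `"firth"` (penalized likelihood).
#' @param separation_fallback switch to Firth estimation automatically when
#'   separation is detected under maximum likelihood.
#' @return An `adjusted_model_spec` list.
#' @export
adjusted_model_spec <- function(covariates = c(paste0("PC", 1:5),
                                               "exome_variant_count"),
                                estimation = c("ml", "firth"),
                                separation_fallback = TRUE) {
  structure(list(covariates = covariates,
                 estimation = match.arg(estimation),
                 separation_fallback = separation_fallback),
            class = "adjusted_model_spec")
}

# Firth-penalized logistic regression by Newton-Raphson on the modified
# score U*(b) = X' (y - p + h (0.5 - p)), h = hat diagonal.
firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) return(list(converged = FALSE))
    h <- rowSums((x %*% inv) * x) * w
    u <- drop(crossprod(x, y - p + h * (0.5 - p)))
    step <- drop(inv %*% u)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      se <- sqrt(diag(inv))
      return(list(coef = beta, se = se, converged = TRUE))
    }
  }
  list(converged = FALSE)
}

#' Covariate-adjusted burden model for one gene
#'
#' Logistic regression of case status on the carrier indicator plus the
#' configured covariates, reporting the Wald two-sided P for the carrier
#' coefficient. When separation is detected (non-convergence, fitted
#' probabilities at 0/1 or an exploding carrier coefficient) and the
#' fallback is enabled, a Firth-penalized fit is used and the switch
#' recorded.
#'
#' @param carrier logical/0-1 vector of carrier status per sample (`NA`
#'   excluded with their rows).
#' @param is_case logical vector of case status.
#' @param covariates data frame or matrix of covariate columns named as in
#'   the model spec.
#' @param spec an [adjusted_model_spec()].
#' @return List with `log_or`, `se`, `p`, `or`, `method` (`"ml"` or
#'   `"firth"`), and `converged`.
#' @export
adjusted_burden_model <- function(carrier, is_case, covariates,
                                  spec = adjusted_model_spec()) {
  covariates <- as.data.frame(covariates)
  miss <- setdiff(spec$covariates, names(covariates))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  keep <- !is.na(carrier) & !is.na(is_case) &
    stats::complete.cases(covariates[spec$covariates])
  carrier <- as.numeric(carrier[keep])
  y <- as.numeric(is_case[keep])
  if (length(unique(carrier)) < 2)
    return(list(log_or = NA_real_, se = NA_real_, p = NA_real_,
                or = NA_real_, method = NA_character_, converged = FALSE,
                note = "degenerate carrier predictor"))
  covs <- scale(as.matrix(covariates[keep, spec$covariates, drop = FALSE]))
  covs[, apply(covs, 2, function(z) all(is.nan(z)))] <- 0  # constant covariate
  x <- cbind(`(Intercept)` = 1, carrier = carrier, covs)
  fit_ml <- NULL
  separated <- FALSE
  if (spec$estimation == "ml") {
    fit_ml <- suppressWarnings(
      stats::glm.fit(x, y, family = stats::binomial()))
    p_hat <- fit_ml$fitted.values
    separated <- !fit_ml$converged ||
      any(p_hat < 1e-8 | p_hat > 1 - 1e-8) ||
      abs(fit_ml$coefficients["carrier"]) > 15
  }
  use_firth <- spec$estimation == "firth" ||
    (separated && spec$separation_fallback)
  if (use_firth) {
    ff <- firth_logistic(x, y)
    if (!ff$converged)
      return(list(log_or = NA_real_, se = NA_real_, p = NA_real_,
                  or = NA_real_, method = "firth", converged = FALSE))
    b <- ff$coef[2]; se <- ff$se[2]
    method <- "firth"
  } else {
    if (is.null(fit_ml) || !fit_ml$converged)
      return(list(log_or = NA_real_, se = NA_real_, p = NA_real_,
                  or = NA_real_, method = "ml", converged = FALSE))
    b <- fit_ml$coefficients["carrier"]
    # Wald SE from the final IRLS information matrix
    w <- fit_ml$weights
    info <- crossprod(x * sqrt(w))
    se <- sqrt(diag(solve(info)))[2]
    method <- "ml"
  }
  b <- unname(b); se <- unname(se)
  list(log_or = b, se = se, p = 2 * stats::pnorm(-abs(b / se)),
       or = exp(b), method = method, converged = TRUE)
}

#' Secondary stratified analyses
#'
#' Rebuilds the per-gene stratum tables under the post-hoc restrictions
#' (female-only, male-only, acute-subtype cases versus all controls, and
#' female acute-subtype cases versus female controls) and reruns the
#' stratified association. Sex-restricted analyses filter both cases and
#' controls to the given sex; subtype restrictions never touch controls.
#'
#' @param carriers a [collapse_carriers()] result.
#' @param samples sample sheet aligned with the carrier columns.
#' @param alpha_exome significance threshold passed to the scans.
#' @return Named list of [gene_burden_scan()] data frames for
#'   `female_only`, `male_only`, `apac_vs_controls`,
#'   `female_apac_vs_female_controls`.
#' @export
secondary_analyses <- function(carriers, samples, alpha_exome = ALPHA_EXOME) {
  run <- function(sample_filter, case_filter = NULL) {
    keep <- sample_filter
    smp <- samples[keep, , drop = FALSE]
    cm <- carriers$carrier[, keep, drop = FALSE]
    if (!is.null(case_filter)) {
      drop_cases <- smp$is_case & !case_filter[keep]
      smp <- smp[!drop_cases, , drop = FALSE]
      cm <- cm[, !drop_cases, drop = FALSE]
    }
    gene_burden_scan(stratum_tables(cm, smp, "cohort"), alpha_exome)
  }
  female <- samples$sex == "female"
  male <- samples$sex == "male"
  apac <- samples$phenotype == "APAC"
  list(
    female_only = run(female),
    male_only = run(male),
    apac_vs_controls = run(rep(TRUE, nrow(samples)), apac),
    female_apac_vs_female_controls = run(female, apac)
  )
}

#' Project a gene's carriers onto the top two ancestry axes
#'
#' Report-only diagnostic for confounding by population stratification:
#' carrier and non-carrier coordinates on PC1/PC2 plus a two-sample
#' Wilcoxon location test per axis.
#'
#' @param carrier logical vector of carrier status per sample (`NA`
#'   excluded).
#' @param pcs score matrix from [compute_pca()] (needs `PC1`, `PC2`).
#' @return Data frame with `sample_id`, `carrier`, `PC1`, `PC2`; the
#'   per-axis Wilcoxon P values are in the `location_p` attribute.
#' @export
carrier_pc_projection <- function(carrier, pcs) {
  keep <- !is.na(carrier)
  df <- data.frame(sample_id = rownames(pcs)[keep],
                   carrier = as.logical(carrier[keep]),
                   PC1 = pcs[keep, "PC1"], PC2 = pcs[keep, "PC2"],
                   stringsAsFactors = FALSE)
  pvals <- vapply(c("PC1", "PC2"), function(axis) {
    if (!any(df$carrier) || all(df$carrier)) return(NA_real_)
    stats::wilcox.test(df[[axis]][df$carrier],
                       df[[axis]][!df$carrier], exact = FALSE)$p.value
  }, numeric(1))
  attr(df, "location_p") <- pvals
  df
}
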