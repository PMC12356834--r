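## Statistical power for the collapsing design, predictor concordance
## against laboratory functional status, and variant-subset burden tests.

#' Power scenario for the stratified collapsing design
#'
#' @param control_carrier_freq cumulative qualifying-carrier frequency
#'   among controls (carrier-based parameterization) or cumulative
#'   alternate-allele frequency (allele-based).
#' @param odds_ratio carrier (or allele) odds ratio under the alternative.
#' @param strata data frame with columns `n_cases`, `n_controls` (one row
#'   per stratum).
#' @param alpha two-sided significance threshold.
#' @param parameterization `"carrier"`: one Bernoulli trial per person at
#'   the carrier frequency; `"allele"`: two trials per person (one per
#'   chromosome) at the same frequency, i.e. the comparison is of allele
#'   counts rather than carrier counts.
#' @param n_replicates Monte-Carlo replicates for [simulated_power()].
#' @param seed seed for the simulation path.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(control_carrier_freq, odds_ratio,
                           strata = data.frame(n_cases = 4667L,
                                               n_controls = 5473L),
                           alpha = 2.5e-6,
                           parameterization = c("carrier", "allele"),
                           n_replicates = 10000L, seed = 1L) {
  stopifnot(control_carrier_freq > 0, control_carrier_freq < 1,
            odds_ratio > 0, alpha > 0, alpha < 1,
            all(c("n_cases", "n_controls") %in% names(strata)))
  parameterization <- match.arg(parameterization)
  q <- control_carrier_freq
  if (case_carrier_prob(q, odds_ratio) >= 1 - 1e-6)
    stop("implied case frequency is numerically 1")
  structure(as.list(environment()), class = "power_scenario")
}

scenario_trials <- function(scenario) {
  mult <- if (scenario$parameterization == "allele") 2L else 1L
  list(n1 = scenario$strata$n_cases * mult,
       n0 = scenario$strata$n_controls * mult)
}

#' Analytic power of the collapsing burden comparison
#'
#' Normal-approximation power of the two-proportion comparison at the
#' scenario's alpha: the case frequency follows the exact odds transform
#' `p1 = OR q / (1 - q + OR q)`; the critical value uses the pooled
#' variance under the null and the alternative uses the unpooled variance.
#' Strata are pooled by total size for this analytic path.
#'
#' @param scenario a [power_scenario()].
#' @return Power in `[0, 1]`.
#' @export
analytic_power <- function(scenario) {
  tr <- scenario_trials(scenario)
  n1 <- sum(tr$n1); n0 <- sum(tr$n0)
  q <- scenario$control_carrier_freq
  p1 <- case_carrier_prob(q, scenario$odds_ratio)
  z <- stats::qnorm(1 - scenario$alpha / 2)
  pbar <- (n1 * p1 + n0 * q) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + q * (1 - q) / n0)
  delta <- p1 - q
  # both rejection tails under the alternative
  stats::pnorm((delta - z * se0) / se1) + stats::pnorm((-delta - z * se0) / se1)
}

#' Simulated power of the stratified collapsing burden test
#'
#' Draws per-stratum case and control carrier (or allele) counts
#' binomially under the alternative, computes the Cochran-Mantel-Haenszel
#' statistic for every replicate, and returns the fraction of replicates
#' rejecting at the scenario's alpha together with its binomial
#' Monte-Carlo standard error.
#'
#' @param scenario a [power_scenario()].
#' @return List with `power`, `se`, and `n_replicates`.
#' @export
simulated_power <- function(scenario) {
  set.seed(scenario$seed)
  tr <- scenario_trials(scenario)
  k <- length(tr$n1); reps <- scenario$n_replicates
  q <- scenario$control_carrier_freq
  p1 <- case_carrier_prob(q, scenario$odds_ratio)
  # k x reps count matrices
  a <- matrix(as.numeric(stats::rbinom(k * reps, tr$n1, p1)), k, reps)
  c_ <- matrix(as.numeric(stats::rbinom(k * reps, tr$n0, q)), k, reps)
  b <- tr$n1 - a; d <- tr$n0 - c_
  n <- a + b + c_ + d
  e <- (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  chisq <- colSums(a - e)^2 / colSums(v)
  reject <- !is.na(chisq) &
    stats::pchisq(chisq, 1, lower.tail = FALSE) < scenario$alpha
  pow <- mean(reject)
  list(power = pow, se = sqrt(pow * (1 - pow) / reps), n_replicates = reps)
}

#' Tabulate analytic and simulated power over a scenario grid
#'
#' @param q_grid,or_grid,alpha_grid vectors of control carrier frequencies,
#'   odds ratios and significance thresholds.
#' @param strata per-stratum sizes (see [power_scenario()]).
#' @param parameterizations which parameterizations to include.
#' @param n_replicates,seed simulation settings.
#' @return Data frame with one row per grid cell and columns for both
#'   power estimates and the Monte-Carlo SE.
#' @export
power_grid <- function(q_grid = c(0.005, 0.01, 0.02),
                       or_grid = c(1.7, 2.0, 2.5),
                       alpha_grid = c(0.05, 2.5e-6),
                       strata = data.frame(n_cases = 4667L,
                                           n_controls = 5473L),
                       parameterizations = c("carrier", "allele"),
                       n_replicates = 10000L, seed = 1L) {
  grid <- expand.grid(q = q_grid, odds_ratio = or_grid, alpha = alpha_grid,
                      parameterization = parameterizations,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- power_scenario(grid$q[i], grid$odds_ratio[i], strata,
                         grid$alpha[i], grid$parameterization[i],
                         n_replicates, seed + i)
    sim <- simulated_power(sc)
    data.frame(analytic = analytic_power(sc), simulated = sim$power,
               mc_se = sim$se)
  })
  cbind(grid, do.call(rbind, res))
}

#' Concordance of a bioinformatic predictor with laboratory function
#'
#' Sensitivity (correctly called impaired / laboratory-impaired) and
#' specificity (correctly called normal / laboratory-normal) of a
#' deleteriousness predictor against laboratory functional status, plus a
#' two-sided Fisher exact P for the difference in correct-classification
#' proportions between the impaired and normal groups.
#'
#' @param calls data frame with columns `lab_status` (`"impaired"` /
#'   `"normal"`) and `call` (`"deleterious"` / `"benign"`); rows with
#'   missing calls are excluded.
#' @return List with `sensitivity`, `specificity`, the underlying counts,
#'   and `p` (Fisher exact).
#' @export
predictor_concordance <- function(calls) {
  calls <- calls[!is.na(calls$call) & !is.na(calls$lab_status), , drop = FALSE]
  stopifnot(all(calls$lab_status %in% c("impaired", "normal")),
            all(calls$call %in% c("deleterious", "benign")))
  imp <- calls$lab_status == "impaired"
  if (!any(imp) || all(imp))
    stop("need at least one variant of each laboratory status")
  correct <- ifelse(imp, calls$call == "deleterious", calls$call == "benign")
  n_imp <- sum(imp); n_norm <- sum(!imp)
  corr_imp <- sum(correct[imp]); corr_norm <- sum(correct[!imp])
  tab <- matrix(c(corr_imp, n_imp - corr_imp,
                  corr_norm, n_norm - corr_norm), 2, byrow = TRUE)
  list(sensitivity = corr_imp / n_imp,
       specificity = corr_norm / n_norm,
       n_impaired = n_imp, n_normal = n_norm,
       correct_impaired = corr_imp, correct_normal = corr_norm,
       p = stats::fisher.test(tab)$p.value)
}

#' Stratified burden test restricted to a variant subset
#'
#' Rebuilds carrier status using only the named qualifying variants (for
#' example the laboratory-confirmed functionally deficient set) and reruns
#' the stratified association with the same machinery as the main scan,
#' applying the Haldane-Anscombe path on zero cells.
#'
#' @param genotypes QC-passing [genotype_matrix].
#' @param variant_subset non-empty character vector of variant ids.
#' @param samples sample sheet aligned with the genotype rows.
#' @param stratify_by stratification passed to [stratum_tables()].
#' @return List with `or`, `ci`, `p`, `chisq`, `corrected` (zero-cell
#'   correction applied to the OR), and the per-stratum `strata` table.
#' @export
subset_burden_test <- function(genotypes, variant_subset, samples,
                               stratify_by = "cohort") {
  if (length(variant_subset) == 0) stop("variant subset is empty")
  gm <- data.frame(variant_id = variant_subset, gene = "subset",
                   stringsAsFactors = FALSE)
  carriers <- collapse_carriers(genotypes, variant_subset, gm)
  if (nrow(carriers$carrier) == 0)
    stop("no subset variant present in the genotype matrix")
  st <- stratum_tables(carriers, samples, stratify_by)[["subset"]]
  ct <- cmh_test(st)
  orr <- mh_common_or(st)
  list(or = orr$or, ci = orr$ci, corrected = orr$corrected,
       chisq = ct$chisq, p = ct$p, strata = st)
}
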