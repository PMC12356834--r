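test_that("single-stratum CMH equals the Pearson chi-square and crude OR", {
  set.seed(30)
  for (i in 1:50) {
    st <- draw_carrier_tables(runif(1, 0.02, 0.2), runif(1, 0.5, 4),
                              sample(50:400, 1), sample(50:400, 1))
    m <- matrix(c(st$a, st$b, st$c, st$d), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ct <- cmh_test(st)
    px <- suppressWarnings(chisq.test(m, correct = FALSE))
    n <- sum(m)
    # the CMH variance carries an (n - 1) denominator: the statistic is
    # exactly (n - 1)/n times the Pearson chi-square, equal in the limit
    expect_equal(ct$chisq, unname(px$statistic) * (n - 1) / n,
                 tolerance = 1e-10)
    expect_equal(ct$p, px$p.value, tolerance = 2e-2)
    if (all(m > 0))
      expect_equal(mh_common_or(st)$or, (st$a * st$d) / (st$b * st$c),
                   tolerance = 1e-12)
  }
})

test_that("multi-stratum CMH and MH OR match the independent oracle to 1e-10", {
  set.seed(31)
  n_checked <- 0
  for (i in 1:250) {
    k <- sample(2:5, 1)
    st <- draw_carrier_tables(runif(1, 0.02, 0.15), runif(1, 0.5, 4),
                              sample(80:400, k), sample(80:400, k))
    arr <- array(0, dim = c(2, 2, k))
    for (j in 1:k)
      arr[, , j] <- matrix(c(st$a[j], st$b[j], st$c[j], st$d[j]), 2,
                           byrow = TRUE)
    or_ours <- mh_common_or(st)
    if (or_ours$corrected) next
    mt <- mantelhaen.test(arr, correct = FALSE)
    ct <- cmh_test(st)
    expect_equal(ct$chisq, unname(mt$statistic), tolerance = 1e-10)
    expect_equal(ct$p, mt$p.value, tolerance = 1e-10)
    expect_equal(or_ours$or, unname(mt$estimate), tolerance = 1e-10)
    expect_equal(unname(or_ours$ci), as.numeric(mt$conf.int),
                 tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 200)
})

test_that("perfectly balanced tables give a null CMH statistic", {
  st <- data.frame(stratum = c("s1", "s2"),
                   a = c(10L, 6L), b = c(90L, 54L),
                   c = c(20L, 12L), d = c(180L, 108L))  # a = E exactly
  ct <- cmh_test(st)
  expect_equal(ct$chisq, 0)
  expect_equal(ct$p, 1)
  expect_equal(mh_common_or(st)$or, 1)
})

test_that("Haldane-Anscombe correction follows the classic convention", {
  r <- haldane_anscombe_or(1, 9, 0, 10)
  expect_equal(r$or, (1.5 * 10.5) / (9.5 * 0.5), tolerance = 1e-12)
  expect_true(r$corrected)
  r2 <- haldane_anscombe_or(5, 5, 5, 5)
  expect_equal(r2$or, 1)
  expect_false(r2$corrected)
  r3 <- haldane_anscombe_or(0, 10, 0, 10)
  expect_equal(r3$or, 1)
})

test_that("OR is collapsible over strata with identical margins and OR", {
  one <- data.frame(stratum = "s", a = 2L, b = 8L, c = 1L, d = 9L)
  both <- rbind(one, transform(one, stratum = "t"))
  expect_equal(mh_common_or(both)$or, (2 * 9) / (8 * 1), tolerance = 1e-12)
})

test_that("gene scan ranks spiked genes, keeps degenerate genes, and is order-invariant", {
  set.seed(32)
  ds <- discovery_strata()
  tabs <- list()
  for (g in sprintf("G%02d", 1:20))
    tabs[[g]] <- draw_carrier_tables(0.01, 1, ds$n_cases, ds$n_controls)
  tabs[["RISK"]] <- draw_carrier_tables(0.01, 2.14, ds$n_cases, ds$n_controls)
  tabs[["EMPTY"]] <- data.frame(stratum = "s1", a = 0L, b = 100L,
                                c = 0L, d = 100L)
  res <- gene_burden_scan(tabs)
  expect_equal(res$gene[1], "RISK")
  expect_true(res$exome_wide_significant[1] == (res$p_cmh[1] < 2.5e-6))
  expect_true("EMPTY" %in% res$gene)
  expect_true(is.na(res$p_cmh[res$gene == "EMPTY"]))
  res2 <- gene_burden_scan(rev(tabs))
  expect_equal(res2$p_cmh[match(res$gene, res2$gene)], res$p_cmh)
})

test_that("null exomes stay below the Bonferroni expectation", {
  set.seed(33)
  ds <- discovery_strata()
  n_genes <- 400
  p <- vapply(seq_len(n_genes), function(i) {
    ct <- cmh_test(draw_carrier_tables(0.01, 1, ds$n_cases, ds$n_controls))
    if (is.na(ct$p)) 1 else ct$p
  }, numeric(1))
  expect_equal(sum(p < 2.5e-6), 0)
  # and the nominal-level rejection rate is near its size
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_genes))
})

test_that("adjusted model matches the unadjusted fit when covariates are orthogonal", {
  set.seed(34)
  n <- 1500
  carrier <- rbinom(n, 1, 0.05)
  y <- rbinom(n, 1, plogis(-1 + log(2.5) * carrier))
  covs <- data.frame(matrix(rnorm(n * 5), n, 5))
  names(covs) <- paste0("PC", 1:5)
  covs$exome_variant_count <- rpois(n, 100)
  fit <- adjusted_burden_model(carrier, y == 1, covs)
  raw <- glm(y ~ carrier, family = binomial)
  expect_equal(fit$method, "ml")
  expect_equal(fit$log_or, unname(coef(raw)["carrier"]), tolerance = 0.08)
  raw_p <- summary(raw)$coefficients["carrier", 4]
  expect_equal(log10(fit$p), log10(raw_p), tolerance = 0.35)
})

test_that("adjustment attenuates a built-in ancestry confounder", {
  set.seed(35)
  n <- 3000
  pc1 <- rnorm(n)
  carrier <- rbinom(n, 1, plogis(-3 + 1.5 * pc1))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * pc1))      # no direct carrier effect
  covs <- data.frame(PC1 = pc1, PC2 = rnorm(n), PC3 = rnorm(n),
                     PC4 = rnorm(n), PC5 = rnorm(n),
                     exome_variant_count = rpois(n, 100))
  fit_adj <- adjusted_burden_model(carrier, y == 1, covs)
  fit_raw <- glm(y ~ carrier, family = binomial)
  expect_lt(abs(fit_adj$log_or), abs(unname(coef(fit_raw)["carrier"])))
})

test_that("degenerate carrier vectors and separation are handled", {
  set.seed(36)
  n <- 200
  covs <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
                     PC4 = rnorm(n), PC5 = rnorm(n),
                     exome_variant_count = rpois(n, 50))
  res0 <- adjusted_burden_model(rep(0, n), rbinom(n, 1, 0.5) == 1, covs)
  expect_false(res0$converged)
  # perfect separation: all carriers are cases
  carrier <- c(rep(1, 10), rep(0, n - 10))
  y <- c(rep(TRUE, 10), rbinom(n - 10, 1, 0.4) == 1)
  res1 <- adjusted_burden_model(carrier, y, covs)
  expect_equal(res1$method, "firth")
  expect_true(res1$converged)
  expect_true(is.finite(res1$log_or))
})

test_that("secondary analyses restrict cases and never controls", {
  set.seed(37)
  n <- 400
  d <- matrix(rbinom(n, 2, 0.08), n, 1)
  g <- make_geno(d)
  phen <- c(rep("APAC", 60), rep("PACG_chronic", 140), rep("control", 200))
  smp <- make_samples(g, stratum = rep(c("SG", "HK"), n / 2),
                      sex = sample(c("female", "male"), n, replace = TRUE),
                      phenotype = phen)
  cm <- collapse_carriers(g, "v001",
                          data.frame(variant_id = "v001", gene = "G1"))
  sec <- secondary_analyses(cm, smp)
  expect_named(sec, c("female_only", "male_only", "apac_vs_controls",
                      "female_apac_vs_female_controls"))
  apac_tab <- sec$apac_vs_controls$strata[[1]]
  expect_equal(sum(apac_tab$a + apac_tab$b), 60)
  full_tab <- stratum_tables(cm, smp)[["G1"]]
  expect_equal(sum(apac_tab$c + apac_tab$d), sum(full_tab$c + full_tab$d))
  # sex-restricted controls match the sex filter alone
  f_tab <- sec$female_only$strata[[1]]
  expect_equal(sum(f_tab$c + f_tab$d),
               sum(!smp$is_case & smp$sex == "female"))
  # with no true sex difference the CIs overlap
  f <- sec$female_only; m <- sec$male_only
  expect_true(f$ci_low[1] <= m$ci_high[1] && m$ci_low[1] <= f$ci_high[1])
})

test_that("carrier PC projection reports all samples and a null location test", {
  set.seed(38)
  n <- 300
  pcs <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(sprintf("S%03d", 1:n), c("PC1", "PC2")))
  carrier <- rbinom(n, 1, 0.1) == 1
  proj <- carrier_pc_projection(carrier, pcs)
  expect_equal(nrow(proj), n)
  expect_equal(sum(proj$carrier), sum(carrier))
  expect_gt(min(attr(proj, "location_p")), 0.001)
  # carriers drawn from a shifted stratum are detected
  carrier2 <- pcs[, "PC1"] > quantile(pcs[, "PC1"], 0.9)
  proj2 <- carrier_pc_projection(carrier2, pcs)
  expect_lt(attr(proj2, "location_p")["PC1"], 1e-6)
})
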