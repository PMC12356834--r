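test_that("HWE exact test matches brute-force enumeration exhaustively (n <= 30)", {
  for (n in c(1:10, 15, 20, 25, 30)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      n2 <- n - n0 - n1
      expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                   tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", n0, n1, n2))
    }
  }
})

test_that("HWE exact test handles canonical cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)          # monomorphic
  expect_equal(hwe_exact_test(2, 4, 2), hwe_oracle(2, 4, 2), tolerance = 1e-12)
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("allelic-balance masking is strict and het-only", {
  dos <- matrix(c(1L, 1L, 1L, 2L, 0L, 1L), 1)
  af <- matrix(c(0.50, 0.15, 0.20, 0.95, 0.01, NA), 1)
  g <- make_geno(dos, alt_frac = af)
  res <- apply_allelic_balance(g)
  out <- res$genotypes$dosage[1, ]
  expect_identical(unname(out),
                   c(1L, NA_integer_, NA_integer_, 2L, 0L, 1L))
  expect_equal(res$n_masked, 2L)   # 0.15 and the boundary 0.20
  expect_equal(res$n_skipped, 1L)  # het without an alt fraction
})

test_that("differential missingness equals the Fisher oracle and is symmetric", {
  expect_equal(differential_missingness_test(100, 0, 100, 0), 1)
  expect_equal(differential_missingness_test(90, 10, 100, 0),
               fisher_oracle(90, 10, 100, 0), tolerance = 1e-12)
  expect_equal(differential_missingness_test(90, 10, 100, 0),
               differential_missingness_test(100, 0, 90, 10))
})

test_that("variant QC fails low call rate and applies the sibling rule", {
  set.seed(1)
  n <- 100
  # v1 clean; v2 94% call rate; v3/v4 siblings where v3 violates HWE
  d <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3),
             c(rep(1L, 60), rep(0L, 40)), rbinom(n, 2, 0.05))
  d[1:6, 2] <- NA
  g <- make_geno(d)
  variants <- data.frame(
    variant_id = colnames(g$dosage),
    chrom = "1", pos = c(1L, 2L, 3L, 3L), ref = "A",
    alt = c("G", "G", "C", "T"),
    parent_site_id = c("1:1:A", "1:2:A", "1:3:A", "1:3:A"),
    vqslod = NA_real_, stringsAsFactors = FALSE)
  smp <- make_samples(g)
  rep_ <- variant_qc(variants, g, smp)
  expect_false(rep_$pass[2])
  expect_true("call_rate" %in% rep_$reasons[[2]])
  expect_false(rep_$pass[3])
  expect_true("hwe" %in% rep_$reasons[[3]])
  expect_false(rep_$pass[4])
  expect_true("sibling_failed" %in% rep_$reasons[[4]])
  expect_true(rep_$pass[1])
})

test_that("variant QC is blind to phenotype except differential missingness", {
  set.seed(8)
  n <- 120
  d <- matrix(rbinom(n * 20, 2, runif(20, 0.05, 0.4)), n, 20, byrow = TRUE)
  d[sample(length(d), 150)] <- NA
  g <- make_geno(d)
  variants <- data.frame(variant_id = colnames(g$dosage), chrom = "1",
                         pos = seq_len(20), ref = "A", alt = "G",
                         parent_site_id = paste0("1:", seq_len(20), ":A"),
                         vqslod = NA_real_, stringsAsFactors = FALSE)
  smp <- make_samples(g)
  smp_perm <- smp
  perm <- sample(n)
  smp_perm$phenotype <- smp$phenotype[perm]
  smp_perm$is_case <- smp$is_case[perm]
  r1 <- variant_qc(variants, g, smp)
  r2 <- variant_qc(variants, g, smp_perm)
  non_dm <- function(r) lapply(r$reasons, setdiff, "differential_missingness")
  expect_identical(non_dm(r1), non_dm(r2))
})

test_that("a clean simulated study passes variant QC almost entirely", {
  cfg <- sim_config(seed = 21, base_missingness = 0, ab_noise = 0,
                    n_common = 50L)
  paths <- simulate_study(cfg, tempfile("clean_"))
  vc <- read_vcf(paths$vcf)
  smp <- read_samples(paths$samples)
  rep_ <- variant_qc(vc$variants, vc$genotypes, smp)
  expect_gte(mean(rep_$pass), 0.99)
})

test_that("LD pruning removes duplicates and satisfies its r^2 postcondition", {
  set.seed(3)
  n <- 400
  x <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  dup <- cbind(x, x[, 1:3])    # exact duplicates -> r^2 = 1
  colnames(dup) <- sprintf("c%02d", seq_len(ncol(dup)))
  kept <- ld_prune(dup, 0.1)
  expect_false(any(c("c41", "c42", "c43") %in% kept) &&
                 !all(c("c01", "c02", "c03") %in% kept))
  # exactly one member of each duplicate pair survives
  for (pair in list(c("c01", "c41"), c("c02", "c42"), c("c03", "c43")))
    expect_equal(sum(pair %in% kept), 1L)
  # mutually independent variants are essentially all retained
  expect_gte(length(kept), 38L)
  r2 <- cor(dup[, kept], use = "pairwise.complete.obs")^2
  diag(r2) <- 0
  expect_lte(max(r2), 0.1)
})

test_that("PCA separates simulated populations and is permutation-equivariant", {
  set.seed(5)
  n <- 80; m <- 300
  af1 <- runif(m, 0.1, 0.5); af2 <- pmin(0.9, af1 + 0.15)
  d <- rbind(matrix(rbinom(n / 2 * m, 2, rep(af1, each = n / 2)), n / 2, m),
             matrix(rbinom(n / 2 * m, 2, rep(af2, each = n / 2)), n / 2, m))
  rownames(d) <- sprintf("S%03d", 1:n)
  pcs <- compute_pca(d, 3)
  grp <- rep(1:2, each = n / 2)
  sep <- abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1]))
  spread <- max(sd(pcs[grp == 1, 1]), sd(pcs[grp == 2, 1]))
  expect_gt(sep, 2 * spread)

  perm <- sample(n)
  pcs_perm <- compute_pca(d[perm, ], 3)
  expect_equal(pcs_perm[rownames(pcs), ], pcs, tolerance = 1e-8)
})

test_that("PCA finds no structure when there is none", {
  set.seed(6)
  n <- 80; m <- 300
  d <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.5), each = n)), n, m)
  rownames(d) <- sprintf("S%03d", 1:n)
  pcs <- compute_pca(d, 2)
  grp <- rep(1:2, each = n / 2)
  expect_gt(t.test(pcs[grp == 1, 1], pcs[grp == 2, 1])$p.value, 0.01)
})

test_that("KING kinship identifies duplicates and sample QC keeps one of the pair", {
  set.seed(9)
  n <- 40; m <- 4000
  d <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.5), each = n)), n, m)
  d[2, ] <- d[1, ]             # duplicate pair: samples 1 and 2
  g <- make_geno(d)
  phi <- king_kinship(g$dosage)
  expect_gt(phi[1, 2], 0.45)
  expect_lt(max(phi[-(1:2), -(1:2)], na.rm = TRUE), 0.0884)

  smp <- make_samples(g, phenotype = c("PACG_chronic",
                                       rep("control", n - 1)))
  rep_ <- sample_qc(smp, g, qc_thresholds(), kinship = phi)
  expect_true(rep_$pass[1])    # the case is preferred
  expect_false(rep_$pass[2])
  expect_equal(sum(!rep_$pass), 1L)
})

test_that("sample QC applies the coverage and call-rate thresholds", {
  set.seed(10)
  n <- 30; m <- 200
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  d[2, 1:20] <- NA             # call rate 0.90
  g <- make_geno(d)
  smp <- make_samples(g)
  smp$frac_bases_20x <- rep(0.95, n)
  smp$frac_bases_20x[1] <- 0.79
  rep_ <- sample_qc(smp, g, qc_thresholds())
  expect_true("coverage" %in% rep_$reasons[[1]])
  expect_true("call_rate" %in% rep_$reasons[[2]])
  expect_equal(sum(!rep_$pass), 2L)
})

test_that("singleton counts match a brute-force recount", {
  set.seed(11)
  d <- matrix(rbinom(200, 2, 0.05), 20, 10)
  d[sample(200, 10)] <- NA
  g <- make_geno(d)
  counts <- count_singletons(g)
  brute <- sapply(seq_len(nrow(d)), function(i) {
    sum(sapply(seq_len(ncol(d)), function(j) {
      carriers <- which(!is.na(d[, j]) & d[, j] >= 1)
      length(carriers) == 1 && carriers == i
    }))
  })
  expect_equal(unname(counts), brute)
})
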