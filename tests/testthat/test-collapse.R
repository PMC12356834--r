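test_that("group MAF counts alleles per group and folds to the minor allele", {
  d <- matrix(0L, 500, 2)
  d[1, 1] <- 1L                     # one het among 500 diploids
  d[, 2] <- 2L; d[1:5, 2] <- 1L     # alt frequency 0.995
  g <- make_geno(d)
  smp <- make_samples(g)
  maf <- group_maf(g, smp, groups = rep("ALL", 500))
  expect_equal(maf["v001", "ALL"], 0.001)
  expect_equal(maf["v002", "ALL"], 0.005)
})

test_that("the rare rule requires MAF below the bound in every group", {
  # 0.5% in group A, 2% in group B
  dA <- matrix(0L, 200, 1); dA[1:2, 1] <- 1L
  dB <- matrix(0L, 200, 1); dB[1:8, 1] <- 1L
  g <- make_geno(rbind(dA, dB))
  smp <- make_samples(g, stratum = rep(c("A", "B"), each = 200))
  maf <- group_maf(g, smp)
  expect_equal(unname(maf[1, ]), c(2 / 400, 8 / 400))
  ann <- data.frame(variant_id = "v001", gene = "G1",
                    consequence = "stop_gained", cadd_scaled = NA_real_,
                    usable = TRUE, known = TRUE, stringsAsFactors = FALSE)
  expect_length(select_qualifying(ann, maf), 0)
})

test_that("qualifying selection applies strict PTV/CADD boundaries", {
  maf <- matrix(0.004, 4, 1, dimnames = list(paste0("v", 1:4), "SG"))
  ann <- data.frame(
    variant_id = paste0("v", 1:4),
    gene = "G1",
    consequence = c("missense", "stop_gained", "synonymous", "missense"),
    cadd_scaled = c(10.0, NA, 25, 10.01),
    usable = TRUE, known = TRUE, stringsAsFactors = FALSE)
  qual <- select_qualifying(ann, maf)
  expect_false("v1" %in% qual)   # CADD exactly 10 fails the strict bound
  expect_true("v2" %in% qual)    # PTV qualifies without CADD
  expect_false("v3" %in% qual)   # synonymous never qualifies
  expect_true("v4" %in% qual)
})

test_that("dominant collapsing marks carriers once and respects gene boundaries", {
  d <- rbind(c(1L, 0L, 0L),
             c(1L, 1L, 0L),      # two qualifying hets in gene A: one carrier
             c(0L, 0L, 1L),
             c(NA, NA, 0L),      # unknown for gene A
             c(0L, 0L, 0L))
  g <- make_geno(d)
  gm <- data.frame(variant_id = c("v001", "v002", "v003"),
                   gene = c("A", "A", "B"), stringsAsFactors = FALSE)
  cm <- collapse_carriers(g, gm$variant_id, gm)
  expect_identical(unname(cm$carrier["A", ]), c(TRUE, TRUE, FALSE, NA, FALSE))
  expect_identical(unname(cm$carrier["B", ]), c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_setequal(cm$variants$A, c("v001", "v002"))
})

test_that("stratum tables reproduce a cohort-scale fixture exactly", {
  # counts mimicking a large biobank validation cohort:
  # 24 carriers among 1,759 cases, 3,864 among 467,880 controls
  n_case <- 1759L; n_ctrl <- 467880L
  carrier <- matrix(c(rep(TRUE, 24), rep(FALSE, n_case - 24),
                      rep(TRUE, 3864), rep(FALSE, n_ctrl - 3864)), nrow = 1,
                    dimnames = list("G1", sprintf("S%06d", 1:(n_case + n_ctrl))))
  smp <- data.frame(
    sample_id = colnames(carrier),
    stratum = "UKB",
    sex = "female",
    phenotype = c(rep("PACG_chronic", n_case), rep("control", n_ctrl)),
    is_case = c(rep(TRUE, n_case), rep(FALSE, n_ctrl)),
    stringsAsFactors = FALSE)
  st <- stratum_tables(carrier, smp)[["G1"]]
  expect_identical(c(st$a, st$b, st$c, st$d),
                   c(24L, 1735L, 3864L, 464016L))
  cf <- carrier_frequency(st)
  expect_equal(cf$case_pct, 1.4)
  expect_equal(cf$control_pct, 0.83)
})

test_that("stratification restrictions behave as specified", {
  set.seed(20)
  n <- 200
  d <- matrix(rbinom(n, 2, 0.05), n, 1)
  g <- make_geno(d)
  phen <- c(rep("APAC", 30), rep("PACG_chronic", 70), rep("control", 100))
  smp <- make_samples(g, stratum = rep(c("SG", "HK"), n / 2),
                      sex = rep(c("female", "female", "male", "male"),
                                length.out = n),
                      phenotype = phen)
  gm <- data.frame(variant_id = "v001", gene = "G1")
  cm <- collapse_carriers(g, "v001", gm)

  full <- stratum_tables(cm, smp, "cohort")[["G1"]]
  apac <- stratum_tables(cm, smp, "apac")[["G1"]]
  # APAC restriction drops chronic cases, leaves controls untouched
  expect_equal(sum(apac$a + apac$b), 30)
  expect_equal(apac$c, full$c)
  expect_equal(apac$d, full$d)
  # conservation: strata partition the analyzable samples
  expect_equal(sum(full$a + full$b), sum(smp$is_case))
  expect_equal(sum(full$a + full$b + full$c + full$d), n)
  # sex stratification splits cohorts and keeps totals
  bysex <- stratum_tables(cm, smp, "cohort_sex")[["G1"]]
  expect_equal(sum(bysex$a + bysex$b + bysex$c + bysex$d), n)
  expect_gt(nrow(bysex), nrow(full))
})

test_that("carrier tables are invariant to variant and sample ordering", {
  set.seed(22)
  n <- 100; m <- 12
  d <- matrix(rbinom(n * m, 2, 0.03), n, m)
  g <- make_geno(d)
  smp <- make_samples(g, stratum = rep(c("SG", "HK"), n / 2))
  vids <- colnames(g$dosage)
  gm <- data.frame(variant_id = vids,
                   gene = rep(c("A", "B", "C"), each = 4))
  t1 <- stratum_tables(collapse_carriers(g, vids, gm), smp)

  pv <- sample(m); ps <- sample(n)
  g2 <- subset_genotypes(g, samples = ps, variants = pv)
  t2 <- stratum_tables(collapse_carriers(g2, vids[pv], gm),
                       smp[ps, , drop = FALSE])
  for (gene in names(t1)) {
    a1 <- t1[[gene]][order(t1[[gene]]$stratum), ]
    a2 <- t2[[gene]][order(t2[[gene]]$stratum), ]
    rownames(a1) <- rownames(a2) <- NULL
    expect_identical(a1, a2)
  }
})

test_that("exome variant count equals a brute-force recount and is monotone", {
  set.seed(23)
  d <- matrix(rbinom(300, 2, 0.2), 30, 10)
  d[sample(300, 20)] <- NA
  g <- make_geno(d)
  evc <- exome_variant_count(g)
  brute <- apply(d, 1, function(r) sum(!is.na(r) & r >= 1))
  expect_equal(unname(evc), unname(brute))
  expect_equal(unname(evc[rowSums(d >= 1, na.rm = TRUE) == 0]), integer(0))
  # masking calls never increases the count
  d2 <- d; d2[1, ] <- NA
  expect_lte(exome_variant_count(make_geno(d2))[1], evc[1])
})
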