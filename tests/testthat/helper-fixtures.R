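# Fixture builders and independent brute-force oracles used across the suite.

# ---- fixture builders -------------------------------------------------

write_fixture_vcf <- function(body_lines,
                              samples = c("S1", "S2", "S3"),
                              path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

make_geno <- function(dosage, depth = NULL, alt_frac = NULL,
                      sample_prefix = "S", variant_prefix = "v") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- sprintf("%s%03d", sample_prefix, seq_len(nrow(dosage)))
  colnames(dosage) <- sprintf("%s%03d", variant_prefix, seq_len(ncol(dosage)))
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m); dimnames(m) <- dimnames(dosage); m
  }
  genotype_matrix(dosage, fix(depth), fix(alt_frac))
}

make_samples <- function(geno, stratum = "SG", phenotype = NULL,
                         sex = NULL, n_cases = NULL) {
  ids <- rownames(geno$dosage)
  n <- length(ids)
  if (is.null(phenotype)) {
    nc <- if (is.null(n_cases)) floor(n / 2) else n_cases
    phenotype <- c(rep("PACG_chronic", nc), rep("control", n - nc))
  }
  data.frame(sample_id = ids,
             stratum = rep_len(stratum, n),
             sex = if (is.null(sex)) rep_len(c("female", "male"), n) else
               rep_len(sex, n),
             phenotype = phenotype,
             is_case = phenotype != "control",
             stringsAsFactors = FALSE)
}

# ---- independent oracles ----------------------------------------------

# Exact HWE P by brute force: conditional distribution of the heterozygote
# count given the allele count, derived by normalizing multinomial
# genotype-configuration probabilities at an arbitrary allele frequency
# (the conditional law is free of it).
hwe_oracle <- function(n_homref, n_het, n_homalt, p = 0.3) {
  n <- n_homref + n_het + n_homalt
  n_alt <- 2 * n_homalt + n_het
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  h1 <- Filter(function(h) (n_alt - h) %% 2 == 0 && n_alt - h >= 0 &&
                 n - h - (n_alt - h) / 2 >= 0, 0:n)
  w <- vapply(h1, function(h)
    stats::dmultinom(c(n - h - (n_alt - h) / 2, h, (n_alt - h) / 2),
                     prob = probs), numeric(1))
  w <- w / sum(w)
  obs <- w[h1 == n_het]
  if (length(obs) != 1) stop("observed configuration not found")
  sum(w[w <= obs * (1 + 1e-10)])
}

# Two-sided Fisher exact P by explicit hypergeometric enumeration with
# binomial coefficients (independent of stats::fisher.test / dhyper).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Exact rejection probability of the stratified CMH test under independent
# binomial carrier counts (enumeration oracle for simulated_power; single
# stratum).
exact_power_oracle <- function(n1, n0, q, or, alpha) {
  p1 <- or * q / (1 - q + or * q)
  a <- 0:n1; c <- 0:n0
  pa <- stats::dbinom(a, n1, p1); pc <- stats::dbinom(c, n0, q)
  A <- matrix(a, length(a), length(c))
  C <- matrix(c, length(a), length(c), byrow = TRUE)
  B <- n1 - A; D <- n0 - C; N <- n1 + n0
  E <- (A + B) * (A + C) / N
  V <- (A + B) * (C + D) * (A + C) * (B + D) / (N^2 * (N - 1))
  chisq <- (A - E)^2 / V
  rej <- !is.na(chisq) & stats::pchisq(chisq, 1, lower.tail = FALSE) < alpha
  sum(outer(pa, pc)[rej])
}

# Per-stratum carrier-count tables drawn from the generative carrier model
# (control carrier frequency q, case carrier odds q-odds * OR).
draw_carrier_tables <- function(q, or, n_cases, n_controls) {
  p1 <- or * q / (1 - q + or * q)
  a <- stats::rbinom(length(n_cases), n_cases, p1)
  c <- stats::rbinom(length(n_controls), n_controls, q)
  data.frame(stratum = paste0("s", seq_along(n_cases)),
             a = as.integer(a), b = as.integer(n_cases - a),
             c = as.integer(c), d = as.integer(n_controls - c))
}

# Discovery-stage stratum sizes (4,667 cases / 5,473 controls over 4 sites)
discovery_strata <- function() {
  list(n_cases = c(1680L, 1161L, 933L, 893L),
       n_controls = c(1970L, 1369L, 1094L, 1040L))
}
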