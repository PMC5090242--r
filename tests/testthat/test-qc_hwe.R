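test_that("HWE exact test equals the enumeration oracle on random counts", {
  set.seed(10)
  for (i in 1:300) {
    n <- sample(1:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa),
                 oracle_hwe_exact(nAA, nAa, naa), tolerance = 1e-12,
                 info = sprintf("(%d,%d,%d)", nAA, nAa, naa))
  }
})

test_that("HWE exact test behaves at the boundaries", {
  # extreme heterozygote deficit
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)
  # monomorphic: only one configuration exists
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  # maximal heterozygosity with equal allele counts, checked via the oracle
  expect_equal(hwe_exact_test(0, 10, 0), oracle_hwe_exact(0, 10, 0),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "at least 1")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact P is invariant to swapping the homozygote counts", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:60, 1); h <- sample(0:60, 1); b <- sample(0:60, 1)
    if (a + h + b == 0) next
    expect_equal(hwe_exact_test(a, h, b), hwe_exact_test(b, h, a),
                 tolerance = 1e-14)
  }
})

test_that("chi-square HWE variant agrees with the exact test at large n", {
  # both tests should give similar tail calls for clearly out-of-HWE data
  p_exact <- hwe_exact_test(400, 100, 500)
  p_chi <- hwe_chisq_test(400, 100, 500)$p_value
  expect_lt(p_exact, 1e-10)
  expect_lt(p_chi, 1e-10)
})

test_that("call rates count non-missing entries along each axis", {
  codes <- matrix(0L, 10, 5)
  ds <- toy_dataset(codes)
  expect_equal(snp_call_rate(ds), rep(1, 5), ignore_attr = TRUE)
  codes[1, 2] <- NA
  ds <- toy_dataset(codes)
  expect_equal(snp_call_rate(ds, 2), 0.9)
  expect_equal(sample_call_rate(ds, 1), 0.8)
  expect_error(snp_call_rate(ds, "nope"), "unknown")

  set.seed(12)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE), 20, 10)
  ds <- toy_dataset(codes)
  expect_equal(unname(snp_call_rate(ds)), colSums(!is.na(codes)) / 20)
  expect_equal(unname(sample_call_rate(ds)), rowSums(!is.na(codes)) / 10)
})

test_that("minor allele frequency matches the allele-count oracle", {
  ds <- toy_dataset(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(as.numeric(minor_allele_freq(ds, 1)), 0.5)
  ds0 <- toy_dataset(matrix(0L, 4, 1))
  expect_equal(as.numeric(minor_allele_freq(ds0, 1)), 0)

  set.seed(13)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 300, TRUE,
                         prob = c(0.2, 0.3, 0.45, 0.05)), 30, 10)
  ds <- toy_dataset(codes)
  f <- minor_allele_freq(ds)
  for (j in 1:10) {
    g <- codes[, j][!is.na(codes[, j])]
    raw <- sum(g) / (2 * length(g))
    expect_equal(as.numeric(f[j]), min(raw, 1 - raw))
    expect_equal(attr(f, "flipped")[[j]], raw > 0.5)
  }
})

test_that("QC cascade removes SNPs for the documented reasons, in order", {
  set.seed(14)
  n <- 100
  m <- 20
  codes <- replicate(m, simulate_genotypes_hwe(0.3, n))
  # phenotype assigned at random so genotype columns are independent of it
  pheno <- sample(rep(c("case", "control"), n / 2))
  is_ctrl <- pheno == "control"
  codes[1:5, 2] <- NA                        # call rate 0.95 < 0.98
  codes[, 3] <- 0L                           # monomorphic -> MAF 0
  codes[, 4] <- 1L                           # all heterozygous: HWE failure
  chr <- rep("1", m); chr[5] <- "X"          # non-autosomal
  ds <- toy_dataset(codes, chr = chr)
  samples <- data.frame(sample_id = ds$sample_ids, phenotype = pheno,
                        stringsAsFactors = FALSE)
  qc <- apply_qc(ds, samples)
  expect_equal(unname(qc$removed["non_autosomal"]), 1L)
  expect_equal(unname(qc$removed["sample_rate"]), 0L)
  expect_equal(unname(qc$removed["snp_rate"]), 1L)
  expect_equal(unname(qc$removed["maf"]), 1L)
  expect_equal(unname(qc$removed["hwe"]), 1L)
  expect_false(any(c("s2", "s3", "s4", "s5") %in% qc$dataset$snps$snp_id))
  # reconciliation: removals plus survivors account for every input SNP
  expect_equal(sum(qc$removed[c("non_autosomal", "snp_rate", "maf", "hwe")]) +
                 qc$n_snps_out, qc$n_snps_in)
})

test_that("QC drops low-success samples and is idempotent", {
  set.seed(15)
  codes <- replicate(5, simulate_genotypes_hwe(0.4, 40))
  codes[1, 1:3] <- NA                       # sample rate 0.4 < 0.9
  ds <- toy_dataset(codes)
  samples <- data.frame(sample_id = ds$sample_ids,
                        phenotype = rep(c("case", "control"), 20),
                        stringsAsFactors = FALSE)
  qc1 <- apply_qc(ds, samples)
  expect_equal(unname(qc1$removed["sample_rate"]), 1L)
  expect_equal(qc1$n_samples_out, 39L)
  qc2 <- apply_qc(qc1$dataset, qc1$samples)
  expect_equal(sum(qc2$removed), 0L)
  expect_identical(qc2$dataset$matrix, qc1$dataset$matrix)
})

test_that("under the null the HWE filter removes about the nominal fraction", {
  set.seed(16)
  m <- 4000
  codes <- vapply(stats::runif(m, 0.1, 0.5),
                  function(f) simulate_genotypes_hwe(f, 500), integer(500))
  cc <- cbind(colSums(codes == 0L), colSums(codes == 1L),
              colSums(codes == 2L))
  p <- vapply(seq_len(m), function(j)
    hwe_exact_test(cc[j, 1], cc[j, 2], cc[j, 3]), numeric(1))
  # the exact test is conservative: rejection rate at alpha=1e-4 should be
  # at most about nominal (binomial upper bound ~ 3 expected under alpha)
  expect_lte(sum(p < 1e-4), 4)
})

test_that("qq_data pairs sorted observations with uniform quantiles", {
  expect_equal(qq_data(0.3)$expected, -log10(0.5))
  qq <- qq_data(rep(1, 5))
  expect_equal(qq$observed, rep(0, 5))
  expect_equal(qq$expected, -log10((1:5 - 0.5) / 5))
  expect_error(qq_data(c(0.5, 0)), "\\(0, 1\\]")

  set.seed(17)
  qq <- qq_data(stats::runif(10000))
  # uniform draws hug the diagonal away from the extreme tail
  body <- qq$expected < 3
  expect_lt(max(abs(qq$observed[body] - qq$expected[body])), 0.3)
})
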