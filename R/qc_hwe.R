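#' Quality-control thresholds
#'
#' Default thresholds for SNP/sample filtering: per-sample genotyping success
#' rate >= 0.90, per-SNP call rate >= 0.98, minor allele frequency >= 0.05,
#' Hardy-Weinberg exact-test P in controls >= 1e-4, autosomes (chromosomes
#' 1-22) only.
#'
#' @param min_sample_rate minimum per-sample genotyping success rate.
#' @param min_snp_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha HWE exact-test significance level (SNPs with control
#'   P below it are removed).
#' @param autosomes_only drop SNPs on non-autosomal chromosome labels.
#' @param maf_subset `"controls"` (default) or `"all"`: samples used for the
#'   MAF filter. HWE always uses controls.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_rate = 0.90, min_snp_rate = 0.98,
                          min_maf = 0.05, hwe_alpha = 1e-4,
                          autosomes_only = TRUE, maf_subset = "controls") {
  stopifnot(min_sample_rate > 0, min_sample_rate <= 1,
            min_snp_rate > 0, min_snp_rate <= 1,
            min_maf >= 0, min_maf < 1,
            hwe_alpha > 0, hwe_alpha < 1,
            maf_subset %in% c("controls", "all"))
  structure(list(min_sample_rate = min_sample_rate,
                 min_snp_rate = min_snp_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, autosomes_only = autosomes_only,
                 maf_subset = maf_subset),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from genotype counts.
#' Conditional on the observed allele counts, the heterozygote count follows
#' a known discrete distribution; the P-value is the sum of probabilities of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. Probabilities are computed by the standard two-directional
#' recurrence from the distribution's mode and normalized, so the test is
#' exact for any sample size.
#'
#' @param n_AA count of major-allele homozygotes.
#' @param n_Aa count of heterozygotes.
#' @param n_aa count of minor-allele homozygotes.
#' @return the exact two-sided P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be three non-negative integers")
  n <- sum(counts)
  if (n < 1L) stop("total genotype count must be at least 1")

  rare <- 2L * min(n_AA, n_aa) + n_Aa      # minor allele count
  common <- 2L * n - rare
  if (rare == 0L) return(1)                # monomorphic: single configuration

  # heterozygote counts share the parity of the rare-allele count
  mode_h <- floor(rare * common / (2 * n))
  if ((mode_h %% 2L) != (rare %% 2L)) mode_h <- mode_h + 1L
  h_vals <- seq(rare %% 2L, min(rare, common), by = 2L)
  probs <- numeric(length(h_vals))
  mi <- match(mode_h, h_vals)
  probs[mi] <- 1
  if (mi > 1L) for (i in (mi - 1L):1L) {
    h <- h_vals[i + 1L]                    # step h -> h - 2
    a <- (rare - h) / 2; b <- (common - h) / 2
    probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * (a + 1) * (b + 1))
  }
  if (mi < length(h_vals)) for (i in (mi + 1L):length(h_vals)) {
    h <- h_vals[i - 1L]                    # step h -> h + 2
    a <- (rare - h) / 2; b <- (common - h) / 2
    probs[i] <- probs[i - 1L] * 4 * a * b / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, h_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Hardy-Weinberg chi-square test (comparison variant)
#'
#' One-degree-of-freedom goodness-of-fit chi-square against Hardy-Weinberg
#' expected genotype counts, without continuity correction. Provided for
#' comparison with [hwe_exact_test()]; the exact test is used by
#' [apply_qc()].
#'
#' @inheritParams hwe_exact_test
#' @return list with `statistic` and `p_value`.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("total genotype count must be at least 1")
  q <- (2 * n_aa + n_Aa) / (2 * n)
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) return(list(statistic = 0, p_value = 1))
  stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Per-SNP call rate
#'
#' Fraction of non-missing genotype calls for one SNP (or all SNPs).
#'
#' @param dataset a [genotype_dataset()].
#' @param snp SNP id or index; `NULL` returns the vector for all SNPs.
#' @return numeric in \[0, 1\].
#' @export
snp_call_rate <- function(dataset, snp = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  rates <- colMeans(!is.na(dataset$matrix))
  if (is.null(snp)) return(rates)
  i <- if (is.character(snp)) match(snp, dataset$snps$snp_id) else snp
  if (anyNA(i)) stop("unknown SNP id: ", snp)
  unname(rates[i])
}

#' Per-sample genotyping success rate
#'
#' @param dataset a [genotype_dataset()].
#' @param sample sample id or index; `NULL` returns the vector for all
#'   samples.
#' @return numeric in \[0, 1\].
#' @export
sample_call_rate <- function(dataset, sample = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  rates <- rowMeans(!is.na(dataset$matrix))
  if (is.null(sample)) return(rates)
  i <- if (is.character(sample)) match(sample, dataset$sample_ids) else sample
  if (anyNA(i)) stop("unknown sample id: ", sample)
  unname(rates[i])
}

#' Minor allele frequency
#'
#' Computes the frequency of the coded (minor) allele among non-missing calls
#' in an optional sample subset: `(het + 2 * minor-hom) / (2 * n_nonmissing)`.
#' If the subset frequency exceeds 0.5 (the coded allele is not minor in the
#' subset) the value is folded to `1 - f` and the flip is flagged.
#'
#' @param dataset a [genotype_dataset()].
#' @param snp SNP id or index; `NULL` for all SNPs.
#' @param subset sample ids or indices to use (default all samples).
#' @return for one SNP, a numeric with attribute `flipped`; for all SNPs a
#'   numeric vector with attribute `flipped` (logical vector). All-missing
#'   SNPs give `NA`.
#' @export
minor_allele_freq <- function(dataset, snp = NULL, subset = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$matrix
  if (!is.null(subset)) {
    si <- if (is.character(subset)) match(subset, dataset$sample_ids) else subset
    if (anyNA(si)) stop("unknown sample id(s) in subset")
    g <- g[si, , drop = FALSE]
  }
  nn <- colSums(!is.na(g))
  f <- ifelse(nn > 0, colSums(g, na.rm = TRUE) / (2 * nn), NA_real_)
  flipped <- !is.na(f) & f > 0.5
  f[flipped] <- 1 - f[flipped]
  if (is.null(snp)) {
    attr(f, "flipped") <- flipped
    return(f)
  }
  i <- if (is.character(snp)) match(snp, dataset$snps$snp_id) else snp
  if (anyNA(i)) stop("unknown SNP id: ", snp)
  out <- unname(f[i])
  attr(out, "flipped") <- unname(flipped[i])
  out
}

# genotype counts (major-hom, het, minor-hom) per SNP over a row subset
.geno_counts <- function(g) {
  cbind(n_AA = colSums(g == 0L, na.rm = TRUE),
        n_Aa = colSums(g == 1L, na.rm = TRUE),
        n_aa = colSums(g == 2L, na.rm = TRUE))
}

#' Apply SNP and sample quality-control filters
#'
#' Runs the QC cascade in a fixed order: (1) drop non-autosomal SNPs
#' (chromosome labels other than 1-22), (2) drop samples with genotyping
#' success rate below `min_sample_rate`, (3) drop SNPs with call rate below
#' `min_snp_rate`, (4) drop SNPs with minor allele frequency below `min_maf`
#' (controls only by default), (5) drop SNPs whose control-sample
#' Hardy-Weinberg exact P-value is below `hwe_alpha`. Each step is tallied.
#'
#' @param dataset a [genotype_dataset()].
#' @param samples covariate table with `sample_id` and `phenotype` matching
#'   the dataset.
#' @param thresholds a [qc_thresholds()].
#' @return list of class `qc_report`: `dataset` (filtered), `samples`
#'   (filtered covariate rows), `removed` (named counts per filter),
#'   `n_snps_in`, `n_snps_out`, `n_samples_in`, `n_samples_out`, and
#'   `snp_stats` (per-surviving-SNP call rate, control MAF and HWE P).
#' @export
apply_qc <- function(dataset, samples, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(thresholds, "qc_thresholds"))
  samples <- samples[match(dataset$sample_ids, samples$sample_id), ,
                     drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("covariate table does not cover all genotyped samples")
  n_snps_in <- nrow(dataset$snps)
  n_samples_in <- length(dataset$sample_ids)
  removed <- c(non_autosomal = 0L, sample_rate = 0L, snp_rate = 0L,
               maf = 0L, hwe = 0L)

  # (1) autosomes
  if (thresholds$autosomes_only) {
    keep <- dataset$snps$chr %in% as.character(1:22)
    removed["non_autosomal"] <- sum(!keep)
    dataset <- subset_genotypes(dataset, snps = which(keep))
  }
  # (2) sample success rate
  keep_s <- sample_call_rate(dataset) >= thresholds$min_sample_rate
  removed["sample_rate"] <- sum(!keep_s)
  dataset <- subset_genotypes(dataset, samples = which(keep_s))
  samples <- samples[keep_s, , drop = FALSE]
  # (3) SNP call rate
  keep <- snp_call_rate(dataset) >= thresholds$min_snp_rate
  removed["snp_rate"] <- sum(!keep)
  dataset <- subset_genotypes(dataset, snps = which(keep))

  is_control <- .as_case_indicator(samples$phenotype) == 0L
  maf_rows <- if (thresholds$maf_subset == "controls") which(is_control)
              else seq_len(nrow(samples))
  # (4) MAF
  maf <- minor_allele_freq(dataset, subset = maf_rows)
  keep <- !is.na(maf) & maf >= thresholds$min_maf
  removed["maf"] <- sum(!keep)
  dataset <- subset_genotypes(dataset, snps = which(keep))
  # (5) HWE in controls
  cc <- .geno_counts(dataset$matrix[is_control, , drop = FALSE])
  hwe_p <- vapply(seq_len(nrow(cc)), function(j)
    hwe_exact_test(cc[j, 1L], cc[j, 2L], cc[j, 3L]), numeric(1))
  keep <- hwe_p >= thresholds$hwe_alpha
  removed["hwe"] <- sum(!keep)
  dataset <- subset_genotypes(dataset, snps = which(keep))

  snp_stats <- data.frame(
    snp_id = dataset$snps$snp_id,
    call_rate = snp_call_rate(dataset),
    maf_controls = as.numeric(minor_allele_freq(dataset,
                                                subset = which(is_control))),
    hwe_p_controls = hwe_p[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(dataset = dataset, samples = samples, removed = removed,
                 n_snps_in = n_snps_in, n_snps_out = nrow(dataset$snps),
                 n_samples_in = n_samples_in,
                 n_samples_out = length(dataset$sample_ids),
                 snp_stats = snp_stats, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_snps_in, "SNPs /", x$n_samples_in, "samples in;",
      x$n_snps_out, "SNPs /", x$n_samples_out, "samples surviving\n")
  cat("  removed:", paste(names(x$removed), x$removed, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Quantile-quantile plot data for association P-values
#'
#' Pairs the sorted observed -log10 P-values with the expected quantiles
#' under the uniform null, `-log10((i - 0.5) / m)` for ranks `i = 1..m`.
#'
#' @param p_values vector of P-values in (0, 1].
#' @return data frame with columns `expected` and `observed` (both -log10
#'   scale, decreasing), one row per P-value.
#' @export
qq_data <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("no P-values supplied")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("P-values must lie in (0, 1]")
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(p), decreasing = TRUE))
}
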