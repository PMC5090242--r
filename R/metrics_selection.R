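#' Dominant-model 2x2 contingency table for one SNP
#'
#' Under the dominant genetic model a sample is marker-positive when it
#' carries at least one copy of the minor (variant) allele. Treating
#' marker-positivity as a diagnostic test for case status gives the 2x2
#' table: TP = carrier cases, FP = carrier controls, FN = non-carrier cases,
#' TN = non-carrier controls. Samples with a missing genotype at the SNP are
#' excluded pairwise.
#'
#' @param genotypes a [genotype_dataset()], or an integer dosage vector.
#' @param phenotype binary phenotype aligned with the samples
#'   (`"case"`/`"control"`, logical, or 0/1).
#' @param snp SNP id or index (ignored when `genotypes` is a vector).
#' @return list of class `dominant_table` with integer fields `TP`, `FP`,
#'   `FN`, `TN` and the carrier `orientation` (`"minor"`).
#' @export
dominant_table <- function(genotypes, phenotype, snp = NULL) {
  if (inherits(genotypes, "genotype_dataset")) {
    i <- if (is.character(snp)) match(snp, genotypes$snps$snp_id) else snp
    if (is.null(i) || anyNA(i)) stop("unknown or missing SNP id")
    g <- genotypes$matrix[, i]
  } else {
    g <- as.integer(genotypes)
  }
  y <- .as_case_indicator(phenotype)
  if (length(g) != length(y)) stop("genotype and phenotype lengths differ")
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  if (!any(y == 1L) || !any(y == 0L))
    stop("both cases and controls are required")
  carrier <- g >= 1L
  structure(list(TP = sum(carrier & y == 1L), FP = sum(carrier & y == 0L),
                 FN = sum(!carrier & y == 1L), TN = sum(!carrier & y == 0L),
                 orientation = "minor"),
            class = "dominant_table")
}

#' Performance metrics of a binary marker
#'
#' Computes the table-derived diagnostic metrics of a 2x2 marker-vs-disease
#' table: sensitivity TP/(TP+FN), specificity TN/(FP+TN), Youden index
#' (sensitivity + specificity - 1), positive predictive value TP/(TP+FP),
#' negative predictive value TN/(FN+TN), diagnostic odds ratio
#' (TP*TN)/(FP*FN), and accuracy (TP+TN)/(TP+FN+FP+TN). A metric whose
#' denominator is zero is `NA` and listed in the `undefined` attribute rather
#' than silently reported as 0; a DOR with `FP*FN == 0` but `TP*TN > 0` is
#' `Inf` (flagged `dor_infinite`).
#'
#' @param table a [dominant_table()] or any list with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @return list of class `metric_set` with the seven metrics and flags.
#' @export
performance_metrics <- function(table) {
  TP <- table$TP; FP <- table$FP; FN <- table$FN; TN <- table$TN
  if (anyNA(c(TP, FP, FN, TN)) || any(c(TP, FP, FN, TN) < 0))
    stop("table cells must be non-negative counts")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(TP, TP + FN)
  spec <- div(TN, FP + TN)
  youden <- if (!is.na(sens) && !is.na(spec)) sens + spec - 1 else NA_real_
  ppv <- div(TP, TP + FP)
  npv <- div(TN, FN + TN)
  dor_infinite <- FALSE
  if (FP * FN > 0) {
    dor <- (TP * TN) / (FP * FN)
  } else if (TP * TN > 0) {
    dor <- Inf
    dor_infinite <- TRUE
  } else {
    dor <- NA_real_
  }
  acc <- div(TP + TN, TP + FP + FN + TN)
  out <- list(sensitivity = sens, specificity = spec, youden = youden,
              ppv = ppv, npv = npv, dor = dor, accuracy = acc,
              dor_infinite = dor_infinite)
  undef <- names(out)[vapply(out[1:7], function(v) is.na(v), logical(1))]
  attr(out, "undefined") <- undef
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "youden", "ppv", "npv",
                  "dor", "accuracy")])
  print(round(v, 4))
  invisible(x)
}

#' Net sensitivity of two tests applied in parallel
#'
#' For two tests read in parallel (combined positive if either is positive)
#' and conditionally independent given disease status, the combined
#' sensitivity is `a + b - a*b` (equivalently `1 - (1-a)(1-b)`), which is
#' never below either component.
#'
#' @param sens_a,sens_b component sensitivities in \[0, 1\].
#' @return the net sensitivity.
#' @export
net_sensitivity <- function(sens_a, sens_b) {
  if (any(c(sens_a, sens_b) < 0) || any(c(sens_a, sens_b) > 1))
    stop("sensitivities must lie in [0, 1]")
  sens_a + sens_b - sens_a * sens_b
}

#' Net specificity of two tests applied in parallel
#'
#' With the parallel (either-positive) reading rule, the combined test is
#' negative only when both components are negative, so under conditional
#' independence the combined specificity is the product `a * b`, never above
#' either component.
#'
#' @param spec_a,spec_b component specificities in \[0, 1\].
#' @return the net specificity.
#' @export
net_specificity <- function(spec_a, spec_b) {
  if (any(c(spec_a, spec_b) < 0) || any(c(spec_a, spec_b) > 1))
    stop("specificities must lie in [0, 1]")
  spec_a * spec_b
}

#' Empirical metrics of simultaneous (parallel) two-marker testing
#'
#' Combines two binary markers with the parallel rule — combined positive if
#' either marker is positive — and computes the diagnostic metrics of the
#' combined marker directly from the sample counts. This is the empirical
#' counterpart of [net_sensitivity()]/[net_specificity()]; the two agree (up
#' to sampling noise) when the markers are conditionally independent given
#' disease status.
#'
#' @param carrier_a,carrier_b logical (or 0/1) marker-positivity vectors.
#' @param phenotype binary phenotype aligned with the markers.
#' @return a [performance_metrics()] `metric_set` of the combined marker.
#' @export
empirical_parallel_test <- function(carrier_a, carrier_b, phenotype) {
  a <- as.logical(carrier_a); b <- as.logical(carrier_b)
  if (length(a) != length(b)) stop("marker vectors differ in length")
  y <- .as_case_indicator(phenotype)
  if (length(a) != length(y)) stop("marker and phenotype lengths differ")
  ok <- !is.na(a) & !is.na(b) & !is.na(y)
  comb <- a[ok] | b[ok]; y <- y[ok]
  performance_metrics(list(TP = sum(comb & y == 1L),
                           FP = sum(comb & y == 0L),
                           FN = sum(!comb & y == 1L),
                           TN = sum(!comb & y == 0L)))
}

#' Chi-square association test for one SNP
#'
#' Pearson 1-df chi-square without continuity correction, on either the 2x2
#' allele-count table (`variant = "allelic"`, the default) or the
#' carrier/non-carrier table of the dominant model (`variant = "dominant"`).
#'
#' @param genotypes dosage vector or [genotype_dataset()].
#' @param phenotype binary phenotype.
#' @param snp SNP id/index when `genotypes` is a dataset.
#' @param variant `"allelic"` or `"dominant"`.
#' @return list with `statistic`, `p_value`, `variant`; a table with an
#'   empty margin gives `statistic = 0`, `p_value = 1` and `degenerate =
#'   TRUE`.
#' @export
snp_chisq <- function(genotypes, phenotype, snp = NULL,
                      variant = c("allelic", "dominant")) {
  variant <- match.arg(variant)
  if (inherits(genotypes, "genotype_dataset")) {
    i <- if (is.character(snp)) match(snp, genotypes$snps$snp_id) else snp
    if (is.null(i) || anyNA(i)) stop("unknown or missing SNP id")
    g <- genotypes$matrix[, i]
  } else g <- as.integer(genotypes)
  y <- .as_case_indicator(phenotype)
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  if (variant == "allelic") {
    tab <- rbind(cases = c(minor = sum(g[y == 1L]),
                           major = 2L * sum(y == 1L) - sum(g[y == 1L])),
                 controls = c(minor = sum(g[y == 0L]),
                              major = 2L * sum(y == 0L) - sum(g[y == 0L])))
  } else {
    carrier <- g >= 1L
    tab <- rbind(cases = c(sum(carrier & y == 1L), sum(!carrier & y == 1L)),
                 controls = c(sum(carrier & y == 0L),
                              sum(!carrier & y == 0L)))
  }
  .chisq_2x2(tab, variant)
}

# Pearson chi-square on a 2x2 table, no continuity correction
.chisq_2x2 <- function(tab, variant) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    return(list(statistic = 0, p_value = 1, variant = variant,
                degenerate = TRUE))
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       variant = variant, degenerate = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m_snps number of tests.
#' @return `alpha / m_snps`.
#' @export
bonferroni_threshold <- function(alpha, m_snps) {
  stopifnot(alpha > 0, alpha < 1, m_snps >= 1)
  alpha / m_snps
}

.metric_cols <- c("sensitivity", "specificity", "youden", "ppv", "npv",
                  "dor", "accuracy", "net_sensitivity", "net_specificity",
                  "auc")

#' Per-SNP metric and association table
#'
#' Computes, for every SNP of a dataset, the dominant-model 2x2 table, the
#' seven table-derived performance metrics, the allelic chi-square P-value,
#' and optionally (i) net sensitivity/specificity of parallel testing with a
#' reference binary marker (e.g. APOE e4 carrier status) and (ii) the AUC of
#' a logistic model containing the SNP (dominant coding) plus forced
#' covariates.
#'
#' The per-SNP AUC is a modelling choice: it is the apparent AUC of an
#' unconditional logistic model with the SNP carrier indicator and the
#' supplied covariate design (see [run_stage1()] for the default covariates).
#' With strong covariates all per-SNP AUCs are similar; the SNP-specific
#' signal lives mostly in the other nine metrics.
#'
#' @param dataset a [genotype_dataset()].
#' @param phenotype binary phenotype aligned with the dataset samples.
#' @param reference_marker optional logical vector (parallel-testing partner;
#'   its own sensitivity/specificity are estimated from the same data).
#' @param covariate_design optional numeric matrix (no intercept column) for
#'   the per-SNP AUC model; `NULL` skips AUC computation.
#' @return data frame with one row per SNP: counts, the ten metrics (those
#'   not computable are `NA`), `chi2`, `p_value`.
#' @export
snp_metrics_table <- function(dataset, phenotype, reference_marker = NULL,
                              covariate_design = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  y <- .as_case_indicator(phenotype)
  g <- dataset$matrix
  if (nrow(g) != length(y)) stop("phenotype length mismatch")
  case <- y == 1L
  carrier <- !is.na(g) & g >= 1L
  known <- !is.na(g)

  TP <- colSums(carrier[case, , drop = FALSE])
  FP <- colSums(carrier[!case, , drop = FALSE])
  n_case_known <- colSums(known[case, , drop = FALSE])
  n_ctrl_known <- colSums(known[!case, , drop = FALSE])
  FN <- n_case_known - TP
  TN <- n_ctrl_known - FP

  sens <- ifelse(n_case_known > 0, TP / n_case_known, NA_real_)
  spec <- ifelse(n_ctrl_known > 0, TN / n_ctrl_known, NA_real_)
  youden <- sens + spec - 1
  ppv <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  npv <- ifelse(FN + TN > 0, TN / (FN + TN), NA_real_)
  dor <- ifelse(FP * FN > 0, (TP * TN) / (FP * FN),
                ifelse(TP * TN > 0, Inf, NA_real_))
  acc <- (TP + TN) / (n_case_known + n_ctrl_known)

  net_sens <- net_spec <- rep(NA_real_, ncol(g))
  if (!is.null(reference_marker)) {
    ref <- as.logical(reference_marker)
    ref_tab <- dominant_table(as.integer(ref), y)
    ref_m <- performance_metrics(ref_tab)
    net_sens <- net_sensitivity(ref_m$sensitivity, pmin(pmax(sens, 0), 1))
    net_spec <- net_specificity(ref_m$specificity, pmin(pmax(spec, 0), 1))
  }

  auc <- rep(NA_real_, ncol(g))
  if (!is.null(covariate_design)) {
    X0 <- cbind(`(Intercept)` = 1, covariate_design)
    for (j in seq_len(ncol(g))) {
      okj <- known[, j] & stats::complete.cases(X0)
      Xj <- cbind(X0[okj, , drop = FALSE], carrier = carrier[okj, j])
      fit <- suppressWarnings(
        stats::glm.fit(Xj, y[okj], family = stats::binomial()))
      auc[j] <- .auc_mann_whitney(fit$fitted.values, y[okj])
    }
  }

  data.frame(snp_id = dataset$snps$snp_id, TP = TP, FP = FP, FN = FN,
             TN = TN, sensitivity = sens, specificity = spec,
             youden = youden, ppv = ppv, npv = npv, dor = dor,
             accuracy = acc, net_sensitivity = net_sens,
             net_specificity = net_spec, auc = auc,
             chi2 = NA_real_, p_value = NA_real_,
             row.names = NULL, stringsAsFactors = FALSE) -> out
  chis <- lapply(seq_len(ncol(g)), function(j)
    snp_chisq(g[, j], y, variant = "allelic"))
  out$chi2 <- vapply(chis, `[[`, numeric(1), "statistic")
  out$p_value <- vapply(chis, `[[`, numeric(1), "p_value")
  out
}

#' Select SNPs by the metric-count rule
#'
#' For each candidate SNP, counts how many of the considered performance
#' metrics it attains the maximum value of (over all candidates); all SNPs
#' tied at a metric's maximum earn the count. Candidates are ranked by count
#' (descending) with ties broken by mean metric rank, then AUC, then
#' association P-value, then SNP id. Metric values are rounded to 6 decimals
#' before comparison so float noise cannot manufacture unique maxima; a SNP
#' whose metric is undefined (`NA`) is excluded from that metric's
#' comparison.
#'
#' @param metric_table data frame as from [snp_metrics_table()] (columns
#'   `snp_id` plus the metric columns; `p_value` used for tie-breaks when
#'   present).
#' @param k number of SNPs to select.
#' @param metrics character vector of metric columns to consider; defaults to
#'   all ten (those entirely absent/NA are dropped with a note).
#' @return list of class `selection_result`: `selected` (the top-`k` SNP
#'   ids), `ranking` (full data frame with `metric_count`, `mean_rank` and
#'   rank order), `metrics_used`.
#' @export
select_by_metric_counts <- function(metric_table, k = 5,
                                    metrics = .metric_cols) {
  stopifnot(is.data.frame(metric_table), "snp_id" %in% names(metric_table),
            k >= 1)
  metrics <- intersect(metrics, names(metric_table))
  usable <- metrics[vapply(metrics,
                           function(mcol) any(is.finite(metric_table[[mcol]]) |
                                              is.infinite(metric_table[[mcol]])),
                           logical(1))]
  dropped <- setdiff(metrics, usable)
  if (length(usable) == 0L) stop("no usable metric columns")
  if (nrow(metric_table) < k)
    stop("fewer candidate SNPs (", nrow(metric_table), ") than k = ", k)

  m <- nrow(metric_table)
  counts <- integer(m)
  rank_sum <- numeric(m)
  rank_n <- integer(m)
  for (mcol in usable) {
    v <- round(metric_table[[mcol]], 6)
    # a non-finite value (infinite DOR from a zero cell) has no comparable
    # magnitude and is excluded from this metric's comparison
    v[!is.finite(v)] <- NA_real_
    ok <- !is.na(v)
    if (!any(ok)) next
    mx <- max(v[ok])
    counts[ok & v == mx] <- counts[ok & v == mx] + 1L
    r <- rank(-v[ok], ties.method = "average")
    rank_sum[ok] <- rank_sum[ok] + r
    rank_n[ok] <- rank_n[ok] + 1L
  }
  mean_rank <- ifelse(rank_n > 0, rank_sum / rank_n, Inf)
  auc <- if ("auc" %in% names(metric_table)) metric_table$auc else
    rep(NA_real_, m)
  pv <- if ("p_value" %in% names(metric_table)) metric_table$p_value else
    rep(NA_real_, m)
  ord <- order(-counts, mean_rank, -ifelse(is.na(auc), -Inf, auc),
               ifelse(is.na(pv), Inf, pv), metric_table$snp_id)
  ranking <- metric_table[ord, , drop = FALSE]
  ranking$metric_count <- counts[ord]
  ranking$mean_rank <- mean_rank[ord]
  structure(list(selected = ranking$snp_id[seq_len(k)], ranking = ranking,
                 metrics_used = usable, metrics_dropped = dropped, k = k),
            class = "selection_result")
}

#' Select SNPs by P-value rank, keeping ties
#'
#' Orders SNPs by ascending association P-value and returns the top `k`,
#' extended by every SNP tied with the `k`-th P-value (so more than `k` ids
#' may be returned, mirroring the traditional GWAS ranking convention).
#'
#' @param assoc_table data frame with columns `snp_id` and `p_value`.
#' @param k nominal number of SNPs.
#' @return character vector of selected SNP ids (ties included), with
#'   attribute `p_values`.
#' @export
select_by_pvalue <- function(assoc_table, k = 5) {
  stopifnot(is.data.frame(assoc_table),
            all(c("snp_id", "p_value") %in% names(assoc_table)), k >= 1)
  tab <- assoc_table[!is.na(assoc_table$p_value), , drop = FALSE]
  tab <- tab[order(tab$p_value, tab$snp_id), , drop = FALSE]
  k <- min(k, nrow(tab))
  cutoff <- tab$p_value[k]
  sel <- tab[tab$p_value <= cutoff, , drop = FALSE]
  out <- sel$snp_id
  attr(out, "p_values") <- stats::setNames(sel$p_value, sel$snp_id)
  out
}
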