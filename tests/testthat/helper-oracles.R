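# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementations.

# HWE exact P by direct log-gamma enumeration of the conditional distribution
# of the heterozygote count given allele counts:
# P(h | n, r) = n! / (a! h! b!) * 2^h * r! (2n-r)! / (2n)!  with
# a = (r - h)/2 minor homozygotes, b = n - a - h major homozygotes.
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  r <- 2 * min(n_AA, n_aa) + n_Aa
  if (r == 0) return(1)
  h_vals <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  logp <- vapply(h_vals, function(h) {
    a <- (r - h) / 2
    b <- n - a - h
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(r + 1) + lgamma(2 * n - r + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, h_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]))
}

# conditional logistic log-likelihood by explicit enumeration of all
# case-sized subsets within each stratum
oracle_clogit_loglik <- function(beta, strata_ids, x, y) {
  x <- as.matrix(x)
  ll <- 0
  for (s in unique(strata_ids)) {
    i <- which(strata_ids == s)
    k <- sum(y[i])
    if (k == 0 || k == length(i)) next
    eta <- drop(x[i, , drop = FALSE] %*% beta)
    num <- sum(eta[y[i] == 1])
    subsets <- utils::combn(length(i), k)
    den <- log(sum(apply(subsets, 2, function(ss) exp(sum(eta[ss])))))
    ll <- ll + num - den
  }
  ll
}

# AUC by explicit pairwise comparison
oracle_auc_pairwise <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# the seven table metrics recomputed directly from counts
oracle_table_metrics <- function(TP, FP, FN, TN) {
  list(sensitivity = TP / (TP + FN),
       specificity = TN / (FP + TN),
       youden = TP / (TP + FN) + TN / (FP + TN) - 1,
       ppv = TP / (TP + FP),
       npv = TN / (FN + TN),
       dor = (TP / FP) / (FN / TN),
       accuracy = (TP + TN) / (TP + TN + FP + FN))
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed, max_cell = 80) {
  set.seed(seed)
  data.frame(TP = sample.int(max_cell, n, TRUE),
             FP = sample.int(max_cell, n, TRUE),
             FN = sample.int(max_cell, n, TRUE),
             TN = sample.int(max_cell, n, TRUE))
}

# small genotype dataset built in code
toy_dataset <- function(codes, snp_ids = NULL, chr = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(snp_ids)) snp_ids <- paste0("s", seq_len(m))
  if (is.null(chr)) chr <- rep("1", m)
  genotype_dataset(codes, sprintf("I%03d", seq_len(nrow(codes))),
                   data.frame(snp_id = snp_ids, chr = chr,
                              pos = seq_len(m) * 100L,
                              allele_minor = "A", allele_major = "G",
                              stringsAsFactors = FALSE))
}
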