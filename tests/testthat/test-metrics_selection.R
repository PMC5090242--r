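test_that("dominant table counts carriers by case status", {
  tb <- dominant_table(c(1L, 2L, 0L, 0L, 0L, 1L),
                       c("case", "case", "case", "control", "control",
                         "control"))
  expect_equal(tb[c("TP", "FN", "FP", "TN")],
               list(TP = 2L, FN = 1L, FP = 1L, TN = 2L))

  # all carriers: no negatives at all
  m <- performance_metrics(dominant_table(c(1L, 1L, 2L, 1L), c(1, 1, 0, 0)))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)

  expect_error(dominant_table(c(0L, 1L), c("case", "case")),
               "cases and controls")

  # missing genotypes excluded pairwise
  tb <- dominant_table(c(NA, 1L, 0L, NA), c(1, 1, 0, 0))
  expect_equal(tb$TP + tb$FN + tb$FP + tb$TN, 2L)
})

test_that("dominant table matches direct enumeration on random data", {
  set.seed(20)
  for (i in 1:20) {
    g <- sample(c(0:2, NA), 100, TRUE)
    y <- sample(0:1, 100, TRUE)
    if (length(unique(y)) < 2) next
    tb <- dominant_table(g, y)
    ok <- !is.na(g)
    expect_equal(tb$TP, sum(g[ok] >= 1 & y[ok] == 1))
    expect_equal(tb$TN, sum(g[ok] == 0 & y[ok] == 0))
    expect_equal(tb$FP, sum(g[ok] >= 1 & y[ok] == 0))
    expect_equal(tb$FN, sum(g[ok] == 0 & y[ok] == 1))
  }
})

test_that("all seven table metrics equal their defining formulas", {
  tabs <- random_tables(200, seed = 21)
  for (i in seq_len(nrow(tabs))) {
    m <- performance_metrics(as.list(tabs[i, ]))
    o <- oracle_table_metrics(tabs$TP[i], tabs$FP[i], tabs$FN[i], tabs$TN[i])
    for (nm in names(o))
      expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12,
                   info = paste("row", i, nm))
  }
})

test_that("metric identities hold exactly", {
  tabs <- random_tables(100, seed = 22)
  for (i in seq_len(nrow(tabs))) {
    m <- performance_metrics(as.list(tabs[i, ]))
    n_case <- tabs$TP[i] + tabs$FN[i]
    n_ctrl <- tabs$FP[i] + tabs$TN[i]
    expect_equal(m$youden, m$sensitivity + m$specificity - 1)
    expect_equal(m$accuracy,
                 (m$sensitivity * n_case + m$specificity * n_ctrl) /
                   (n_case + n_ctrl))
    expect_equal(m$dor, (m$sensitivity * m$specificity) /
                   ((1 - m$sensitivity) * (1 - m$specificity)))
    # Bayes' rule at the sample prevalence
    prev <- n_case / (n_case + n_ctrl)
    expect_equal(m$ppv, m$sensitivity * prev /
                   (m$sensitivity * prev + (1 - m$specificity) * (1 - prev)))
    expect_equal(m$npv, m$specificity * (1 - prev) /
                   (m$specificity * (1 - prev) + (1 - m$sensitivity) * prev))
  }
})

test_that("degenerate tables flag metrics instead of zeroing them", {
  perfect <- performance_metrics(list(TP = 10, FP = 0, FN = 0, TN = 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$youden, 1)
  expect_true(is.infinite(perfect$dor))
  expect_true(perfect$dor_infinite)

  no_ctrl_pos <- performance_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(no_ctrl_pos$ppv))
  expect_true("ppv" %in% attr(no_ctrl_pos, "undefined"))
})

test_that("a strong marker reproduces the expected Youden index", {
  # sensitivity 0.56 and specificity 0.90 give Youden 0.46
  tb <- list(TP = 56, FN = 44, TN = 90, FP = 10)
  m <- performance_metrics(tb)
  expect_equal(m$sensitivity, 0.56)
  expect_equal(m$specificity, 0.90)
  expect_equal(round(m$youden, 2), 0.46)
})

test_that("net sensitivity and specificity follow the parallel-test algebra", {
  expect_equal(round(net_sensitivity(0.50, 0.56), 2), 0.78)
  expect_equal(net_sensitivity(1, 0.3), 1)
  expect_equal(net_specificity(1, 0.3), 0.3)
  expect_error(net_sensitivity(1.2, 0.5), "\\[0, 1\\]")
  expect_error(net_specificity(-0.1, 0.5), "\\[0, 1\\]")

  set.seed(23)
  a <- runif(100); b <- runif(100)
  expect_equal(net_sensitivity(a, b), 1 - (1 - a) * (1 - b))
  expect_equal(net_sensitivity(a, b), net_sensitivity(b, a))
  expect_equal(net_specificity(a, b), net_specificity(b, a))
  expect_true(all(net_sensitivity(a, b) >= pmax(a, b)))
  expect_true(all(net_specificity(a, b) <= pmin(a, b)))
})

test_that("empirical parallel testing reduces to single-marker cases", {
  set.seed(24)
  y <- rep(c(1, 0), each = 50)
  a <- stats::rbinom(100, 1, ifelse(y == 1, 0.7, 0.3)) == 1
  none <- rep(FALSE, 100)
  ma <- performance_metrics(dominant_table(as.integer(a), y))
  expect_equal(empirical_parallel_test(a, none, y)$sensitivity,
               ma$sensitivity)
  expect_equal(empirical_parallel_test(a, none, y)$specificity,
               ma$specificity)
  expect_equal(empirical_parallel_test(a, a, y)$youden, ma$youden)
  expect_error(empirical_parallel_test(a[1:10], a, y), "length")
})

test_that("empirical parallel testing matches the formula under conditional independence", {
  set.seed(25)
  n <- 1e4
  y <- rep(c(1, 0), each = n / 2)
  sens_a <- 0.5; sens_b <- 0.56; spec_a <- 0.89; spec_b <- 0.90
  a <- stats::rbinom(n, 1, ifelse(y == 1, sens_a, 1 - spec_a)) == 1
  b <- stats::rbinom(n, 1, ifelse(y == 1, sens_b, 1 - spec_b)) == 1
  emp <- empirical_parallel_test(a, b, y)
  ns <- net_sensitivity(sens_a, sens_b)
  np <- net_specificity(spec_a, spec_b)
  se_s <- sqrt(ns * (1 - ns) / (n / 2))
  se_p <- sqrt(np * (1 - np) / (n / 2))
  expect_lt(abs(emp$sensitivity - ns), 3 * se_s)
  expect_lt(abs(emp$specificity - np), 3 * se_p)
})

test_that("chi-square tests agree with the textbook statistic", {
  # equal carrier fractions: no association signal
  res <- snp_chisq(c(1L, 0L, 1L, 0L), c(1, 1, 0, 0), variant = "dominant")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(26)
  for (i in 1:30) {
    g <- sample(0:2, 120, TRUE)
    y <- sample(0:1, 120, TRUE)
    res <- snp_chisq(g, y, variant = "dominant")
    ref <- suppressWarnings(
      stats::chisq.test(table(g >= 1, y), correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

    res_a <- snp_chisq(g, y, variant = "allelic")
    alle <- rbind(c(sum(g[y == 1]), 2 * sum(y == 1) - sum(g[y == 1])),
                  c(sum(g[y == 0]), 2 * sum(y == 0) - sum(g[y == 0])))
    ref_a <- suppressWarnings(stats::chisq.test(alle, correct = FALSE))
    expect_equal(res_a$statistic, unname(ref_a$statistic), tolerance = 1e-10)
  }
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  thr <- bonferroni_threshold(0.05, 500941)
  expect_equal(thr, 0.05 / 500941)
  expect_equal(signif(thr, 1), 1e-7)
  expect_equal(bonferroni_threshold(0.01, 250) * 250, 0.01)
})

test_that("metric-count selection counts maxima and breaks ties as documented", {
  base <- data.frame(
    snp_id = sprintf("snp%02d", 1:6),
    sensitivity = c(0.9, 0.5, 0.6, 0.5, 0.5, 0.5),
    specificity = c(0.9, 0.6, 0.5, 0.6, 0.6, 0.6),
    youden = c(0.8, 0.1, 0.1, 0.1, 0.1, 0.1),
    auc = c(0.95, 0.7, 0.7, 0.7, 0.7, 0.7),
    p_value = c(1e-5, 0.2, 0.3, 0.2, 0.2, 0.2))
  sel <- select_by_metric_counts(base, k = 2,
                                 metrics = c("sensitivity", "specificity",
                                             "youden", "auc"))
  expect_equal(sel$ranking$snp_id[1], "snp01")
  expect_equal(sel$ranking$metric_count[1], 4L)

  # two identical SNPs tie on everything; order falls back to snp_id
  two <- base[c(2, 2), ]; two$snp_id <- c("b", "a")
  sel2 <- select_by_metric_counts(two, k = 2,
                                  metrics = c("sensitivity", "specificity"))
  expect_equal(sel2$ranking$snp_id, c("a", "b"))

  expect_error(select_by_metric_counts(base, k = 10), "fewer candidate")
})

test_that("metric-count selection matches a brute-force recount", {
  set.seed(27)
  cols <- c("sensitivity", "specificity", "youden", "ppv", "npv", "dor",
            "accuracy", "auc")
  for (rep in 1:10) {
    tab <- as.data.frame(matrix(round(runif(20 * 8), 3), 20, 8))
    names(tab) <- cols
    tab$snp_id <- sprintf("s%02d", 1:20)
    sel <- select_by_metric_counts(tab, k = 5, metrics = cols)
    brute <- sapply(seq_len(20), function(i)
      sum(vapply(cols, function(mc)
        round(tab[[mc]][i], 6) == max(round(tab[[mc]], 6)), logical(1))))
    expect_equal(sel$ranking$metric_count[match(tab$snp_id,
                                                sel$ranking$snp_id)],
                 unname(brute))
    # permutation invariance of the selected set
    perm <- tab[sample(20), ]
    sel_p <- select_by_metric_counts(perm, k = 5, metrics = cols)
    expect_equal(sel_p$selected, sel$selected)
  }
})

test_that("P-value selection keeps ties at the boundary", {
  tab <- data.frame(snp_id = letters[1:7],
                    p_value = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.05, 0.9))
  sel <- select_by_pvalue(tab, k = 5)
  expect_length(sel, 6)
  expect_setequal(as.character(sel), letters[1:6])

  tab$p_value <- seq(0.01, 0.07, by = 0.01)
  expect_length(select_by_pvalue(tab, k = 5), 5)

  set.seed(28)
  tab2 <- data.frame(snp_id = sprintf("x%03d", 1:100),
                     p_value = runif(100))
  sel2 <- select_by_pvalue(tab2, k = 10)
  expect_equal(as.character(sel2),
               tab2$snp_id[order(tab2$p_value)][1:10])
})
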