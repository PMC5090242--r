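test_that("logistic fit reproduces closed forms", {
  # intercept-only: logit of the case fraction
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(matrix(nrow = 100, ncol = 0), y)
  expect_equal(unname(fit$coef[1]), log(30 / 70), tolerance = 1e-8)

  # single binary predictor: log odds ratio of the 2x2 table
  set.seed(30)
  x <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, ifelse(x == 1, 0.7, 0.4))
  fit <- fit_logistic(cbind(x = x), y)
  tab <- table(x, y)
  or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(unname(fit$coef["x"]), log(or), tolerance = 1e-8)
})

test_that("logistic fit matches a direct likelihood optimizer", {
  set.seed(31)
  n <- 50
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- fit_logistic(X, y)
  nll <- function(beta) {
    eta <- beta[1] + X %*% beta[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(unname(fit$coef), opt$par, tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
})

test_that("separation is flagged rather than silently reported", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  expect_warning(fit <- fit_logistic(cbind(x = x), y), "separation")
  expect_false(fit$converged)
})

test_that("conditional logistic equals the matched-pair closed form", {
  set.seed(32)
  n <- 80
  sid <- rep(seq_len(n), each = 2)
  y <- rep(c(1, 0), n)
  x <- rbinom(2 * n, 1, 0.45)
  fit <- fit_conditional_logistic(sid, cbind(x = x), y)
  xm <- matrix(x, 2)
  d10 <- sum(xm[1, ] == 1 & xm[2, ] == 0)
  d01 <- sum(xm[1, ] == 0 & xm[2, ] == 1)
  expect_equal(unname(fit$coef["x"]), log(d10 / d01), tolerance = 1e-6)
  # null conditional log-likelihood is -sum log C(n_s, k_s) = -n log 2
  expect_equal(fit$loglik_null, -n * log(2), tolerance = 1e-10)
})

test_that("conditional likelihood equals subset enumeration on small strata", {
  set.seed(33)
  for (rep in 1:5) {
    sizes <- sample(2:6, 8, TRUE)
    sid <- rep(seq_along(sizes), sizes)
    n <- length(sid)
    y <- unlist(lapply(sizes, function(k) {
      v <- rep(0, k); v[sample(k, sample(1:(k - 1), 1))] <- 1; v
    }))
    x <- cbind(z = rnorm(n), w = rbinom(n, 1, 0.5))
    fit <- suppressMessages(fit_conditional_logistic(sid, x, y))
    expect_equal(fit$loglik, oracle_clogit_loglik(fit$coef, sid, x, y),
                 tolerance = 1e-10)
    expect_equal(fit$loglik_null, oracle_clogit_loglik(c(0, 0), sid, x, y),
                 tolerance = 1e-10)
    # the fitted coefficients maximize the enumerated likelihood
    opt <- stats::optim(c(0, 0), function(b)
      -oracle_clogit_loglik(b, sid, x, y), method = "BFGS",
      control = list(reltol = 1e-14))
    expect_equal(unname(fit$coef), opt$par, tolerance = 1e-5)
  }
})

test_that("uninformative strata are dropped with a message", {
  sid <- c(1, 1, 2, 2, 3, 3)
  y <- c(1, 0, 1, 1, 1, 0)       # stratum 2 has no control
  x <- cbind(x = c(1, 0, 1, 0, 0, 1))
  expect_message(fit <- fit_conditional_logistic(sid, x, y), "dropped")
  expect_equal(fit$n_strata_used, 2L)
  expect_equal(fit$n_strata_dropped, 1L)
})

test_that("point derivation follows the divide-by-reference rule", {
  coefs <- c(age_gt75 = 2.42, female = 0.37, edu_le6 = 2.11,
             apoe_e4 = 0.91, apoc1 = 0.64)
  pm <- derive_points(coefs, "female")
  expect_equal(pm$table$points, c(7L, 1L, 6L, 2L, 2L))
  expect_equal(pm$score_range, c(0L, 18L))

  # the convention is round-half-up to NEAREST: 2.46 -> 2, 6.54 -> 7
  expect_equal(derive_points(c(a = 0.91, ref = 0.37), "ref")$table$points,
               c(2L, 1L))
  expect_equal(derive_points(c(a = 2.42, ref = 0.37), "ref")$table$points,
               c(7L, 1L))

  eq <- derive_points(c(a = 0.5, b = 0.5, c = 0.5), "b")
  expect_equal(eq$table$points, c(1L, 1L, 1L))

  expect_error(derive_points(c(a = 1, ref = -0.2), "ref"), "positive")
  expect_error(derive_points(coefs, "nope"), "not found")
})

test_that("total scores and risk groups partition as intervals", {
  coefs <- c(age_gt75 = 2.42, female = 0.37, edu_le6 = 2.11,
             apoe_e4 = 0.91, apoc1 = 0.64)
  pm <- derive_points(coefs, "female")
  all_on <- matrix(1, 1, 5,
                   dimnames = list(NULL, names(coefs)))
  expect_equal(total_score(all_on, pm), 18L)
  expect_equal(total_score(all_on * 0, pm), 0L)
  expect_error(total_score(all_on[, 1:3, drop = FALSE], pm), "missing")

  set.seed(34)
  scores <- sample(0:18, 100, TRUE)
  g <- assign_groups(scores)
  expect_equal(as.character(g),
               ifelse(scores <= 6, "low",
                      ifelse(scores <= 11, "moderate", "high")))
  expect_true(is.na(assign_groups(NA_integer_)))
})

test_that("group odds ratios match an indicator-design logistic fit", {
  set.seed(35)
  n <- 600
  scores <- sample(0:18, n, TRUE)
  y <- rbinom(n, 1, plogis(-3 + 0.25 * scores))
  g <- assign_groups(scores)
  rg <- group_aor_and_trend(g, y)
  ind <- cbind(moderate = as.numeric(g == "moderate"),
               high = as.numeric(g == "high"))
  ref <- fit_logistic(ind, y)
  expect_equal(rg$aor$or[2], unname(ref$or["moderate"]), tolerance = 1e-8)
  expect_equal(rg$aor$or[3], unname(ref$or["high"]), tolerance = 1e-8)
  # strongly separated scores give monotone group effects and a tiny trend P
  expect_true(rg$aor$or[2] > 1 && rg$aor$or[3] > rg$aor$or[2])
  expect_lt(rg$p_trend, 1e-6)
})

test_that("DeLong AUC equals the pairwise-comparison definition", {
  expect_equal(auc_delong(c(1, 2, 3, 10, 11, 12),
                          c(0, 0, 0, 1, 1, 1))$auc, 1)

  set.seed(36)
  scores <- sample(1:20, 200, TRUE)   # integer scores force ties
  y <- rbinom(200, 1, 0.4)
  res <- auc_delong(scores, y)
  expect_equal(res$auc, oracle_auc_pairwise(scores, y), tolerance = 1e-12)
  expect_true(res$ci_lower <= res$auc && res$auc <= res$ci_upper)

  # labels independent of scores: AUC near 1/2
  n <- 2000
  s <- rnorm(n); yy <- rbinom(n, 1, 0.5)
  n1 <- sum(yy); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc_delong(s, yy)$auc - 0.5), 3 * se)

  expect_error(auc_delong(1:5, rep(1, 5)), "both outcome classes")
})

test_that("LOOCV optimism bookkeeping is internally consistent", {
  set.seed(37)
  n <- 150
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X[, 1] + 0.8 * X[, 2]))
  cv1 <- loocv_optimism(X, y)
  cv2 <- loocv_optimism(X, y)
  expect_identical(cv1, cv2)                       # deterministic
  expect_equal(cv1$corrected, cv1$cv)              # identity of definitions
  expect_equal(cv1$optimism, cv1$apparent - cv1$cv)

  # pure-noise predictors: apparent exceeds cross-validated
  Xn <- cbind(z = rnorm(n))
  yn <- rbinom(n, 1, 0.5)
  cvn <- loocv_optimism(Xn, yn)
  expect_gte(cvn$optimism, 0)
})

test_that("optimism is small for a well-specified model at validation size", {
  opts <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 619
    X <- cbind(age_gt75 = rbinom(n, 1, 0.5), female = rbinom(n, 1, 0.55),
               edu_le6 = rbinom(n, 1, 0.35), apoe_e4 = rbinom(n, 1, 0.2),
               snp = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-2 + X %*% c(2.42, 0.37, 2.11, 0.91, 0.64)))
    loocv_optimism(X, y)$optimism
  }, numeric(1))
  expect_true(all(abs(opts) < 0.05))
})
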