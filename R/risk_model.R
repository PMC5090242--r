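# Mann-Whitney AUC: P(score_case > score_control) + 0.5 * P(tie)
.auc_mann_whitney <- function(scores, labels) {
  y <- .as_case_indicator(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit an unconditional logistic regression model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (through [stats::glm.fit()]), returning coefficients, standard
#' errors from the observed information, odds ratios with Wald 95%
#' confidence intervals and the log-likelihood. A coefficient diverging past
#' 15 in absolute value is taken as evidence of separation and the fit is
#' flagged non-converged with a warning.
#'
#' @param x numeric design matrix (no intercept column; one is added).
#' @param y binary outcome (0/1, logical, or `"case"`/`"control"`), both
#'   classes present.
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return list of class `logistic_fit`: `terms`, `coef`, `se`, `or`,
#'   `or_ci` (2-column matrix), `loglik`, `converged`, `n`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100) {
  y <- .as_case_indicator(y)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both outcome classes are required")
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  beta <- fit$coefficients
  converged <- fit$converged
  if (any(abs(beta) > 15)) {
    warning("possible separation: a coefficient exceeds 15 in absolute ",
            "value; fit flagged non-converged")
    converged <- FALSE
  }
  # observed-information SEs from the weighted cross-product
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  ll <- -fit$deviance / 2
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- names(beta)
  structure(list(terms = colnames(X), coef = beta, se = se,
                 or = exp(beta), or_ci = ci, loglik = ll,
                 converged = converged, n = length(y),
                 fitted = fit$fitted.values),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  df <- data.frame(coef = x$coef, se = x$se, or = x$or,
                   or_low = x$or_ci[, 1], or_high = x$or_ci[, 2])
  print(round(df, 4))
  cat("logLik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

#' Fit a conditional logistic regression model
#'
#' Maximizes the conditional likelihood of a matched/stratified case-control
#' design: within each stratum the contribution is the probability of the
#' observed case set among all same-sized subsets, which removes the
#' stratum-specific intercepts. Fitting is done through
#' [survival::clogit()] with the exact conditional likelihood
#' (`method = "exact"`). Strata carrying no information (all cases or all
#' controls) are dropped with a message.
#'
#' @param strata_ids stratum (matched-set) identifier per sample.
#' @param x numeric design matrix (no intercept; none is identifiable).
#' @param y binary outcome.
#' @return a `logistic_fit` (no intercept term) with additional fields
#'   `loglik_null` (conditional log-likelihood at beta = 0) and
#'   `n_strata_used`/`n_strata_dropped`.
#' @export
fit_conditional_logistic <- function(strata_ids, x, y) {
  y <- .as_case_indicator(y)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  sid <- as.character(strata_ids)
  stopifnot(length(sid) == length(y), nrow(x) == length(y))
  n_case <- tapply(y, sid, sum)
  n_total <- tapply(y, sid, length)
  informative <- names(n_case)[n_case > 0 & n_case < n_total]
  dropped <- length(unique(sid)) - length(informative)
  if (dropped > 0)
    message(dropped, " stratum/strata without both a case and a control ",
            "dropped from the conditional likelihood")
  keep <- sid %in% informative
  if (!any(keep)) stop("no informative strata")
  df <- data.frame(y = y[keep], sid = sid[keep], time = 1)
  df <- cbind(df, as.data.frame(x[keep, , drop = FALSE]))
  # the clogit trick spelled out: conditional logistic likelihood equals a
  # stratified Cox model with unit times, case events, and the exact
  # partial likelihood
  fml <- stats::as.formula(paste(
    "survival::Surv(time, y) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + "),
    "+ survival::strata(sid)"))
  fit <- survival::coxph(fml, data = df, method = "exact")
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- TRUE
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    warning("possible separation in conditional logistic fit")
    converged <- FALSE
  }
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- names(beta)
  structure(list(terms = colnames(x), coef = beta, se = se, or = exp(beta),
                 or_ci = ci, loglik = fit$loglik[2],
                 loglik_null = fit$loglik[1], converged = converged,
                 n = sum(keep), n_strata_used = length(informative),
                 n_strata_dropped = dropped),
            class = "logistic_fit")
}

# round half up to the nearest integer
.round_half_up <- function(x) floor(x + 0.5)

#' Derive an integer point score from logistic coefficients
#'
#' Converts the coefficients of a logistic model with dichotomous predictors
#' into integer points by dividing each coefficient by the reference
#' coefficient — conventionally the smallest coefficient of a dichotomous
#' predictor (e.g. sex) — and rounding half-up to the nearest integer. The
#' reference predictor itself scores 1 point.
#'
#' @param fit a `logistic_fit`, or a named numeric vector of coefficients.
#' @param reference_term name of the reference term.
#' @param terms optional subset of term names to convert (default: all terms
#'   except an intercept).
#' @return list of class `point_model`: `table` (term, coefficient, points),
#'   `reference_term`, `reference_coef`, `score_range` (0 to the sum of
#'   positive points).
#' @export
derive_points <- function(fit, reference_term, terms = NULL) {
  coefs <- if (inherits(fit, "logistic_fit")) fit$coef else fit
  if (is.null(names(coefs))) stop("coefficients must be named")
  if (!reference_term %in% names(coefs))
    stop("reference term '", reference_term, "' not found")
  ref <- coefs[[reference_term]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference coefficient must be positive; re-specify the reference ",
         "term (conventionally the smallest positive dichotomous coefficient)")
  if (is.null(terms))
    terms <- setdiff(names(coefs), "(Intercept)")
  pts <- .round_half_up(coefs[terms] / ref)
  pts[terms == reference_term] <- 1L
  tab <- data.frame(term = terms, coefficient = unname(coefs[terms]),
                    points = as.integer(unname(pts)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, reference_term = reference_term,
                 reference_coef = ref,
                 score_range = c(0L, sum(pmax(tab$points, 0L)))),
            class = "point_model")
}

#' @export
print.point_model <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("score range:", x$score_range[1], "-", x$score_range[2],
      " (reference:", x$reference_term, ")\n")
  invisible(x)
}

#' Total risk score under a point model
#'
#' Sums the points earned by each sample: a predictor contributes its points
#' when the sample's binary indicator for that predictor is 1.
#'
#' @param indicators numeric/logical matrix or data frame of 0/1 predictor
#'   indicators, columns named as the point model's terms.
#' @param point_model a [derive_points()] result.
#' @return integer vector of total scores; samples with a missing indicator
#'   get `NA` (flagged for exclusion from grouping).
#' @export
total_score <- function(indicators, point_model) {
  stopifnot(inherits(point_model, "point_model"))
  ind <- as.matrix(indicators)
  miss <- setdiff(point_model$table$term, colnames(ind))
  if (length(miss) > 0L)
    stop("indicator column(s) missing: ", paste(miss, collapse = ", "))
  ind <- ind[, point_model$table$term, drop = FALSE]
  if (any(!is.na(ind) & !(ind %in% c(0, 1))))
    stop("indicators must be 0/1")
  as.integer(ind %*% point_model$table$points)
}

#' Assign risk groups from total scores
#'
#' Partitions scores into ordered groups at the given lower cut points. The
#' defaults follow a low 0-6 / moderate 7-11 / high 12-18 stratification.
#'
#' @param scores integer scores.
#' @param cuts increasing lower bounds of the non-reference groups (default
#'   `c(7, 12)`).
#' @param labels group labels (length `length(cuts) + 1`).
#' @return ordered factor of group labels; `NA` scores give `NA`.
#' @export
assign_groups <- function(scores, cuts = c(7, 12),
                          labels = c("low", "moderate", "high")) {
  stopifnot(length(labels) == length(cuts) + 1L, !is.unsorted(cuts))
  cut(scores, breaks = c(-Inf, cuts - 0.5, Inf), labels = labels,
      ordered_result = TRUE)
}

#' Risk-group odds ratios and trend test
#'
#' Fits a logistic model with indicator terms for the non-reference risk
#' groups (lowest group as reference) to estimate per-group (adjusted) odds
#' ratios, and a second fit with the group entered as an ordinal 0, 1, 2, ...
#' score whose Wald test supplies the P-for-trend.
#'
#' @param groups factor from [assign_groups()].
#' @param y binary outcome.
#' @param covariates optional numeric design matrix of adjustment terms.
#' @return list of class `risk_grouping`: `counts` (group x phenotype),
#'   `aor` data frame (group, or, lower, upper; reference group OR fixed at
#'   1), `p_trend`, and the two fits.
#' @export
group_aor_and_trend <- function(groups, y, covariates = NULL) {
  y <- .as_case_indicator(y)
  ok <- !is.na(groups)
  groups <- factor(groups[ok])
  y <- y[ok]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  if (any(table(groups) == 0))
    warning("empty risk group(s) merged upward")
  # plain (treatment-contrast) factor so the design is group indicators
  groups <- factor(as.character(droplevels(groups)),
                   levels = levels(droplevels(groups)))
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least two populated risk groups")
  ind <- stats::model.matrix(~ groups)[, -1, drop = FALSE]
  colnames(ind) <- lv[-1]
  X <- if (is.null(covariates)) ind else cbind(ind, covariates)
  fit <- fit_logistic(X, y)
  ordinal <- as.numeric(groups) - 1
  Xt <- if (is.null(covariates)) cbind(trend = ordinal) else
    cbind(trend = ordinal, covariates)
  fit_trend <- fit_logistic(Xt, y)
  zt <- fit_trend$coef[["trend"]] / fit_trend$se[[which(fit_trend$terms == "trend")]]
  p_trend <- 2 * stats::pnorm(-abs(zt))
  idx <- match(lv[-1], names(fit$coef))
  aor <- data.frame(group = lv,
                    or = c(1, unname(fit$or[idx])),
                    lower = c(NA, unname(fit$or_ci[idx, 1])),
                    upper = c(NA, unname(fit$or_ci[idx, 2])),
                    stringsAsFactors = FALSE)
  counts <- table(group = groups, phenotype = ifelse(y == 1, "case",
                                                     "control"))
  structure(list(counts = counts, aor = aor, p_trend = p_trend,
                 fit = fit, fit_trend = fit_trend),
            class = "risk_grouping")
}

#' AUC with DeLong 95% confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney two-sample statistic
#' (ties counted one half), with the DeLong variance estimate for the
#' confidence interval (through \pkg{pROC}), truncated to \[0, 1\].
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome.
#' @return list with `auc`, `ci_lower`, `ci_upper`.
#' @export
auc_delong <- function(scores, labels) {
  y <- .as_case_indicator(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both outcome classes are required")
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)),
       ci_lower = max(0, ci[1]), ci_upper = min(1, ci[3]))
}

#' Leave-one-out cross-validated optimism of the AUC
#'
#' Refits the logistic model `n` times, each time leaving one sample out and
#' scoring it with the refitted model; the cross-validated AUC is computed
#' from the pooled out-of-fold scores. Optimism is the apparent AUC minus
#' the cross-validated AUC, and the optimism-corrected AUC (apparent minus
#' optimism) therefore equals the cross-validated AUC — the identity is
#' checked on every run.
#'
#' @param x numeric design matrix (no intercept column).
#' @param y binary outcome.
#' @return list of class `cv_result`: `apparent`, `cv`, `optimism`,
#'   `corrected`, `n_failed_folds`.
#' @export
loocv_optimism <- function(x, y) {
  y <- .as_case_indicator(y)
  x <- as.matrix(x)
  n <- length(y)
  full <- fit_logistic(x, y)
  apparent <- .auc_mann_whitney(full$fitted, y)
  X <- cbind(1, x)
  oof <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (!any(yi == 1L) || !any(yi == 0L)) { failed <- failed + 1L; next }
    f <- suppressWarnings(stats::glm.fit(X[-i, , drop = FALSE], yi,
                                         family = stats::binomial()))
    if (!f$converged || anyNA(f$coefficients)) { failed <- failed + 1L; next }
    oof[i] <- stats::plogis(drop(X[i, ] %*% f$coefficients))
  }
  use <- !is.na(oof)
  cv <- .auc_mann_whitney(oof[use], y[use])
  optimism <- apparent - cv
  corrected <- apparent - optimism
  stopifnot(isTRUE(all.equal(corrected, cv)))
  structure(list(apparent = apparent, cv = cv, optimism = optimism,
                 corrected = corrected, n_failed_folds = failed),
            class = "cv_result")
}
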