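#' Matching and restriction criteria for the training set
#'
#' Defaults mirror a tightly matched case-control training design: cases and
#' controls matched on sex and comorbidity history with ages within 5 years,
#' restricted to 18.5 < BMI < 27 (exclusive) and never-smokers, with a
#' control allowed to match more than one case.
#'
#' @param age_tolerance maximum absolute age difference within a pair.
#' @param exact_match_vars covariate columns matched exactly (default sex
#'   only; add comorbidity flags such as `hypertension`, `dm`,
#'   `hypercholesterolemia`, `head_injury` when the control pool is large
#'   enough to support them); columns absent from the data are skipped with
#'   a message.
#' @param bmi_window exclusive (lower, upper) BMI restriction; `NULL`
#'   disables.
#' @param never_smokers_only restrict to samples with `smoking == "never"`.
#' @param allow_control_reuse may one control match several cases (reuse is
#'   a fallback: an unused eligible control is always preferred).
#' @return list of class `match_criteria`.
#' @export
match_criteria <- function(age_tolerance = 5,
                           exact_match_vars = "sex",
                           bmi_window = c(18.5, 27),
                           never_smokers_only = TRUE,
                           allow_control_reuse = TRUE) {
  stopifnot(age_tolerance >= 0)
  if (!is.null(bmi_window))
    stopifnot(length(bmi_window) == 2L, bmi_window[1] < bmi_window[2])
  structure(list(age_tolerance = age_tolerance,
                 exact_match_vars = exact_match_vars,
                 bmi_window = bmi_window,
                 never_smokers_only = never_smokers_only,
                 allow_control_reuse = allow_control_reuse),
            class = "match_criteria")
}

#' Restrict the sample and greedily match controls to cases
#'
#' Applies the restriction criteria (BMI window, smoking history), then
#' processes cases in stable sorted order of `sample_id`; each case is
#' paired with the eligible control (exact-match variables equal, age within
#' tolerance) minimizing the absolute age difference, ties broken by lowest
#' control `sample_id`. A not-yet-used eligible control is always preferred;
#' when none exists and reuse is allowed, the nearest already-used control is
#' reused, so one control can match more than one case but reuse stays the
#' exception. Cases with no eligible control are dropped and counted.
#'
#' @param samples covariate table with `sample_id`, `phenotype`, `age` and
#'   the matching variables.
#' @param criteria a [match_criteria()].
#' @return data frame of the matched samples (one row per pair membership;
#'   a reused control appears once) with a `matched_set_id` column, plus
#'   attributes `n_cases_dropped`, `n_restricted_out` and `pairs` (data
#'   frame of case/control ids per set).
#' @export
restrict_and_match <- function(samples, criteria = match_criteria()) {
  stopifnot(inherits(criteria, "match_criteria"),
            all(c("sample_id", "phenotype", "age") %in% names(samples)))
  df <- as.data.frame(samples)
  n_in <- nrow(df)
  if (!is.null(criteria$bmi_window) && "bmi" %in% names(df))
    df <- df[!is.na(df$bmi) & df$bmi > criteria$bmi_window[1] &
               df$bmi < criteria$bmi_window[2], , drop = FALSE]
  if (criteria$never_smokers_only && "smoking" %in% names(df))
    df <- df[!is.na(df$smoking) & df$smoking == "never", , drop = FALSE]
  n_restricted_out <- n_in - nrow(df)

  vars <- intersect(criteria$exact_match_vars, names(df))
  skipped <- setdiff(criteria$exact_match_vars, names(df))
  if (length(skipped) > 0L)
    message("matching variable(s) absent, skipped: ",
            paste(skipped, collapse = ", "))

  is_case <- .as_case_indicator(df$phenotype) == 1L
  cases <- df[is_case, , drop = FALSE]
  controls <- df[!is_case, , drop = FALSE]
  cases <- cases[order(cases$sample_id), , drop = FALSE]

  key <- function(d) if (length(vars) == 0L) rep("", nrow(d)) else
    do.call(paste, c(d[vars], sep = "\r"))
  case_key <- key(cases); control_key <- key(controls)

  pairs <- list()
  used <- rep(FALSE, nrow(controls))
  dropped <- 0L
  for (i in seq_len(nrow(cases))) {
    elig <- control_key == case_key[i] &
      abs(controls$age - cases$age[i]) <= criteria$age_tolerance
    pool <- elig & !used
    if (!any(pool) && criteria$allow_control_reuse) pool <- elig
    if (!any(pool)) { dropped <- dropped + 1L; next }
    cand <- which(pool)
    dist <- abs(controls$age[cand] - cases$age[i])
    cand <- cand[order(dist, controls$sample_id[cand])]
    j <- cand[1L]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      set_id = sprintf("set%04d", length(pairs) + 1L),
      case_id = cases$sample_id[i], control_id = controls$sample_id[j],
      stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) stop("zero matched pairs")
  pairs <- do.call(rbind, pairs)

  long <- rbind(
    data.frame(sample_id = pairs$case_id, matched_set_id = pairs$set_id,
               stringsAsFactors = FALSE),
    data.frame(sample_id = pairs$control_id, matched_set_id = pairs$set_id,
               stringsAsFactors = FALSE))
  out <- merge(long, df, by = "sample_id", sort = TRUE)
  attr(out, "n_cases_dropped") <- dropped
  attr(out, "n_restricted_out") <- n_restricted_out
  attr(out, "pairs") <- pairs
  out
}

# covariate design used by per-SNP AUC models and the final model:
# age>75, female sex, education <=6 years, APOE e4 carrier
.covariate_design <- function(samples) {
  cbind(age_gt75 = as.numeric(samples$age > 75),
        female = as.numeric(samples$sex == "F"),
        edu_le6 = as.numeric(samples$education <= 6),
        apoe_e4 = as.numeric(samples$apoe_e4))
}

#' Run stage 1: QC, metrics, and SNP selection on the training set
#'
#' On the stage-1 (matched training) data: applies QC, computes the per-SNP
#' metric table (with parallel-testing net sensitivity/specificity against
#' APOE e4 and covariate-adjusted per-SNP AUC), ranks SNPs by the
#' metric-count rule and by P-value, derives QQ/Manhattan plot data, and
#' fits conditional-logistic adjusted odds ratios (conditioned on the
#' matched sets) for the selected SNPs.
#'
#' @param genotypes a [genotype_dataset()] (stage-1 samples).
#' @param samples matched covariate table with `matched_set_id` (e.g. from
#'   [restrict_and_match()]).
#' @param k number of SNPs to select (default 5).
#' @param thresholds a [qc_thresholds()].
#' @param out_dir optional directory: writes `metrics.tsv`,
#'   `qc_report.tsv`, `selection.json`, `qq.tsv`, `manhattan.tsv`.
#' @param compute_auc compute the per-SNP covariate-adjusted AUC column
#'   (disable to speed up large scans; AUC then drops out of the metric-count
#'   rule).
#' @return list of class `stage1_result`: `qc`, `metrics` (per-SNP table),
#'   `selection_metric`, `selection_pvalue`, `aor` (conditional-logistic ORs
#'   for the metric-selected SNPs), `qq`, `manhattan`, `bonferroni`.
#' @export
run_stage1 <- function(genotypes, samples, k = 5,
                       thresholds = qc_thresholds(), out_dir = NULL,
                       compute_auc = TRUE) {
  # metrics and QC use each distinct individual once; the matched-set long
  # structure (reused controls repeated) is kept for the conditional fits
  long <- as.data.frame(samples)
  uni <- long[!duplicated(long$sample_id), , drop = FALSE]
  genotypes <- subset_genotypes(genotypes, samples = uni$sample_id)
  qc <- apply_qc(genotypes, uni, thresholds)
  ds <- qc$dataset
  samp <- qc$samples
  y <- .as_case_indicator(samp$phenotype)

  covar <- if (compute_auc) .covariate_design(samp) else NULL
  metrics <- snp_metrics_table(ds, y,
                               reference_marker = samp$apoe_e4 == 1L,
                               covariate_design = covar)
  sel_metric <- select_by_metric_counts(metrics, k = k)
  sel_p <- select_by_pvalue(metrics, k = k)
  qq <- qq_data(metrics$p_value)
  manhattan <- data.frame(snp_id = ds$snps$snp_id, chr = ds$snps$chr,
                          pos = ds$snps$pos,
                          neg_log10_p = -log10(metrics$p_value),
                          stringsAsFactors = FALSE)

  # conditional-logistic AOR (matched sets) for the metric-selected SNPs,
  # on the long pair structure restricted to QC-surviving samples
  if (!"matched_set_id" %in% names(long))
    stop("stage-1 samples need a 'matched_set_id' column (see ",
         "restrict_and_match)")
  long <- long[long$sample_id %in% ds$sample_ids, , drop = FALSE]
  li <- match(long$sample_id, ds$sample_ids)
  yl <- .as_case_indicator(long$phenotype)
  aor <- lapply(sel_metric$selected, function(id) {
    g <- ds$matrix[li, match(id, ds$snps$snp_id)]
    ok <- !is.na(g)
    fit <- try(suppressMessages(suppressWarnings(fit_conditional_logistic(
      long$matched_set_id[ok],
      cbind(carrier = as.numeric(g[ok] >= 1L)), yl[ok]))), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(snp_id = id, aor = NA_real_, lower = NA_real_,
                        upper = NA_real_, converged = FALSE))
    data.frame(snp_id = id, aor = unname(fit$or[1]),
               lower = unname(fit$or_ci[1, 1]),
               upper = unname(fit$or_ci[1, 2]),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  aor <- do.call(rbind, aor)

  res <- structure(list(
    qc = qc, metrics = metrics, selection_metric = sel_metric,
    selection_pvalue = sel_p, aor = aor, qq = qq, manhattan = manhattan,
    bonferroni = bonferroni_threshold(0.05, nrow(metrics)), k = k
  ), class = "stage1_result")
  if (!is.null(out_dir)) .write_stage1_reports(res, out_dir)
  res
}

.write_stage1_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_tsv(res$metrics, file.path(out_dir, "metrics.tsv"))
  write_results_tsv(res$qc$snp_stats, file.path(out_dir, "qc_report.tsv"))
  write_results_tsv(res$qq, file.path(out_dir, "qq.tsv"))
  write_results_tsv(res$manhattan, file.path(out_dir, "manhattan.tsv"))
  sel <- list(
    metric_rule = res$selection_metric$selected,
    metric_counts = res$selection_metric$ranking$metric_count[
      seq_len(res$k)],
    pvalue_rule = as.character(res$selection_pvalue),
    bonferroni_threshold = res$bonferroni,
    qc_removed = as.list(res$qc$removed))
  jsonlite::write_json(sel, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run stage 2: validation, final model, points, risk groups, LOOCV
#'
#' On the stage-2 (validation) data and the stage-1 selected SNPs:
#' re-checks Hardy-Weinberg equilibrium among controls, recomputes the
#' metric table, evaluates simultaneous (parallel) testing of each SNP with
#' APOE e4, picks the best-overall SNP by metric counts (ties by AUC), fits
#' the final logistic model (age>75, female sex, education <=6 years, APOE
#' e4 carrier, SNP carrier), derives the integer point model (sex as
#' reference coefficient), scores and groups all samples, estimates
#' per-group adjusted odds ratios with a trend test, and reports the
#' apparent AUC with DeLong CI plus the LOOCV optimism-corrected AUC. A
#' conditional-logistic fit stratified on 5-year age intervals (with
#' continuous age kept in the design) supplies the per-SNP validation AOR.
#'
#' @param genotypes a [genotype_dataset()] covering the stage-2 samples.
#' @param samples stage-2 covariate table.
#' @param selected_snps character vector of SNP ids from stage 1.
#' @param group_cuts lower bounds of the moderate/high risk groups.
#' @param out_dir optional directory: writes `metrics.tsv`,
#'   `model_report.json`, `scores.tsv`, `groups.tsv`.
#' @return list of class `stage2_result`: `hwe` (per-SNP control HWE P),
#'   `metrics`, `parallel` (per-SNP empirical + formula net metrics),
#'   `best_snp`, `final_fit`, `age_stratified_aor`, `points`
#'   (a `point_model`), `scores`, `groups`, `grouping` (AORs + trend),
#'   `auc` (with CI), `cv` (a `cv_result`).
#' @export
run_stage2 <- function(genotypes, samples, selected_snps,
                       group_cuts = c(7, 12), out_dir = NULL) {
  missing_snps <- setdiff(selected_snps, genotypes$snps$snp_id)
  if (length(missing_snps) > 0L)
    stop("selected SNP(s) absent from stage-2 data: ",
         paste(missing_snps, collapse = ", "))
  genotypes <- subset_genotypes(genotypes, samples = samples$sample_id)
  ds <- subset_genotypes(genotypes, snps = selected_snps)
  y <- .as_case_indicator(samples$phenotype)

  # HWE re-check among controls
  cc <- .geno_counts(ds$matrix[y == 0L, , drop = FALSE])
  hwe <- data.frame(
    snp_id = selected_snps,
    maf_controls = as.numeric(minor_allele_freq(ds, subset = which(y == 0L))),
    hwe_p_controls = vapply(seq_along(selected_snps), function(j)
      hwe_exact_test(cc[j, 1L], cc[j, 2L], cc[j, 3L]), numeric(1)),
    stringsAsFactors = FALSE)

  covar <- .covariate_design(samples)
  apoe_carrier <- samples$apoe_e4 == 1L
  metrics <- snp_metrics_table(ds, y, reference_marker = apoe_carrier,
                               covariate_design = covar)

  # simultaneous testing of each SNP with APOE e4: empirical and formula
  parallel <- lapply(seq_along(selected_snps), function(j) {
    g <- ds$matrix[, j]
    ok <- !is.na(g)
    emp <- empirical_parallel_test(apoe_carrier[ok], g[ok] >= 1L, y[ok])
    data.frame(snp_id = selected_snps[j],
               net_sensitivity_formula = metrics$net_sensitivity[j],
               net_specificity_formula = metrics$net_specificity[j],
               net_sensitivity_empirical = emp$sensitivity,
               net_specificity_empirical = emp$specificity,
               stringsAsFactors = FALSE)
  })
  parallel <- do.call(rbind, parallel)

  # best overall SNP by metric counts, ties by AUC; fall back if monomorphic
  sel <- select_by_metric_counts(metrics, k = 1)
  ranked <- sel$ranking$snp_id
  best_snp <- NULL
  for (id in ranked) {
    g <- ds$matrix[, match(id, ds$snps$snp_id)]
    if (length(unique(g[!is.na(g)])) > 1L) { best_snp <- id; break }
    warning("SNP ", id, " is monomorphic in stage 2; falling back to the ",
            "next-ranked SNP")
  }
  if (is.null(best_snp)) stop("all selected SNPs monomorphic in stage 2")

  g_best <- ds$matrix[, match(best_snp, ds$snps$snp_id)]
  ok <- !is.na(g_best) & stats::complete.cases(covar)
  X <- cbind(covar, snp_carrier = as.numeric(g_best >= 1L))[ok, , drop = FALSE]
  yk <- y[ok]
  final_fit <- fit_logistic(X, yk)

  # validation AOR conditioned on 5-year age strata, continuous age retained
  age_stratum <- floor(samples$age / 5)
  strat_fit <- try(suppressMessages(suppressWarnings(
    fit_conditional_logistic(
      age_stratum[ok],
      cbind(snp_carrier = as.numeric(g_best[ok] >= 1L), age = samples$age[ok],
            covar[ok, c("female", "edu_le6", "apoe_e4"), drop = FALSE]),
      yk))), silent = TRUE)
  age_stratified_aor <- if (inherits(strat_fit, "try-error")) NULL else
    strat_fit

  points <- derive_points(final_fit, reference_term = "female",
                          terms = colnames(X))
  scores <- rep(NA_integer_, length(y))
  scores[ok] <- total_score(X, points)
  groups <- assign_groups(scores, cuts = group_cuts)
  grouping <- group_aor_and_trend(groups, y)
  auc <- auc_delong(scores[ok], yk)
  cv <- loocv_optimism(X, yk)

  res <- structure(list(
    hwe = hwe, metrics = metrics, parallel = parallel, best_snp = best_snp,
    final_fit = final_fit, age_stratified_aor = age_stratified_aor,
    points = points, scores = scores, groups = groups, grouping = grouping,
    auc = auc, cv = cv, group_cuts = group_cuts,
    sample_ids = samples$sample_id
  ), class = "stage2_result")
  if (!is.null(out_dir)) .write_stage2_reports(res, samples, out_dir)
  res
}

.write_stage2_reports <- function(res, samples, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_tsv(res$metrics, file.path(out_dir, "metrics.tsv"))
  write_results_tsv(
    data.frame(sample_id = samples$sample_id,
               phenotype = samples$phenotype,
               score = res$scores, group = as.character(res$groups),
               stringsAsFactors = FALSE),
    file.path(out_dir, "scores.tsv"))
  grp <- as.data.frame.matrix(res$grouping$counts)
  grp <- cbind(group = rownames(grp), grp,
               res$grouping$aor[match(rownames(grp),
                                      res$grouping$aor$group), -1])
  write_results_tsv(grp, file.path(out_dir, "groups.tsv"))
  report <- list(
    best_snp = res$best_snp,
    coefficients = as.list(res$final_fit$coef),
    points = stats::setNames(as.list(res$points$table$points),
                             res$points$table$term),
    score_range = res$points$score_range,
    auc = res$auc,
    loocv = res$cv[c("apparent", "cv", "optimism", "corrected")],
    p_trend = res$grouping$p_trend,
    hwe = res$hwe)
  jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the full two-stage study end to end
#'
#' Simulates (or accepts) a two-stage dataset, restricts and matches the
#' stage-1 samples, runs stage-1 selection and stage-2 validation, and
#' returns everything. Deterministic given the configuration seed.
#'
#' @param config a [simulation_config()], or a list with elements
#'   `genotypes` (a [genotype_dataset()]) and `samples` (covariate table with
#'   a `stage` column).
#' @param k SNPs to select in stage 1.
#' @param thresholds a [qc_thresholds()].
#' @param criteria a [match_criteria()].
#' @param group_cuts risk-group lower bounds.
#' @param out_dir optional output directory; stage reports are written to
#'   `stage1/` and `stage2/` subdirectories plus a run `manifest.json`.
#' @return list of class `full_run`: `study`, `matched`, `stage1`, `stage2`.
#' @export
run_full_study <- function(config, k = 5, thresholds = qc_thresholds(),
                           criteria = match_criteria(),
                           group_cuts = c(7, 12), out_dir = NULL) {
  if (inherits(config, "simulation_config")) {
    study <- simulate_study(config)
  } else {
    stopifnot(is.list(config), inherits(config$genotypes, "genotype_dataset"),
              is.data.frame(config$samples))
    study <- config
  }
  samples <- study$samples
  if (!"stage" %in% names(samples)) stop("samples need a 'stage' column")

  s1 <- samples[samples$stage == 1L, , drop = FALSE]
  matched <- restrict_and_match(s1, criteria)
  stage1 <- run_stage1(study$genotypes, matched, k = k,
                       thresholds = thresholds,
                       out_dir = if (is.null(out_dir)) NULL else
                         file.path(out_dir, "stage1"))
  s2 <- samples[samples$stage == 2L, , drop = FALSE]
  stage2 <- run_stage2(study$genotypes, s2,
                       stage1$selection_metric$selected,
                       group_cuts = group_cuts,
                       out_dir = if (is.null(out_dir)) NULL else
                         file.path(out_dir, "stage2"))
  res <- structure(list(study = study, matched = matched, stage1 = stage1,
                        stage2 = stage2), class = "full_run")
  if (!is.null(out_dir)) {
    manifest <- list(
      seed = if (inherits(config, "simulation_config")) config$seed else NA,
      n_samples = nrow(samples),
      n_snps = nrow(study$genotypes$snps),
      stage1_selected = stage1$selection_metric$selected,
      stage2_best_snp = stage2$best_snp,
      k = k, group_cuts = group_cuts,
      package_version = as.character(utils::packageVersion("snpmetrics")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Read a run configuration from a YAML file
#'
#' Configuration files use nested sections `simulate`, `qc`, `selection`,
#' `model`, `matching`; each key overrides the corresponding argument
#' default of [simulation_config()], [qc_thresholds()], [match_criteria()]
#' or [run_full_study()]. Unknown keys raise a schema error naming them.
#'
#' @param path YAML file path.
#' @return list with `config` (a `simulation_config`), `thresholds`,
#'   `criteria`, `k`, `group_cuts`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_sections <- c("simulate", "qc", "selection", "model", "matching")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0L)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  check_keys <- function(given, fn, section) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0L)
      stop("unknown key(s) in [", section, "]: ", paste(bad, collapse = ", "))
    given
  }
  sim <- check_keys(raw$simulate %||% list(), simulation_config, "simulate")
  if (!is.null(sim$causal_snps))
    sim$causal_snps <- as.data.frame(sim$causal_snps)
  if (!is.null(sim$maf_range)) sim$maf_range <- unlist(sim$maf_range)
  if (!is.null(sim$apoe_freqs)) sim$apoe_freqs <- unlist(sim$apoe_freqs)
  if (!is.null(sim$apoe_or)) sim$apoe_or <- unlist(sim$apoe_or)
  if (!is.null(sim$covariate_effects))
    sim$covariate_effects <- unlist(sim$covariate_effects)
  config <- do.call(simulation_config, sim)
  thresholds <- do.call(qc_thresholds,
                        check_keys(raw$qc %||% list(), qc_thresholds, "qc"))
  criteria <- do.call(match_criteria,
                      check_keys(raw$matching %||% list(), match_criteria,
                                 "matching"))
  selection <- raw$selection %||% list()
  model <- raw$model %||% list()
  list(config = config, thresholds = thresholds, criteria = criteria,
       k = selection$k %||% 5,
       group_cuts = unlist(model$group_cuts %||% c(7, 12)),
       seed = config$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
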