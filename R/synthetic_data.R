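#' Configuration for a synthetic two-stage case-control study
#'
#' Bundles the ground-truth parameters of the generator. Defaults describe a
#' two-stage late-onset Alzheimer's-like study: a small matched training set
#' (55 cases / 39 controls), a larger validation set (196 cases / 423
#' controls), biallelic autosomal SNPs in Hardy-Weinberg equilibrium with
#' minor allele frequencies drawn uniformly from `maf_range`, a handful of
#' causal SNPs with dominant-model odds ratios in the moderate-to-strong
#' range, and an APOE-like two-SNP haplotype locus whose epsilon-4 haplotype
#' carries a strong risk effect (heterozygote carrier OR 3.5, homozygote OR
#' 17.7 versus non-carriers).
#'
#' Default causal odds ratios (9, 8, 7, 6, 5) span the strong end of the
#' adjusted odds ratios such two-stage designs report for validated loci, and
#' the default causal minor allele frequencies (0.12-0.50) mirror the control
#' MAFs of validated LOAD markers, keeping planted signals comfortably inside
#' the MAF >= 0.05 quality filter.
#'
#' @param seed integer seed; every draw in [simulate_study()] flows from it.
#' @param m_snps number of autosomal background SNPs (causal SNPs among them).
#' @param maf_range length-2 numeric, uniform range for minor allele
#'   frequencies.
#' @param stage1_cases,stage1_controls,stage2_cases,stage2_controls stage
#'   sample sizes.
#' @param causal_snps data frame with columns `index` (1-based SNP index) and
#'   `or` (dominant-model odds ratio), plus an optional `maf` column fixing
#'   those SNPs' minor allele frequencies (otherwise drawn from `maf_range`);
#'   `NULL` for no causal background SNPs.
#' @param apoe_freqs named numeric, haplotype frequencies for `e2`, `e3`,
#'   `e4`; must sum to 1.
#' @param apoe_or length-2 numeric: odds ratios for one and two e4 haplotypes
#'   versus none.
#' @param covariate_effects named log-odds for `age_gt75`, `female`,
#'   `edu_le6`.
#' @param baseline_prevalence disease probability for a reference individual.
#' @param missing_rate genotype missing-call rate injected uniformly.
#' @param pop_multiplier simulated population size as a multiple of the total
#'   cases requested; raise it if case sampling fails.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              m_snps = 200L,
                              maf_range = c(0.05, 0.5),
                              stage1_cases = 55L, stage1_controls = 39L,
                              stage2_cases = 196L, stage2_controls = 423L,
                              causal_snps = data.frame(
                                index = 1:5,
                                or = c(9, 8, 7, 6, 5),
                                maf = c(0.12, 0.20, 0.45, 0.49, 0.50)),
                              apoe_freqs = c(e2 = 0.08, e3 = 0.84, e4 = 0.08),
                              apoe_or = c(3.5, 17.7),
                              covariate_effects = c(age_gt75 = 2.42,
                                                    female = 0.37,
                                                    edu_le6 = 2.11),
                              baseline_prevalence = 0.05,
                              missing_rate = 0.005,
                              pop_multiplier = 50) {
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2])
  stopifnot(all(c(stage1_cases, stage2_cases) >= 0),
            stage1_cases + stage2_cases >= 1,
            all(c(stage1_controls, stage2_controls) >= 0))
  if (abs(sum(apoe_freqs) - 1) > 1e-8)
    stop("apoe_freqs must sum to 1")
  if (any(apoe_freqs < 0) || any(apoe_freqs >= 1 + 1e-12))
    stop("apoe_freqs must lie in [0, 1)... each frequency in [0,1]")
  if (!is.null(causal_snps)) {
    stopifnot(is.data.frame(causal_snps),
              all(c("index", "or") %in% names(causal_snps)))
    if (any(causal_snps$or <= 0)) stop("causal odds ratios must be positive")
    if (any(causal_snps$index < 1 | causal_snps$index > m_snps))
      stop("causal SNP index out of range")
    if ("maf" %in% names(causal_snps) &&
        any(causal_snps$maf <= 0 | causal_snps$maf >= 1))
      stop("causal SNP maf must lie in (0, 1)")
  }
  stopifnot(all(apoe_or > 0), baseline_prevalence > 0,
            baseline_prevalence < 1, missing_rate >= 0, missing_rate < 1,
            pop_multiplier >= 1)
  structure(list(
    seed = as.integer(seed), m_snps = as.integer(m_snps),
    maf_range = maf_range,
    stage1_cases = as.integer(stage1_cases),
    stage1_controls = as.integer(stage1_controls),
    stage2_cases = as.integer(stage2_cases),
    stage2_controls = as.integer(stage2_controls),
    causal_snps = causal_snps, apoe_freqs = apoe_freqs, apoe_or = apoe_or,
    covariate_effects = covariate_effects,
    baseline_prevalence = baseline_prevalence,
    missing_rate = missing_rate, pop_multiplier = pop_multiplier
  ), class = "simulation_config")
}

#' Simulate Hardy-Weinberg genotypes at one SNP
#'
#' Draws `n` independent minor-allele dosage codes with genotype
#' probabilities `(1-maf)^2`, `2 maf (1-maf)`, `maf^2` for codes 0, 1, 2 —
#' the Hardy-Weinberg proportions, so control genotypes satisfy the null of
#' the HWE test by construction.
#'
#' @param maf minor allele frequency in (0, 1).
#' @param n number of individuals.
#' @return integer vector of codes in `{0, 1, 2}`.
#' @export
simulate_genotypes_hwe <- function(maf, n) {
  if (length(maf) != 1L || !is.finite(maf) || maf <= 0 || maf >= 1)
    stop("maf must be a single value in (0, 1)")
  stopifnot(n >= 1)
  stats::rbinom(n, 2L, maf)
}

#' Simulate an APOE-like two-SNP haplotype locus
#'
#' Each individual receives two haplotypes drawn i.i.d. from `{e2, e3, e4}`
#' with the given frequencies. The e4 haplotype carries the minor allele of
#' an rs429358-like SNP; the e2 haplotype carries the minor allele of an
#' rs7412-like SNP; e3 carries neither. An individual is an e4 carrier when
#' at least one of their haplotypes is e4.
#'
#' @param freqs numeric length 3 (e2, e3, e4 frequencies), summing to 1.
#' @param n number of individuals.
#' @return a list with integer vectors `rs429358`, `rs7412` (dosage codes),
#'   `n_e4` (e4 haplotype count) and logical `e4_carrier`.
#' @export
simulate_apoe_locus <- function(freqs, n) {
  freqs <- unname(freqs)
  if (length(freqs) != 3L || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 3 non-negative values summing to 1")
  stopifnot(n >= 1)
  h1 <- sample.int(3L, n, replace = TRUE, prob = freqs)
  h2 <- sample.int(3L, n, replace = TRUE, prob = freqs)
  n_e4 <- (h1 == 3L) + (h2 == 3L)
  n_e2 <- (h1 == 1L) + (h2 == 1L)
  list(rs429358 = as.integer(n_e4), rs7412 = as.integer(n_e2),
       n_e4 = as.integer(n_e4), e4_carrier = n_e4 >= 1L)
}

# truncated-normal draw by rejection (vectorized, cheap at these scales)
.rtnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a two-stage case-control genotype study
#'
#' Generates a large source population with covariates and risk genotypes,
#' assigns disease status from a logistic model (baseline prevalence,
#' dominant causal-SNP effects, APOE-like locus effects, covariate effects),
#' then retrospectively samples the configured numbers of cases and controls
#' per stage, emulating case-control ascertainment. Stage-1 subjects are
#' drawn from the population subset satisfying the training-set restriction
#' criteria (18.5 < BMI < 27, never-smokers), so that stage-1 sizes are the
#' sizes entering matching. Genotype missingness is injected uniformly at
#' `missing_rate`.
#'
#' Background (non-causal) SNPs are independent of disease by construction,
#' so they are drawn only for the sampled individuals; causal SNPs and the
#' APOE-like locus are drawn for the whole population before disease
#' assignment.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_study` with elements `genotypes`
#'   (a [genotype_dataset()] including the two APOE-like SNPs as the last two
#'   columns, ids `rs429358_sim`/`rs7412_sim`), `samples` (a covariate table
#'   with `stage`, comorbidity flags and `apoe_e4`), and `truth` (the config
#'   plus realized causal-SNP minor allele frequencies).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  n_cases_needed <- cfg$stage1_cases + cfg$stage2_cases
  n_controls_needed <- cfg$stage1_controls + cfg$stage2_controls
  n_pop <- ceiling(cfg$pop_multiplier * max(n_cases_needed, 1L))

  ## population covariates
  age <- .rtnorm_min(n_pop, 75, 6, 65)
  female <- stats::rbinom(n_pop, 1L, 0.55)
  # education (years): mixture of primary-or-less, secondary, tertiary
  edu_grp <- sample.int(3L, n_pop, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  education <- c(stats::rpois(n_pop, 3),
                 stats::rpois(n_pop, 9) + 3L,
                 stats::rpois(n_pop, 2) + 13L)[cbind(seq_len(n_pop) +
                                                       (edu_grp - 1L) * n_pop)]
  bmi <- stats::rnorm(n_pop, 23.5, 3)
  smoking <- stats::rbinom(n_pop, 1L, 0.25)
  hypertension <- stats::rbinom(n_pop, 1L, 0.45)
  dm <- stats::rbinom(n_pop, 1L, 0.20)
  hypercholesterolemia <- stats::rbinom(n_pop, 1L, 0.28)
  head_injury <- stats::rbinom(n_pop, 1L, 0.05)

  ## risk genotypes for the whole population
  mafs <- stats::runif(cfg$m_snps, cfg$maf_range[1], cfg$maf_range[2])
  causal <- cfg$causal_snps
  if (!is.null(causal) && "maf" %in% names(causal))
    mafs[causal$index] <- causal$maf
  causal_geno <- NULL
  if (!is.null(causal) && nrow(causal) > 0L) {
    causal_geno <- vapply(causal$index,
                          function(j) simulate_genotypes_hwe(mafs[j], n_pop),
                          integer(n_pop))
  }
  apoe <- simulate_apoe_locus(cfg$apoe_freqs, n_pop)

  ## disease assignment: intercept calibrated so the realized population
  ## prevalence equals baseline_prevalence (with strong risk effects a raw
  ## qlogis(prevalence) intercept would inflate the population prevalence
  ## far above the target)
  eta <- numeric(n_pop)
  if (!is.null(causal_geno))
    for (k in seq_len(nrow(causal)))
      eta <- eta + log(causal$or[k]) * (causal_geno[, k] >= 1L)
  eta <- eta + ifelse(apoe$n_e4 == 1L, log(cfg$apoe_or[1]),
                      ifelse(apoe$n_e4 >= 2L, log(cfg$apoe_or[2]), 0))
  ce <- cfg$covariate_effects
  eta <- eta + ce[["age_gt75"]] * (age > 75) + ce[["female"]] * female +
    ce[["edu_le6"]] * (education <= 6)
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + eta)) - cfg$baseline_prevalence,
    interval = c(-50, 50), tol = 1e-10)$root
  disease <- stats::rbinom(n_pop, 1L, stats::plogis(intercept + eta))

  ## retrospective stage sampling
  restricted <- bmi > 18.5 & bmi < 27 & smoking == 0L
  pick <- function(pool, n, what) {
    if (length(pool) < n)
      stop("population has only ", length(pool), " ", what, " but ", n,
           " requested; increase pop_multiplier")
    if (n == 0L) integer(0) else sample(pool, n)
  }
  s1_cases <- pick(which(disease == 1L & restricted), cfg$stage1_cases,
                   "restricted cases (stage 1)")
  s1_controls <- pick(which(disease == 0L & restricted), cfg$stage1_controls,
                      "restricted controls (stage 1)")
  used <- c(s1_cases, s1_controls)
  s2_cases <- pick(setdiff(which(disease == 1L), used), cfg$stage2_cases,
                   "cases (stage 2)")
  s2_controls <- pick(setdiff(which(disease == 0L), used),
                      cfg$stage2_controls, "controls (stage 2)")
  idx <- c(s1_cases, s1_controls, s2_cases, s2_controls)
  stage <- rep(c(1L, 1L, 2L, 2L),
               c(length(s1_cases), length(s1_controls),
                 length(s2_cases), length(s2_controls)))
  n_samp <- length(idx)

  ## background SNPs only for sampled individuals (independent of disease)
  geno <- matrix(stats::rbinom(n_samp * cfg$m_snps, 2L,
                               rep(mafs, each = n_samp)),
                 n_samp, cfg$m_snps)
  if (!is.null(causal_geno))
    geno[, causal$index] <- causal_geno[idx, , drop = FALSE]
  geno <- cbind(geno, apoe$rs429358[idx], apoe$rs7412[idx])

  if (cfg$missing_rate > 0) {
    drop_mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[drop_mask] <- NA_integer_
  }

  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  snp_ids <- c(sprintf("snp%05d", seq_len(cfg$m_snps)),
               "rs429358_sim", "rs7412_sim")
  snps <- data.frame(
    snp_id = snp_ids,
    chr = as.character(rep_len(1:22, cfg$m_snps + 2L)),
    pos = seq_len(cfg$m_snps + 2L) * 1000L,
    allele_minor = "A", allele_major = "G",
    stringsAsFactors = FALSE
  )
  genotypes <- genotype_dataset(geno, sample_ids, snps)

  samples <- data.frame(
    sample_id = sample_ids,
    phenotype = ifelse(disease[idx] == 1L, "case", "control"),
    age = round(age[idx], 1),
    sex = ifelse(female[idx] == 1L, "F", "M"),
    education = as.integer(education[idx]),
    bmi = round(bmi[idx], 1),
    smoking = ifelse(smoking[idx] == 1L, "ever", "never"),
    apoe_e4 = as.integer(apoe$e4_carrier[idx]),
    stage = stage,
    hypertension = hypertension[idx],
    dm = dm[idx],
    hypercholesterolemia = hypercholesterolemia[idx],
    head_injury = head_injury[idx],
    stringsAsFactors = FALSE
  )
  class(samples) <- c("sample_table", "data.frame")

  truth <- list(config = cfg, mafs = mafs,
                causal_snp_ids = if (is.null(causal)) character(0)
                                 else snp_ids[causal$index])
  structure(list(genotypes = genotypes, samples = samples, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  tab <- table(x$samples$stage, x$samples$phenotype)
  cat("simulated_study:", nrow(x$samples), "samples,",
      nrow(x$genotypes$snps), "SNPs\n")
  print(tab)
  invisible(x)
}
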