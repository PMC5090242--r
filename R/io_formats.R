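#' Construct a genotype dataset
#'
#' A `genotype_dataset` holds a samples-by-SNPs matrix of minor-allele dosage
#' codes (0, 1, 2 or `NA` for a missing call) together with SNP map metadata.
#' Codes count copies of the *minor* allele, i.e. the less frequent allele
#' among all non-missing calls in the source data, with frequency ties broken
#' by taking the lexicographically smaller allele as minor.
#'
#' @param matrix integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers, one per row.
#' @param snps data frame with columns `snp_id`, `chr`, `pos`, `allele_minor`,
#'   `allele_major`; one row per matrix column. Positions are 1-based as in
#'   PLINK `.map` files.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(matrix, sample_ids, snps) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  stopifnot(is.character(sample_ids), is.data.frame(snps))
  required <- c("snp_id", "chr", "pos", "allele_minor", "allele_major")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0L)
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(matrix) != length(sample_ids))
    stop("matrix has ", nrow(matrix), " rows but ", length(sample_ids),
         " sample ids")
  if (ncol(matrix) != nrow(snps))
    stop("matrix has ", ncol(matrix), " columns but ", nrow(snps), " SNPs")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated SNP ids")
  if (any(!is.na(snps$pos) & snps$pos < 1))
    stop("SNP positions must be positive (1-based)")
  bad <- matrix[!is.na(matrix)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(matrix) <- list(sample_ids, snps$snp_id)
  structure(
    list(matrix = matrix, sample_ids = sample_ids,
         snps = as.data.frame(snps, stringsAsFactors = FALSE)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$sample_ids), "samples x",
      nrow(x$snps), "SNPs\n")
  miss <- mean(is.na(x$matrix))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$matrix)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param x a `genotype_dataset`.
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return the subsetted `genotype_dataset`.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  vi <- if (is.null(snps)) seq_len(nrow(x$snps)) else {
    if (is.character(snps)) match(snps, x$snps$snp_id) else snps
  }
  if (anyNA(vi)) stop("unknown SNP id(s)")
  genotype_dataset(x$matrix[si, vi, drop = FALSE], x$sample_ids[si],
                   x$snps[vi, , drop = FALSE])
}

# Decide the minor allele among non-missing single-character allele calls.
# Frequency tie at 0.5 -> lexicographically smaller allele, so orientation is
# deterministic given the file.
.orient_alleles <- function(a1, a2, snp_id, line_hint = NULL) {
  alleles <- c(a1, a2)
  alleles <- alleles[alleles != "0"]
  tab <- sort(table(alleles))
  if (length(tab) > 2L)
    stop("SNP ", snp_id, " has more than 2 distinct alleles: ",
         paste(names(tab), collapse = ", "))
  if (length(tab) == 0L) {
    # all calls missing: arbitrary placeholder alleles, all codes NA anyway
    return(list(minor = "N", major = "N"))
  }
  if (length(tab) == 1L)
    return(list(minor = names(tab), major = names(tab)))
  if (tab[[1L]] == tab[[2L]]) {
    nm <- sort(names(tab))
    list(minor = nm[1L], major = nm[2L])
  } else {
    list(minor = names(tab)[1L], major = names(tab)[2L])
  }
}

#' Read PLINK text genotype files
#'
#' Parses a whitespace-delimited PLINK `.ped`/`.map` pair into a
#' [genotype_dataset()]. Each `.ped` row has six leading fields (family id,
#' individual id, paternal id, maternal id, sex, phenotype) followed by two
#' allele calls per SNP; `"0"` denotes a missing allele, and a `0 0` pair
#' becomes a missing genotype. The minor allele at each SNP is the less
#' frequent allele among all non-missing calls in the file (ties broken
#' lexicographically), and genotype codes count minor-allele copies.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file (4 columns: chromosome, SNP id,
#'   genetic distance, base-pair position).
#' @return a [genotype_dataset()]. The individual id (second `.ped` field) is
#'   used as the sample id.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L))
    stop("map parse error at line ", which(nf != 4L)[1L],
         ": expected 4 fields, got ", nf[nf != 4L][1L])
  map <- data.frame(
    chr = vapply(map_fields, `[[`, "", 1L),
    snp_id = vapply(map_fields, `[[`, "", 2L),
    pos = as.integer(vapply(map_fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * m
  nf <- lengths(ped_fields)
  if (any(nf != expected))
    stop("ped parse error at line ", which(nf != expected)[1L],
         ": expected ", expected, " fields, got ", nf[nf != expected][1L])
  n <- length(ped_fields)
  sample_ids <- vapply(ped_fields, `[[`, "", 2L)

  # alleles as an n x 2m character matrix
  am <- matrix(unlist(lapply(ped_fields, function(f) f[-(1:6)])),
               nrow = n, byrow = TRUE)
  codes <- matrix(NA_integer_, n, m)
  minor <- major <- character(m)
  for (j in seq_len(m)) {
    a1 <- am[, 2L * j - 1L]
    a2 <- am[, 2L * j]
    ori <- .orient_alleles(a1, a2, map$snp_id[j])
    minor[j] <- ori$minor
    major[j] <- ori$major
    ok <- a1 != "0" & a2 != "0"
    codes[ok, j] <- (a1[ok] == ori$minor) + (a2[ok] == ori$minor)
  }
  snps <- data.frame(snp_id = map$snp_id, chr = map$chr, pos = map$pos,
                     allele_minor = minor, allele_major = major,
                     stringsAsFactors = FALSE)
  genotype_dataset(codes, sample_ids, snps)
}

#' Write PLINK text genotype files
#'
#' Inverse of [read_ped_map()]: emits a `.ped`/`.map` pair from a
#' [genotype_dataset()]. Missing genotypes are written as `0 0`. An optional
#' phenotype vector is written in the sixth `.ped` column using PLINK coding
#' (2 = case, 1 = control, -9 = missing).
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @param phenotype optional binary vector (`"case"`/`"control"`, logical, or
#'   0/1) aligned with the dataset's samples.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path, phenotype = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$snps
  writeLines(paste(map$chr, map$snp_id, 0L, map$pos, sep = "\t"), map_path)

  phe <- rep("-9", length(dataset$sample_ids))
  if (!is.null(phenotype)) {
    phe <- ifelse(.as_case_indicator(phenotype) == 1L, "2", "1")
  }
  g <- dataset$matrix
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix(rep(map$allele_major, each = n), n, m)
  a2 <- a1
  a1[g >= 1L & !is.na(g)] <- rep(map$allele_minor, each = n)[g >= 1L & !is.na(g)]
  a2[g == 2L & !is.na(g)] <- rep(map$allele_minor, each = n)[g == 2L & !is.na(g)]
  a1[is.na(g)] <- "0"; a2[is.na(g)] <- "0"
  geno_cols <- matrix("", n, 2L * m)
  geno_cols[, seq(1L, 2L * m, by = 2L)] <- a1
  geno_cols[, seq(2L, 2L * m, by = 2L)] <- a2
  lead <- cbind(dataset$sample_ids, dataset$sample_ids, "0", "0", "0", phe)
  lines <- apply(cbind(lead, geno_cols), 1L, paste, collapse = " ")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

# normalize a phenotype representation to an integer 0/1 case indicator
.as_case_indicator <- function(phenotype) {
  if (is.logical(phenotype)) return(as.integer(phenotype))
  if (is.numeric(phenotype)) {
    if (!all(phenotype %in% c(0, 1)))
      stop("numeric phenotype must be 0/1")
    return(as.integer(phenotype))
  }
  ph <- tolower(as.character(phenotype))
  if (!all(ph %in% c("case", "control")))
    stop("phenotype values must be 'case'/'control', logical, or 0/1")
  as.integer(ph == "case")
}

.required_covariate_cols <- c("sample_id", "phenotype", "age", "sex")

#' Read a sample covariate/phenotype table
#'
#' Reads a tab-separated table with one row per sample. Required columns:
#' `sample_id`, `phenotype` (`case`/`control`), `age` (years), `sex`
#' (`F`/`M`). Recognised optional columns are typed on read: `education`
#' (years), `bmi` (kg/m2), `smoking` (`ever`/`never`), `apoe_e4` (0/1 carrier
#' flag), `stage` (1/2), `matched_set_id`, `stratum_id`, and binary
#' comorbidity flags. Unknown columns are preserved untouched.
#'
#' @param tsv_path path to the TSV file.
#' @return a data frame of class `sample_table`.
#' @export
read_covariates <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("covariate file not found: ", tsv_path)
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(.required_covariate_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("covariate table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in covariate table")
  if (!all(df$phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  df$age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(df$age)) stop("non-numeric or missing age")
  if (any(df$age <= 0)) stop("age must be positive")
  for (col in c("education", "bmi"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  for (col in c("apoe_e4", "stage", "hypertension", "dm",
                "hypercholesterolemia", "head_injury"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample covariate/phenotype table
#'
#' @param samples a data frame as returned by [read_covariates()] or
#'   [simulate_study()].
#' @param tsv_path output path.
#' @return invisibly, the path.
#' @export
write_covariates <- function(samples, tsv_path) {
  utils::write.table(samples, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(tsv_path)
}

#' Write a results table as TSV
#'
#' Writes a list of records (or a data frame) sharing one schema as a
#' tab-separated file, header first. Floats are formatted at a fixed number of
#' significant digits so the file is stable across platforms.
#'
#' @param records a data frame, or a list of named lists with identical names.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @return invisibly, the path.
#' @export
write_results_tsv <- function(records, path, digits = 6) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    stopifnot(is.list(records))
    if (length(records) == 0L)
      stop("empty record list needs a data.frame with columns for the header")
    nms <- names(records[[1L]])
    ok <- vapply(records, function(r) identical(names(r), nms), logical(1))
    if (!all(ok)) stop("records do not share a schema")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  out <- df
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (col in names(out)[num])
    out[[col]] <- signif(out[[col]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
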