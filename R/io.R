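#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Parses whitespace-delimited PED/MAP (missing allele coded `"0"`) and
#' recodes each SNP to minor-allele dosage. The minor allele is the less
#' frequent allele over all samples; an exact 50/50 tie is broken
#' alphabetically so the coding is deterministic. A genotype with exactly one
#' missing allele is treated as fully missing (PLINK semantics). Monomorphic
#' SNPs keep the observed allele as major and get the alphabetically first
#' unused base as a placeholder minor allele (they fall at the QC MAF filter
#' anyway).
#'
#' @param ped_path,map_path file paths. MAP has 4 columns (chrom, snp_id,
#'   genetic distance, position); PED has 6 mandatory columns then two allele
#'   columns per SNP.
#' @return A [genotype_matrix()]. The PED phenotype column (1/2/-9) is kept in
#'   attribute `"ped_phenotype"`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric", "integer"))
  m <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * m
  nf <- lengths(fields)
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1L]
    stop(sprintf("PED row %d has %d fields; expected %d for %d MAP SNPs",
                 bad, nf[bad], expected, m))
  }
  ped <- do.call(rbind, fields)
  samples <- ped[, 2L]
  ped_pheno <- suppressWarnings(as.numeric(ped[, 6L]))
  n <- nrow(ped)

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  a1[half] <- "0"; a2[half] <- "0"

  dosage <- matrix(NA_integer_, n, m)
  allele_minor <- allele_major <- character(m)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    tab <- sort(table(obs))
    if (length(tab) > 2L)
      stop(sprintf("SNP %s has %d alleles; biallelic data required",
                   map$snp_id[j], length(tab)))
    if (length(tab) == 0L) {
      allele_major[j] <- "A"; allele_minor[j] <- "C"
      next
    }
    if (length(tab) == 1L) {
      allele_major[j] <- names(tab)
      allele_minor[j] <- setdiff(bases, names(tab))[1L]
      dosage[, j] <- ifelse(a1[, j] == "0", NA_integer_, 0L)
      next
    }
    if (tab[[1L]] == tab[[2L]]) {  # tie: alphabetically first is minor
      minor <- sort(names(tab))[1L]
    } else minor <- names(tab)[1L]
    major <- setdiff(names(tab), minor)
    allele_minor[j] <- minor; allele_major[j] <- major
    d <- (a1[, j] == minor) + (a2[, j] == minor)
    d[a1[, j] == "0"] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  gm <- genotype_matrix(
    dosage,
    data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
               allele_minor = allele_minor, allele_major = allele_major,
               stringsAsFactors = FALSE),
    samples
  )
  attr(gm, "ped_phenotype") <- ped_pheno
  gm
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param geno a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param pheno optional [phenotype_table] used to fill the PED phenotype
#'   column (2 = case, 1 = control); `-9` when absent.
#' @param sex value for the PED sex column (default 2, an all-female cohort).
#' @export
write_ped_map <- function(geno, ped_path, map_path, pheno = NULL, sex = 2L) {
  s <- geno$snps
  utils::write.table(
    data.frame(s$chrom, s$snp_id, 0, s$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ph <- rep(-9L, length(geno$samples))
  if (!is.null(pheno)) {
    i <- match(geno$samples, pheno$sample_id)
    ph[!is.na(i)] <- ifelse(pheno$status[i[!is.na(i)]] == "case", 2L, 1L)
  }
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- geno$dosage[, j]
    mi <- s$allele_minor[j]; ma <- s$allele_major[j]
    al[, 2L * j - 1L] <- ifelse(is.na(d), "0", ifelse(d >= 1L, mi, ma))
    al[, 2L * j] <- ifelse(is.na(d), "0", ifelse(d == 2L, mi, ma))
  }
  ped <- cbind(geno$samples, geno$samples, "0", "0", as.character(sex), ph, al)
  writeLines(apply(ped, 1L, paste, collapse = " "), ped_path)
  invisible(ped_path)
}

#' Read the per-sample covariate table
#'
#' Tab-delimited with a header; expected columns `sample_id`, `status`,
#' `age`, `bmi`, `anc_eur`, `anc_afr`, `anc_nat`, `ses`, `education`.
#' Status may be coded `case`/`control`, `1`/`0`, or — with
#' `dialect = "plink"` — `2`/`1`. Ancestry proportions must sum to 1 within
#' 1e-6. Rows with missing status are an error; missing covariates are kept
#' and flagged in the `incomplete` column.
#'
#' @param path TSV path.
#' @param dialect `"labels"` (case/control or 1/0) or `"plink"` (2 = case,
#'   1 = control).
#' @return A data.frame of class `phenotype_table`.
#' @export
read_covariates <- function(path, dialect = c("labels", "plink")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  phenotype_table(df, dialect = dialect)
}

#' Construct/validate a phenotype table
#'
#' @param df data.frame with the columns documented in [read_covariates()].
#' @param dialect status coding, see [read_covariates()].
#' @return The validated data.frame with `status` as a `"case"/"control"`
#'   factor and an `incomplete` logical column; class `phenotype_table`.
#' @export
phenotype_table <- function(df, dialect = c("labels", "plink")) {
  dialect <- match.arg(dialect)
  need <- c("sample_id", "status", "age", "bmi",
            "anc_eur", "anc_afr", "anc_nat", "ses", "education")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(is.na(df$status)))
    stop("missing status for sample(s): ",
         paste(df$sample_id[is.na(df$status)], collapse = ", "))
  st <- tolower(as.character(df$status))
  map <- if (dialect == "plink") c("2" = "case", "1" = "control")
         else c("case" = "case", "control" = "control",
                "1" = "case", "0" = "control")
  bad <- !(st %in% names(map))
  if (any(bad))
    stop("unknown status code(s): ", paste(unique(st[bad]), collapse = ", "),
         " (dialect '", dialect, "')")
  df$status <- factor(unname(map[st]), levels = c("control", "case"))
  anc <- df$anc_eur + df$anc_afr + df$anc_nat
  off <- which(abs(anc - 1) > 1e-6)
  if (length(off))
    stop("ancestry proportions do not sum to 1 for sample(s): ",
         paste(df$sample_id[off], collapse = ", "))
  if (any(c(df$anc_eur, df$anc_afr, df$anc_nat) < -1e-12, na.rm = TRUE))
    stop("negative ancestry proportion")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  df$incomplete <- !stats::complete.cases(
    df[, c("age", "bmi", "anc_eur", "ses", "education")])
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a covariate table
#'
#' @param pheno a `phenotype_table`.
#' @param path output TSV path.
#' @export
write_covariates <- function(pheno, path) {
  out <- as.data.frame(pheno)
  out$incomplete <- NULL
  out$status <- as.character(out$status)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as TSV with a JSON twin
#'
#' The TSV carries the table at printed precision; the `.json` twin written
#' alongside (same path, `.json` extension) keeps full precision.
#'
#' @param results a data.frame from the association, RDM or haplotype stage.
#' @param path output path; `format` defaults from its extension.
#' @param format `"tsv"` or `"json"`; `"tsv"` also writes the JSON twin.
#' @param digits significant digits for the TSV rendering.
#' @export
write_report <- function(results, path, format = c("tsv", "json"), digits = 6L) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "json") {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null")
    return(invisible(path))
  }
  pretty <- results
  num <- vapply(pretty, is.numeric, logical(1))
  pretty[num] <- lapply(pretty[num], signif, digits = digits)
  utils::write.table(pretty, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(results, sub("\\.[^.]*$", ".json", path),
                       dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
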