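#' Genotype matrix container
#'
#' The central data structure of the pipeline: an n-samples x m-SNPs matrix of
#' minor-allele dosages (0/1/2, `NA` for missing) plus per-SNP metadata.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}, counting copies of the minor allele. Row and column
#'   names are taken as sample and SNP ids if `samples`/`snps` are missing.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_minor`, `allele_major` and optionally `gene`.
#' @param samples character vector of sample ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps`, `samples`.
#' @export
genotype_matrix <- function(dosage, snps, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) stop("sample ids are required (rownames or `samples`)")
  samples <- as.character(samples)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "allele_minor", "allele_major")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snps table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(snps) != ncol(dosage))
    stop("snps table has ", nrow(snps), " rows but dosage has ", ncol(dosage), " columns")
  if (length(samples) != nrow(dosage))
    stop("length(samples) != nrow(dosage)")
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id")
  if (anyDuplicated(samples)) stop("duplicated sample id")
  if (any(snps$pos < 1)) stop("positions must be >= 1")
  same <- snps$allele_minor == snps$allele_major
  if (any(same)) stop("allele_minor equals allele_major for ",
                      paste(snps$snp_id[same], collapse = ", "))
  ok <- dosage %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(samples, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a `genotype_matrix`.
#' @param samples,snps character ids or logical/integer indices; `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(x$samples) else
    if (is.character(samples)) match(samples, x$samples) else samples
  vi <- if (is.null(snps)) seq_len(nrow(x$snps)) else
    if (is.character(snps)) match(snps, x$snps$snp_id) else snps
  if (is.numeric(si) && anyNA(si)) stop("unknown sample id(s)")
  if (is.numeric(vi) && anyNA(vi)) stop("unknown snp id(s)")
  genotype_matrix(x$dosage[si, vi, drop = FALSE],
                  x$snps[vi, , drop = FALSE],
                  x$samples[si])
}
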