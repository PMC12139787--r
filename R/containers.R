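# Matrix-backed containers for genotype data. Genotypes are SNP-major:
# rows are SNPs, columns are individuals. Panel accessions are inbred and
# homozygous, coded 0/1 (NA = missing). Field-sample calls additionally use
# 2 for a heterozygous call.

HET_CALL <- 2L

#' Construct a genotype panel
#'
#' The reference population at sowing: one column per inbred accession, one
#' row per biallelic SNP, entries 0/1 (alternate-allele dosage over a
#' homozygous genome) or `NA` for missing. Heterozygous entries are not
#' permitted in a panel.
#'
#' @param genotypes Integer matrix, SNPs x accessions, values in {0, 1, NA}.
#' @param accessions Data frame with columns `accession_id`, `group`,
#'   `lat`, `lon` (one row per panel column).
#' @param snps Data frame with columns `chrom`, `pos` (1-based), one row per
#'   panel row.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, accessions, snps) {
  accessions <- tibble::as_tibble(accessions)
  snps <- tibble::as_tibble(snps)
  stopifnot(is.matrix(genotypes))
  if (nrow(genotypes) != nrow(snps)) {
    stop("`genotypes` must have one row per SNP", call. = FALSE)
  }
  if (ncol(genotypes) != nrow(accessions)) {
    stop("`genotypes` must have one column per accession", call. = FALSE)
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("panel genotypes must be biallelic homozygous calls coded 0/1", call. = FALSE)
  }
  if (anyDuplicated(accessions$accession_id)) {
    stop("duplicated accession ids in panel", call. = FALSE)
  }
  check_latlon(accessions$lat, accessions$lon)
  storage.mode(genotypes) <- "integer"
  colnames(genotypes) <- accessions$accession_id
  structure(
    list(genotypes = genotypes, accessions = accessions, snps = snps),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d accessions x %d SNPs, %d groups\n",
    ncol(x$genotypes), nrow(x$genotypes), dplyr::n_distinct(x$accessions$group)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Construct a set of field-sample genotype calls
#'
#' Per-sample SNP calls aligned to a panel's SNP order. Calls are coded
#' 0/1 for homozygous genotypes, 2 for a heterozygous call, `NA` for missing.
#'
#' @param calls Integer matrix, SNPs x samples, values in {0, 1, 2, NA}.
#' @param samples Data frame with columns `sample_id`, `site_id` (one row per
#'   call column).
#' @param snps Data frame with columns `chrom`, `pos`, matching the panel.
#' @return An object of class `sample_calls`.
#' @export
sample_calls <- function(calls, samples, snps) {
  samples <- tibble::as_tibble(samples)
  snps <- tibble::as_tibble(snps)
  stopifnot(is.matrix(calls))
  if (nrow(calls) != nrow(snps)) stop("`calls` must have one row per SNP", call. = FALSE)
  if (ncol(calls) != nrow(samples)) stop("`calls` must have one column per sample", call. = FALSE)
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% c(0L, 1L, HET_CALL))) {
    stop("sample calls must be coded 0/1 (hom), 2 (het) or NA (missing)", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids", call. = FALSE)
  storage.mode(calls) <- "integer"
  colnames(calls) <- samples$sample_id
  structure(
    list(calls = calls, samples = samples, snps = snps),
    class = "sample_calls"
  )
}

#' @export
print.sample_calls <- function(x, ...) {
  cat(sprintf(
    "<sample_calls> %d samples x %d SNPs from %d site(s)\n",
    ncol(x$calls), nrow(x$calls), dplyr::n_distinct(x$samples$site_id)
  ))
  invisible(x)
}

#' @export
dim.sample_calls <- function(x) dim(x$calls)

# Fail unless sample calls and panel share the same SNP grid (chrom, pos).
check_snp_congruence <- function(calls, panel) {
  if (nrow(calls$snps) != nrow(panel$snps) ||
      !identical(calls$snps$chrom, panel$snps$chrom) ||
      !identical(calls$snps$pos, panel$snps$pos)) {
    stop("sample calls and panel are not on the same SNP grid (chrom, pos)",
         call. = FALSE)
  }
  invisible(NULL)
}
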