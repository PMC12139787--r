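# Plain-text interchange: TSV genotype matrices, VCF, metadata CSVs.
#
# TSV layout: one row per SNP, columns `chrom`, `pos`, then one column per
# individual (0/1 hom, 2 het, empty = missing). Coordinates and group labels
# travel in sidecar CSVs.

#' Write / read a genotype panel as TSV plus metadata CSV
#'
#' @param panel A [genotype_panel()].
#' @param path TSV path for the genotype matrix.
#' @param metadata_path CSV path for accession metadata
#'   (`accession_id`, `group`, `lat`, `lon`).
#' @return `path`, invisibly (writer); a [genotype_panel()] (reader).
#' @export
write_panel_tsv <- function(panel, path, metadata_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- dplyr::bind_cols(panel$snps,
                          tibble::as_tibble(as.data.frame(panel$genotypes)))
  readr::write_tsv(tab, path)
  readr::write_csv(panel$accessions, metadata_path)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path, metadata_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  g <- as.matrix(tab[, setdiff(names(tab), c("chrom", "pos")), drop = FALSE])
  storage.mode(g) <- "integer"
  if (!identical(colnames(g), meta$accession_id)) {
    meta <- meta[match(colnames(g), meta$accession_id), ]
    if (anyNA(meta$accession_id)) {
      stop("metadata CSV does not cover every accession column", call. = FALSE)
    }
  }
  genotype_panel(g, meta,
                 tibble::tibble(chrom = as.character(tab$chrom), pos = as.integer(tab$pos)))
}

#' Write / read field-sample calls as TSV plus sample metadata CSV
#'
#' @param calls A [sample_calls()].
#' @param path TSV path for the call matrix (0/1 hom, 2 het, empty missing).
#' @param metadata_path CSV path for sample metadata (`sample_id`, `site_id`).
#' @return `path`, invisibly (writer); a [sample_calls()] (reader).
#' @export
write_calls_tsv <- function(calls, path, metadata_path) {
  stopifnot(inherits(calls, "sample_calls"))
  tab <- dplyr::bind_cols(calls$snps,
                          tibble::as_tibble(as.data.frame(calls$calls)))
  readr::write_tsv(tab, path)
  readr::write_csv(calls$samples, metadata_path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path, metadata_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), c("chrom", "pos")), drop = FALSE])
  storage.mode(m) <- "integer"
  sample_calls(m, meta,
               tibble::tibble(chrom = as.character(tab$chrom), pos = as.integer(tab$pos)))
}

# genotype matrix -> VCF GT strings
gt_string <- function(v) {
  out <- rep("./.", length(v))
  out[!is.na(v) & v == 0L] <- "0/0"
  out[!is.na(v) & v == 1L] <- "1/1"
  out[!is.na(v) & v == HET_CALL] <- "0/1"
  out
}

vcf_body <- function(genotypes, snps, ids) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fieldsel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  if (nrow(genotypes) == 0) return(header)
  gt <- apply(genotypes, 1, gt_string)
  gt <- if (is.matrix(gt)) t(gt) else matrix(gt, ncol = 1)
  body <- paste(
    snps$chrom, snps$pos, sprintf("snp%d", seq_len(nrow(snps))),
    "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  c(header, body)
}

#' Write a genotype panel or sample calls as VCF
#'
#' Biallelic sites with 1-based positions; homozygous genotypes as
#' `0/0`/`1/1`, heterozygous calls as `0/1`, missing as `./.`. REF/ALT are
#' placeholder alleles (`A`/`T`): the package works in 0/1 dosage space.
#'
#' @param x A [genotype_panel()] or [sample_calls()].
#' @param path Output VCF path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "genotype_panel")) {
    writeLines(vcf_body(x$genotypes, x$snps, x$accessions$accession_id), path)
  } else if (inherits(x, "sample_calls")) {
    writeLines(vcf_body(x$calls, x$snps, x$samples$sample_id), path)
  } else {
    stop("`x` must be a genotype_panel or sample_calls", call. = FALSE)
  }
  invisible(path)
}

# Parse a VCF into a 0/1/2/NA dosage matrix via vcfR.
vcf_to_matrix <- function(path, allow_het) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  m <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  norm <- gsub("\\|", "/", gt)
  m[norm %in% c("0/0", "0")] <- 0L
  m[norm %in% c("1/1", "1")] <- 1L
  m[norm %in% c("0/1", "1/0")] <- HET_CALL
  unparsed <- !is.na(norm) & !norm %in% c("0/0", "1/1", "0/1", "1/0", "./.", "0", "1", ".")
  if (any(unparsed)) {
    stop("VCF contains non-biallelic or unsupported GT values", call. = FALSE)
  }
  if (!allow_het && any(m == HET_CALL, na.rm = TRUE)) {
    stop("heterozygous genotypes are not permitted in a panel VCF", call. = FALSE)
  }
  rownames(m) <- NULL
  snps <- tibble::tibble(
    chrom = as.character(vcfR::getCHROM(v)),
    pos = as.integer(vcfR::getPOS(v))
  )
  list(m = m, snps = snps)
}

#' Read a genotype panel or sample calls from VCF
#'
#' @param path VCF path.
#' @param metadata_path Sidecar CSV: accession metadata (`accession_id`,
#'   `group`, `lat`, `lon`) for a panel; sample metadata (`sample_id`,
#'   `site_id`) for calls.
#' @return A [genotype_panel()] / [sample_calls()].
#' @export
read_panel_vcf <- function(path, metadata_path) {
  p <- vcf_to_matrix(path, allow_het = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  meta <- meta[match(colnames(p$m), meta$accession_id), ]
  if (anyNA(meta$accession_id)) {
    stop("metadata CSV does not cover every VCF sample column", call. = FALSE)
  }
  genotype_panel(p$m, meta, p$snps)
}

#' @rdname read_panel_vcf
#' @export
read_calls_vcf <- function(path, metadata_path) {
  p <- vcf_to_matrix(path, allow_het = TRUE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  meta <- meta[match(colnames(p$m), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata CSV does not cover every VCF sample column", call. = FALSE)
  }
  sample_calls(p$m, meta, p$snps)
}
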