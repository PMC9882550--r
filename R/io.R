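#' Tabular writers for pipeline artifacts
#'
#' Plain-text writers for the pipeline's interchange formats: measurement and
#' covariate TSVs, dosage TSVs, PLINK-dialect phenotype files
#' (`FID IID value`), summary-statistics TSVs and a minimal VCFv4.2 with GT
#' genotypes. Each writer can emit a JSON sidecar recording the provenance
#' (config and seed) next to the file.
#'
#' @param x the object to write.
#' @param path output file path.
#' @param sidecar optional list written as `<path>.json`.
#' @return the path, invisibly.
#' @name writers
NULL

write_sidecar <- function(path, sidecar) {
  if (!is.null(sidecar)) {
    keep <- sidecar[!vapply(sidecar, is.function, TRUE)]
    jsonlite::write_json(keep, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writers
#' @export
write_tsv_artifact <- function(x, path, sidecar = NULL) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, sidecar)
}

#' @rdname writers
#' @export
read_tsv_artifact <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writers
#' @param values named numeric vector (names = individual ids).
#' @export
write_phenotype <- function(values, path, sidecar = NULL) {
  d <- data.frame(FID = names(values), IID = names(values),
                  pheno = unname(values))
  utils::write.table(d, path, sep = " ", quote = FALSE, row.names = FALSE)
  write_sidecar(path, sidecar)
}

#' @rdname writers
#' @param genotypes dosage matrix with rownames = ids.
#' @export
write_dosage <- function(genotypes, path, sidecar = NULL) {
  d <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  write_tsv_artifact(d, path, sidecar)
}

#' @rdname writers
#' @param maf per-SNP minor allele frequencies (for the INFO field).
#' @export
write_vcf <- function(genotypes, path, maf = NULL, sidecar = NULL) {
  ids <- rownames(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    info <- if (is.null(maf)) "." else sprintf("AF=%.6g", maf[j])
    row <- c("1", as.character(j), colnames(genotypes)[j], "A", "G", ".",
             "PASS", info, "GT", gt_code[genotypes[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  write_sidecar(path, sidecar)
}

#' @rdname writers
#' @param res an `assoc_result` table.
#' @param or also emit `OR = exp(BETA)` (odds-ratio convention for
#'   bounded-logit traits).
#' @export
write_sumstats <- function(res, path, maf = NULL, or = FALSE,
                           sidecar = NULL) {
  d <- data.frame(SNP = res$snp, A1 = "G", A2 = "A",
                  MAF = if (is.null(maf)) NA else maf[res$snp],
                  BETA = res$beta, SE = res$se, P = res$p, N = res$n)
  if (or) d$OR <- exp(res$beta)
  write_tsv_artifact(d, path, sidecar)
}
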