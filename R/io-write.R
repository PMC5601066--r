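#' Write pooled variant records as a VCF 4.2 file
#'
#' Emits one VCF data line per record with the phred call quality in `QUAL`
#' and two sample columns carrying `RO` (reference observation count) and
#' `AO` (alternate observation count) FORMAT fields, the allele-depth
#' convention of FreeBayes-style pooled calling. The output is plain text
#' and round-trips through [read_pooled_vcf()].
#'
#' @param variants Tibble with columns `chromosome`, `pos`, `ref`, `alt`,
#'   `qual`, `ro_high`, `ao_high`, `ro_low`, `ao_low`; an optional
#'   `marker_id` becomes the `ID` column.
#' @param path Output file path.
#' @param high_name,low_name Sample column names for the two pools.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(variants, path, high_name = "HIGH", low_name = "LOW") {
  id <- if ("marker_id" %in% names(variants)) variants$marker_id else "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscan",
    '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="Reference allele observation count">',
    '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", high_name, low_name, sep = "\t")
  )
  body <- paste(
    variants$chromosome, variants$pos, id, variants$ref, variants$alt,
    format(variants$qual, trim = TRUE, scientific = FALSE), ".", ".",
    "RO:AO",
    paste(variants$ro_high, variants$ao_high, sep = ":"),
    paste(variants$ro_low, variants$ao_low, sep = ":"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write panel phenotypes, genotypes and planted truth to disk
#'
#' Companion writers for the synthetic-data generator: a phenotype CSV
#' (`variety_id`, `habit`, `trait`), a genotype CSV (varieties x markers,
#' inbred codes 0/2/NA) and a truth TSV listing the planted causal markers
#' and their additive effects.
#'
#' @param panel A `variety_panel`.
#' @param dir Output directory (created if absent).
#' @param habit Growth-habit label written to the phenotype CSV.
#' @return Named character vector of the files written, invisibly.
#' @export
write_panel_csv <- function(panel, dir, habit = "spring") {
  stopifnot(inherits(panel, "variety_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pheno_path <- file.path(dir, "phenotypes.csv")
  geno_path <- file.path(dir, "genotypes.csv")
  truth_path <- file.path(dir, "truth.tsv")

  pheno <- tibble::add_column(panel$phenotypes, habit = habit, .after = "variety_id")
  write.csv(pheno, pheno_path, row.names = FALSE, quote = FALSE)

  geno <- data.frame(variety_id = rownames(panel$genotypes), panel$genotypes,
                     check.names = FALSE)
  write.csv(geno, geno_path, row.names = FALSE, quote = FALSE)

  truth <- panel$markers[panel$markers$causal,
                         c("marker_id", "chromosome", "pos", "effect")]
  utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(phenotypes = pheno_path, genotypes = geno_path, truth = truth_path))
}

#' Read a genotype CSV written by [write_panel_csv()]
#'
#' @param path Genotype CSV with a `variety_id` column followed by one
#'   column per marker (codes 0/2/NA).
#' @return Integer matrix, varieties x markers.
#' @export
read_genotype_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  mode(geno) <- "integer"
  rownames(geno) <- df[[1]]
  geno
}

#' Write QTL calls as TSV and BED
#'
#' The TSV mirrors the columns of a published QTL summary (name, contrast,
#' chromosome, interval, supporting marker count, peak, max AFD); the BED
#' file converts the internal 1-based closed intervals to 0-based
#' half-open spans.
#'
#' @param qtl QTL calls from [call_qtl()].
#' @param tsv_path,bed_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_qtl <- function(qtl, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(qtl, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(qtl$chromosome, format(qtl$start - 1, scientific = FALSE, trim = TRUE),
                      format(qtl$end, scientific = FALSE, trim = TRUE), qtl$name)
    utils::write.table(bed, bed_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}
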