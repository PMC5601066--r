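#' Read pooled variant records from a VCF file
#'
#' Ingests a VCF 4.2 produced by pooled-continuous variant calling, keeping
#' one record per biallelic SNP line with per-pool reference/alternate read
#' counts taken from the `RO`/`AO` FORMAT fields (with `AD` as fallback).
#' Multiallelic lines, indels and MNPs are skipped and counted, matching a
#' calling pipeline run with complex/MNP/indel output disabled. Records
#' with a missing depth field get zero counts and are flagged; records with
#' a malformed depth field are skipped and counted.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param high_pool_name,low_pool_name Sample column names of the high and
#'   low phenotype pools; absence from the header is fatal.
#' @return A tibble with columns `chromosome`, `pos`, `marker_id`, `ref`,
#'   `alt`, `qual`, `ro_high`, `ao_high`, `ro_low`, `ao_low`, `flagged`.
#'   Attribute `skipped` tallies skipped lines by reason.
#' @export
read_pooled_vcf <- function(path, high_pool_name, low_pool_name) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (nm in c(high_pool_name, low_pool_name)) {
    if (!nm %in% samples) {
      abort(sprintf("pool '%s' not found in VCF header (samples: %s)",
                    nm, paste(samples, collapse = ", ")))
    }
  }
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  n_in <- nrow(fix)
  if (n_in == 0) abort("VCF contains no variant records")

  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_snp <- !is_multi &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")

  depths <- extract_pool_depths(vcf, c(high_pool_name, low_pool_name))
  malformed <- depths$malformed & !is_multi & is_snp
  keep <- is_snp & !malformed

  out <- tibble::tibble(
    chromosome = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    marker_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                       NA_character_, fix$ID[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = as.numeric(fix$QUAL[keep]),
    ro_high = depths$ro[keep, 1],
    ao_high = depths$ao[keep, 1],
    ro_low = depths$ro[keep, 2],
    ao_low = depths$ao[keep, 2],
    flagged = depths$missing[keep]
  )
  attr(out, "skipped") <- tibble::tibble(
    reason = c("multiallelic", "indel_or_mnp", "malformed_depth"),
    n = c(sum(is_multi), sum(!is_multi & !is_snp), sum(malformed))
  )
  out
}

# Pull RO/AO (or AD) per sample. Returns integer matrices plus per-record
# missing/malformed indicators.
extract_pool_depths <- function(vcf, pools) {
  has_field <- function(f) any(grepl(paste0("(^|:)", f, "(:|$)"), vcf@gt[, "FORMAT"]))
  n <- nrow(vcf@gt)
  ro <- matrix(NA_integer_, n, length(pools))
  ao <- matrix(NA_integer_, n, length(pools))
  malformed <- rep(FALSE, n)

  if (has_field("RO") && has_field("AO")) {
    ro_raw <- vcfR::extract.gt(vcf, element = "RO")[, pools, drop = FALSE]
    ao_raw <- vcfR::extract.gt(vcf, element = "AO")[, pools, drop = FALSE]
  } else if (has_field("AD")) {
    ad <- vcfR::extract.gt(vcf, element = "AD")[, pools, drop = FALSE]
    ro_raw <- matrix(sub(",.*$", "", ad), nrow = n)
    ao_raw <- matrix(
      vapply(strsplit(as.vector(ad), ",", fixed = TRUE),
             function(x) if (length(x) >= 2) x[2] else NA_character_,
             character(1)),
      nrow = n
    )
  } else {
    abort("VCF carries neither RO/AO nor AD FORMAT fields")
  }
  for (j in seq_along(pools)) {
    ro_j <- suppressWarnings(as.integer(ro_raw[, j]))
    ao_j <- suppressWarnings(as.integer(ao_raw[, j]))
    # value present but unparseable -> malformed; absent -> zero, flagged
    malformed <- malformed |
      (!is.na(ro_raw[, j]) & ro_raw[, j] != "." & is.na(ro_j)) |
      (!is.na(ao_raw[, j]) & ao_raw[, j] != "." & is.na(ao_j))
    ro[, j] <- ro_j
    ao[, j] <- ao_j
  }
  missing <- (is.na(ro) | is.na(ao)) %*% rep(1, length(pools)) > 0
  ro[is.na(ro)] <- 0L
  ao[is.na(ao)] <- 0L
  list(ro = ro, ao = ao, missing = as.vector(missing) & !malformed,
       malformed = malformed)
}
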