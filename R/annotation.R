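#' Default diastase-related annotation filters
#'
#' The PFAM domains and description keywords used to pull putative
#' diastase (starch-degrading) genes out of a genome annotation: the
#' alpha-amylase catalytic and C-terminal domains, the alpha-amylase
#' inhibitor and glycosyl hydrolase family 14 (beta-amylase) domains, the
#' maltogenic amylase C-terminal domain, and the keywords "amylase" and
#' "dextrin".
#'
#' @return A list with character vectors `pfam` and `keywords`.
#' @export
diastase_filters <- function() {
  list(
    pfam = c("PF00128", "PF01356", "PF01373", "PF02806", "PF16657"),
    keywords = c("amylase", "dextrin")
  )
}

#' Find candidate genes by PFAM domain or description keyword
#'
#' Returns the union of genes carrying any of the given PFAM accessions
#' and genes whose functional description contains any keyword as a
#' case-insensitive substring (so "amylase" hits both "beta-amylase 5" and
#' "Alpha-amylase/trypsin inhibitor"), deduplicated by gene id. The
#' defaults are the diastase filters of [diastase_filters()].
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `description` and `pfam` (comma/semicolon-separated accessions
#'   or a list column).
#' @param pfam Character vector of PFAM accessions to match.
#' @param keywords Character vector of description substrings to match.
#' @return The matching rows of `genes`, with a `matched_by` column
#'   (`"pfam"`, `"keyword"` or `"both"`).
#' @export
find_candidate_genes <- function(genes,
                                 pfam = diastase_filters()$pfam,
                                 keywords = diastase_filters()$keywords) {
  genes <- tibble::as_tibble(genes)
  pf <- genes$pfam %||% character(nrow(genes))
  pfam_terms <- if (is.list(pf)) pf else strsplit(as.character(pf), "[,;]\\s*")
  hit_pfam <- vapply(pfam_terms, function(terms) {
    any(toupper(trimws(terms)) %in% toupper(pfam))
  }, logical(1))
  desc <- tolower(genes$description %||% character(nrow(genes)))
  hit_kw <- rep(FALSE, nrow(genes))
  for (kw in keywords) {
    hit_kw <- hit_kw | grepl(tolower(kw), desc, fixed = TRUE)
  }
  out <- genes[hit_pfam | hit_kw, ]
  out$matched_by <- dplyr::case_when(
    hit_pfam[hit_pfam | hit_kw] & hit_kw[hit_pfam | hit_kw] ~ "both",
    hit_pfam[hit_pfam | hit_kw] ~ "pfam",
    .default = "keyword"
  )
  out
}

#' Collocate candidate genes with called QTL
#'
#' A gene is collocated with a QTL when its span intersects the QTL
#' interval extended on each side by the applicable QTL-independence gap
#' (the same centromere-aware gap as [call_qtl()]): a gene within the gap
#' of a QTL would not have founded an independent QTL, so it belongs to
#' the QTL's candidate region. Genes on chromosomes absent from the QTL
#' table are ignored; a gene whose chromosome name matches no QTL and no
#' centromere entry triggers a warning only when `quiet = FALSE`.
#'
#' @param qtl QTL calls from [call_qtl()].
#' @param genes Gene table as in [find_candidate_genes()] (possibly
#'   already filtered by it).
#' @inheritParams call_qtl
#' @param quiet Suppress the chromosome-mismatch warning.
#' @return A tibble with one row per (QTL, collocated gene) pair: the QTL
#'   `name`, `chromosome`, `start`, `end`, then `gene_id`, `gene_start`,
#'   `gene_end`, `description` and the gene's distance to the QTL interval
#'   (0 when overlapping).
#' @export
collocate_qtl_genes <- function(qtl, genes, centromeres = NULL,
                                gap_centromeric = 400e6, gap_other = 10e6,
                                centromere_rule = c("span", "flank"),
                                quiet = FALSE) {
  centromere_rule <- match.arg(centromere_rule)
  cent <- as_centromere_map(centromeres)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(genes$start <= genes$end))
  orphan <- setdiff(unique(genes$chromosome), unique(qtl$chromosome))
  if (!quiet && length(orphan) > 0 && nrow(qtl) > 0) {
    warn(paste("genes on chromosomes with no QTL ignored:",
               paste(orphan, collapse = ", ")))
  }
  rows <- purrr::pmap(qtl, function(name, contrast, chromosome, start, end,
                                    n_markers, peak, max_afd, ...) {
    g <- genes[genes$chromosome == chromosome, ]
    if (nrow(g) == 0) return(NULL)
    ci <- cent[cent$chromosome == chromosome, ]
    hit <- vapply(seq_len(nrow(g)), function(i) {
      gap <- applicable_gap(min(g$start[i], start), max(g$end[i], end), ci,
                            gap_centromeric, gap_other, centromere_rule)
      g$start[i] <= end + gap && g$end[i] >= start - gap
    }, logical(1))
    g <- g[hit, ]
    if (nrow(g) == 0) return(NULL)
    tibble::tibble(
      name = name, chromosome = chromosome, start = start, end = end,
      gene_id = g$gene_id, gene_start = g$start, gene_end = g$end,
      description = g$description %||% NA_character_,
      distance = pmax(0, pmax(g$start - end, start - g$end))
    )
  })
  dplyr::bind_rows(rows)
}

#' Read a gene annotation table from GFF3 or flat TSV
#'
#' GFF3 input (via rtracklayer) keeps `gene`-type records and pulls the
#' gene id, functional description and PFAM accessions from the
#' `ID`/`description`/`pfam` attributes. TSV input must already carry
#' columns `gene_id`, `chromosome`, `start`, `end`, `description`, `pfam`.
#' Coordinates are 1-based inclusive in both cases.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A gene tibble as consumed by [find_candidate_genes()].
#' @export
read_gene_table <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    out <- tibble::as_tibble(utils::read.delim(path))
    stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(out)))
    return(out)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  md <- as.data.frame(gr)
  tibble::tibble(
    gene_id = md$ID,
    chromosome = as.character(md$seqnames),
    start = md$start,
    end = md$end,
    description = md$description %||% NA_character_,
    pfam = md$pfam %||% NA_character_
  )
}
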