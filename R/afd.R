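#' Per-variant allele frequencies and their difference between pools
#'
#' Reference allele frequencies are taken directly from read counts,
#' `raf = ro / (ro + ao)` in each pool, and the allele frequency difference
#' is the high-pool frequency minus the low-pool frequency:
#' \deqn{AFD = RAF_{high} - RAF_{low} \in [-1, 1].}
#' Zero depth in a pool violates the post-filter contract and is an error.
#'
#' @param variants Tibble of filtered pooled variants (columns `ro_high`,
#'   `ao_high`, `ro_low`, `ao_low` at minimum).
#' @return The input with columns `raf_high`, `raf_low`, `afd` appended.
#' @export
#' @examples
#' v <- tibble::tibble(ro_high = 150, ao_high = 50, ro_low = 25, ao_low = 75)
#' compute_afd(v)$afd # 0.5
compute_afd <- function(variants) {
  depth_h <- variants$ro_high + variants$ao_high
  depth_l <- variants$ro_low + variants$ao_low
  if (any(depth_h == 0 | depth_l == 0)) {
    abort("zero-depth pool encountered; apply filter_variants() first")
  }
  dplyr::mutate(
    variants,
    raf_high = .data$ro_high / depth_h,
    raf_low = .data$ro_low / depth_l,
    afd = .data$raf_high - .data$raf_low
  )
}

#' Cluster associated markers into independent QTL
#'
#' Markers whose `|AFD|` exceeds `threshold` are scanned along each
#' chromosome in position order and chained into a single QTL while the
#' separation between consecutive passing markers stays below the
#' applicable independence gap; two passing markers separated by at least
#' the gap, with no passing marker between them, start independent QTL.
#' The gap is `gap_centromeric` when the span between the two markers
#' intersects the chromosome's centromere interval (physical distance per
#' unit of recombination being hugely inflated there) and `gap_other`
#' elsewhere. Each QTL reports the interval spanned by its member markers,
#' the member count, and the position and signed AFD of the peak (largest
#' `|AFD|`, ties broken by smallest position).
#'
#' @param records AFD records from [compute_afd()] (columns `chromosome`,
#'   `pos`, `afd`).
#' @param threshold Absolute AFD above which a marker is associated
#'   (strict inequality; default 0.75).
#' @param centromeres Centromere intervals: a data frame with columns
#'   `chromosome` (or `name`), `cent_start`, `cent_end`, e.g.
#'   `sim_config()$chromosomes` or [read_centromere_tsv()]. Chromosomes
#'   absent from the map are treated as having no centromeric region, with
#'   a warning. `NULL` means no centromeric regions at all.
#' @param gap_centromeric,gap_other Independence gaps in bp (defaults
#'   400 Mbp and 10 Mbp).
#' @param contrast Label stamped on the calls and used in QTL names.
#' @param sign_mode `"absolute"` (default) clusters on `|AFD|` alone;
#'   `"strict"` additionally splits clusters where the AFD sign flips.
#' @param centromere_rule `"span"` (default) applies the centromeric gap
#'   when the span between the two markers intersects the centromere;
#'   `"flank"` when either flanking marker lies inside it.
#' @return A tibble of QTL calls: `name`, `contrast`, `chromosome`,
#'   `start`, `end`, `n_markers`, `peak`, `max_afd`.
#' @export
call_qtl <- function(records, threshold = 0.75, centromeres = NULL,
                     gap_centromeric = 400e6, gap_other = 10e6,
                     contrast = "pool", sign_mode = c("absolute", "strict"),
                     centromere_rule = c("span", "flank")) {
  sign_mode <- match.arg(sign_mode)
  centromere_rule <- match.arg(centromere_rule)
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  cent <- as_centromere_map(centromeres)

  passing <- records[abs(records$afd) > threshold, c("chromosome", "pos", "afd")]
  if (nrow(passing) == 0) {
    return(tibble::tibble(
      name = character(), contrast = character(), chromosome = character(),
      start = numeric(), end = numeric(), n_markers = integer(),
      peak = numeric(), max_afd = numeric()
    ))
  }
  passing <- dplyr::arrange(passing, .data$chromosome, .data$pos)

  chroms_no_cent <- setdiff(unique(passing$chromosome), cent$chromosome)
  if (!is.null(centromeres) && length(chroms_no_cent) > 0) {
    warn(paste("no centromere interval for:",
               paste(chroms_no_cent, collapse = ", "),
               "- treated as non-centromeric"))
  }

  calls <- passing |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_map(function(d, key) {
      chr <- key$chromosome[[1]]
      ci <- cent[cent$chromosome == chr, ]
      new_cluster <- vapply(seq_len(nrow(d))[-1], function(i) {
        gap <- applicable_gap(d$pos[i - 1], d$pos[i], ci,
                              gap_centromeric, gap_other, centromere_rule)
        split <- (d$pos[i] - d$pos[i - 1]) >= gap
        if (sign_mode == "strict") {
          split <- split || sign(d$afd[i]) != sign(d$afd[i - 1])
        }
        split
      }, logical(1))
      cluster <- cumsum(c(TRUE, new_cluster))
      d |>
        dplyr::mutate(cluster = cluster) |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(
          chromosome = chr,
          start = min(.data$pos),
          end = max(.data$pos),
          n_markers = dplyr::n(),
          peak = .data$pos[order(-abs(.data$afd), .data$pos)[1]],
          max_afd = .data$afd[order(-abs(.data$afd), .data$pos)[1]],
          .groups = "drop"
        ) |>
        dplyr::select(!"cluster")
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chromosome, .data$start)

  calls |>
    dplyr::mutate(
      name = sprintf("%s-%d", contrast, dplyr::row_number()),
      contrast = contrast,
      .before = 1
    )
}

# gap applicable between two passing markers at p1 < p2 on one chromosome
applicable_gap <- function(p1, p2, cent_row, gap_centromeric, gap_other, rule) {
  if (nrow(cent_row) == 0) return(gap_other)
  cs <- cent_row$cent_start[[1]]
  ce <- cent_row$cent_end[[1]]
  centromeric <- if (rule == "span") {
    p1 <= ce && p2 >= cs
  } else {
    (p1 >= cs && p1 <= ce) || (p2 >= cs && p2 <= ce)
  }
  if (centromeric) gap_centromeric else gap_other
}

# normalise any centromere-interval table to (chromosome, cent_start, cent_end)
as_centromere_map <- function(x) {
  if (is.null(x)) {
    return(tibble::tibble(chromosome = character(), cent_start = numeric(),
                          cent_end = numeric()))
  }
  x <- tibble::as_tibble(x)
  if (!"chromosome" %in% names(x) && "name" %in% names(x)) {
    x <- dplyr::rename(x, chromosome = "name")
  }
  stopifnot(all(c("chromosome", "cent_start", "cent_end") %in% names(x)))
  out <- x[!is.na(x$cent_start), c("chromosome", "cent_start", "cent_end")]
  stopifnot(all(out$cent_start <= out$cent_end))
  out
}

#' Read a per-chromosome centromere interval table
#'
#' @param path TSV with columns `chromosome`, `cent_start`, `cent_end`
#'   (1-based bp).
#' @return A tibble usable as the `centromeres` argument of [call_qtl()].
#' @export
read_centromere_tsv <- function(path) {
  as_centromere_map(utils::read.delim(path))
}

#' Significance level implied by an AFD threshold between inbred pools
#'
#' An absolute allele frequency difference observed between two pools of
#' fully homozygous lines can be translated into a conventional
#' significance level by asking what a per-line test would say in the most
#' favourable case: population allele frequencies equal and pool
#' frequencies estimated perfectly. The implied 2x2 line-count table has
#' one pool fixed for the reference allele and the other at reference
#' frequency `1 - threshold`; for threshold 0.75 and pools of 12 this is
#' `[[12, 0], [3, 9]]`. The returned value is `-log10` of the two-sided
#' p-value of the Pearson chi-squared statistic (1 df, no continuity
#' correction) on that table — approximately 3.8 for the default
#' parameters.
#'
#' @param threshold Absolute AFD in (0, 1].
#' @param pool_size Lines per pool (default 12); `threshold * pool_size`
#'   is rounded to a whole line count.
#' @return `-log10(p)` as a single number, with the table and statistic
#'   attached as attributes `table` and `chi2`.
#' @seealso [afd_threshold_table()] to feed the table to a different test.
#' @export
#' @examples
#' threshold_significance(0.75, 12) # about 3.8
threshold_significance <- function(threshold = 0.75, pool_size = 12) {
  tab <- afd_threshold_table(threshold, pool_size)
  res <- pearson_chisq_2x2(tab)
  structure(res$neglog10p, table = tab, chi2 = res$chi2)
}

#' @rdname threshold_significance
#' @export
afd_threshold_table <- function(threshold = 0.75, pool_size = 12) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  n_low_ref <- round((1 - threshold) * pool_size)
  matrix(c(pool_size, 0, n_low_ref, pool_size - n_low_ref),
         nrow = 2, byrow = TRUE,
         dimnames = list(pool = c("high", "low"), allele = c("ref", "alt")))
}
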