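#' Post-calling filtering cascade for pooled variants
#'
#' Applies the three-rule cascade used after pooled variant calling, in
#' order, attributing each excluded variant to the first rule it fails:
#'
#' 1. **quality** — call quality below `min_qual` phred (kept iff
#'    `qual >= min_qual`);
#' 2. **fixed allele** — reference allele frequency below `fixed_raf` in
#'    *both* pools, i.e. the variant is a fixed difference of the whole
#'    material against the reference genome rather than a polymorphism
#'    between the pools (set `fixed_rule = "either"` for the stricter
#'    reading that drops a variant near-fixed for the alternate allele in
#'    just one pool);
#' 3. **depth** — fewer than `min_reads` allele-informative reads
#'    (`ro + ao`) in either pool, the guard against allele-frequency
#'    sampling error.
#'
#' Each rule is a pure predicate of one record, so the *set* of kept
#' variants does not depend on rule order; only the per-rule attribution
#' does.
#'
#' @param variants Tibble of pooled variants as returned by
#'   [read_pooled_vcf()] or [simulate_pooled_reads()].
#' @param min_qual Minimum phred call quality (default 50).
#' @param fixed_raf Reference allele frequency below which a pool counts as
#'   fixed for the alternate allele (default 0.01).
#' @param min_reads Minimum reads per pool (default 100).
#' @param fixed_rule `"both"` (default) or `"either"`.
#' @return The kept variants, with attributes `exclusions` (tibble
#'   `rule`, `excluded`) and `n_input`; see [filter_tally()].
#' @export
#' @examples
#' v <- tibble::tibble(chromosome = "1H", pos = 1:3, ref = "A", alt = "G",
#'                     qual = c(49, 60, 60),
#'                     ro_high = c(500, 2, 120), ao_high = c(10, 510, 30),
#'                     ro_low = c(400, 1, 98),  ao_low = c(20, 480, 2))
#' filter_tally(filter_variants(v))
filter_variants <- function(variants, min_qual = 50, fixed_raf = 0.01,
                            min_reads = 100, fixed_rule = c("both", "either")) {
  fixed_rule <- match.arg(fixed_rule)
  stopifnot(min_qual >= 0, fixed_raf >= 0, fixed_raf < 0.5, min_reads >= 1)

  depth_h <- variants$ro_high + variants$ao_high
  depth_l <- variants$ro_low + variants$ao_low
  raf_h <- ifelse(depth_h > 0, variants$ro_high / depth_h, NA_real_)
  raf_l <- ifelse(depth_l > 0, variants$ro_low / depth_l, NA_real_)

  fail_qual <- variants$qual < min_qual
  low_h <- !is.na(raf_h) & raf_h < fixed_raf
  low_l <- !is.na(raf_l) & raf_l < fixed_raf
  fail_fixed <- if (fixed_rule == "both") low_h & low_l else low_h | low_l
  fail_depth <- depth_h < min_reads | depth_l < min_reads

  first_fail <- dplyr::case_when(
    fail_qual ~ "quality",
    fail_fixed ~ "fixed_allele",
    fail_depth ~ "min_depth",
    .default = "kept"
  )
  kept <- variants[first_fail == "kept", ]
  attr(kept, "exclusions") <- tibble::tibble(
    rule = c("quality", "fixed_allele", "min_depth"),
    excluded = c(sum(first_fail == "quality"),
                 sum(first_fail == "fixed_allele"),
                 sum(first_fail == "min_depth"))
  )
  attr(kept, "n_input") <- nrow(variants)
  kept
}

#' Exclusion tally of a filtering run
#'
#' @param kept The tibble returned by [filter_variants()].
#' @return A tibble with one row per cascade stage (`input`, the three
#'   rules, `kept`) and the count attributed to each.
#' @export
filter_tally <- function(kept) {
  ex <- attr(kept, "exclusions")
  if (is.null(ex)) abort("not a filter_variants() result: no exclusion tally")
  tibble::tibble(
    stage = c("input", ex$rule, "kept"),
    n = c(attr(kept, "n_input"), ex$excluded, nrow(kept))
  )
}
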