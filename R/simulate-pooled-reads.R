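#' Simulate pooled sequencing read counts for two contrasting sets
#'
#' Emulates exome-capture sequencing of equimolar DNA pools: for each marker
#' and each pool, the true pool reference allele frequency is the fraction of
#' reference-homozygous lines among the pool's non-missing genotypes, the
#' read total is drawn from the configured coverage law (Poisson or negative
#' binomial, independent across markers), and reference read counts are
#' binomial with success probability `RAF (1 - e) + (1 - RAF) e` where `e`
#' is the per-read base error. Every record carries a phred-scaled call
#' quality from `config$qual` (constant by default; supply a function to
#' inject low-quality records).
#'
#' A marker at which a pool has no non-missing genotypes is flagged
#' (`flagged = TRUE`) and emitted with zero depth in that pool.
#'
#' @param panel A `variety_panel` from [simulate_panel()].
#' @param sets A `contrast_sets` object (see [select_contrasting_sets()]) or
#'   any list with character vectors `high_members` and `low_members`.
#' @param config The [sim_config()] used for coverage, error and quality.
#' @return A tibble with one row per marker: `chromosome`, `pos`,
#'   `marker_id`, `ref`, `alt`, `qual`, per-pool reference/alternate read
#'   counts (`ro_high`, `ao_high`, `ro_low`, `ao_low`), the generating truth
#'   (`true_raf_high`, `true_raf_low`) and a `flagged` column.
#' @export
simulate_pooled_reads <- function(panel, sets, config) {
  stopifnot(inherits(panel, "variety_panel"), inherits(config, "sim_config"))
  high <- sets$high_members
  low <- sets$low_members
  missing_ids <- setdiff(c(high, low), rownames(panel$genotypes))
  if (length(missing_ids) > 0) {
    abort(paste("set members absent from panel:", paste(missing_ids, collapse = ", ")))
  }
  set.seed(config$seed + 1L)
  m <- nrow(panel$markers)

  raf_h <- pool_raf(panel$genotypes[high, , drop = FALSE])
  raf_l <- pool_raf(panel$genotypes[low, , drop = FALSE])
  flagged <- is.na(raf_h) | is.na(raf_l)

  depth_h <- draw_depth(config, m)
  depth_l <- draw_depth(config, m)
  depth_h[is.na(raf_h)] <- 0L
  depth_l[is.na(raf_l)] <- 0L

  e <- config$base_error
  p_h <- ifelse(is.na(raf_h), 0, raf_h * (1 - e) + (1 - raf_h) * e)
  p_l <- ifelse(is.na(raf_l), 0, raf_l * (1 - e) + (1 - raf_l) * e)
  ro_h <- rbinom(m, depth_h, p_h)
  ro_l <- rbinom(m, depth_l, p_l)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)

  qual <- if (is.function(config$qual)) config$qual(m) else rep(config$qual, m)

  tibble::tibble(
    chromosome = panel$markers$chromosome,
    pos = panel$markers$pos,
    marker_id = panel$markers$marker_id,
    ref = ref,
    alt = alt,
    qual = as.numeric(qual),
    ro_high = ro_h,
    ao_high = depth_h - ro_h,
    ro_low = ro_l,
    ao_low = depth_l - ro_l,
    true_raf_high = raf_h,
    true_raf_low = raf_l,
    flagged = flagged
  )
}

# per-marker reference allele frequency of a pool: ref-hom lines over
# non-missing lines; NA when every genotype in the pool is missing
pool_raf <- function(geno) {
  n_ref <- colSums(geno == 2L, na.rm = TRUE)
  n_obs <- colSums(!is.na(geno))
  ifelse(n_obs == 0, NA_real_, n_ref / n_obs)
}

draw_depth <- function(config, m) {
  switch(config$coverage_law,
    poisson = rpois(m, config$mean_coverage),
    negative_binomial = rnbinom(m, size = config$coverage_dispersion,
                                mu = config$mean_coverage)
  )
}
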