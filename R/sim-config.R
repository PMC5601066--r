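#' Simulation configuration for a synthetic inbred variety panel
#'
#' Bundles every knob of the synthetic-data generator: panel size, genome
#' layout, founder allele frequencies, planted additive QTL, trait noise,
#' pool size and the pooled-read coverage model. The defaults emulate the
#' study conditions the pipeline is designed for: a few hundred fully inbred
#' varieties genotyped at array-scale marker density, contrasting sets of 12
#' lines, and exome-capture pool coverage in the low hundreds of reads per
#' variant.
#'
#' @param n_varieties Number of inbred varieties in the panel.
#' @param chromosomes Data frame with columns `name`, `length` (bp),
#'   `cent_start`, `cent_end` (1-based bp, centromere interval). The default
#'   is a single 700 Mbp chromosome with a 300--400 Mbp centromere.
#' @param n_markers Total number of biallelic markers, spread across
#'   chromosomes proportionally to their length.
#' @param founder_freq Either a length-2 numeric giving the bounds of a
#'   uniform law for per-marker reference allele frequency (default
#'   `c(0.05, 0.95)`), or a function `f(m)` returning `m` frequencies.
#' @param n_qtl Number of causal markers.
#' @param qtl_freq Optional length-2 range; when given, the founder
#'   reference allele frequency of each causal marker is redrawn uniformly
#'   from it, so planted QTL segregate at controlled frequencies while the
#'   genomic background follows `founder_freq`.
#' @param qtl_effects Additive effect sizes, trait units per reference
#'   allele dose at a causal marker; recycled/truncated to length `n_qtl`.
#' @param noise_sd Standard deviation of the Gaussian trait noise.
#' @param pool_size Number of lines per contrasting set (default 12).
#' @param mean_coverage Mean reads per pool per variant (default 275,
#'   matching exome-capture pool coverage of a few hundred fold).
#' @param coverage_law `"poisson"` or `"negative_binomial"`.
#' @param coverage_dispersion Size parameter of the negative binomial
#'   coverage law (ignored for Poisson).
#' @param base_error Per-read probability of reading the wrong allele, in
#'   `[0, 0.5)`.
#' @param missing_genotype_rate Fraction of genotype calls set to missing.
#' @param qual Phred-scaled call quality attached to every simulated
#'   variant record; either a single value (default 60) or a function
#'   `f(m)` returning `m` values, used to inject low-quality records.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_panel()], [simulate_pooled_reads()]
#' @export
#' @examples
#' cfg <- sim_config(n_varieties = 100, n_markers = 200, n_qtl = 1,
#'                   qtl_effects = 15, noise_sd = 8, seed = 1)
#' cfg$pool_size
sim_config <- function(n_varieties = 400,
                       chromosomes = default_chromosomes(),
                       n_markers = 1000,
                       founder_freq = c(0.05, 0.95),
                       n_qtl = 0,
                       qtl_freq = NULL,
                       qtl_effects = numeric(),
                       noise_sd = 1,
                       pool_size = 12,
                       mean_coverage = 275,
                       coverage_law = c("poisson", "negative_binomial"),
                       coverage_dispersion = 10,
                       base_error = 0,
                       missing_genotype_rate = 0,
                       qual = 60,
                       seed = 1L) {
  coverage_law <- match.arg(coverage_law)
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (!all(c("cent_start", "cent_end") %in% names(chromosomes))) {
    chromosomes$cent_start <- NA_real_
    chromosomes$cent_end <- NA_real_
  }
  ok_cent <- is.na(chromosomes$cent_start) |
    (chromosomes$cent_start >= 1 & chromosomes$cent_end <= chromosomes$length &
       chromosomes$cent_start <= chromosomes$cent_end)
  if (!all(ok_cent)) {
    abort("centromere interval must lie inside its chromosome")
  }
  if (n_varieties < 2) abort("n_varieties must be at least 2")
  if (pool_size < 2) abort("pool_size must be at least 2")
  if (mean_coverage <= 0) abort("mean_coverage must be positive")
  if (n_qtl > n_markers) {
    abort("n_qtl exceeds n_markers: cannot place that many causal markers")
  }
  qtl_effects <- rep_len(as.numeric(qtl_effects), n_qtl)
  if (n_qtl > 0 && !all(is.finite(qtl_effects))) {
    abort("all QTL effect sizes must be finite")
  }
  if (base_error < 0 || base_error >= 0.5) abort("base_error must be in [0, 0.5)")
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1) {
    abort("missing_genotype_rate must be in [0, 1)")
  }
  if (!is.null(qtl_freq)) {
    stopifnot(is.numeric(qtl_freq), length(qtl_freq) == 2,
              qtl_freq[1] >= 0, qtl_freq[2] <= 1, qtl_freq[1] <= qtl_freq[2])
  }
  if (is.numeric(founder_freq)) {
    stopifnot(length(founder_freq) == 2, founder_freq[1] >= 0,
              founder_freq[2] <= 1, founder_freq[1] <= founder_freq[2])
  } else if (!is.function(founder_freq)) {
    abort("founder_freq must be a length-2 numeric range or a function")
  }
  structure(
    list(
      n_varieties = as.integer(n_varieties),
      chromosomes = chromosomes,
      n_markers = as.integer(n_markers),
      founder_freq = founder_freq,
      n_qtl = as.integer(n_qtl),
      qtl_freq = qtl_freq,
      qtl_effects = qtl_effects,
      noise_sd = noise_sd,
      pool_size = as.integer(pool_size),
      mean_coverage = mean_coverage,
      coverage_law = coverage_law,
      coverage_dispersion = coverage_dispersion,
      base_error = base_error,
      missing_genotype_rate = missing_genotype_rate,
      qual = qual,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default synthetic genome layout
#'
#' Seven chromosomes of barley-like physical size (500--700 Mbp) with broad
#' central centromeric regions, named `1H`..`7H`.
#'
#' @return A tibble with columns `name`, `length`, `cent_start`, `cent_end`.
#' @export
default_chromosomes <- function() {
  len <- c(558e6, 768e6, 700e6, 647e6, 670e6, 583e6, 657e6)
  tibble::tibble(
    name = paste0(1:7, "H"),
    length = len,
    cent_start = round(len * 0.35),
    cent_end = round(len * 0.65)
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Fields of the YAML map one-to-one onto [sim_config()] arguments;
#' `chromosomes` is given as a list of `{name, length, cent_start, cent_end}`
#' records. Absent fields take the `sim_config()` defaults.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the one in the file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$chromosomes)) {
    raw$chromosomes <- dplyr::bind_rows(lapply(raw$chromosomes, tibble::as_tibble))
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  varieties:", x$n_varieties, " markers:", x$n_markers,
      "on", nrow(x$chromosomes), "chromosome(s)\n")
  cat("  QTL:", x$n_qtl,
      if (x$n_qtl > 0) paste0("(effects ", paste(signif(x$qtl_effects, 3), collapse = ", "), ")"),
      " noise sd:", x$noise_sd, "\n")
  cat("  pools of", x$pool_size, "| coverage", x$mean_coverage,
      paste0("(", x$coverage_law, ")"), "| base error", x$base_error, "\n")
  invisible(x)
}
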