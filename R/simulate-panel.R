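#' Simulate an inbred variety panel with planted additive QTL
#'
#' Draws a fully inbred panel: every genotype is homozygous reference
#' (coded 2), homozygous alternate (coded 0) or missing (`NA`), with the
#' reference-homozygote probability at each marker given by its founder
#' reference allele frequency. `n_qtl` marker columns are designated causal
#' and the trait of each variety is the sum of additive effects over causal
#' markers at which it is reference-homozygous, plus Gaussian noise:
#' \deqn{y_i = \sum_k a_k\, [g_{ik} = 2] + \varepsilon_i,\quad
#'       \varepsilon_i \sim N(0, \sigma^2).}
#' Heterozygotes never occur, matching an essentially fully selfing crop,
#' so pooled allele frequencies move in steps of 1/(pool size).
#'
#' @param config A [sim_config()] object.
#' @return A `variety_panel`: a list with
#'   * `phenotypes` — tibble `variety_id`, `trait`;
#'   * `genotypes` — integer matrix varieties x markers, codes 0/2/`NA`,
#'     rownames variety ids, colnames marker ids;
#'   * `markers` — tibble `marker_id`, `chromosome`, `pos`, `founder_raf`,
#'     `causal`, `effect`, positions strictly increasing within chromosome.
#' @export
#' @examples
#' panel <- simulate_panel(sim_config(n_varieties = 50, n_markers = 100,
#'                                    n_qtl = 1, qtl_effects = 10,
#'                                    noise_sd = 2, seed = 7))
#' panel
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_varieties
  m <- config$n_markers

  markers <- place_markers(config$chromosomes, m)
  markers$founder_raf <- founder_frequencies(config, m)

  causal_idx <- if (config$n_qtl > 0) sort(sample.int(m, config$n_qtl)) else integer()
  if (!is.null(config$qtl_freq) && length(causal_idx) > 0) {
    markers$founder_raf[causal_idx] <-
      runif(length(causal_idx), config$qtl_freq[1], config$qtl_freq[2])
  }
  markers$causal <- seq_len(m) %in% causal_idx
  markers$effect <- 0
  markers$effect[causal_idx] <- config$qtl_effects

  # inbred: each line is ref-hom (2) w.p. founder_raf, else alt-hom (0)
  geno <- matrix(
    2L * rbinom(n * m, 1L, rep(markers$founder_raf, each = n)),
    nrow = n, ncol = m,
    dimnames = list(sprintf("var%04d", seq_len(n)), markers$marker_id)
  )

  dose <- (geno[, causal_idx, drop = FALSE] == 2L) * 1
  trait <- as.numeric(dose %*% config$qtl_effects) + rnorm(n, 0, config$noise_sd)

  if (config$missing_genotype_rate > 0) {
    drop <- runif(n * m) < config$missing_genotype_rate
    geno[drop] <- NA_integer_
  }

  structure(
    list(
      phenotypes = tibble::tibble(variety_id = rownames(geno), trait = trait),
      genotypes = geno,
      markers = markers
    ),
    class = "variety_panel"
  )
}

# spread markers over chromosomes proportionally to physical length,
# positions strictly increasing within each chromosome
place_markers <- function(chromosomes, m) {
  w <- chromosomes$length / sum(chromosomes$length)
  counts <- diff(round(cumsum(c(0, w * m))))
  counts[length(counts)] <- m - sum(counts[-length(counts)])
  per_chr <- purrr::pmap(
    list(chromosomes$name, chromosomes$length, counts),
    function(name, len, k) {
      if (k == 0) return(NULL)
      tibble::tibble(
        chromosome = name,
        pos = sort(sample.int(len, k))
      )
    }
  )
  out <- dplyr::bind_rows(per_chr)
  out$marker_id <- sprintf("mk%05d", seq_len(nrow(out)))
  out[, c("marker_id", "chromosome", "pos")]
}

founder_frequencies <- function(config, m) {
  f <- config$founder_freq
  if (is.function(f)) {
    freqs <- f(m)
    stopifnot(length(freqs) == m, all(freqs >= 0 & freqs <= 1))
    freqs
  } else {
    runif(m, f[1], f[2])
  }
}

#' @export
print.variety_panel <- function(x, ...) {
  cat("<variety_panel>", nrow(x$genotypes), "varieties x",
      ncol(x$genotypes), "markers;",
      sum(x$markers$causal), "causal\n")
  cat("  trait: mean", signif(mean(x$phenotypes$trait), 4),
      "sd", signif(sd(x$phenotypes$trait), 4), "\n")
  invisible(x)
}
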