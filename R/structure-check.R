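#' Population-structure check of a contrasting-set selection
#'
#' If set membership were confounded with population structure, markers
#' across the genome would segregate between the high and low sets more
#' often than chance allows. For every marker this runs a Pearson
#' chi-squared test of homogeneity (1 df, no continuity correction) on the
#' 2x2 allele-by-set count table over the selected lines (one allele call
#' per inbred line; missing genotypes dropped), then compares the sorted
#' p-values with their expected order statistics under no structure,
#' together with a pointwise 95% envelope.
#'
#' With a dozen lines per set the 2x2 tables are small and the chi-squared
#' p-value is discrete and conservative, so the expected quantiles are, by
#' default, taken from the exact permutation null of each marker's table
#' (set labels permuted with margins fixed, i.e. the reference-allele count
#' in the high set is hypergeometric), estimated by Monte Carlo: the
#' envelope is the pointwise 2.5%--97.5% band of the sorted null p-value
#' vectors. `null = "uniform"` instead pairs the sorted p-values with the
#' uniform order statistics `i/(m+1)` and a `Beta(i, m-i+1)` envelope, the
#' textbook construction appropriate for continuous p-values.
#'
#' Markers monomorphic within the selected lines carry no information and
#' are recorded with `p = 1` and flagged.
#'
#' @param genotypes Genotype matrix (codes 0/2/`NA`) whose rows cover the
#'   members of both sets.
#' @param sets A `contrast_sets` object, or a named list with
#'   `high_members` / `low_members` row names of `genotypes`.
#' @param null `"permutation"` (default) or `"uniform"` (see Details).
#' @param n_null Monte-Carlo replicates for the permutation null.
#' @param seed Seed for the permutation null draws.
#' @return A `structure_check` object: list with `per_marker` (tibble
#'   `marker`, `chi2`, `p`, `degenerate`) and `qq` (tibble `expected`,
#'   `observed`, `env_low`, `env_high`, sorted ascending). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
structure_check <- function(genotypes, sets, null = c("permutation", "uniform"),
                            n_null = 200, seed = 1L) {
  null <- match.arg(null)
  high <- genotypes[sets$high_members, , drop = FALSE]
  low <- genotypes[sets$low_members, , drop = FALSE]
  if (nrow(high) == 0 || nrow(low) == 0) abort("both sets must be non-empty")

  ref_h <- colSums(high == 2L, na.rm = TRUE)
  n_h <- colSums(!is.na(high))
  ref_l <- colSums(low == 2L, na.rm = TRUE)
  n_l <- colSums(!is.na(low))
  stat <- chisq_2x2_vec(ref_h, n_h - ref_h, ref_l, n_l - ref_l)
  per_marker <- tibble::tibble(
    marker = colnames(genotypes) %||% as.character(seq_along(ref_h)),
    chi2 = unname(stat$chi2),
    p = unname(stat$p),
    degenerate = unname(stat$degenerate)
  )

  m <- nrow(per_marker)
  i <- seq_len(m)
  if (null == "uniform") {
    qq <- tibble::tibble(
      expected = i / (m + 1),
      observed = sort(per_marker$p),
      env_low = qbeta(0.025, i, m - i + 1),
      env_high = qbeta(0.975, i, m - i + 1)
    )
  } else {
    set.seed(seed)
    # one hypergeometric draw per marker per replicate: margins fixed,
    # set labels exchangeable under no structure
    K <- ref_h + ref_l
    N <- n_h + n_l
    a <- matrix(rhyper(m * n_null, rep(K, n_null), rep(N - K, n_null),
                       rep(n_h, n_null)), nrow = m)
    null_p <- matrix(
      chisq_2x2_vec(as.vector(a), rep(n_h, n_null) - as.vector(a),
                    rep(K, n_null) - as.vector(a),
                    rep(n_l - K, n_null) + as.vector(a))$p,
      nrow = m
    )
    sorted <- apply(null_p, 2, sort)
    qq <- tibble::tibble(
      expected = apply(sorted, 1, stats::median),
      observed = sort(per_marker$p),
      env_low = apply(sorted, 1, stats::quantile, probs = 0.025, names = FALSE),
      env_high = apply(sorted, 1, stats::quantile, probs = 0.975, names = FALSE)
    )
  }
  structure(list(per_marker = per_marker, qq = qq, null = null),
            class = "structure_check")
}

# vectorised Pearson chi-squared (1 df, no correction) on 2x2 counts
# [[a, b], [c, d]]; zero-marginal tables get chi2 = 0, p = 1, degenerate
chisq_2x2_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  degenerate <- (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(degenerate, 0, n * (a * d - b * c)^2 / denom)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       degenerate = degenerate)
}

#' @export
print.structure_check <- function(x, ...) {
  g <- glance(x)
  cat("<structure_check>", g$n_markers, "markers;",
      g$n_degenerate, "monomorphic;",
      sprintf("%.1f%% of quantiles inside the 95%% envelope (%s null)\n",
              100 * g$prop_in_envelope, x$null))
  invisible(x)
}

#' @rdname structure_check
#' @param x A `structure_check` object.
#' @param ... Unused.
#' @method tidy structure_check
#' @export
tidy.structure_check <- function(x, ...) x$qq

#' @rdname structure_check
#' @method glance structure_check
#' @export
glance.structure_check <- function(x, ...) {
  inside <- x$qq$observed >= x$qq$env_low & x$qq$observed <= x$qq$env_high
  tibble::tibble(
    n_markers = nrow(x$per_marker),
    n_degenerate = sum(x$per_marker$degenerate),
    prop_in_envelope = mean(inside),
    median_p = stats::median(x$per_marker$p)
  )
}

#' @rdname structure_check
#' @param object A `structure_check` object.
#' @method autoplot structure_check
#' @export
autoplot.structure_check <- function(object, ...) {
  ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_low, ymax = .data$env_high),
                         fill = "grey80") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = "Expected p-value quantile under no structure",
                  y = "Observed p-value quantile",
                  title = "Homogeneity-test QQ against no population structure") +
    ggplot2::theme_minimal()
}
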