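# Pearson chi-squared on a 2x2 table, 1 df, no continuity correction.
# A zero row or column marginal makes the statistic undefined; by
# convention it is reported as 0 (p = 1) and flagged degenerate.
pearson_chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  n <- sum(tab)
  r <- rowSums(tab)
  cc <- colSums(tab)
  if (n == 0 || any(r == 0) || any(cc == 0)) {
    return(list(chi2 = 0, p = 1, neglog10p = 0, degenerate = TRUE))
  }
  delta <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
  if (correct) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / prod(r, cc)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       neglog10p = chisq_to_neglog10p(chi2, df = 1), degenerate = FALSE)
}

#' Chi-squared test of homogeneity on a 2x2 count table
#'
#' The test used to ask whether marker genotypes are distributed
#' homogeneously across two contrasting sets: Pearson chi-squared with 1
#' degree of freedom and, by default, no continuity correction (the
#' convention under which the companion `-log10 p` conversions reproduce
#' published 2x2 results for pooled-set validation). Counts are per line
#' (one allele call per inbred line), not per chromosome. A table with a
#' zero marginal is degenerate: the statistic is reported as 0 and flagged.
#'
#' @param counts 2x2 non-negative count matrix, rows = sets, columns =
#'   alleles (orientation does not affect the statistic).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A tibble with `chi2`, `p`, `neglog10p`, `degenerate`.
#' @export
#' @examples
#' chisq_homogeneity(matrix(c(12, 0, 0, 12), 2, byrow = TRUE))
chisq_homogeneity <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  res <- pearson_chisq_2x2(counts, correct = correct)
  tibble::tibble(chi2 = res$chi2, p = res$p, neglog10p = res$neglog10p,
                 degenerate = res$degenerate)
}

#' Convert a chi-squared statistic to -log10 p
#'
#' Upper-tail probability of the chi-squared distribution on the log scale,
#' so very large statistics convert without underflow.
#'
#' @param chi2 Non-negative statistic (vectorised).
#' @param df Degrees of freedom (default 1).
#' @return `-log10` of the upper-tail p-value.
#' @export
#' @examples
#' chisq_to_neglog10p(14.29) # 3.80
chisq_to_neglog10p <- function(chi2, df = 1) {
  stopifnot(all(chi2 >= 0))
  -pchisq(chi2, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' True allele frequency difference from individual genotypes
#'
#' The "true" AFD against which pooled-read estimates are validated: the
#' per-set reference allele frequency over non-missing individually
#' genotyped lines, high set minus low set.
#'
#' @param high,low Genotype codes (0 = alt-hom, 2 = ref-hom, `NA` missing)
#'   for one marker over the members of each set.
#' @return A tibble with `raf_high`, `raf_low`, `true_afd` and the
#'   non-missing counts `n_high`, `n_low`. A set with no usable calls
#'   yields `NA` frequencies and a warning.
#' @export
#' @examples
#' true_afd_from_genotypes(rep(2, 12), c(rep(2, 3), rep(0, 9)))
true_afd_from_genotypes <- function(high, low) {
  f <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(c(NA_real_, 0))
    c(mean(g == 2), length(g))
  }
  fh <- f(high)
  fl <- f(low)
  if (is.na(fh[1]) || is.na(fl[1])) {
    warn("a set has no non-missing genotypes; true AFD undefined")
  }
  tibble::tibble(raf_high = fh[1], raf_low = fl[1],
                 true_afd = fh[1] - fl[1],
                 n_high = as.integer(fh[2]), n_low = as.integer(fl[2]))
}

#' Agreement between estimated and true allele frequencies
#'
#' Two complementary summaries of how well pooled-read estimates track the
#' truth. `identity_r2` is the variance explained by the one-to-one line:
#' \deqn{R^2 = 1 - \frac{\sum (est - true)^2}{\sum (est - \bar{est})^2},}
#' i.e. residuals are taken about `y = x` (not a fitted slope), so any bias
#' or attenuation costs variance explained. `abs_correlation` is the
#' Pearson correlation of `|est|` with `|true|`, the summary used when the
#' quantities are signed frequency differences.
#'
#' @param data Data frame with the estimate and truth columns.
#' @param est,true Column names (tidy-eval) of the estimated and true
#'   values.
#' @return An object of class `raf_comparison` with `glance()` and
#'   `autoplot()` methods; `glance()` returns `n`, `identity_r2`,
#'   `abs_correlation`, `rmse`.
#' @export
compare_estimated_true <- function(data, est, true) {
  est_v <- dplyr::pull(data, {{ est }})
  true_v <- dplyr::pull(data, {{ true }})
  keep <- is.finite(est_v) & is.finite(true_v)
  est_v <- est_v[keep]
  true_v <- true_v[keep]
  if (length(est_v) < 3) abort("need at least 3 complete (est, true) pairs")
  ss_est <- sum((est_v - mean(est_v))^2)
  if (ss_est == 0) {
    warn("zero variance in estimates; identity R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((est_v - true_v)^2) / ss_est
  }
  structure(
    list(
      pairs = tibble::tibble(est = est_v, true = true_v),
      identity_r2 = r2,
      abs_correlation = if (sd(abs(est_v)) > 0 && sd(abs(true_v)) > 0) {
        cor(abs(est_v), abs(true_v))
      } else {
        NA_real_
      },
      rmse = sqrt(mean((est_v - true_v)^2))
    ),
    class = "raf_comparison"
  )
}

#' @export
print.raf_comparison <- function(x, ...) {
  cat("<raf_comparison>", nrow(x$pairs), "pairs | identity R^2:",
      signif(x$identity_r2, 3), "| |r|:", signif(x$abs_correlation, 3), "\n")
  invisible(x)
}

#' @rdname compare_estimated_true
#' @param x,object A `raf_comparison` object.
#' @param ... Unused.
#' @method glance raf_comparison
#' @export
glance.raf_comparison <- function(x, ...) {
  tibble::tibble(n = nrow(x$pairs), identity_r2 = x$identity_r2,
                 abs_correlation = x$abs_correlation, rmse = x$rmse)
}

#' @rdname compare_estimated_true
#' @method autoplot raf_comparison
#' @export
autoplot.raf_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$true, y = .data$est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "True reference allele frequency",
      y = "Estimated reference allele frequency",
      title = sprintf("Identity-line R² = %.2f", object$identity_r2)
    ) +
    ggplot2::theme_minimal()
}

#' One-sided pooled-variance t-test of trait by carried allele
#'
#' Tests whether lines carrying the putative high allele at a marker have a
#' higher trait mean than lines carrying the low allele, using the
#' two-sample pooled-variance t statistic with `n1 + n2 - 2` degrees of
#' freedom and a one-sided p-value for the alternative
#' `mean(high) > mean(low)` (set `alternative = "two.sided"` for the
#' symmetric test). Group means, standard errors and counts are reported
#' alongside the test.
#'
#' @param data Data frame with one row per line.
#' @param trait Column (tidy-eval) with the trait value.
#' @param allele Column (tidy-eval) with the carried-allele label.
#' @param high_allele,low_allele Values of `allele` defining the groups;
#'   defaults `"H"` and `"L"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An `allele_trait_test` object; `tidy()` gives per-group rows
#'   (`allele`, `n`, `mean`, `sem`), `glance()` the test (`t`, `df`, `p`).
#' @export
#' @examples
#' d <- data.frame(dp = c(104, 98, 101, 88, 90, 86),
#'                 allele = rep(c("H", "L"), each = 3))
#' glance(allele_trait_ttest(d, dp, allele))
allele_trait_ttest <- function(data, trait, allele,
                               high_allele = "H", low_allele = "L",
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  y <- dplyr::pull(data, {{ trait }})
  g <- dplyr::pull(data, {{ allele }})
  y_h <- y[g == high_allele & is.finite(y)]
  y_l <- y[g == low_allele & is.finite(y)]
  n1 <- length(y_h)
  n2 <- length(y_l)
  if (n1 < 2 || n2 < 2) abort("both allele groups need at least 2 lines")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(y_h) + (n2 - 1) * var(y_l)) / df
  zero_var <- sp2 == 0
  tstat <- (mean(y_h) - mean(y_l)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (alternative == "greater") {
    pt(tstat, df, lower.tail = FALSE)
  } else {
    2 * pt(abs(tstat), df, lower.tail = FALSE)
  }
  structure(
    list(
      groups = tibble::tibble(
        allele = c(high_allele, low_allele),
        n = c(n1, n2),
        mean = c(mean(y_h), mean(y_l)),
        sem = c(sd(y_h) / sqrt(n1), sd(y_l) / sqrt(n2))
      ),
      t = tstat, df = df, p = p,
      alternative = alternative,
      flag_zero_variance = zero_var
    ),
    class = "allele_trait_test"
  )
}

#' @export
print.allele_trait_test <- function(x, ...) {
  cat("<allele_trait_test> t =", signif(x$t, 3), " df =", x$df,
      " p =", signif(x$p, 3), paste0("(", x$alternative, ")"), "\n")
  print(x$groups)
  invisible(x)
}

#' @rdname allele_trait_ttest
#' @param x A fitted `allele_trait_test`.
#' @param ... Unused.
#' @method tidy allele_trait_test
#' @export
tidy.allele_trait_test <- function(x, ...) x$groups

#' @rdname allele_trait_ttest
#' @method glance allele_trait_test
#' @export
glance.allele_trait_test <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p = x$p, alternative = x$alternative,
                 zero_variance = x$flag_zero_variance)
}
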