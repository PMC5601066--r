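test_that("chi-squared homogeneity reproduces closed-form and degenerate cases", {
  expect_equal(chisq_homogeneity(matrix(c(12, 0, 0, 12), 2, byrow = TRUE))$chi2, 24)
  balanced <- chisq_homogeneity(matrix(c(6, 6, 6, 6), 2, byrow = TRUE))
  expect_equal(balanced$chi2, 0)
  expect_equal(balanced$neglog10p, 0)
  degen <- chisq_homogeneity(matrix(c(12, 0, 12, 0), 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$chi2, 0)
  expect_equal(degen$p, 1)
  # the continuity-corrected variant is available and differs
  tab <- matrix(c(10, 2, 4, 8), 2, byrow = TRUE)
  expect_lt(chisq_homogeneity(tab, correct = TRUE)$chi2,
            chisq_homogeneity(tab)$chi2)
})

test_that("chi-squared statistics convert to published -log10 p values", {
  # printed (chi2, -log10 p) pairs from per-marker set-homogeneity tests
  expect_equal(round(chisq_to_neglog10p(18.62), 2), 4.80)
  expect_equal(round(chisq_to_neglog10p(14.29), 2), 3.80)
  expect_equal(round(chisq_to_neglog10p(12.8), 2), 3.46)
  expect_equal(chisq_to_neglog10p(0), 0)
  # survives statistics that would underflow the p-value itself
  expect_gt(chisq_to_neglog10p(3000), 600)
})

test_that("the 1-df conversion agrees with the squared-normal identity", {
  z <- seq(0.1, 6, by = 0.1)
  expect_equal(chisq_to_neglog10p(z^2, df = 1),
               -log10(2 * pnorm(-abs(z))), tolerance = 1e-10)
})

test_that("homogeneity is invariant to row/column swaps and transposition", {
  set.seed(61)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    base <- chisq_homogeneity(tab)$chi2
    expect_equal(chisq_homogeneity(tab[2:1, ])$chi2, base)
    expect_equal(chisq_homogeneity(tab[, 2:1])$chi2, base)
    expect_equal(chisq_homogeneity(t(tab))$chi2, base)
  }
})

test_that("true AFD from genotypes handles missing calls by per-set recount", {
  full <- true_afd_from_genotypes(rep(2, 12), c(rep(2, 3), rep(0, 9)))
  expect_equal(full$true_afd, 0.75)
  with_missing <- true_afd_from_genotypes(
    c(rep(2, 10), NA, NA),
    c(rep(2, 2), rep(0, 6), rep(NA, 4))
  )
  expect_equal(with_missing$true_afd, 0.75)
  expect_equal(with_missing$n_high, 10L)
  expect_equal(with_missing$n_low, 8L)
  expect_warning(res <- true_afd_from_genotypes(rep(NA, 5), rep(0, 5)),
                 "undefined")
  expect_true(is.na(res$true_afd))

  set.seed(71)
  for (i in 1:10) {
    h <- sample(c(0L, 2L, NA), 12, replace = TRUE)
    l <- sample(c(0L, 2L, NA), 12, replace = TRUE)
    if (all(is.na(h)) || all(is.na(l))) next
    got <- true_afd_from_genotypes(h, l)
    brute <- sum(h == 2, na.rm = TRUE) / sum(!is.na(h)) -
      sum(l == 2, na.rm = TRUE) / sum(!is.na(l))
    expect_equal(got$true_afd, brute)
  }
})

test_that("identity-line R2 follows its stated formula", {
  exact <- compare_estimated_true(
    tibble::tibble(e = c(0.1, 0.4, 0.8), t = c(0.1, 0.4, 0.8)), e, t)
  expect_equal(exact$identity_r2, 1)
  expect_equal(exact$abs_correlation, 1)

  # constant offset of 0.5 on five spread true values, evaluated by hand:
  # sum of squared residuals about y = x is 5 * 0.25 = 1.25, spread of the
  # estimates about their mean is 0.4, so R2 = 1 - 1.25/0.4 = -2.125
  truth <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  offset <- compare_estimated_true(
    tibble::tibble(e = truth + 0.5, t = truth), e, t)
  expect_equal(offset$identity_r2, -2.125)

  expect_error(compare_estimated_true(tibble::tibble(e = 1:2, t = 1:2), e, t),
               "at least 3")
  expect_warning(
    flat <- compare_estimated_true(tibble::tibble(e = rep(0.5, 5),
                                                  t = truth), e, t),
    "zero variance")
  expect_true(is.na(flat$identity_r2))
})

test_that("pooled estimates at deep coverage recover true frequencies with R2 > 0.9", {
  for (seed in c(101, 202)) {
    cfg <- sim_config(n_varieties = 24, n_markers = 800, mean_coverage = 100,
                      base_error = 0.001, seed = seed)
    set.seed(seed)
    geno <- matrix(2L * rbinom(24 * 800, 1, runif(800, 0.05, 0.95)),
                   nrow = 24, byrow = TRUE)
    panel <- make_panel(geno)
    sets <- list(high_members = rownames(panel$genotypes)[1:12],
                 low_members = rownames(panel$genotypes)[13:24])
    reads <- simulate_pooled_reads(panel, sets, cfg)
    rec <- compute_afd(filter_variants(reads, min_reads = 50))
    pairs <- tibble::tibble(est = c(rec$raf_high, rec$raf_low),
                            true = c(rec$true_raf_high, rec$true_raf_low))
    cmp <- compare_estimated_true(pairs, est, true)
    expect_gt(cmp$identity_r2, 0.9)
  }
})

test_that("the allele t-test matches published tail probabilities and stats::t.test", {
  # one-sided pooled-t conversions printed in marker-validation tables
  expect_equal(round(pt(1.9, 80, lower.tail = FALSE), 3), 0.031)
  expect_equal(round(pt(2.75, 74, lower.tail = FALSE), 3), 0.004)

  set.seed(81)
  d <- tibble::tibble(
    dp = c(rnorm(33, 101.5, 10), rnorm(43, 88.1, 10)),
    allele = rep(c("H", "L"), c(33, 43))
  )
  fit <- allele_trait_ttest(d, dp, allele)
  expect_equal(fit$df, 33 + 43 - 2)
  oracle <- t.test(dp ~ factor(allele, c("H", "L")), data = d,
                   var.equal = TRUE, alternative = "greater")
  expect_equal(fit$t, unname(oracle$statistic))
  expect_equal(fit$p, oracle$p.value)
  expect_equal(glance(fit)$p, fit$p)
  grp <- tidy(fit)
  expect_equal(grp$n, c(33L, 43L))
  expect_equal(grp$mean[1], mean(d$dp[d$allele == "H"]))
  expect_equal(grp$sem[2], sd(d$dp[d$allele == "L"]) / sqrt(43))

  two <- allele_trait_ttest(d, dp, allele, alternative = "two.sided")
  expect_equal(two$p, t.test(dp ~ factor(allele, c("H", "L")), data = d,
                             var.equal = TRUE)$p.value)
})

test_that("degenerate t-test inputs behave as documented", {
  d0 <- tibble::tibble(y = c(5, 7, 5, 7), g = c("H", "H", "L", "L"))
  fit <- allele_trait_ttest(d0, y, g)
  expect_equal(fit$t, 0)
  expect_equal(fit$p, 0.5)
  flat <- tibble::tibble(y = c(3, 3, 1, 1), g = c("H", "H", "L", "L"))
  fit2 <- allele_trait_ttest(flat, y, g)
  expect_true(fit2$flag_zero_variance)
  expect_true(is.infinite(fit2$t))
  expect_error(allele_trait_ttest(tibble::tibble(y = 1:3, g = c("H", "L", "L")),
                                  y, g), "at least 2")
})

test_that("df equals n1 + n2 - 2 across random group sizes", {
  set.seed(91)
  for (i in 1:10) {
    n1 <- sample(2:50, 1)
    n2 <- sample(2:50, 1)
    d <- tibble::tibble(y = rnorm(n1 + n2), g = rep(c("H", "L"), c(n1, n2)))
    expect_equal(allele_trait_ttest(d, y, g)$df, n1 + n2 - 2)
  }
})

test_that("markers selected for extreme estimated AFD regress toward the mean", {
  # pools constructed so true |AFD| spreads around the 0.75 threshold
  # (high pool ref count ~ Bin(12, 0.8), low ~ Bin(12, 0.2)); read noise at
  # 100x then decides which markers cross it, so the selected estimates
  # should overstate the truth on average
  sel_est <- c()
  sel_true <- c()
  for (seed in 1:3) {
    set.seed(seed)
    m <- 2000
    kh <- rbinom(m, 12, 0.8)
    kl <- rbinom(m, 12, 0.2)
    geno <- matrix(0L, 24, m)
    for (j in seq_len(m)) {
      if (kh[j] > 0) geno[seq_len(kh[j]), j] <- 2L
      if (kl[j] > 0) geno[12 + seq_len(kl[j]), j] <- 2L
    }
    panel <- make_panel(geno)
    sets <- list(high_members = rownames(panel$genotypes)[1:12],
                 low_members = rownames(panel$genotypes)[13:24])
    cfg <- sim_config(n_varieties = 24, n_markers = m, mean_coverage = 100,
                      seed = seed)
    reads <- simulate_pooled_reads(panel, sets, cfg)
    afd <- compute_afd(filter_variants(reads, min_reads = 50))
    hit <- abs(afd$afd) > 0.75
    sel_est <- c(sel_est, abs(afd$afd[hit]))
    sel_true <- c(sel_true, abs(afd$true_raf_high - afd$true_raf_low)[hit])
  }
  expect_gt(length(sel_est), 100)
  expect_lt(mean(sel_true), mean(sel_est))
})
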