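test_that("Euclidean distances reproduce allele-difference counts", {
  g <- matrix(0L, nrow = 3, ncol = 1000,
              dimnames = list(c("a", "b", "c"), NULL))
  g[2, 1:400] <- 2L # b differs from a at exactly 400 markers
  d <- euclidean_distance_matrix(g)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], 20) # sqrt(400): the threshold-20 rationale
  expect_equal(d["a", "c"], 0)  # identical rows
})

test_that("missing genotypes are handled pairwise-complete with rescaling", {
  g <- matrix(c(0, 2, 2, 0,
                2, 2, 0, 0,
                0, NA, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  d <- euclidean_distance_matrix(g)
  brute <- function(u, v) {
    ok <- !is.na(u) & !is.na(v)
    sqrt(sum(((u[ok] - v[ok]) / 2)^2) * length(u) / sum(ok))
  }
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    expect_equal(d[pair[1], pair[2]], brute(g[pair[1], ], g[pair[2], ]))
  }
  g_bad <- rbind(a = c(1, NA, NA), b = c(NA, 1, NA), c = c(1, 1, 1))
  expect_error(euclidean_distance_matrix(g_bad), "undefined")
})

test_that("unconstrained greedy selection returns the trait extremes", {
  set.seed(1)
  geno <- matrix(2L * rbinom(40 * 600, 1, 0.5), nrow = 40)
  panel <- make_panel(geno, trait = rnorm(40))
  top <- select_contrasting_sets(panel, "high", set_size = 5, min_distance = 0)
  expected <- panel$phenotypes$variety_id[order(panel$phenotypes$trait,
                                                decreasing = TRUE)][1:5]
  expect_equal(top$variety_id, expected)
  bottom <- select_contrasting_sets(panel, "low", set_size = 5, min_distance = 0)
  expect_equal(bottom$variety_id,
               panel$phenotypes$variety_id[order(panel$phenotypes$trait)][1:5])
})

test_that("a clone of an admitted line is skipped and logged", {
  geno <- matrix(2L * rbinom(10 * 500, 1, 0.5), nrow = 10)
  geno[2, ] <- geno[1, ] # ranks 1 and 2 are clones
  panel <- make_panel(geno, trait = 10:1)
  sel <- select_contrasting_sets(panel, "high", set_size = 3, min_distance = 5)
  expect_equal(sel$variety_id, c("v001", "v003", "v004"))
  log <- attr(sel, "skip_log")
  expect_equal(log$variety_id, "v002")
  expect_match(log$reason, "below 5")
})

test_that("forced members are admitted regardless of rank or distance", {
  geno <- matrix(2L * rbinom(20 * 500, 1, 0.5), nrow = 20)
  panel <- make_panel(geno, trait = 20:1)
  sel <- select_contrasting_sets(panel, "high", set_size = 4, min_distance = 0,
                                 forced = "v019")
  expect_true("v019" %in% sel$variety_id)
  expect_equal(sel$variety_id[1], "v019")
  expect_error(
    select_contrasting_sets(panel, "high", set_size = 4, forced = "ghost"),
    "ghost"
  )
})

test_that("selection matches an independent greedy re-implementation", {
  set.seed(42)
  n <- 200
  geno <- matrix(2L * rbinom(n * 800, 1, runif(800, 0.1, 0.9)),
                 nrow = n, byrow = TRUE)
  panel <- make_panel(geno, trait = rnorm(n))
  d <- euclidean_distance_matrix(panel$genotypes)
  thr <- quantile(d[upper.tri(d)], 0.1) # excludes ~10% of pairs
  for (tail in c("high", "low")) {
    sel <- select_contrasting_sets(panel, tail, set_size = 12,
                                   min_distance = thr)
    oracle <- greedy_oracle(panel$phenotypes$variety_id,
                            panel$phenotypes$trait, d, tail, 12, thr)
    expect_equal(sel$variety_id, oracle)
    dd <- d[sel$variety_id, sel$variety_id]
    expect_true(all(dd[upper.tri(dd)] >= thr))
  }
})

test_that("selection is deterministic and exhaustion raises a clear error", {
  geno <- matrix(2L * rbinom(30 * 400, 1, 0.5), nrow = 30)
  panel <- make_panel(geno, trait = rep(1, 30)) # all tied: input order decides
  s1 <- select_contrasting_sets(panel, "high", set_size = 6, min_distance = 0)
  s2 <- select_contrasting_sets(panel, "high", set_size = 6, min_distance = 0)
  expect_identical(s1$variety_id, s2$variety_id)
  expect_equal(s1$variety_id, rownames(panel$genotypes)[1:6])
  expect_error(
    select_contrasting_sets(panel, "high", set_size = 6, min_distance = 1e6),
    "exhausted"
  )
})

test_that("raising min_distance never makes the high set more extreme", {
  set.seed(7)
  geno <- matrix(2L * rbinom(150 * 600, 1, 0.5), nrow = 150)
  panel <- make_panel(geno, trait = rnorm(150))
  thresholds <- c(0, 10, 14, 16, 17)
  means <- vapply(thresholds, function(th) {
    mean(select_contrasting_sets(panel, "high", set_size = 12,
                                 min_distance = th)$trait)
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-12))
})

test_that("paired set selection yields disjoint sets meeting the invariants", {
  set.seed(3)
  geno <- matrix(2L * rbinom(120 * 700, 1, runif(700, 0.1, 0.9)),
                 nrow = 120, byrow = TRUE)
  panel <- make_panel(geno, trait = rnorm(120))
  sets <- select_contrast_sets(panel, set_size = 12, min_distance = 10)
  expect_length(intersect(sets$high_members, sets$low_members), 0)
  expect_length(sets$high_members, 12)
  expect_length(sets$low_members, 12)
})

test_that("homogeneity tests give p = 1 for balanced markers and chi2 = 24 for perfect partition", {
  geno <- matrix(0L, nrow = 24, ncol = 3,
                 dimnames = list(sprintf("v%02d", 1:24), c("same", "split", "mono")))
  geno[c(1:6, 13:18), "same"] <- 2L   # identical allele counts in both sets
  geno[1:12, "split"] <- 2L           # 12 ref vs 0 ref: perfect partition
  sets <- list(high_members = rownames(geno)[1:12],
               low_members = rownames(geno)[13:24])
  sc <- structure_check(geno, sets)
  pm <- sc$per_marker
  expect_equal(pm$p[pm$marker == "same"], 1)
  expect_equal(pm$chi2[pm$marker == "split"], 24)
  expect_true(pm$degenerate[pm$marker == "mono"])
  expect_equal(pm$p[pm$marker == "mono"], 1)
})

test_that("null-simulated panels stay inside the QQ envelope", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 24
    m <- 2000
    p <- runif(m, 0.05, 0.95)
    g <- matrix(2L * rbinom(n * m, 1, rep(p, each = n)), n, m,
                dimnames = list(sprintf("v%02d", 1:n), sprintf("mk%04d", 1:m)))
    sets <- list(high_members = rownames(g)[1:12],
                 low_members = rownames(g)[13:24])
    sc <- structure_check(g, sets, seed = seed)
    expect_gte(glance(sc)$prop_in_envelope, 0.9)
    # envelope brackets its centre and both quantile vectors are sorted
    expect_true(all(sc$qq$env_low <= sc$qq$expected + 1e-12))
    expect_true(all(sc$qq$expected <= sc$qq$env_high + 1e-12))
    expect_true(!is.unsorted(sc$qq$observed))
    expect_true(!is.unsorted(sc$qq$expected))
  }
})

test_that("the uniform-order-statistic envelope is available and well formed", {
  set.seed(5)
  g <- matrix(2L * rbinom(24 * 200, 1, 0.5), 24, 200,
              dimnames = list(sprintf("v%02d", 1:24), NULL))
  sets <- list(high_members = rownames(g)[1:12],
               low_members = rownames(g)[13:24])
  sc <- structure_check(g, sets, null = "uniform")
  m <- 200
  expect_equal(sc$qq$expected, seq_len(m) / (m + 1))
  expect_equal(sc$qq$env_low, qbeta(0.025, seq_len(m), m - seq_len(m) + 1))
  expect_true(all(sc$qq$env_low <= sc$qq$expected))
  expect_true(all(sc$qq$expected <= sc$qq$env_high))
})
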