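test_that("Mann-Whitney U is the first group's pair count", {
  x <- 11:20; y <- 1:13
  mw <- mann_whitney_pair(x + 100, y)      # complete separation, n = (10, 13)
  expect_equal(mw$U, 130)
  expect_lt(mw$p, 0.001)
  expect_equal(mann_whitney_pair(1:6, 1:6)$U, 18)   # x = y -> n1 n2 / 2
  set.seed(2)
  for (rep in 1:20) {
    x <- sample(0:30, sample(4:12, 1), replace = TRUE)
    y <- sample(0:30, sample(4:12, 1), replace = TRUE)
    expect_equal(mann_whitney_pair(x, y)$U, brute_U(x, y), tolerance = 1e-12)
  }
})

test_that("Cliff's delta is the oriented dominance and matches the U identity", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  cd <- cliffs_delta(c(1, 2), c(5, 6, 7))
  expect_equal(cd$delta, 1)
  expect_equal(cd$band, "large")
  expect_equal(cliffs_delta(c(5, 5), c(1, 2))$delta, -1)
  set.seed(4)
  for (rep in 1:20) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1))
    mw <- mann_whitney_pair(x, y)
    cd <- cliffs_delta(x, y)
    expect_equal(abs(cd$delta), abs(1 - 2 * mw$U / (mw$n1 * mw$n2)),
                 tolerance = 1e-12)
    direct <- (sum(outer(x, y, `<`)) - sum(outer(x, y, `>`))) /
      (length(x) * length(y))
    expect_equal(cd$delta, direct, tolerance = 1e-12)
  }
  expect_equal(cliffs_delta(rnorm(5), rnorm(5) + 100)$band, "large")
})

test_that("Hodges-Lehmann estimator is the median pairwise difference", {
  expect_equal(hodges_lehmann(c(4, 5, 6), c(1, 2, 3)), 3)
  expect_equal(hodges_lehmann(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  for (rep in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    expect_equal(hodges_lehmann(x, y),
                 median(as.vector(outer(x, y, `-`))), tolerance = 1e-12)
  }
  # a pure location shift is recovered exactly
  x <- rnorm(9)
  expect_equal(hodges_lehmann(x + 2.5, x), 2.5)
})

test_that("BH adjustment follows the step-up rule with external m", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  p <- c(0.04, 0.001, 0.02)
  q <- bh_fdr(p)
  expect_equal(q, c(0.04, 0.003, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(rep(0.1, 5), m = 3), "at least")
})

test_that("Kruskal-Wallis wrapper handles ties, separation, and degeneracy", {
  expect_equal(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), 3))$H, 0)
  g <- rep(c("WHO_I", "WHO_II", "GBM"), times = c(10, 5, 13))
  v <- c(rnorm(10), rnorm(5) + 50, rnorm(13) + 100)
  expect_lt(kruskal_wallis(v, g)$p, 0.001)
  # null calibration: p approximately uniform under permuted labels
  set.seed(10)
  ps <- replicate(200, {
    kruskal_wallis(rnorm(28), sample(g))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("compare_groups assembles gated pairwise tables with joint FDR", {
  set.seed(12)
  tbl <- tibble::tibble(
    group = rep(c("WHO_I", "WHO_II", "GBM"), times = c(10, 5, 13)),
    m1 = c(rnorm(10), rnorm(5) + 3, rnorm(13) + 6),
    m2 = rnorm(28))
  cmp <- compare_groups(tbl, c("m1", "m2"))
  td <- tidy(cmp)
  expect_equal(nrow(td), 6)
  expect_equal(nrow(glance(cmp)), 2)
  expect_true(all(td$q >= td$p - 1e-12))
  expect_true(all(abs(td$cliffs_delta) <= 1))
  expect_true(all(td$gated[td$metric == "m1"]))
  # q is BH with m = metrics x contrasts, in input order
  expect_equal(td$q, bh_fdr(td$p, m = 6))
})

test_that("bootstrap ordering is seeded, consistent, and converged", {
  g <- rep(c("WHO_I", "WHO_II", "GBM"), times = c(10, 5, 13))
  set.seed(30)
  sep <- c(rnorm(10, 0, 0.1), rnorm(5, 5, 0.1), rnorm(13, 10, 0.1))
  b1 <- bootstrap_ordering(sep, g, n_iter = 2000, seed = 1)
  expect_gte(b1$p_intermediate, 0.99)
  low <- c(rnorm(10, 5, 0.1), rnorm(5, -10, 0.1), rnorm(13, 10, 0.1))
  expect_lte(bootstrap_ordering(low, g, n_iter = 2000, seed = 1)$p_intermediate, 0.01)
  # same seed -> identical; different seeds agree within Monte-Carlo error
  v <- c(rnorm(10), rnorm(5) + 0.5, rnorm(13) + 1)
  r1 <- bootstrap_ordering(v, g, n_iter = 10000, seed = 7)
  r2 <- bootstrap_ordering(v, g, n_iter = 10000, seed = 7)
  expect_identical(r1$p_intermediate, r2$p_intermediate)
  expect_identical(r1$ci_gbm_minus_who2, r2$ci_gbm_minus_who2)
  r3 <- bootstrap_ordering(v, g, n_iter = 10000, seed = 8)
  expect_lt(abs(r1$p_intermediate - r3$p_intermediate), 0.02)
  expect_error(bootstrap_ordering(c(1, 2, 3), c("WHO_I", "WHO_II", "GBM")),
               "at least 2")
})

test_that("Spearman rho equals rank-then-Pearson with near-zero null mean", {
  expect_equal(spearman_test(1:10, (1:10)^3)$rho, 1)
  set.seed(14)
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(spearman_test(x, y)$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  rhos <- replicate(200, spearman_test(rnorm(28), rnorm(28))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("the association suite reports the expected pairs and flags constants", {
  set.seed(16)
  tbl <- tibble::tibble(
    delta_g_prime = rnorm(10), delta_tan_delta = rnorm(10),
    radial_auc = rnorm(10), skel_length_density = runif(10),
    branch_point_density = runif(10), shell_voxel_count = rpois(10, 500),
    tumor_slice_area_mm2 = runif(10, 300, 900))
  out <- association_suite(tbl)
  expect_equal(nrow(out), 8)
  expect_true(all(is.finite(out$rho)))
  tbl$delta_g_prime <- 1
  expect_warning(expect_warning(expect_warning(
    out2 <- association_suite(tbl), "constant"), "constant"), "constant")
  expect_true(any(is.nan(out2$rho)))
})
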