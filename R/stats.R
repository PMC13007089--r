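#' Mann-Whitney U test for one pairwise contrast
#'
#' U is the statistic of the first group: the number of (x > y) pairs
#' plus half the ties. The two-sided p-value is exact when
#' `n1 * n2 <= 400` and there are no ties, otherwise a normal
#' approximation with tie correction is used.
#'
#' @param x,y Numeric vectors (first and second group).
#' @return A list: `U`, `p`, `n1`, `n2`.
#' @export
mann_whitney_pair <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = (n1 * n2 <= 400) && !ties)$p.value)
  list(U = U, p = p, n1 = n1, n2 = n2)
}

#' Cliff's delta effect size
#'
#' delta = (#\{y > x pairs\} - #\{y < x pairs\}) / (n1 n2): the dominance
#' of the second group over the first, identically 1 - 2U/(n1 n2) with U
#' from [mann_whitney_pair()]. The magnitude band follows the
#' conventional cuts: negligible < 0.147, small < 0.33, medium < 0.474,
#' large otherwise.
#'
#' @param x,y Numeric vectors.
#' @return A list: `delta`, `band`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  mw <- mann_whitney_pair(x, y)
  delta <- 1 - 2 * mw$U / (mw$n1 * mw$n2)
  list(delta = delta, band = cliffs_band(delta))
}

#' Cliff's delta from a reported U statistic
#'
#' The dominance identity delta = 1 - 2U/(n1 n2) lets the effect size be
#' recovered from a published Mann-Whitney U statistic (first-group
#' convention) and the two group sizes alone.
#'
#' @param U U statistic of the first group.
#' @param n1,n2 Group sizes.
#' @return A list: `delta`, `band`.
#' @export
cliffs_delta_from_u <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) abort("U must lie in [0, n1*n2]")
  delta <- 1 - 2 * U / (n1 * n2)
  list(delta = delta, band = cliffs_band(delta))
}

cliffs_band <- function(delta) {
  a <- abs(delta)
  if (a < 0.147) "negligible" else if (a < 0.33) "small"
  else if (a < 0.474) "medium" else "large"
}

#' Hodges-Lehmann shift estimator
#'
#' Median of all n1 x n2 pairwise differences (first group minus second
#' group): the magnitude and direction of the location shift.
#'
#' @param x,y Numeric vectors.
#' @return Numeric scalar.
#' @export
hodges_lehmann <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  median(outer(x, y, `-`))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, clipped
#' at 1, returned in input order. `m` may exceed the number of supplied
#' p-values when the list is a subset of a larger family (the pipeline
#' uses the full family of metrics x contrasts).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Total number of hypotheses (default `length(p)`).
#' @return Numeric q-values in input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (m < length(p)) abort("m must be at least length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction and a chi-square p-value on k - 1
#' degrees of freedom. All-identical values give H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return A list: `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("need at least two groups with values")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(droplevels(groups)) - 1L))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Full nonparametric group comparison of per-case metrics
#'
#' For each metric: a Kruskal-Wallis test across the three groups, then
#' all three pairwise Mann-Whitney contrasts with Cliff's delta and
#' Hodges-Lehmann shifts, with Benjamini-Hochberg FDR adjustment applied
#' jointly across all metrics x contrasts (m = number of metrics x 3).
#' Pairwise rows are always computed; `gated` flags whether the overall
#' test reached p < 0.05, and `significant` marks q < 0.05.
#'
#' @param metrics Tibble with a `group` column and one column per metric
#'   (one row per case).
#' @param metric_cols Character vector of metric column names.
#' @return An `instability_comparison` object with `$kruskal` and
#'   `$pairwise` tibbles; see [tidy.instability_comparison()].
#' @export
compare_groups <- function(metrics, metric_cols) {
  g <- group_factor(metrics$group)
  contrasts <- list(c("WHO_I", "WHO_II"), c("WHO_I", "GBM"), c("WHO_II", "GBM"))
  kw <- purrr::map_dfr(metric_cols, function(mc) {
    res <- kruskal_wallis(metrics[[mc]], g)
    tibble::tibble(metric = mc, H = res$H, p_kw = res$p)
  })
  pw <- purrr::map_dfr(metric_cols, function(mc) {
    purrr::map_dfr(contrasts, function(ct) {
      xv <- metrics[[mc]][g == ct[1]]
      yv <- metrics[[mc]][g == ct[2]]
      mw <- mann_whitney_pair(xv, yv)
      cd <- cliffs_delta(xv, yv)
      tibble::tibble(metric = mc, group1 = ct[1], group2 = ct[2],
                     U = mw$U, p = mw$p, cliffs_delta = cd$delta,
                     band = cd$band, hl_shift = hodges_lehmann(xv, yv))
    })
  })
  pw$q <- bh_fdr(pw$p, m = length(metric_cols) * length(contrasts))
  pw <- dplyr::left_join(pw, kw, by = "metric")
  pw$gated <- pw$p_kw < 0.05
  pw$significant <- pw$q < 0.05
  structure(list(kruskal = kw, pairwise = pw), class = "instability_comparison")
}

#' @export
print.instability_comparison <- function(x, ...) {
  cat("<instability_comparison>\n")
  print(x$kruskal)
  print(x$pairwise[, c("metric", "group1", "group2", "U", "p", "q",
                       "cliffs_delta", "hl_shift", "significant")])
  invisible(x)
}

#' Tidy / glance methods for group comparisons
#'
#' `tidy()` returns the pairwise contrast table (one row per metric and
#' contrast); `glance()` returns the per-metric Kruskal-Wallis table.
#'
#' @param x An `instability_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.instability_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.instability_comparison
#' @export
glance.instability_comparison <- function(x, ...) x$kruskal

#' Bootstrap check of the intermediate position of WHO II
#'
#' Case-resampling bootstrap (with replacement, within each group): per
#' iteration the three group medians are recomputed and WHO II is scored
#' as intermediate when its median lies strictly between the WHO I and
#' GBM medians in either consistent direction. Also returns percentile
#' 95% confidence intervals for the (WHO II - WHO I) and (GBM - WHO II)
#' median differences. Fully seeded.
#'
#' @param values Numeric per-case metric values.
#' @param groups Group labels aligned with `values`.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile intervals.
#' @return A `bootstrap_result` list: `p_intermediate`,
#'   `ci_who2_minus_who1`, `ci_gbm_minus_who2`, `n_iter`, `seed`.
#' @export
bootstrap_ordering <- function(values, groups, n_iter = 10000, seed = 1L,
                               conf = 0.95) {
  g <- group_factor(groups)
  vs <- split(values, g)
  if (any(vapply(vs, length, 0L) < 2)) abort("each group needs at least 2 cases")
  meds <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(b) {
      vapply(vs, function(v) median(sample(v, replace = TRUE)), numeric(1))
    }, numeric(3))
  })
  m1 <- meds[1, ]; m2 <- meds[2, ]; m3 <- meds[3, ]
  intermediate <- (m1 < m2 & m2 < m3) | (m1 > m2 & m2 > m3)
  alpha <- (1 - conf) / 2
  structure(list(
    p_intermediate = mean(intermediate),
    ci_who2_minus_who1 = unname(quantile(m2 - m1, c(alpha, 1 - alpha))),
    ci_gbm_minus_who2 = unname(quantile(m3 - m2, c(alpha, 1 - alpha))),
    n_iter = n_iter, seed = seed), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> P(intermediate) = %.3f over %d iterations\n",
              x$p_intermediate, x$n_iter))
  cat(sprintf("  WHO II - WHO I median diff 95%% CI: [%.3g, %.3g]\n",
              x$ci_who2_minus_who1[1], x$ci_who2_minus_who1[2]))
  cat(sprintf("  GBM - WHO II median diff 95%% CI: [%.3g, %.3g]\n",
              x$ci_gbm_minus_who2[1], x$ci_gbm_minus_who2[2]))
  invisible(x)
}

#' Tie-corrected Spearman correlation
#'
#' rho is the Pearson correlation of the ranks (midranks for ties), with
#' a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list: `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Spearman association suite
#'
#' Tie-corrected Spearman correlations (two-sided) between the rim-shell
#' mechanical contrasts and the topology metrics, plus the size-bias
#' checks of radial persistence against tumor size proxies.
#'
#' @param metrics Per-case metrics tibble containing `delta_g_prime`,
#'   `delta_tan_delta`, `radial_auc`, `skel_length_density`,
#'   `branch_point_density`, `shell_voxel_count`, `tumor_slice_area_mm2`.
#' @return A tibble with columns `x`, `y`, `rho`, `p`, `n`.
#' @export
association_suite <- function(metrics) {
  if (nrow(metrics) < 4) abort("need at least 4 cases for associations")
  pairs <- rbind(
    expand.grid(x = c("delta_g_prime", "delta_tan_delta"),
                y = c("radial_auc", "skel_length_density", "branch_point_density"),
                stringsAsFactors = FALSE),
    data.frame(x = "radial_auc", y = c("shell_voxel_count", "tumor_slice_area_mm2")))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    xv <- metrics[[pairs$x[i]]]
    yv <- metrics[[pairs$y[i]]]
    ok <- is.finite(xv) & is.finite(yv)
    if (length(unique(xv[ok])) < 2 || length(unique(yv[ok])) < 2) {
      warn(sprintf("constant column in association %s ~ %s", pairs$x[i], pairs$y[i]))
      return(tibble::tibble(x = pairs$x[i], y = pairs$y[i],
                            rho = NaN, p = NaN, n = sum(ok)))
    }
    sp <- spearman_test(xv[ok], yv[ok])
    tibble::tibble(x = pairs$x[i], y = pairs$y[i],
                   rho = sp$rho, p = sp$p, n = sum(ok))
  })
}
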