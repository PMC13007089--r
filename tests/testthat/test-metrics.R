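mk_field <- function(I) {
  structure(list(I = array(I, c(length(I), 1, 1)),
                 valid_mask = array(is.finite(I), c(length(I), 1, 1))),
            class = "instability_field")
}

test_that("scalar summaries match counting and a sort-based percentile oracle", {
  f <- mk_field(rep(0.03, 10))
  ss <- scalar_summaries(f)
  expect_equal(ss$median_I, 0.03)
  expect_equal(unname(ss$frac_above[1]), 1)
  expect_equal(unname(ss$frac_above[2]), 0)

  f2 <- mk_field(c(-0.1, 0.01, 0.03, 0.06))
  ss2 <- scalar_summaries(f2)
  expect_equal(unname(ss2$frac_above), c(0.5, 0.25))

  set.seed(21)
  for (rep in 1:20) {
    v <- rnorm(sample(10:200, 1))
    ss3 <- scalar_summaries(mk_field(v))
    expect_equal(ss3$median_I, median(sort(v)), tolerance = 1e-12)
    expect_equal(ss3$p95_I, unname(quantile(sort(v), 0.95)), tolerance = 1e-12)
  }
})

test_that("histogram entropy hits its analytic anchors", {
  expect_equal(histogram_entropy(mk_field(rep(0.05, 50))), 0)
  centers <- (seq_len(32) - 0.5) * 0.4 / 32
  expect_equal(histogram_entropy(mk_field(centers)), 5)
  expect_equal(histogram_entropy(mk_field(c(0.05, 0.05, 0.35, 0.35))), 1)
  # negatives fall outside the [0, 0.4] support and are excluded
  expect_equal(histogram_entropy(mk_field(c(-1, rep(0.05, 3)))), 0)
  expect_warning(e <- histogram_entropy(mk_field(rep(-1, 4))), "undefined")
  expect_true(is.nan(e))
})

test_that("radial profiles integrate by trapezoid over bin centers", {
  lbl <- array(rep(1:6, each = 10), c(60, 1, 1))
  rp <- radial_profile(array(0.07, c(60, 1, 1)), lbl)
  expect_equal(rp$profile, rep(0.07, 6))
  expect_equal(rp$radial_auc, 0.7)            # c * (11 - 1)

  lin <- array(rep(seq(0.5, 0, length.out = 6), each = 10), c(60, 1, 1))
  rp2 <- radial_profile(lin, lbl)
  expect_equal(rp2$radial_auc, 0.5 * 10 / 2)  # triangle, a = 0.5

  # bin means equal brute-force per-bin averages
  set.seed(5)
  I <- array(rnorm(60), c(60, 1, 1))
  rp3 <- radial_profile(I, lbl)
  for (k in 1:6) expect_equal(rp3$profile[k], mean(I[lbl == k]), tolerance = 1e-12)

  # empty interior bin is interpolated; trailing empties truncate
  I4 <- array(rnorm(60), c(60, 1, 1))
  I4[lbl == 3] <- NaN
  I4[lbl >= 5] <- NaN
  rp4 <- radial_profile(I4, lbl)
  expect_equal(rp4$profile[3], NA_real_)
  m1 <- mean(I4[lbl == 1]); m2 <- mean(I4[lbl == 2]); m4 <- mean(I4[lbl == 4])
  expect_equal(rp4$radial_auc,
               pracma::trapz(c(1, 3, 5, 7), c(m1, m2, (m2 + m4) / 2, m4)),
               tolerance = 1e-12)
  one <- array(NaN, c(60, 1, 1)); one[lbl == 2] <- 0.1
  expect_warning(r1 <- radial_profile(one, lbl), "fewer than 2")
  expect_true(is.nan(r1$radial_auc))
})

test_that("tail-AUC closed form equals numeric survival integration", {
  expect_equal(tail_auc(mk_field(rep(0.1, 7))), 0.1)
  expect_equal(tail_auc(mk_field(c(0.3, 0.5, 10))), 0.3)
  expect_equal(tail_auc(mk_field(c(0.2, 0.2, -0.1, -0.1))), 0.1)
  set.seed(8)
  for (rep in 1:20) {
    v <- rnorm(100, 0.05, 0.1)
    ts <- seq(0, 0.30, by = 5e-4)
    surv <- vapply(ts, function(t) mean(v > t), numeric(1))
    expect_lt(abs(tail_auc(mk_field(v)) - pracma::trapz(ts, surv)), 1e-4)
  }
})

test_that("slice morphology matches pixel geometry", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_warning(mo <- slice_morphology(matrix(FALSE, 3, 3), c(1, 1)), "empty")
  expect_true(is.nan(mo$ipr))
  m1 <- slice_morphology(one, c(2, 2))
  expect_equal(m1$area_mm2, 4)
  expect_equal(m1$perimeter_mm, 8)
  expect_equal(m1$ipr, 4 / pi, tolerance = 1e-12)     # P^2/(4 pi A) for a square
  expect_equal(slice_morphology(one, c(2, 2), ipr_convention = "classic")$ipr,
               pi / 4, tolerance = 1e-12)

  # rasterized disc: edge-count perimeter carries the 4/pi bias; Crofton is closer
  n <- 45
  idx <- as.matrix(expand.grid(1:n, 1:n))
  disc <- matrix(sqrt(rowSums((idx - 23)^2)) <= 20, n, n)
  me <- slice_morphology(disc, c(1, 1))
  expect_equal(me$ipr, 16 / pi^2, tolerance = 0.08)
  mc <- slice_morphology(disc, c(1, 1), perimeter = "crofton")
  expect_lt(mc$ipr, me$ipr)
  expect_lt(abs(mc$ipr - 1), 0.15)
  # convexity: a convex shape is ~1, scattered pixels are far below 1
  expect_lt(abs(me$convexity - 1), 0.08)
  scat <- matrix(FALSE, 21, 21); scat[cbind(c(1, 20, 3, 18), c(2, 19, 17, 4))] <- TRUE
  expect_lt(slice_morphology(scat, c(1, 1))$convexity, 0.1)
})

test_that("skeletonization preserves thin structures and counts branches", {
  line <- matrix(TRUE, 1, 20)
  sl <- skeleton_metrics(line)
  expect_equal(sl$skel_length_density, 1)
  expect_equal(sl$branch_point_density, 0)

  plus <- matrix(FALSE, 7, 7); plus[4, ] <- TRUE; plus[, 4] <- TRUE
  sp_ <- skeleton_metrics(plus)
  expect_equal(sp_$n_skeleton_px, 13L)      # already one pixel wide
  expect_equal(sp_$n_branch_px, 1L)         # only the center joins >= 3 segments
  expect_equal(sp_$branch_point_density, 1 / 13)

  sq <- skeleton_metrics(matrix(TRUE, 9, 9))
  expect_lt(sq$skel_length_density, 0.2)
  # branch count agrees with an independent crossing-number recount
  set.seed(13)
  blob <- matrix(runif(900) < 0.4, 30, 30)
  sk <- skeleton_metrics(blob)
  s <- sk$skeleton
  recount <- 0
  pad <- matrix(FALSE, 32, 32); pad[2:31, 2:31] <- s
  for (i in 2:31) for (j in 2:31) {
    if (!pad[i, j]) next
    ring <- c(pad[i-1,j], pad[i-1,j+1], pad[i,j+1], pad[i+1,j+1],
              pad[i+1,j], pad[i+1,j-1], pad[i,j-1], pad[i-1,j-1])
    trans <- sum(!ring & c(ring[-1], ring[1]))
    if (trans >= 3) recount <- recount + 1
  }
  expect_equal(sk$n_branch_px, recount)
})

test_that("no skeleton pixel has a fully occupied 2x2 neighborhood", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(runif(625) < 0.45, 25, 25)
    s <- thin_skeleton(m)
    blocks <- s[-1, -1] & s[-25, -1] & s[-1, -25] & s[-25, -25]
    expect_false(any(blocks))
  }
})

test_that("binary opening behaves as expected before re-skeletonization", {
  # a map already open w.r.t. the disc is unchanged
  n <- 25
  idx <- as.matrix(expand.grid(1:n, 1:n))
  disc <- matrix(sqrt(rowSums((idx - 13)^2)) <= 8, n, n)
  os <- opening_sensitivity(disc, c(1, 1), radius_mm = 1.5)
  base <- skeleton_metrics(peristab:::binary_open_2d(disc, 2))
  expect_equal(os$n_open_px, sum(peristab:::binary_open_2d(disc, 2)))
  expect_equal(os$skel_length_density, base$skel_length_density)
  # an isolated pixel is removed entirely
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_warning(ol <- opening_sensitivity(lone, c(1, 1)), "emptied")
  expect_true(is.nan(ol$skel_length_density))
})

test_that("rim-shell contrasts are differences of positivity-filtered medians", {
  rim <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  shell <- array(c(FALSE, FALSE, TRUE, TRUE), c(4, 1, 1))
  gp <- array(c(3, 3, 2, 2), c(4, 1, 1))
  td <- array(c(0.5, 0.5, 0.5, 0.5), c(4, 1, 1))
  rc <- rim_shell_contrast(gp, td, rim, shell)
  expect_equal(rc$delta_g_prime, 1)
  expect_equal(rc$delta_tan_delta, 0)
  set.seed(17)
  for (rep in 1:10) {
    n <- 30
    rimN <- array(rep(c(TRUE, FALSE), each = n / 2), c(n, 1, 1))
    gpN <- array(rlnorm(n, meanlog = 1), c(n, 1, 1))
    tdN <- array(rlnorm(n, sdlog = 0.2), c(n, 1, 1))
    rcN <- rim_shell_contrast(gpN, tdN, rimN, !rimN)
    expect_equal(rcN$delta_g_prime,
                 median(gpN[rimN]) - median(gpN[!rimN]), tolerance = 1e-12)
  }
})

test_that("case metrics sweep recomputes topology per threshold, monotone in tau", {
  cs <- small_case(seed = 12, archetype = "branched", group = "GBM")
  cf <- compute_case(cs)
  cm <- case_metrics(cf)
  expect_equal(nrow(cm), 4)
  expect_true(all(diff(cm$threshold_tau) > 0))
  expect_true(all(cm$frac_above_005 <= cm$frac_above_002))
  # suprathreshold voxel count is non-increasing in tau
  counts <- vapply(cm$threshold_tau,
                   function(t) sum(peristab:::supra_slice(cf, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(cm$tail_auc <= 0.30))
  expect_true(cm$entropy_bits[1] >= 0 && cm$entropy_bits[1] <= 5)
  # a single threshold collapses the across-tau median to itself
  cm1 <- case_metrics(cf, taus = 0.02)
  sw1 <- sweep_medians(cm1)
  expect_equal(sw1$skel_length_density, cm1$skel_length_density)
})
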