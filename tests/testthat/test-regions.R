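test_that("anisotropic EDT reproduces hand geometry", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  d <- anisotropic_edt(m, c(3, 3, 3))
  expect_equal(d[4, 3, 3], 3)
  expect_equal(d[4, 4, 3], 3 * sqrt(2))
  expect_equal(d[3, 3, 3], 0)
  m2 <- array(FALSE, c(3, 3, 3)); m2[2, 2, 2] <- TRUE
  expect_equal(anisotropic_edt(m2, c(1, 1, 5))[2, 2, 3], 5)
  expect_error(anisotropic_edt(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("EDT matches the brute-force oracle on random masks", {
  set.seed(42)
  for (rep in 1:20) {
    sp <- runif(3, 0.5, 4)
    m <- array(runif(512) < 0.12, c(8, 8, 8))
    if (!any(m)) m[sample(512, 1)] <- TRUE
    expect_lt(max(abs(anisotropic_edt(m, sp) - brute_edt(m, sp))), 1e-9)
  }
})

test_that("parenchyma refinement erodes the brain surface, not the tumor cavity", {
  brain <- array(FALSE, c(7, 7, 7)); brain[2:6, 2:6, 2:6] <- TRUE
  tumor <- array(FALSE, c(7, 7, 7)); tumor[4, 4, 4] <- TRUE
  # no erosion: plain set difference
  expect_identical(make_parenchyma_mask(brain, tumor, apply_erosion = FALSE),
                   brain & !tumor)
  # 5^3 cube erodes to its 3^3 core
  core <- make_parenchyma_mask(brain, array(FALSE, c(7, 7, 7)), erode_voxels = 1)
  expect_identical(which(core), which(array(FALSE, c(7,7,7)) | {
    a <- array(FALSE, c(7, 7, 7)); a[3:5, 3:5, 3:5] <- TRUE; a
  }))
  # the rim layer around the tumor survives the erosion
  par <- make_parenchyma_mask(brain, tumor, erode_voxels = 1)
  expect_true(par[3, 4, 4] && par[5, 4, 4])
  expect_false(any(par & tumor))
  expect_error(make_parenchyma_mask(brain, array(FALSE, c(7,7,7)), erode_voxels = 3),
               "empty")
})

test_that("rim is the face-adjacent parenchymal layer", {
  par <- array(TRUE, c(7, 7, 7))
  tumor <- array(FALSE, c(7, 7, 7)); tumor[4, 4, 4] <- TRUE
  rim <- rim_mask(tumor, par & !tumor)
  expect_equal(sum(rim), 6)
  # tumor face flush against the parenchyma boundary: rim only on interior faces
  par2 <- array(FALSE, c(7, 7, 7)); par2[1:4, , ] <- TRUE
  tumor2 <- array(FALSE, c(7, 7, 7)); tumor2[4, 4, 4] <- TRUE
  rim2 <- rim_mask(tumor2, par2 & !tumor2)
  expect_equal(sum(rim2), 5)
  expect_false(rim2[5, 4, 4])
  expect_error(rim_mask(tumor, array(FALSE, c(7, 7, 7))), "rim is empty")

  # every rim voxel is face-adjacent to the tumor, on random blobs
  set.seed(7)
  for (rep in 1:10) {
    tm <- array(runif(1000) < 0.08, c(10, 10, 10))
    if (!any(tm)) next
    pm <- array(TRUE, c(10, 10, 10)) & !tm
    r <- rim_mask(tm, pm)
    idx <- which(r, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      nb <- 0
      for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        p <- idx[k, ] + o
        if (all(p >= 1) && all(p <= 10)) nb <- nb + tm[p[1], p[2], p[3]]
      }
      expect_gte(nb, 1)
    }
  }
})

test_that("shell matches a brute-force band and respects the skull guard", {
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  brain <- array(sqrt(rowSums((idx - 8.5)^2)) <= 7.5, c(16, 16, 16))
  tumor <- array(sqrt(rowSums((idx - 8.5)^2)) <= 2.5, c(16, 16, 16))
  par <- brain & !tumor
  d <- anisotropic_edt(tumor, c(1, 1, 1))
  sg <- shell_mask(d, par, brain, c(1, 1, 1), r_max_mm = 6, guard_mm = 2)
  bf_d <- brute_edt(tumor, c(1, 1, 1))
  bf_g <- brute_edt(!brain, c(1, 1, 1)) <= 2
  expect_identical(sg$shell, bf_d > 0 & bf_d <= 6 & par & !bf_g)
  # dropping the guard can only enlarge the shell
  sg0 <- shell_mask(d, par, brain, c(1, 1, 1), r_max_mm = 6, guard_mm = 0)
  expect_true(all(sg0$shell | !sg$shell))

  # tumor abutting the brain edge: guard strips everything within 2 mm
  tumor2 <- array(sqrt(rowSums(sweep(idx, 2, c(8.5, 8.5, 13))^2)) <= 2.5,
                  c(16, 16, 16))
  par2 <- brain & !tumor2
  d2 <- anisotropic_edt(tumor2, c(1, 1, 1))
  sg2 <- shell_mask(d2, par2, brain, c(1, 1, 1))
  gdist <- brute_edt(!brain, c(1, 1, 1))
  expect_true(all(gdist[sg2$shell] > 2))
})

test_that("radial bins are half-open 2 mm bands restricted to parenchyma", {
  cs <- small_case(seed = 2)
  rg <- region_masks(cs)
  lbl <- rg$radial_label
  d <- rg$dist_tumor_mm
  on <- lbl > 0
  expect_true(all(d[on] > (lbl[on] - 1) * 2 & d[on] <= lbl[on] * 2))
  # bins partition the 0-12 mm guarded parenchymal band
  band <- d > 0 & d <= 12 & rg$parenchyma & !rg$guard
  expect_identical(on, band)
})

test_that("maximal tumor slice follows area with low-index ties", {
  idx <- as.matrix(expand.grid(1:9, 1:9, 1:9))
  ball <- array(sqrt(rowSums((idx - 5)^2)) <= 3.2, c(9, 9, 9))
  expect_equal(max_tumor_slice(ball), 5)
  two <- array(FALSE, c(5, 5, 4)); two[2:3, 2:3, 2] <- TRUE; two[2:3, 2:3, 3] <- TRUE
  expect_equal(max_tumor_slice(two), 2)
  set.seed(11)
  blob <- array(runif(400) < 0.2, c(10, 10, 4))
  blob[1, 1, 1] <- TRUE
  expect_equal(max_tumor_slice(blob),
               which.max(apply(blob, 3, sum)))
})

test_that("region masks satisfy their joint invariants on synthetic cases", {
  for (seed in c(4, 9)) {
    cs <- small_case(seed = seed, archetype = "branched", group = "GBM")
    rg <- region_masks(cs)
    expect_false(any(rg$rim & cs$tumor_mask))
    expect_false(any(rg$shell & cs$tumor_mask))
    expect_true(all(rg$parenchyma[rg$rim]))
    expect_true(all((rg$parenchyma & !rg$guard)[rg$shell]))
    expect_true(all(rg$dist_tumor_mm[rg$shell] > 0 & rg$dist_tumor_mm[rg$shell] <= 6))
    expect_equal(sum(cs$tumor_mask[, , rg$analysis_slice]),
                 max(apply(cs$tumor_mask, 3, sum)))
  }
})

test_that("shell and radial bins are invariant to whole-voxel translation", {
  cs <- small_case(seed = 6)
  rg <- region_masks(cs)
  # translate every input by one voxel along x
  tr <- function(a) { out <- array(FALSE, dim = dim(a)); out[2:dim(a)[1], , ] <- a[1:(dim(a)[1]-1), , ]; out }
  cs2 <- cs
  cs2$tumor_mask <- tr(cs$tumor_mask)
  cs2$brain_mask <- tr(cs$brain_mask)
  rg2 <- region_masks(cs2)
  expect_identical(rg2$shell[2:32, , ], rg$shell[1:31, , ])
  expect_identical(rg2$radial_label[2:32, , ], rg$radial_label[1:31, , ])
})
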