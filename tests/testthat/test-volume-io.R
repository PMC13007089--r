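test_that("NIfTI write/read round-trips values and geometry", {
  dir <- withr::local_tempdir()
  geom <- grid_geometry(c(4, 4, 4), c(3, 3, 3))
  vol <- array(1, dim = c(4, 4, 4))
  path <- file.path(dir, "ones.nii.gz")
  write_volume(vol, geom, path)
  rt <- read_volume(path)
  expect_identical(rt$data, vol)
  expect_equal(rt$geometry$affine, geom$affine, tolerance = 1e-6)
  expect_equal(rt$geometry$spacing, c(3, 3, 3))

  # float32 payloads survive bit-exactly when representable
  v32 <- array(as.numeric(sample(0:255, 64, replace = TRUE)), dim = c(4, 4, 4))
  p32 <- file.path(dir, "f32.nii.gz")
  write_volume(v32, geom, p32, datatype = "float")
  expect_identical(read_volume(p32)$data, v32)
})

test_that("a synthetic 3 mm phantom file reads back with 3 mm spacing", {
  dir <- withr::local_tempdir()
  cs <- small_case(seed = 3)
  path <- file.path(dir, "gp.nii.gz")
  write_volume(cs$g_storage, cs$geometry, path)
  expect_equal(read_volume(path)$geometry$spacing, c(3, 3, 3))
})

test_that("grid validation rejects shape and affine mismatches", {
  a <- grid_geometry(c(8, 8, 8), c(3, 3, 3))
  b <- grid_geometry(c(8, 8, 7), c(3, 3, 3))
  expect_error(check_grid_compatible(a, b), "shapes differ")
  aff <- diag(c(3, 3, 3, 1)); aff[1, 4] <- 0.5
  c_ <- grid_geometry(c(8, 8, 8), c(3, 3, 3), affine = aff)
  expect_error(check_grid_compatible(a, c_), "affines differ")
  expect_true(check_grid_compatible(a, a))
  # spacing must be recoverable from the affine
  expect_error(grid_geometry(c(8, 8, 8), c(3, 3, 2.9), affine = diag(c(3, 3, 3, 1))),
               "disagree")
  expect_error(read_volume(file.path(tempdir(), "no_such_file.nii")), "exist")
})

test_that("resampling is exact on identical grids and preserves constants", {
  g <- grid_geometry(c(8, 8, 8), c(2, 2, 2))
  v <- array(rnorm(512), dim = c(8, 8, 8))
  expect_equal(resample_to_reference(v, g, g, order = "nearest"), v)

  up <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  const <- array(7, dim = c(8, 8, 8))
  out <- resample_to_reference(const, g, up, order = "linear")
  expect_true(all(out[2:15, 2:15, 2:15] == 7))
  # linear interpolation never exceeds the input range
  r <- resample_to_reference(v, g, up, order = "linear")
  expect_lte(max(r), max(v))
  expect_gte(min(r), min(pmin(v, 0)))
})

test_that("mask resampling stays binary and survives down-up round trip", {
  g <- grid_geometry(c(16, 16, 16), c(1, 1, 1))
  ctr <- 8.5
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  ball <- array(sqrt(rowSums((idx - ctr)^2)) <= 5, dim = c(16, 16, 16))
  half <- grid_geometry(c(8, 8, 8), c(2, 2, 2), affine = {
    a <- diag(c(2, 2, 2, 1)); a[1:3, 4] <- 0.5; a
  })
  down <- resample_to_reference(ball, g, half, order = "nearest", binary = TRUE)
  expect_type(down, "logical")
  back <- resample_to_reference(down, half, g, order = "nearest", binary = TRUE)
  expect_gte(dice(ball, back), 0.8)
  expect_error(resample_to_reference(ball, g, half, order = "linear", binary = TRUE),
               "not allowed")
})

test_that("cohort manifests round-trip and are validated", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(c(1, 1, 1), base_seed = 5, out_dir = dir,
                         grid = small_grid())
  expect_equal(nrow(man), 3)
  expect_equal(length(list.files(dir, pattern = "\\.nii\\.gz$")), 12)
  rt <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(rt$case_id, man$case_id)
  expect_true(all(file.exists(rt$g_storage)))

  cs <- read_case(rt[1, ])
  expect_s3_class(cs, "elastogram_case")
  expect_equal(cs$group, "WHO_I")

  bad <- rt; bad$group[2] <- "WHO_III"
  tmp <- file.path(dir, "bad.csv")
  readr::write_csv(bad, tmp)
  expect_error(read_manifest(tmp), "unknown diagnostic group")
  dup <- rt; dup$case_id[2] <- dup$case_id[1]
  readr::write_csv(dup, tmp)
  expect_error(read_manifest(tmp), "unique")
})

test_that("cases written to disk reload identically", {
  dir <- withr::local_tempdir()
  generate_cohort(c(1, 1, 1), base_seed = 11, out_dir = dir, grid = small_grid())
  syn <- synth_cohort(c(1, 1, 1), base_seed = 11, grid = small_grid())
  rt <- read_manifest(file.path(dir, "manifest.csv"))
  cs <- read_case(rt[1, ])
  expect_equal(cs$g_loss, syn$cases[[1]]$g_loss, tolerance = 1e-12)
  expect_identical(cs$tumor_mask, syn$cases[[1]]$tumor_mask)
})
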