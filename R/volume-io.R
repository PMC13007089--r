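#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file and returns the data in the file's native voxel
#' order together with its grid geometry; no reorientation is applied.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param binary If `TRUE`, the volume is thresholded at `> 0.5` and
#'   returned as a logical array (tolerates fractional masks produced by
#'   upstream resampling).
#' @return A list with `data` (3D array) and `geometry` (`grid_geometry`).
#' @export
read_volume <- function(path, binary = FALSE) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "could not read %s as NIfTI: %s", path, conditionMessage(e))))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing))) {
    abort(sprintf("NaN/invalid voxel spacing on axis %d in %s",
                  which(!is.finite(spacing))[1], path))
  }
  affine <- structure(RNifti::xform(img), code = NULL)
  data <- array(as.numeric(img), dim = dim(img)[1:3])
  geom <- grid_geometry(dim(data), spacing, affine = unclass(affine)[1:4, 1:4])
  if (binary) data <- data > 0.5
  list(data = data, geometry = geom)
}

#' Write a NIfTI volume
#'
#' @param data 3D numeric or logical array.
#' @param geometry `grid_geometry` giving spacing and affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk type: `"double"` (default, lossless for R
#'   numerics), `"float"`, or `"uint8"` (for binary masks).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, geometry, path,
                         datatype = c("double", "float", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  aff <- geometry$affine
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, geometry$shape, 1L, 1L, 1L, 1L),
    pixdim = c(1, geometry$spacing, 0, 0, 0, 0),
    sform_code = 2L, qform_code = 0L,
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ]))
  img <- RNifti::asNifti(data, reference = hdr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Regrid a volume onto a reference geometry
#'
#' Regrids an already-aligned volume from its source lattice onto a
#' reference lattice by sampling in world (mm) space through both affines.
#' This performs no registration; the two affines must describe overlapping
#' fields of view.
#'
#' @param data 3D array on the `source` grid.
#' @param source,reference `grid_geometry` objects.
#' @param order `"nearest"` or `"linear"` interpolation.
#' @param binary Set for masks; forbids linear interpolation and returns a
#'   logical array.
#' @return 3D array on the `reference` grid; voxels falling outside the
#'   source field of view are 0.
#' @export
resample_to_reference <- function(data, source, reference,
                                  order = c("nearest", "linear"),
                                  binary = FALSE) {
  order <- match.arg(order)
  if (binary && order == "linear") {
    abort("linear interpolation is not allowed for binary masks; use order = \"nearest\"")
  }
  sh <- reference$shape
  idx <- cbind(
    rep(seq_len(sh[1]), times = sh[2] * sh[3]),
    rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]),
    rep(seq_len(sh[3]), each = sh[1] * sh[2]))
  world <- voxel_to_world(idx, reference)
  src <- world_to_voxel(world, source)

  inside <- src[, 1] >= 0.5 & src[, 1] <= source$shape[1] + 0.5 &
    src[, 2] >= 0.5 & src[, 2] <= source$shape[2] + 0.5 &
    src[, 3] >= 0.5 & src[, 3] <= source$shape[3] + 0.5
  if (!any(inside)) {
    abort("source and reference fields of view do not overlap")
  }

  out <- numeric(prod(sh))
  if (order == "nearest") {
    s <- pmin(pmax(round(src), 1),
              matrix(source$shape, nrow(src), 3, byrow = TRUE))
    lin <- s[, 1] + source$shape[1] * (s[, 2] - 1 + source$shape[2] * (s[, 3] - 1))
    out[inside] <- data[lin[inside]]
  } else {
    s <- src[inside, , drop = FALSE]
    f0 <- pmin(pmax(floor(s), 1), matrix(source$shape - 1, nrow(s), 3, byrow = TRUE))
    w <- pmin(pmax(s - f0, 0), 1)
    acc <- numeric(nrow(s))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wgt <- (if (dx) w[, 1] else 1 - w[, 1]) *
        (if (dy) w[, 2] else 1 - w[, 2]) *
        (if (dz) w[, 3] else 1 - w[, 3])
      lin <- (f0[, 1] + dx) +
        source$shape[1] * ((f0[, 2] + dy) - 1 + source$shape[2] * ((f0[, 3] + dz) - 1))
      acc <- acc + wgt * data[lin]
    }
    out[inside] <- acc
  }
  out <- array(out, dim = sh)
  if (binary) out > 0.5 else out
}

#' One subject's elastogram case
#'
#' Bundles the storage/loss modulus volumes with the tumor and brain masks
#' on a shared grid. All four volumes must live on one lattice (identical
#' shapes; affines equal within 1e-4), and at least half of the tumor must
#' lie inside the brain mask (tumors may abut the mask edge, so full
#' containment is not required at load).
#'
#' @param case_id Character scalar.
#' @param group One of `"WHO_I"`, `"WHO_II"`, `"GBM"`, or `NA`.
#' @param g_storage,g_loss Numeric 3D arrays (kPa).
#' @param tumor_mask,brain_mask Logical 3D arrays.
#' @param geometry `grid_geometry` shared by all volumes.
#' @return An `elastogram_case` object.
#' @export
elastogram_case <- function(case_id, group, g_storage, g_loss,
                            tumor_mask, brain_mask, geometry) {
  dims <- list(dim(g_storage), dim(g_loss), dim(tumor_mask), dim(brain_mask))
  for (d in dims) {
    if (!identical(as.integer(d), as.integer(geometry$shape))) {
      abort(sprintf("case %s: volume shape %s does not match grid %s",
                    case_id, paste(d, collapse = "x"),
                    paste(geometry$shape, collapse = "x")))
    }
  }
  tumor_mask <- tumor_mask > 0.5
  brain_mask <- brain_mask > 0.5
  n_tumor <- sum(tumor_mask)
  if (n_tumor == 0) abort(sprintf("case %s: tumor mask is empty", case_id))
  overlap <- sum(tumor_mask & brain_mask) / n_tumor
  if (overlap < 0.5) {
    abort(sprintf("case %s: only %.0f%% of the tumor lies inside the brain mask (>= 50%% required)",
                  case_id, 100 * overlap))
  }
  if (!is.na(group)) group <- as.character(group_factor(group))
  structure(list(case_id = as.character(case_id), group = group,
                 g_storage = g_storage, g_loss = g_loss,
                 tumor_mask = tumor_mask, brain_mask = brain_mask,
                 geometry = geometry),
            class = "elastogram_case")
}

#' @export
print.elastogram_case <- function(x, ...) {
  cat(sprintf("<elastogram_case> %s [%s], %s voxels, tumor %d vox\n",
              x$case_id, x$group %||% "ungrouped",
              paste(x$geometry$shape, collapse = "x"), sum(x$tumor_mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

manifest_cols <- c("case_id", "group", "g_storage", "g_loss",
                   "tumor_mask", "brain_mask")

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `case_id`, `group`, `g_storage`,
#' `g_loss`, `tumor_mask`, `brain_mask` (the last four are NIfTI paths,
#' resolved relative to the manifest's directory when not absolute).
#'
#' @param path Manifest CSV path.
#' @return A tibble, one row per case, with paths made absolute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(manifest_cols, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(m$case_id)) abort("manifest case_ids are not unique")
  m$group <- as.character(group_factor(m$group))
  root <- dirname(normalizePath(path))
  for (col in manifest_cols[3:6]) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(root, m[[col]][rel])
  }
  tibble::as_tibble(m)
}

#' Write a cohort manifest
#'
#' @param manifest Tibble with the manifest columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest[, intersect(c(manifest_cols, "seed"), names(manifest))], path)
  invisible(path)
}

#' Load one case from manifest paths
#'
#' @param record One manifest row (list or one-row data frame).
#' @return An `elastogram_case`.
#' @export
read_case <- function(record) {
  gp <- read_volume(record$g_storage)
  gl <- read_volume(record$g_loss)
  tm <- read_volume(record$tumor_mask, binary = TRUE)
  bm <- read_volume(record$brain_mask, binary = TRUE)
  for (other in list(gl$geometry, tm$geometry, bm$geometry)) {
    check_grid_compatible(gp$geometry, other)
  }
  elastogram_case(record$case_id, record$group, gp$data, gl$data,
                  tm$data, bm$data, gp$geometry)
}
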