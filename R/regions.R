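#' Anisotropy-aware Euclidean distance transform
#'
#' For every background voxel, the minimum Euclidean distance in mm to any
#' foreground voxel center, honouring per-axis voxel spacing; foreground
#' voxels hold 0. Exact (Felzenszwalb-Huttenlocher separable lower
#' envelope), not a chamfer approximation.
#'
#' @param mask Logical 3D array (foreground = `TRUE`); must be nonempty.
#' @param spacing Positive mm triple.
#' @return Numeric 3D array of distances in mm.
#' @export
anisotropic_edt <- function(mask, spacing) {
  if (!any(mask)) abort("distance transform of an empty mask is undefined")
  d <- .edt_cpp(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
  array(d, dim = dim(mask))
}

# shift a 3D logical array by (dx,dy,dz) voxels, padding with `fill`
shift3d <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

neighbor_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[rowSums(abs(offs)) > 0, ]
    unname(split(as.matrix(offs), seq_len(nrow(offs))))
  } else {
    abort("connectivity must be 6 or 26")
  }
}

#' Binary dilation / erosion of a 3D mask
#'
#' Structuring element is the face (6-) or full (26-) neighborhood,
#' applied `iterations` times. Voxels beyond the array border count as
#' background.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 or 26.
#' @param iterations Number of passes.
#' @return Logical 3D array.
#' @export
binary_dilate <- function(mask, connectivity = 6, iterations = 1) {
  offs <- neighbor_offsets(connectivity)
  out <- mask > 0
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- acc | shift3d(out, o[1], o[2], o[3], fill = FALSE)
    out <- acc
  }
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, connectivity = 6, iterations = 1) {
  offs <- neighbor_offsets(connectivity)
  out <- mask > 0
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- acc & shift3d(out, o[1], o[2], o[3], fill = FALSE)
    out <- acc
  }
  out
}

#' Parenchyma mask
#'
#' Brain minus tumor, optionally eroded to avoid partial-volume effects at
#' the cortical surface. In the study design the erosion is applied for
#' meningioma cases and skipped for glioblastoma; see [region_masks()]'s
#' `erosion` policy.
#'
#' @param brain_mask,tumor_mask Logical 3D arrays on one grid.
#' @param erode_voxels Erosion depth in voxels (6-connectivity).
#' @param apply_erosion Whether to apply the erosion at all.
#' @return Logical parenchyma mask.
#' @export
make_parenchyma_mask <- function(brain_mask, tumor_mask, erode_voxels = 1,
                                 apply_erosion = TRUE) {
  brain <- brain_mask > 0
  if (apply_erosion && erode_voxels > 0) {
    # erode the brain surface before removing the tumor: the erosion
    # targets cortical partial-volume voxels, and eroding after the
    # subtraction would also strip the rim layer around the tumor cavity
    brain <- binary_erode(brain, connectivity = 6, iterations = erode_voxels)
  }
  par <- brain & !(tumor_mask > 0)
  if (!any(par)) abort("parenchyma mask is empty after erosion")
  par
}

#' Tumor rim mask
#'
#' The one-voxel-thick parenchymal layer immediately outside the tumor:
#' `dilate(tumor, 1) \ tumor`, intersected with the parenchyma. Face
#' (6-)connectivity by default gives the thinnest physically adjacent
#' layer on anisotropic grids; 26-connectivity is available.
#'
#' @param tumor_mask,parenchyma Logical 3D arrays.
#' @param connectivity 6 (default) or 26.
#' @param case_id Optional label used in error messages.
#' @return Logical rim mask.
#' @export
rim_mask <- function(tumor_mask, parenchyma, connectivity = 6, case_id = NULL) {
  if (!any(tumor_mask)) abort("tumor mask is empty")
  rim <- binary_dilate(tumor_mask, connectivity = connectivity) &
    !(tumor_mask > 0) & (parenchyma > 0)
  if (!any(rim)) {
    abort(sprintf("rim is empty (tumor lies outside the parenchyma)%s",
                  if (is.null(case_id)) "" else paste0(" for case ", case_id)))
  }
  rim
}

#' Peritumoral shell and skull guard
#'
#' The shell is the parenchymal band 0-6 mm outside the tumor boundary,
#' excluding the skull guard: voxels within `guard_mm` of the brain-mask
#' exterior ("skull" is operationalized as the brain-mask complement,
#' since no skull image exists in the data contract).
#'
#' @param dist_tumor_mm Distance-to-tumor volume from [anisotropic_edt()].
#' @param parenchyma,brain_mask Logical 3D arrays.
#' @param spacing mm triple.
#' @param r_max_mm Outer shell radius (mm).
#' @param guard_mm Guard width from the brain exterior (mm).
#' @return List with logical `shell` and `guard` volumes.
#' @export
shell_mask <- function(dist_tumor_mm, parenchyma, brain_mask, spacing,
                       r_max_mm = 6, guard_mm = 2) {
  exterior <- !(brain_mask > 0)
  if (!any(exterior)) abort("brain mask covers the whole grid; no exterior to guard against")
  guard <- anisotropic_edt(exterior, spacing) <= guard_mm
  shell <- dist_tumor_mm > 0 & dist_tumor_mm <= r_max_mm & (parenchyma > 0) & !guard
  if (!any(shell)) abort("peritumoral shell is empty")
  list(shell = shell, guard = guard)
}

#' Concentric radial distance bins
#'
#' Labels parenchymal voxels (outside the guard) by half-open 2-mm
#' distance bins `(2(k-1), 2k]`, k = 1..`n_bins`; 0 elsewhere.
#'
#' @param dist_tumor_mm Distance volume (mm).
#' @param parenchyma Logical parenchyma mask.
#' @param guard Logical guard mask.
#' @param bin_width_mm Bin width (mm).
#' @param n_bins Number of bins.
#' @return Integer 3D array of bin labels.
#' @export
radial_labels <- function(dist_tumor_mm, parenchyma, guard,
                          bin_width_mm = 2, n_bins = 6) {
  k <- ceiling(dist_tumor_mm / bin_width_mm)
  k[dist_tumor_mm <= 0 | k > n_bins | !(parenchyma > 0) | (guard > 0)] <- 0
  array(as.integer(k), dim = dim(dist_tumor_mm))
}

#' Axial slice of maximal tumor area
#'
#' @param tumor_mask Logical 3D array.
#' @return 1-based axial (third-axis) index of the slice with the largest
#'   in-slice tumor voxel count; ties broken by the lowest index.
#' @export
max_tumor_slice <- function(tumor_mask) {
  if (!any(tumor_mask)) abort("tumor mask is empty")
  counts <- apply(tumor_mask, 3, sum)
  which.max(counts)
}

#' Derive all analysis regions for a case
#'
#' Computes the parenchyma, rim, shell, skull guard, distance-to-tumor
#' volume, radial bin labels and the analysis slice for one case.
#'
#' @param case An [elastogram_case()].
#' @param erosion Parenchyma-erosion policy: `"by_group"` erodes by
#'   `erode_voxels` for meningioma cases (WHO_I/WHO_II) only, mirroring
#'   the partial-volume refinement of the study design; `"always"` /
#'   `"never"` override globally.
#' @param erode_voxels Erosion depth in voxels.
#' @param r_max_mm,guard_mm Shell radius and skull-guard width (mm).
#' @param radial_max_mm Outer extent of the radial bins (mm).
#' @param rim_connectivity 6 or 26 for the rim dilation.
#' @return A `region_masks` list: `parenchyma`, `rim`, `shell`, `guard`,
#'   `dist_tumor_mm`, `radial_label`, `analysis_slice`.
#' @export
region_masks <- function(case, erosion = c("by_group", "always", "never"),
                         erode_voxels = 1, r_max_mm = 6, guard_mm = 2,
                         radial_max_mm = 12, rim_connectivity = 6) {
  erosion <- match.arg(erosion)
  apply_erosion <- switch(erosion,
    by_group = !is.na(case$group %||% NA) && case$group %in% c("WHO_I", "WHO_II"),
    always = TRUE,
    never = FALSE)
  spacing <- case$geometry$spacing
  parenchyma <- make_parenchyma_mask(case$brain_mask, case$tumor_mask,
                                     erode_voxels = erode_voxels,
                                     apply_erosion = apply_erosion)
  dist <- anisotropic_edt(case$tumor_mask, spacing)
  rim <- rim_mask(case$tumor_mask, parenchyma, connectivity = rim_connectivity,
                  case_id = case$case_id)
  sg <- shell_mask(dist, parenchyma, case$brain_mask, spacing,
                   r_max_mm = r_max_mm, guard_mm = guard_mm)
  rl <- radial_labels(dist, parenchyma, sg$guard, bin_width_mm = 2,
                      n_bins = as.integer(radial_max_mm / 2))
  structure(list(parenchyma = parenchyma, rim = rim, shell = sg$shell,
                 guard = sg$guard, dist_tumor_mm = dist, radial_label = rl,
                 analysis_slice = max_tumor_slice(case$tumor_mask)),
            class = "region_masks")
}
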