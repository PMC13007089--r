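#' Scalar summaries of the instability field
#'
#' Median and 95th percentile over all valid shell voxels (negative values
#' included), plus the fraction of valid voxels exceeding each threshold.
#'
#' @param field An [instability_map()] result.
#' @param thresholds Numeric vector of instability cutoffs.
#' @return A list: `median_I`, `p95_I`, and `frac_above` (named vector).
#' @export
scalar_summaries <- function(field, thresholds = c(0.02, 0.05)) {
  v <- field$I[field$valid_mask]
  if (length(v) == 0) abort("instability field has no valid voxels")
  fr <- vapply(thresholds, function(t) mean(v > t), numeric(1))
  list(median_I = median(v),
       p95_I = unname(quantile(v, 0.95)),
       frac_above = setNames(fr, paste0("frac_above_", format(thresholds))))
}

#' Histogram entropy of the instability field
#'
#' Shannon entropy (base 2) of the instability histogram over `n_bins`
#' equal bins spanning `range`; voxels outside the range are excluded.
#' With 32 bins the entropy lies in \[0, 5\] bits.
#'
#' @param field An [instability_map()] result, or a numeric vector.
#' @param n_bins Number of histogram bins.
#' @param range Histogram support (instability units).
#' @return Entropy in bits; `NaN` with a warning if no voxel falls in range.
#' @export
histogram_entropy <- function(field, n_bins = 32, range = c(0, 0.4)) {
  v <- if (inherits(field, "instability_field")) field$I[field$valid_mask] else field
  v <- v[is.finite(v) & v >= range[1] & v <= range[2]]
  if (length(v) == 0) {
    warn("no instability values inside the histogram range; entropy undefined")
    return(NaN)
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Radial instability profile and its area under the curve
#'
#' Mean instability per 2-mm concentric distance bin (up to 12 mm by
#' default), and the trapezoidal integral of the bin means over the bin
#' centers (1, 3, ..., 11 mm) — the radial persistence of the mechanical
#' perturbation. Empty interior bins are linearly interpolated from their
#' neighbors; empty leading/trailing bins truncate the integration range.
#'
#' @param I Instability volume (NaN where invalid), typically the 0-12 mm
#'   band field.
#' @param radial_label Integer bin-label volume from [radial_labels()].
#' @param bin_width_mm Bin width (mm).
#' @param min_I Optional lower cutoff: only voxels with `I > min_I` enter
#'   the bin means (used by the threshold sweep); `NULL` uses all valid
#'   voxels.
#' @return A list: `profile` (per-bin means, NA where empty),
#'   `bin_centers_mm`, `radial_auc`.
#' @export
radial_profile <- function(I, radial_label, bin_width_mm = 2, min_I = NULL) {
  n_bins <- max(radial_label)
  if (n_bins < 1) abort("radial label volume has no bins")
  keep <- is.finite(I) & radial_label > 0
  if (!is.null(min_I)) keep <- keep & I > min_I
  vals <- I[keep]
  labs <- radial_label[keep]
  prof <- rep(NA_real_, n_bins)
  if (length(vals) > 0) {
    means <- tapply(vals, factor(labs, levels = seq_len(n_bins)), mean)
    prof <- as.numeric(means)
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_width_mm
  nonempty <- which(!is.na(prof))
  if (length(nonempty) < 2) {
    warn("fewer than 2 nonempty radial bins; radial AUC undefined")
    return(list(profile = prof, bin_centers_mm = centers, radial_auc = NaN))
  }
  lo <- min(nonempty); hi <- max(nonempty)
  seg <- prof[lo:hi]
  if (anyNA(seg)) { # interpolate empty interior bins
    seg <- approx(x = centers[lo:hi][!is.na(seg)], y = seg[!is.na(seg)],
                  xout = centers[lo:hi])$y
  }
  auc <- pracma::trapz(centers[lo:hi], seg)
  list(profile = prof, bin_centers_mm = centers, radial_auc = auc)
}

#' Tail area under the survival function
#'
#' \eqn{\int_0^{t_{max}} P(I > t)\,dt}, the integrated survival function
#' of the instability distribution, computed in closed form as the mean of
#' `min(max(I, 0), t_max)` over valid voxels.
#'
#' @param field An [instability_map()] result.
#' @param t_max Upper integration limit (instability units).
#' @return Numeric scalar in \[0, `t_max`\].
#' @export
tail_auc <- function(field, t_max = 0.30) {
  v <- field$I[field$valid_mask]
  if (length(v) == 0) abort("instability field has no valid voxels")
  mean(pmin(pmax(v, 0), t_max))
}

# total exposed-edge perimeter (mm) of a 2D binary map
exposed_edge_perimeter <- function(m, spacing_inplane) {
  sx <- spacing_inplane[1]; sy <- spacing_inplane[2]
  # edges perpendicular to axis 1 have length sy, and vice versa
  p <- 0
  p <- p + sum(m & !shift2d(m, 1, 0)) * sy + sum(m & !shift2d(m, -1, 0)) * sy
  p <- p + sum(m & !shift2d(m, 0, 1)) * sx + sum(m & !shift2d(m, 0, -1)) * sx
  p
}

# Crofton 4-direction perimeter estimate (mm), isotropic in-plane spacing
crofton_perimeter <- function(m, spacing_inplane) {
  s <- spacing_inplane[1]
  n_h <- sum(m & !shift2d(m, 0, 1)) + sum(m & !shift2d(m, 0, -1))
  n_v <- sum(m & !shift2d(m, 1, 0)) + sum(m & !shift2d(m, -1, 0))
  n_d1 <- sum(m & !shift2d(m, 1, 1)) + sum(m & !shift2d(m, -1, -1))
  n_d2 <- sum(m & !shift2d(m, 1, -1)) + sum(m & !shift2d(m, -1, 1))
  pi * s * (0.25 * (n_h + n_v) + 0.25 / sqrt(2) * (n_d1 + n_d2)) / 2
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Slice morphology: isoperimetric ratio and convexity
#'
#' On the thresholded instability map of the analysis slice, computes the
#' total suprathreshold area A (mm^2), the boundary perimeter P (mm), the
#' isoperimetric ratio, and convexity = A / area of the convex hull of
#' the suprathreshold pixel centers.
#'
#' The isoperimetric ratio is reported in the complexity convention
#' P^2/(4*pi*A) by default (1 for a perfect disc, larger for irregular
#' boundaries); the classic 4*pi*A/P^2 form is available via
#' `ipr_convention = "classic"`. The perimeter estimator is the exposed
#' pixel-edge count by default (which carries a known discretization
#' constant of 4/pi for a disc); a Crofton estimator is available.
#'
#' @param map Logical matrix (suprathreshold region on the slice).
#' @param spacing_inplane In-plane mm pair.
#' @param ipr_convention `"complexity"` (P^2/(4*pi*A)) or `"classic"`.
#' @param perimeter `"edges"` or `"crofton"`.
#' @return A list: `area_mm2`, `perimeter_mm`, `ipr`, `convexity`.
#' @export
slice_morphology <- function(map, spacing_inplane,
                             ipr_convention = c("complexity", "classic"),
                             perimeter = c("edges", "crofton")) {
  ipr_convention <- match.arg(ipr_convention)
  perimeter <- match.arg(perimeter)
  m <- map > 0
  n <- sum(m)
  if (n == 0) {
    warn("empty suprathreshold map; slice morphology undefined")
    return(list(area_mm2 = NaN, perimeter_mm = NaN, ipr = NaN, convexity = NaN))
  }
  px_area <- prod(spacing_inplane)
  A <- n * px_area
  P <- if (perimeter == "edges") exposed_edge_perimeter(m, spacing_inplane)
       else crofton_perimeter(m, spacing_inplane)
  ipr <- if (ipr_convention == "complexity") P^2 / (4 * pi * A) else 4 * pi * A / P^2
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * spacing_inplane[1], idx[, 2] * spacing_inplane[2])
  hull_area <- if (nrow(pts) >= 3) {
    h <- grDevices::chull(pts)
    shoelace_area(pts[h, , drop = FALSE])
  } else 0
  convexity <- if (hull_area > 0) A / hull_area else NaN
  list(area_mm2 = A, perimeter_mm = P, ipr = ipr, convexity = convexity)
}

#' Skeleton metrics after a light binary opening
#'
#' Applies an in-plane binary opening with a disc structuring element of
#' the given physical radius before skeletonization, to test that
#' filament/branch descriptors are not artifacts of pixel-scale noise.
#'
#' @param map Logical matrix.
#' @param spacing_inplane In-plane mm pair.
#' @param radius_mm Opening radius (mm); the pixel radius is
#'   `round(radius_mm / spacing)`, minimum 1.
#' @return As [skeleton_metrics()], plus `n_open_px`; all-NaN with a
#'   warning if the opening empties the map.
#' @export
opening_sensitivity <- function(map, spacing_inplane, radius_mm = 1.5) {
  r_px <- max(1L, as.integer(round(radius_mm / spacing_inplane[1])))
  opened <- binary_open_2d(map > 0, r_px)
  if (!any(opened)) {
    warn("binary opening emptied the suprathreshold map")
    return(c(skeleton_metrics(opened), list(n_open_px = 0L)))
  }
  c(skeleton_metrics(opened), list(n_open_px = as.integer(sum(opened))))
}

#' Rim-shell contrast in storage modulus and damping
#'
#' Differences of region medians (rim minus shell) for the storage
#' modulus and the damping ratio, with the same positivity exclusions as
#' the rim reference.
#'
#' @param g_storage Numeric 3D array (kPa).
#' @param tan_delta Damping-ratio array.
#' @param rim,shell Logical region masks.
#' @return A list: `delta_g_prime` (kPa), `delta_tan_delta`.
#' @export
rim_shell_contrast <- function(g_storage, tan_delta, rim, shell) {
  med2 <- function(vals) {
    ok <- is.finite(vals) & vals > 0
    if (!any(ok)) abort("region has no valid voxels for the rim-shell contrast")
    median(vals[ok])
  }
  if (!any(rim) || !any(shell)) abort("rim and shell must both be nonempty")
  list(delta_g_prime = med2(g_storage[rim]) - med2(g_storage[shell]),
       delta_tan_delta = med2(tan_delta[rim]) - med2(tan_delta[shell]))
}
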