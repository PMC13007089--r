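#' Per-case occupancy, skeleton and branch maps
#'
#' Binarizes the instability field at `tau` on the analysis slice, crops
#' a square physical patch centered on the tumor's slice centroid
#' (zero-padded where the patch exceeds the image), nearest-neighbor
#' resamples it to a uniform grid, then skeletonizes and marks branch
#' points (pixels where three or more skeleton segments converge) on the
#' resampled mask.
#'
#' @param field An [instability_map()] result (shell-domain field).
#' @param case The [elastogram_case()] the field belongs to.
#' @param regions The case's [region_masks()].
#' @param tau Instability threshold.
#' @param patch_mm Physical patch side (mm).
#' @param grid_n Resampled patch side (pixels).
#' @return A `case_maps` list: `occupancy`, `skeleton`, `branch` (logical
#'   `grid_n` x `grid_n` matrices), `valid` (pixels that sampled inside
#'   the brain), `effective_radius_mm`, `patch_origin_mm`, `normalized`,
#'   `case_id`, `group`.
#' @export
case_maps <- function(field, case, regions, tau = 0.02,
                      patch_mm = 120, grid_n = 256) {
  sp <- case$geometry$spacing
  k <- regions$analysis_slice
  tumor_sl <- case$tumor_mask[, , k]
  if (!any(tumor_sl)) abort("analysis slice contains no tumor")
  idx <- which(tumor_sl, arr.ind = TRUE)
  centroid_mm <- c(mean(idx[, 1] - 1) * sp[1], mean(idx[, 2] - 1) * sp[2])

  I_sl <- field$I[, , k]
  supra <- is.finite(I_sl) & I_sl > tau
  if (!any(supra)) {
    warn(sprintf("case %s: no suprathreshold voxels on the analysis slice",
                 case$case_id))
  }

  px <- patch_mm / grid_n
  u <- centroid_mm[1] - patch_mm / 2 + (seq_len(grid_n) - 0.5) * px
  v <- centroid_mm[2] - patch_mm / 2 + (seq_len(grid_n) - 0.5) * px
  iu <- round(u / sp[1]) + 1
  iv <- round(v / sp[2]) + 1
  ok_u <- iu >= 1 & iu <= dim(I_sl)[1]
  ok_v <- iv >= 1 & iv <= dim(I_sl)[2]

  take <- function(m) {
    out <- matrix(FALSE, grid_n, grid_n)
    out[ok_u, ok_v] <- m[iu[ok_u], iv[ok_v]]
    out
  }
  occ <- take(supra)
  valid <- take(case$brain_mask[, , k])

  sk <- if (any(occ)) thin_skeleton(occ) else occ
  br <- branch_points(sk)

  A_mm2 <- sum(tumor_sl) * sp[1] * sp[2]
  structure(list(occupancy = occ, skeleton = sk, branch = br, valid = valid,
                 effective_radius_mm = sqrt(A_mm2 / pi),
                 patch_origin_mm = c(u[1] - px / 2, v[1] - px / 2),
                 pixel_mm = px, normalized = FALSE,
                 case_id = case$case_id, group = case$group),
            class = "case_maps")
}

#' Rescale case maps to a common effective tumor radius
#'
#' Rescales the occupancy mask about the patch center by `R_star_mm /
#' effective_radius_mm` (nearest neighbor), then recomputes the skeleton
#' and branch maps on the rescaled mask so skeletons remain one pixel
#' wide (rescaling a skeleton would break its width).
#'
#' @param cm A [case_maps()] result.
#' @param R_star_mm Common effective radius (mm).
#' @return A `case_maps` object with `normalized = TRUE`.
#' @export
radius_normalize <- function(cm, R_star_mm = 20) {
  if (!is.finite(cm$effective_radius_mm) || cm$effective_radius_mm <= 0) {
    abort("effective radius must be positive")
  }
  f <- R_star_mm / cm$effective_radius_mm
  if (f < 0.2 || f > 5) {
    warn(sprintf("extreme tumor size: radius scale factor %.2f", f))
  }
  n <- nrow(cm$occupancy)
  ctr <- (n + 1) / 2
  # output pixel (i,j) samples input at center + (ij - center)/f
  src <- round(ctr + (seq_len(n) - ctr) / f)
  ok <- src >= 1 & src <= n
  rescale <- function(m) {
    out <- matrix(FALSE, n, n)
    out[ok, ok] <- m[src[ok], src[ok]]
    out
  }
  occ <- rescale(cm$occupancy)
  sk <- if (any(occ)) thin_skeleton(occ) else occ
  br <- branch_points(sk)
  out <- cm
  out$occupancy <- occ
  out$skeleton <- sk
  out$branch <- br
  out$valid <- rescale(cm$valid)
  out$normalized <- TRUE
  out
}

#' Group-average probability maps
#'
#' Voxelwise means of the per-case occupancy/skeleton/branch maps within
#' one diagnostic group, plus an N-map counting how many cases
#' contributed any valid data at each pixel. Probabilities are exact
#' rationals k/n_g. Display ranges follow the fixed conventions 0-1.0
#' (occupancy), 0-0.8 (skeleton), 0-0.6 (branch).
#'
#' @param case_map_list List of [case_maps()] results, one group.
#' @param group Group label.
#' @return A `group_maps` list: `p_occ`, `p_skel`, `p_br`, `n_map`,
#'   `n_cases`, `group`, `normalized`, `display_ranges`.
#' @export
group_probability_maps <- function(case_map_list, group = NULL) {
  if (length(case_map_list) < 1) abort("need at least one case")
  norm <- vapply(case_map_list, `[[`, logical(1), "normalized")
  if (length(unique(norm)) > 1) {
    abort("cannot average a mix of radius-normalized and physical-space maps")
  }
  n <- length(case_map_list)
  acc <- function(fld) Reduce(`+`, lapply(case_map_list, function(cm) cm[[fld]] + 0))
  structure(list(p_occ = acc("occupancy") / n, p_skel = acc("skeleton") / n,
                 p_br = acc("branch") / n, n_map = acc("valid"),
                 n_cases = n, group = group, normalized = norm[1],
                 display_ranges = list(occupancy = c(0, 1.0),
                                       skeleton = c(0, 0.8),
                                       branch = c(0, 0.6))),
            class = "group_maps")
}

#' Tidy a group-maps object into a long tibble
#'
#' @param x A `group_maps` object.
#' @param ... Unused.
#' @return A tibble with columns `map`, `x`, `y`, `p`.
#' @export
tidy.group_maps <- function(x, ...) {
  one <- function(m, name) {
    tibble::tibble(map = name,
                   x = rep(seq_len(nrow(m)), times = ncol(m)),
                   y = rep(seq_len(ncol(m)), each = nrow(m)),
                   p = as.vector(m))
  }
  dplyr::bind_rows(one(x$p_occ, "occupancy"), one(x$p_skel, "skeleton"),
                   one(x$p_br, "branch"))
}

#' Plot group probability maps
#'
#' Heatmaps of the occupancy, skeleton and branch probabilities with the
#' fixed display ranges, faceted by map type.
#'
#' @param object A `group_maps` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_maps <- function(object, ...) {
  df <- tidy.group_maps(object)
  # normalize each map by its display cap so one fill scale serves all
  caps <- c(occupancy = 1.0, skeleton = 0.8, branch = 0.6)
  df$p_scaled <- pmin(df$p / caps[df$map], 1)
  df$map <- factor(df$map, levels = names(caps))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$p_scaled)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P / cap") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Group probability maps",
                                 if (!is.null(object$group)) paste0(" - ", object$group)),
                  subtitle = if (object$normalized) "radius-normalized" else "physical space")
}
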