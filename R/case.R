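#' Compute fields and regions for one case
#'
#' Runs the geometric and field stages for a single case: region masks,
#' damping ratio, rim reference medians, and the instability field on
#' both the 0-6 mm shell (primary analysis domain) and the 0-12 mm
#' parenchymal band (radial profiling domain).
#'
#' @param case An [elastogram_case()].
#' @param erosion,erode_voxels,r_max_mm,guard_mm,radial_max_mm,rim_connectivity
#'   Passed to [region_masks()].
#' @param log_reference Passed to [instability_map()].
#' @return A `case_fields` list: `case`, `regions`, `tan_delta`,
#'   `reference`, `field_shell`, `field_band`.
#' @export
compute_case <- function(case, erosion = "by_group", erode_voxels = 1,
                         r_max_mm = 6, guard_mm = 2, radial_max_mm = 12,
                         rim_connectivity = 6, log_reference = "g_loss") {
  regions <- region_masks(case, erosion = erosion, erode_voxels = erode_voxels,
                          r_max_mm = r_max_mm, guard_mm = guard_mm,
                          radial_max_mm = radial_max_mm,
                          rim_connectivity = rim_connectivity)
  tan_d <- damping_ratio(case$g_storage, case$g_loss)
  ref <- rim_reference(case$g_loss, tan_d, regions$rim)
  if (log_reference == "g_storage") {
    gp <- case$g_storage[regions$rim]
    ok <- is.finite(gp) & gp > 0
    ref$g_storage_med <- median(gp[ok])
  }
  band <- regions$radial_label > 0
  structure(list(
    case = case, regions = regions, tan_delta = tan_d, reference = ref,
    field_shell = instability_map(case$g_loss, tan_d, ref, regions$shell,
                                  log_reference = log_reference),
    field_band = instability_map(case$g_loss, tan_d, ref, band,
                                 log_reference = log_reference)),
    class = "case_fields")
}

# suprathreshold map of the radial-band field on the analysis slice; the
# 0-12 mm band is the topology/morphology domain (a 0-6 mm ring is ~1 px
# wide at 3 mm voxels and cannot carry skeleton structure)
supra_slice <- function(cf, tau) {
  I_sl <- cf$field_band$I[, , cf$regions$analysis_slice]
  is.finite(I_sl) & I_sl > tau
}

#' Per-case metrics table
#'
#' All scalar descriptors of one case, one row per instability threshold.
#' Threshold-independent quantities (median, 95th percentile, fixed
#' 0.02/0.05 exceedance fractions, entropy, tail-AUC, the unrestricted
#' 0-12 mm radial profile and its AUC, pneg, rim-shell contrasts, size
#' proxies) repeat across rows and are evaluated on the shell domain;
#' the threshold-dependent topology metrics (slice morphology, skeleton
#' length and branch-point densities, and the suprathreshold-conditional
#' radial AUC `radial_auc_tau`) are recomputed at each threshold on the
#' 0-12 mm radial-band domain of the analysis slice.
#'
#' @param cf A [compute_case()] result.
#' @param taus Instability thresholds to evaluate.
#' @param entropy_bins,entropy_range Histogram entropy parameters.
#' @param tail_t_max Upper limit of the survival-function integral.
#' @param ipr_convention,perimeter Passed to [slice_morphology()].
#' @return A tibble, one row per threshold.
#' @export
case_metrics <- function(cf, taus = c(0.015, 0.02, 0.025, 0.03),
                         entropy_bins = 32, entropy_range = c(0, 0.4),
                         tail_t_max = 0.30,
                         ipr_convention = "complexity", perimeter = "edges") {
  case <- cf$case
  regions <- cf$regions
  sp <- case$geometry$spacing
  ss <- scalar_summaries(cf$field_shell, thresholds = c(0.02, 0.05))
  ent <- histogram_entropy(cf$field_shell, n_bins = entropy_bins,
                           range = entropy_range)
  rp <- radial_profile(cf$field_band$I, regions$radial_label)
  ta <- tail_auc(cf$field_shell, t_max = tail_t_max)
  pn <- negative_fraction(cf$field_shell)
  rc <- rim_shell_contrast(case$g_storage, cf$tan_delta, regions$rim,
                           regions$shell)
  tumor_sl <- case$tumor_mask[, , regions$analysis_slice]
  area_mm2 <- sum(tumor_sl) * sp[1] * sp[2]

  prof_cols <- setNames(as.list(rp$profile),
                        paste0("radial_mean_", seq_along(rp$profile)))
  purrr::map_dfr(taus, function(tau) {
    m <- supra_slice(cf, tau)
    morph <- if (any(m)) {
      slice_morphology(m, sp[1:2], ipr_convention = ipr_convention,
                       perimeter = perimeter)
    } else list(area_mm2 = NaN, perimeter_mm = NaN, ipr = NaN, convexity = NaN)
    sk <- skeleton_metrics(m)
    rpt <- suppressWarnings(
      radial_profile(cf$field_band$I, regions$radial_label, min_I = tau))
    dplyr::bind_cols(
      tibble::tibble(
        case_id = case$case_id, group = case$group %||% NA_character_,
        threshold_tau = tau,
        median_I = ss$median_I, p95_I = ss$p95_I,
        frac_above_002 = unname(ss$frac_above[1]),
        frac_above_005 = unname(ss$frac_above[2]),
        entropy_bits = ent,
        radial_auc = rp$radial_auc, radial_auc_tau = rpt$radial_auc,
        tail_auc = ta,
        ipr = morph$ipr, convexity = morph$convexity,
        skel_length_density = sk$skel_length_density,
        branch_point_density = sk$branch_point_density,
        pneg = pn,
        shell_voxel_count = sum(cf$field_shell$valid_mask),
        tumor_slice_area_mm2 = area_mm2,
        delta_g_prime = rc$delta_g_prime,
        delta_tan_delta = rc$delta_tan_delta),
      tibble::as_tibble(prof_cols))
  })
}

#' Across-threshold medians of the sweep metrics
#'
#' Summarizes each case's threshold-dependent topology metrics by their
#' median across the swept thresholds, to avoid single-cutoff dependence.
#'
#' @param metrics A [case_metrics()] (or cohort) tibble.
#' @return A tibble, one row per case.
#' @export
sweep_medians <- function(metrics) {
  metrics |>
    dplyr::group_by(.data$case_id, .data$group) |>
    dplyr::summarise(
      radial_auc_tau = median(.data$radial_auc_tau, na.rm = TRUE),
      skel_length_density = median(.data$skel_length_density, na.rm = TRUE),
      branch_point_density = median(.data$branch_point_density, na.rm = TRUE),
      ipr = median(.data$ipr, na.rm = TRUE),
      convexity = median(.data$convexity, na.rm = TRUE),
      .groups = "drop")
}

#' Skeleton metrics after morphological opening, for one case
#'
#' @param cf A [compute_case()] result.
#' @param tau Instability threshold.
#' @param radius_mm In-plane opening radius (mm).
#' @return A one-row tibble with the opened-map skeleton metrics.
#' @export
case_opening_sensitivity <- function(cf, tau = 0.02, radius_mm = 1.5) {
  m <- supra_slice(cf, tau)
  sp <- cf$case$geometry$spacing
  os <- if (any(m)) opening_sensitivity(m, sp[1:2], radius_mm = radius_mm)
        else list(skel_length_density = NaN, branch_point_density = NaN,
                  n_open_px = 0L)
  tibble::tibble(case_id = cf$case$case_id,
                 group = cf$case$group %||% NA_character_,
                 threshold_tau = tau,
                 skel_length_density_open = os$skel_length_density,
                 branch_point_density_open = os$branch_point_density,
                 n_open_px = os$n_open_px)
}

#' Compute metrics for a whole cohort
#'
#' Maps [compute_case()] and [case_metrics()] over a list of cases and
#' binds the results into one tidy table (one row per case x threshold).
#'
#' @param cases List of [elastogram_case()] objects.
#' @param taus Instability thresholds.
#' @param ... Passed to [compute_case()] and [case_metrics()].
#' @return A tibble.
#' @export
cohort_metrics <- function(cases, taus = c(0.015, 0.02, 0.025, 0.03), ...) {
  dots <- list(...)
  cc_args <- dots[names(dots) %in% names(formals(compute_case))]
  cm_args <- dots[names(dots) %in% setdiff(names(formals(case_metrics)), "taus")]
  purrr::map_dfr(cases, function(cs) {
    cf <- do.call(compute_case, c(list(cs), cc_args))
    do.call(case_metrics, c(list(cf, taus = taus), cm_args))
  })
}
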