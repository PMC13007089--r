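#' Voxelwise damping ratio
#'
#' tan(delta) = G''/G' wherever both moduli are strictly positive; `NaN`
#' elsewhere (zero/negative voxels are excluded downstream, never clamped).
#'
#' @param g_storage,g_loss Numeric 3D arrays (kPa) on one grid.
#' @return Numeric 3D array.
#' @export
damping_ratio <- function(g_storage, g_loss) {
  out <- array(NaN, dim = dim(g_storage))
  ok <- is.finite(g_storage) & is.finite(g_loss) & g_storage > 0 & g_loss > 0
  out[ok] <- g_loss[ok] / g_storage[ok]
  out
}

#' Rim reference medians
#'
#' Median loss modulus and median damping ratio over the rim, after joint
#' exclusion of invalid voxels: a voxel with non-positive G'' or a
#' non-finite/non-positive damping ratio is dropped from both medians.
#'
#' @param g_loss Numeric 3D array (kPa).
#' @param tan_delta Damping-ratio array from [damping_ratio()].
#' @param rim Logical rim mask.
#' @return A `rim_reference` list: `g_loss_med` (kPa), `tan_delta_med`,
#'   `n_valid_rim_voxels`.
#' @export
rim_reference <- function(g_loss, tan_delta, rim) {
  if (!any(rim)) abort("rim mask is empty")
  gl <- g_loss[rim]
  td <- tan_delta[rim]
  ok <- is.finite(gl) & gl > 0 & is.finite(td) & td > 0
  if (!any(ok)) abort("no valid rim voxels after positivity exclusion")
  structure(list(g_loss_med = median(gl[ok]),
                 tan_delta_med = median(td[ok]),
                 n_valid_rim_voxels = sum(ok)),
            class = "rim_reference")
}

#' @export
print.rim_reference <- function(x, ...) {
  cat(sprintf("<rim_reference> G''_med = %.4g kPa, tan(delta)_med = %.4g (n = %d)\n",
              x$g_loss_med, x$tan_delta_med, x$n_valid_rim_voxels))
  invisible(x)
}

#' Voxelwise instability field
#'
#' The rim-referenced instability index
#' \deqn{I(x) = \ln\!\big(G''(x)/G''_{r,med}\big)\,
#'       \big(\tan\delta(x) - (\tan\delta)_{r,med}\big)}
#' evaluated on every valid voxel of the domain mask. The logarithmic term
#' is the viscous contrast against the rim; the second term is the phase
#' deviation; their product is positive only when both deviate
#' concurrently in the same direction. Voxels failing positivity are NaN.
#'
#' @param g_loss Numeric 3D array (kPa).
#' @param tan_delta Damping-ratio array.
#' @param reference A [rim_reference()].
#' @param domain_mask Logical mask on which to evaluate I (the peritumoral
#'   shell for the primary metrics; the 0-12 mm parenchymal band for
#'   radial profiling).
#' @param log_reference Which rim median the log contrast is referenced
#'   to. `"g_loss"` (default) follows the viscous-contrast reading of the
#'   index; `"g_storage"` is a sensitivity variant that divides by the rim
#'   median storage modulus instead and requires `g_storage_med` in
#'   `reference`.
#' @return An `instability_field` list: `I` (NaN outside the valid
#'   domain), `reference`, `valid_mask`.
#' @export
instability_map <- function(g_loss, tan_delta, reference, domain_mask,
                            log_reference = c("g_loss", "g_storage")) {
  log_reference <- match.arg(log_reference)
  denom <- if (log_reference == "g_loss") reference$g_loss_med else reference$g_storage_med
  if (is.null(denom) || !is.finite(denom) || denom <= 0) {
    abort("reference median must be positive")
  }
  if (!is.finite(reference$tan_delta_med)) abort("reference tan(delta) median must be finite")
  valid <- (domain_mask > 0) & is.finite(g_loss) & g_loss > 0 &
    is.finite(tan_delta) & tan_delta > 0
  I <- array(NaN, dim = dim(g_loss))
  I[valid] <- log(g_loss[valid] / denom) *
    (tan_delta[valid] - reference$tan_delta_med)
  structure(list(I = I, reference = reference, valid_mask = valid),
            class = "instability_field")
}

#' Fraction of negative instability voxels
#'
#' The share of valid shell voxels with I < 0, indicating locally
#' elastically dominated (mechanically stable) behavior.
#'
#' @param field An [instability_map()] result.
#' @return Numeric scalar in \[0, 1\].
#' @export
negative_fraction <- function(field) {
  v <- field$I[field$valid_mask]
  if (length(v) == 0) abort("instability field has no valid voxels")
  mean(v < 0)
}
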