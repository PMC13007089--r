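#' Archetype parameters for the phantom generator
#'
#' Each diagnostic group is emulated by one peritumoral archetype:
#' `"compact"` (benign-meningioma-like) carries a smooth, radially
#' decaying rim elevation of dissipation; `"irregular"`
#' (atypical-meningioma-like) restricts that elevation to a random
#' angular sector and adds 1-2 filaments; `"branched"` (GBM-like) paints
#' the elevation along ragged radial tendrils that bifurcate as they
#' advance, over a nearly flat low-level baseline elevation.
#'
#' Elevation applies multiplicatively to the loss modulus and the damping
#' ratio; the storage modulus follows as G'' / tan(delta). Noise is
#' multiplicative lognormal, drawn independently on (G'', tan(delta)) so
#' both moduli carry lognormal noise while the two factors of the
#' instability index stay independent under the null. A small dropout
#' fraction of voxels is zeroed to exercise the positivity exclusion.
#'
#' @param name `"compact"`, `"irregular"` or `"branched"`.
#' @param ... Overrides for any default field: `g_prime_base`,
#'   `g_loss_base` (kPa), `noise_cv`, `rim_amplitude`, `decay_length_mm`,
#'   `n_tendrils`, `branch_prob`, `tendril_width_mm`, `tendril_length_mm`,
#'   `smooth_fwhm_mm`, `sector_deg`, `dropout_frac`, `tumor_g_prime`,
#'   `tumor_g_loss`.
#' @return An `archetype_params` list.
#' @export
archetype_params <- function(name = c("compact", "irregular", "branched"), ...) {
  name <- match.arg(name)
  base <- list(
    g_prime_base = 2.5, g_loss_base = 1.0, dropout_frac = 0.01,
    tendril_width_mm = 2, tendril_length_mm = 14, sector_deg = 360)
  per <- switch(name,
    compact = list(noise_cv = 0.06, rim_amplitude = 2.2, decay_length_mm = 4,
                   n_tendrils = 0, branch_prob = 0, smooth_fwhm_mm = 4,
                   tumor_g_prime = 4.5, tumor_g_loss = 1.2),
    irregular = list(noise_cv = 0.08, rim_amplitude = 1.8, decay_length_mm = 4,
                     n_tendrils = 2, branch_prob = 0.25, smooth_fwhm_mm = 3,
                     sector_deg = 140, tendril_amplitude = 2.2,
                     tumor_g_prime = 3.5, tumor_g_loss = 1.1),
    branched = list(noise_cv = 0.20, rim_amplitude = 1.3, decay_length_mm = 7,
                    n_tendrils = 8, branch_prob = 0.35, smooth_fwhm_mm = 2.5,
                    tendril_width_mm = 2.5, tendril_length_mm = 18,
                    tendril_amplitude = 2.2, tumor_g_prime = 1.6,
                    tumor_g_loss = 1.1))
  p <- utils::modifyList(utils::modifyList(base, per), list(...))
  p$name <- name
  stopifnot(p$rim_amplitude >= 0, p$branch_prob >= 0, p$branch_prob <= 1,
            p$decay_length_mm > 0, p$tendril_width_mm > 0,
            p$tendril_length_mm > 0, p$noise_cv >= 0,
            p$dropout_frac >= 0, p$dropout_frac < 1)
  structure(p, class = "archetype_params")
}

#' Phantom geometry specification
#'
#' @param grid A [grid_geometry()]; default 64x64x32 voxels at 3 mm
#'   isotropic, matching a typical brain MRE acquisition scale.
#' @param brain_semiaxes_mm Ellipsoid semiaxes of the brain (mm).
#' @param tumor_center_vox Tumor center, 1-based voxel indices; default
#'   the grid center.
#' @param tumor_radius_mm Mean tumor radius (mm); must span at least 2
#'   voxels in-plane.
#' @param lobulation Amplitude of the low-order directional perturbation
#'   of the tumor boundary radius.
#' @param seed Integer seed; the phantom is fully deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = grid_geometry(c(64, 64, 32), c(3, 3, 3)),
                         brain_semiaxes_mm = c(80, 80, 42),
                         tumor_center_vox = NULL,
                         tumor_radius_mm = 15, lobulation = 0.12,
                         seed = 1L) {
  if (is.null(tumor_center_vox)) tumor_center_vox <- (grid$shape + 1) / 2
  if (tumor_radius_mm < 2 * max(grid$spacing[1:2])) {
    abort("tumor radius must span at least 2 voxels in-plane")
  }
  structure(list(grid = grid, brain_semiaxes_mm = brain_semiaxes_mm,
                 tumor_center_vox = tumor_center_vox,
                 tumor_radius_mm = tumor_radius_mm,
                 lobulation = lobulation, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing of a 3D array, truncated kernels
# renormalized at the edges so constants are preserved exactly
smooth_gaussian <- function(vol, spacing, fwhm_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    if (s < 1e-3) next
    n <- dim(vol)[ax]
    r <- min(n - 1, max(1, ceiling(3 * s)))
    k <- dnorm(-r:r, sd = s)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1, i - r):pmin(n, i + r)
      w <- k[j - i + r + 1]
      K[i, j] <- w / sum(w)
    }
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = dv[1])
    vol <- aperm(array(v, dim = dv), order(perm))
  }
  vol
}

# point-to-segment distances for a matrix of points (n x 3), in mm
seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) {
    return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  }
  t <- pmin(pmax((sweep(pts, 2, a) %*% ab) / len2, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((pts - proj)^2))
}

# grow the tendril polylines (axial plane at z_mm) as random walks from
# the tumor surface, with per-step bifurcation; returns segment list
grow_tendrils <- function(n_tendrils, branch_prob, length_mm, center_mm,
                          radius_fun, z_mm, max_segments = 80) {
  segs <- list()
  if (n_tendrils < 1) return(segs)
  step_mm <- 3
  for (t in seq_len(n_tendrils)) {
    theta0 <- 2 * pi * (t - 1) / n_tendrils + rnorm(1, sd = pi / (2 * n_tendrils))
    r0 <- radius_fun(theta0)
    stack <- list(list(
      pos = center_mm[1:2] + r0 * c(cos(theta0), sin(theta0)),
      dir = theta0,
      left = length_mm * runif(1, 0.7, 1.3)))
    while (length(stack) > 0 && length(segs) < max_segments) {
      w <- stack[[1]]
      stack <- stack[-1]
      while (w$left > 0 && length(segs) < max_segments) {
        w$dir <- w$dir + rnorm(1, sd = 0.25)
        nxt <- w$pos + step_mm * c(cos(w$dir), sin(w$dir))
        segs[[length(segs) + 1]] <- rbind(c(w$pos, z_mm), c(nxt, z_mm))
        w$pos <- nxt
        w$left <- w$left - step_mm
        if (runif(1) < branch_prob && w$left > 0) {
          # symmetric fork: the parent ends and two arms diverge, so the
          # bifurcation rasterizes as a clean Y-junction
          half <- runif(1, 0.5, 0.9)
          for (side in c(-1, 1)) {
            stack[[length(stack) + 1]] <- list(
              pos = w$pos, dir = w$dir + side * half,
              left = w$left * runif(1, 0.7, 1))
          }
          break
        }
      }
    }
  }
  segs
}

#' Generate one synthetic elastogram case
#'
#' Builds an ellipsoidal brain with a lobulated spherical tumor and
#' archetype-specific peritumoral elevation of dissipation (see
#' [archetype_params()]), deterministic for a fixed `spec$seed`. Moduli
#' are strictly positive inside the brain (except deliberate dropout
#' zeros) and 0 outside; the tumor interior receives distinct moduli.
#'
#' @param spec A [phantom_spec()].
#' @param params An [archetype_params()].
#' @param case_id Case label.
#' @param group Optional diagnostic group label for the case.
#' @return An [elastogram_case()].
#' @export
generate_phantom <- function(spec, params, case_id = "phantom", group = NA) {
  withr::with_seed(spec$seed, {
    g <- spec$grid
    sh <- g$shape
    sp <- g$spacing
    x <- (seq_len(sh[1]) - 1) * sp[1]
    y <- (seq_len(sh[2]) - 1) * sp[2]
    z <- (seq_len(sh[3]) - 1) * sp[3]
    X <- array(rep(x, times = sh[2] * sh[3]), dim = sh)
    Y <- array(rep(rep(y, each = sh[1]), times = sh[3]), dim = sh)
    Z <- array(rep(z, each = sh[1] * sh[2]), dim = sh)

    brain_c <- (sh - 1) / 2 * sp
    a <- spec$brain_semiaxes_mm
    brain <- ((X - brain_c[1]) / a[1])^2 + ((Y - brain_c[2]) / a[2])^2 +
      ((Z - brain_c[3]) / a[3])^2 <= 1

    # lobulated tumor: direction-dependent radius with three random
    # quadrupole-like terms (drawn first for reproducibility)
    vdirs <- matrix(rnorm(9), 3, 3)
    vdirs <- vdirs / sqrt(rowSums(vdirs^2))
    coefs <- rnorm(3)
    tc <- (spec$tumor_center_vox - 1) * sp
    dx <- X - tc[1]; dy <- Y - tc[2]; dz <- Z - tc[3]
    rr <- sqrt(dx^2 + dy^2 + dz^2)
    rr_safe <- pmax(rr, 1e-9)
    ux <- dx / rr_safe; uy <- dy / rr_safe; uz <- dz / rr_safe
    pert <- 0
    for (m in 1:3) {
      dot <- ux * vdirs[m, 1] + uy * vdirs[m, 2] + uz * vdirs[m, 3]
      pert <- pert + coefs[m] * (dot^2 - 1 / 3)
    }
    radius <- spec$tumor_radius_mm * (1 + spec$lobulation * pert)
    tumor <- rr <= radius
    if (!any(tumor)) abort("tumor has zero volume on this grid")
    if (any(tumor & !brain)) abort("tumor breaches the brain boundary")

    # radial elevation component (isotropic exponential decay outside tumor)
    d_out <- anisotropic_edt(tumor, sp)
    elev <- params$rim_amplitude * exp(-d_out / params$decay_length_mm)

    # optional angular sector restriction (irregular archetype)
    if (params$sector_deg < 360) {
      sector_c <- runif(1, 0, 2 * pi)
      half <- params$sector_deg / 2 * pi / 180
      ang <- atan2(dy, dx)
      diff <- abs(((ang - sector_c + pi) %% (2 * pi)) - pi)
      taper <- 20 * pi / 180
      wgt <- pmin(1, pmax(0, (half + taper - diff) / taper))
      elev <- elev * wgt
    }

    # tendril component, painted along bifurcating planar random walks
    if (params$n_tendrils > 0) {
      slice_k <- max_tumor_slice(tumor)
      z_mm <- (slice_k - 1) * sp[3]
      rad_fun <- function(theta) {
        u <- c(cos(theta), sin(theta), 0)
        p <- 0
        for (m in 1:3) p <- p + coefs[m] * (sum(u * vdirs[m, ])^2 - 1 / 3)
        spec$tumor_radius_mm * (1 + spec$lobulation * p)
      }
      segs <- grow_tendrils(params$n_tendrils, params$branch_prob,
                            params$tendril_length_mm, tc, rad_fun, z_mm)
      if (length(segs) > 0) {
        near <- which(abs(Z - z_mm) <= 3 * params$tendril_width_mm &
                        d_out > 0 &
                        d_out <= params$tendril_length_mm * 1.5 + 6)
        if (length(near) > 0) {
          pts <- cbind(X[near], Y[near], Z[near])
          dmin <- rep(Inf, length(near))
          for (s in segs) dmin <- pmin(dmin, seg_dist(pts, s[1, ], s[2, ]))
          t_amp <- if (is.null(params$tendril_amplitude)) {
            # filaments must exceed the rim reference level to register
            # as positive instability over a decaying radial baseline
            2.2 * params$rim_amplitude
          } else params$tendril_amplitude
          tadd <- numeric(prod(sh))
          tadd[near] <- t_amp * exp(-(dmin / params$tendril_width_mm)^2)
          elev <- elev + array(tadd, dim = sh)
        }
      }
    }

    elev <- smooth_gaussian(elev, sp, params$smooth_fwhm_mm)

    # multiplicative lognormal noise, independent on (G'', tan delta)
    sigma <- sqrt(log(1 + params$noise_cv^2))
    noise_field <- function() {
      zf <- array(rnorm(prod(sh)), dim = sh)
      zf <- smooth_gaussian(zf, sp, params$smooth_fwhm_mm)
      sdz <- stats::sd(zf)
      if (sdz > 0) zf <- zf / sdz
      exp(sigma * zf)
    }
    n_loss <- noise_field()
    n_tan <- noise_field()

    tan_base <- params$g_loss_base / params$g_prime_base
    g_loss <- params$g_loss_base * (1 + elev) * n_loss
    tan_d <- tan_base * (1 + elev) * n_tan
    g_loss[tumor] <- params$tumor_g_loss * n_loss[tumor]
    tan_d[tumor] <- (params$tumor_g_loss / params$tumor_g_prime) * n_tan[tumor]
    g_storage <- g_loss / tan_d

    # dropout: zero a small fraction of brain voxels in one modulus to
    # exercise the downstream positivity exclusion
    if (params$dropout_frac > 0) {
      bidx <- which(brain)
      n_drop <- round(params$dropout_frac * length(bidx))
      if (n_drop > 0) {
        drop <- sample(bidx, n_drop)
        which_mod <- runif(n_drop) < 0.5
        g_loss[drop[which_mod]] <- 0
        g_storage[drop[!which_mod]] <- 0
      }
    }

    g_loss[!brain] <- 0
    g_storage[!brain] <- 0

    elastogram_case(case_id, group, g_storage, g_loss, tumor, brain, g)
  })
}

#' Generate a synthetic cohort in memory
#'
#' One case per subject, with per-case seeds `base_seed + case index` and
#' mild per-case variation of tumor radius and center. Group assignment:
#' WHO_I = compact, WHO_II = irregular, GBM = branched.
#'
#' @param n_per_group Integer triple (WHO_I, WHO_II, GBM).
#' @param base_seed Integer base seed.
#' @param params Named list of [archetype_params()] per group; defaults.
#' @param grid Shared [grid_geometry()].
#' @return A list with `cases` (list of [elastogram_case()]) and `manifest`
#'   (tibble of case_id, group, seed).
#' @export
synth_cohort <- function(n_per_group = c(10, 5, 13), base_seed = 42,
                         params = NULL,
                         grid = grid_geometry(c(64, 64, 32), c(3, 3, 3))) {
  if (any(n_per_group < 1)) abort("need at least one case per group")
  if (is.null(params)) {
    params <- list(WHO_I = archetype_params("compact"),
                   WHO_II = archetype_params("irregular"),
                   GBM = archetype_params("branched"))
  }
  groups <- rep(GROUP_LEVELS, times = n_per_group)
  cases <- vector("list", length(groups))
  seeds <- base_seed + seq_along(groups)
  for (i in seq_along(groups)) {
    gname <- groups[i]
    case_id <- sprintf("case_%03d", i)
    # per-case anatomical variation, deterministic from the case seed
    geomvar <- withr::with_seed(seeds[i] + 10000L, {
      list(radius = runif(1, 13, 19),
           center = (grid$shape + 1) / 2 + c(round(runif(2, -2, 2)), 0),
           lob = runif(1, 0.08, 0.16))
    })
    sp <- phantom_spec(grid = grid,
                       tumor_center_vox = geomvar$center,
                       tumor_radius_mm = geomvar$radius,
                       lobulation = geomvar$lob,
                       seed = seeds[i])
    cases[[i]] <- generate_phantom(sp, params[[gname]], case_id = case_id,
                                   group = gname)
  }
  manifest <- tibble::tibble(case_id = vapply(cases, `[[`, "", "case_id"),
                             group = groups, seed = seeds)
  list(cases = cases, manifest = manifest)
}

#' Generate a synthetic cohort on disk
#'
#' Writes the four NIfTI volumes per case, a manifest CSV, and a JSON
#' sidecar per case recording the generator parameters and seed.
#'
#' @inheritParams synth_cohort
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble (with file paths), invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n_per_group = c(10, 5, 13), base_seed = 42,
                            out_dir, params = NULL,
                            grid = grid_geometry(c(64, 64, 32), c(3, 3, 3))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory %s", out_dir))
  syn <- synth_cohort(n_per_group, base_seed, params, grid)
  if (is.null(params)) {
    params <- list(WHO_I = archetype_params("compact"),
                   WHO_II = archetype_params("irregular"),
                   GBM = archetype_params("branched"))
  }
  rows <- purrr::map2(syn$cases, seq_along(syn$cases), function(cs, i) {
    paths <- file.path(out_dir, paste0(cs$case_id, "_",
      c("gstorage", "gloss", "tumor", "brain"), ".nii.gz"))
    write_volume(cs$g_storage, cs$geometry, paths[1])
    write_volume(cs$g_loss, cs$geometry, paths[2])
    write_volume(cs$tumor_mask, cs$geometry, paths[3], datatype = "uint8")
    write_volume(cs$brain_mask, cs$geometry, paths[4], datatype = "uint8")
    side <- params[[cs$group]]
    jsonlite::write_json(
      list(case_id = cs$case_id, group = cs$group,
           seed = syn$manifest$seed[i], params = unclass(side)),
      file.path(out_dir, paste0(cs$case_id, "_params.json")),
      auto_unbox = TRUE, digits = NA)
    tibble::tibble(case_id = cs$case_id, group = cs$group,
                   g_storage = basename(paths[1]), g_loss = basename(paths[2]),
                   tumor_mask = basename(paths[3]), brain_mask = basename(paths[4]),
                   seed = syn$manifest$seed[i])
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
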