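#' Pipeline configuration
#'
#' All tunable constants of the analysis in one place, with the study
#' defaults: shell 0-6 mm with a 2 mm skull guard, radial profiling to
#' 12 mm, primary threshold 0.02 with the sweep \{0.015, 0.02, 0.025,
#' 0.03\}, 120 mm / 256 px group-map patches, common effective radius
#' R* = 20 mm, 32-bin \[0, 0.4\] entropy histogram, tail integral to
#' 0.30, and a 10,000-iteration bootstrap.
#'
#' @param ... Overrides for any field; see Details in the package
#'   vignette. Key fields: `manifest` (path to a cohort manifest; if
#'   `NULL` a synthetic cohort is generated), `synth_n` (cohort sizes),
#'   `out_dir`, `seed`, `thresholds`, `tau_primary`, `r_max_mm`,
#'   `guard_mm`, `radial_max_mm`, `patch_mm`, `grid_n`, `r_star_mm`,
#'   `entropy_bins`, `entropy_range`, `tail_t_max`, `bootstrap_n_iter`,
#'   `ipr_convention`, `perimeter`, `erosion`, `opening_radius_mm`,
#'   `log_reference`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    manifest = NULL,
    synth_n = c(10, 5, 13),
    out_dir = "peristab_out",
    seed = 42L,
    thresholds = c(0.015, 0.02, 0.025, 0.03),
    tau_primary = 0.02,
    r_max_mm = 6, guard_mm = 2, radial_max_mm = 12,
    patch_mm = 120, grid_n = 256, r_star_mm = 20,
    entropy_bins = 32, entropy_range = c(0, 0.4),
    tail_t_max = 0.30,
    bootstrap_n_iter = 10000,
    ipr_convention = "complexity", perimeter = "edges",
    erosion = "by_group", erode_voxels = 1,
    opening_radius_mm = 1.5,
    log_reference = "g_loss")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable fingerprint for the run log; not cryptographic
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %% 1e9
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow: `synth` (generate or load the
#' cohort), `compute` (per-case regions, instability fields, metrics,
#' maps), `compare` (group statistics, probability maps, robustness
#' suite). All randomness flows from `config$seed`; rerunning with the
#' same config reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("synth", "compute", "compare")`.
#' @param write_volumes Also write per-case instability NIfTI volumes.
#' @return A `pipeline_result` list: `metrics`, `sweep`, `comparison`,
#'   `comparison_sweep`, `group_maps`, `group_maps_normalized`,
#'   `bootstrap`, `associations`, `opening`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("synth", "compute", "compare"),
                         write_volumes = FALSE) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("peristab run, config hash %d, seed %d\n",
              config_hash(config), config$seed), file = log_path)

  # --- synth / load -------------------------------------------------------
  if ("synth" %in% stages && is.null(config$manifest)) {
    logf("synth: generating cohort n = (%s), base seed %d",
         paste(config$synth_n, collapse = ", "), config$seed)
    syn <- synth_cohort(config$synth_n, base_seed = config$seed)
    cases <- syn$cases
    manifest <- syn$manifest
  } else {
    if (is.null(config$manifest)) abort("no manifest and synth stage not requested")
    manifest <- read_manifest(config$manifest)
    logf("load: %d cases from %s", nrow(manifest), config$manifest)
    cases <- purrr::map(seq_len(nrow(manifest)),
                        function(i) read_case(manifest[i, ]))
  }
  result <- list(manifest = manifest, config = config)
  if (!("compute" %in% stages)) return(structure(result, class = "pipeline_result"))

  # --- compute ------------------------------------------------------------
  fields <- purrr::map(cases, function(cs) {
    tryCatch(
      compute_case(cs, erosion = config$erosion,
                   erode_voxels = config$erode_voxels,
                   r_max_mm = config$r_max_mm, guard_mm = config$guard_mm,
                   radial_max_mm = config$radial_max_mm,
                   log_reference = config$log_reference),
      error = function(e) abort(sprintf("case %s failed validation: %s",
                                        cs$case_id, conditionMessage(e))))
  })
  metrics <- purrr::map_dfr(fields, case_metrics,
                            taus = config$thresholds,
                            entropy_bins = config$entropy_bins,
                            entropy_range = config$entropy_range,
                            tail_t_max = config$tail_t_max,
                            ipr_convention = config$ipr_convention,
                            perimeter = config$perimeter)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  logf("compute: wrote metrics for %d cases x %d thresholds",
       length(fields), length(config$thresholds))

  cmaps <- purrr::map(fields, function(cf) {
    withCallingHandlers(
      case_maps(cf$field_band, cf$case, cf$regions, tau = config$tau_primary,
                patch_mm = config$patch_mm, grid_n = config$grid_n),
      warning = function(w) {
        logf("warning [%s]: %s", cf$case$case_id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  cmaps_norm <- purrr::map(cmaps, radius_normalize, R_star_mm = config$r_star_mm)

  for (i in seq_along(fields)) {
    cf <- fields[[i]]
    rep_path <- file.path(out_dir, paste0(cf$case$case_id, "_report.json"))
    jsonlite::write_json(list(
      case_id = cf$case$case_id, group = cf$case$group,
      rim_reference = unclass(cf$reference),
      metrics = as.list(metrics[metrics$case_id == cf$case$case_id &
                                  metrics$threshold_tau == config$tau_primary, ]),
      config_hash = config_hash(config)),
      rep_path, auto_unbox = TRUE, digits = NA)
    if (write_volumes) {
      write_volume(cf$field_shell$I, cf$case$geometry,
                   file.path(out_dir, paste0(cf$case$case_id, "_instability.nii.gz")))
    }
  }
  result$metrics <- metrics
  result$sweep <- sweep_medians(metrics)
  result$case_maps <- cmaps
  result$case_maps_normalized <- cmaps_norm
  if (!("compare" %in% stages)) return(structure(result, class = "pipeline_result"))

  # --- compare ------------------------------------------------------------
  primary <- metrics[metrics$threshold_tau == config$tau_primary, ]
  metric_cols <- c("tail_auc", "frac_above_002", "frac_above_005",
                   "entropy_bits", "ipr", "convexity",
                   "branch_point_density", "skel_length_density", "radial_auc")
  comparison <- compare_groups(primary, metric_cols)
  readr::write_csv(tidy(comparison), file.path(out_dir, "pairwise_stats.csv"))
  readr::write_csv(glance(comparison), file.path(out_dir, "kruskal_stats.csv"))

  sweep_cols <- c("radial_auc_tau", "skel_length_density", "branch_point_density")
  comparison_sweep <- compare_groups(result$sweep, sweep_cols)

  groups <- vapply(cmaps, function(cm) cm$group %||% NA_character_, "")
  gmaps <- lapply(split(cmaps, groups), group_probability_maps)
  gmaps_norm <- lapply(split(cmaps_norm, groups), group_probability_maps)
  for (g in names(gmaps)) {
    gmaps[[g]]$group <- g
    gmaps_norm[[g]]$group <- g
    ggplot2::ggsave(file.path(out_dir, paste0("group_maps_", g, ".png")),
                    autoplot(gmaps[[g]]), width = 9, height = 3.4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, paste0("group_maps_", g, "_normalized.png")),
                    autoplot(gmaps_norm[[g]]), width = 9, height = 3.4, dpi = 120)
  }

  boot <- lapply(setNames(sweep_cols, sweep_cols), function(mc) {
    bootstrap_ordering(result$sweep[[mc]], result$sweep$group,
                       n_iter = config$bootstrap_n_iter,
                       seed = config$seed + 1000L)
  })
  jsonlite::write_json(lapply(boot, unclass),
                       file.path(out_dir, "bootstrap.json"),
                       auto_unbox = TRUE, digits = NA)

  assoc <- association_suite(primary)
  readr::write_csv(assoc, file.path(out_dir, "associations.csv"))

  opening <- purrr::map_dfr(fields, case_opening_sensitivity,
                            tau = config$tau_primary,
                            radius_mm = config$opening_radius_mm)
  readr::write_csv(opening, file.path(out_dir, "opening_sensitivity.csv"))

  logf("compare: %d significant pairwise contrasts at q < 0.05",
       sum(tidy(comparison)$significant, na.rm = TRUE))

  result$comparison <- comparison
  result$comparison_sweep <- comparison_sweep
  result$group_maps <- gmaps
  result$group_maps_normalized <- gmaps_norm
  result$bootstrap <- boot
  result$associations <- assoc
  result$opening <- opening
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cases", nrow(x$manifest)))
  if (!is.null(x$metrics)) {
    cat(sprintf(", %d metric rows", nrow(x$metrics)))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf(", %d significant contrasts",
                sum(x$comparison$pairwise$significant, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Plot radial instability profiles by group
#'
#' Mean-of-case radial profiles with per-case traces, from a cohort
#' metrics table.
#'
#' @param metrics A [cohort_metrics()] tibble (any single threshold's rows).
#' @return A ggplot object.
#' @export
plot_radial_profiles <- function(metrics) {
  prof_cols <- grep("^radial_mean_", names(metrics), value = TRUE)
  df <- metrics |>
    dplyr::distinct(.data$case_id, .data$group,
                    dplyr::across(dplyr::all_of(prof_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(prof_cols), names_to = "bin",
                        values_to = "mean_I") |>
    dplyr::mutate(distance_mm = 2 * as.integer(sub("radial_mean_", "", .data$bin)) - 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm, y = .data$mean_I,
                                   color = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$case_id), alpha = 0.35) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "distance from tumor boundary (mm)",
                  y = "mean instability I", color = "group")
}
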