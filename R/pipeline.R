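#' Reproducible pipeline runs
#'
#' Thin, file-oriented wrappers tying the modules into a reproducible
#' pipeline: each writes tidy CSV/JSON artifacts into an output directory
#' together with a `manifest` recording the seed and a hash of the full
#' configuration, so reruns under an identical configuration are
#' byte-identical. The wrappers never compute anything the exported
#' functions do not.
#'
#' @name pipelines
NULL

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate scenario trajectories and compensation curves
#'
#' Simulates all requested inoculum designs under one model parametrization
#' and writes the trajectories plus their normalized biomass difference
#' against the 100WT control.
#'
#' @param params A [model_params] object.
#' @param designs Design tibble (see [scenario_presets()]); must contain a
#'   `100WT` row to serve as reference.
#' @param out_dir Output directory (created if needed).
#' @param t_end Simulation horizon in hours.
#' @param glucose_od Glucose pool at t = 0 (OD-equivalent); default follows
#'   the saturation-minus-inoculum convention of the 100WT culture.
#' @param seed Seed recorded in the manifest (the simulation itself is
#'   deterministic).
#' @return Invisibly, a named list of written file paths.
#' @rdname pipelines
#' @export
pipeline_simulate <- function(params = default_model_params(),
                              designs = scenario_presets(),
                              out_dir = ".", t_end = 10,
                              glucose_od = NULL, seed = 1L) {
  if (!"100WT" %in% designs$mix_label) {
    stop("designs must include the `100WT` reference mix", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_od0 <- designs$initial_od[designs$mix_label == "100WT"][1]
  g0 <- if (is.null(glucose_od)) 0.5 - ref_od0 else glucose_od

  trajs <- lapply(seq_len(nrow(designs)), function(i) {
    d <- designs[i, ]
    init <- initial_state(B_WT0 = d$wt_fraction * d$initial_od,
                          TS0 = d$ts_fraction * d$initial_od, C_g0 = g0)
    traj <- simulate_lysis(params, init, t_end = t_end)
    tibble::tibble(mix = d$mix_label, time_h = traj$time, C_g = traj$C_g,
                   C_l = traj$C_l, B_WT = traj$B_WT,
                   B_TS_total = traj$B_TS_total, od = traj$od)
  })
  traj_tbl <- dplyr::bind_rows(trajs)

  ref <- dplyr::filter(traj_tbl, .data$mix == "100WT")
  delta_tbl <- traj_tbl |>
    dplyr::group_by(.data$mix) |>
    dplyr::group_modify(function(g, key) {
      nd <- normalized_delta_biomass(
        tibble::tibble(time = g$time_h, od = g$od),
        tibble::tibble(time = ref$time_h, od = ref$od)
      )
      tibble::tibble(time_h = nd$time, delta_biomass = nd$delta_biomass)
    }) |>
    dplyr::ungroup()

  paths <- list(
    trajectories = file.path(out_dir, "trajectories.csv"),
    delta_biomass = file.path(out_dir, "normalized_delta_biomass.csv"),
    manifest = file.path(out_dir, "simulate_manifest.json")
  )
  utils::write.csv(traj_tbl, paths$trajectories, row.names = FALSE)
  utils::write.csv(delta_tbl, paths$delta_biomass, row.names = FALSE)
  cfg <- list(params = unclass(params), designs = as.data.frame(designs),
              t_end = t_end, glucose_od = g0)
  write_json(list(seed = seed, config_hash = config_hash(cfg),
                  files = c(paths$trajectories, paths$delta_biomass)),
             paths$manifest)
  invisible(paths)
}

#' Fit the model to growth-curve data and write a report
#'
#' Runs the three-stage parametrization (plus bootstrap when `n_boot > 0`)
#' and writes a JSON fit report and a parameter-table CSV.
#'
#' @param datasets Named list of [growth_dataset]s, or a growth-curve CSV
#'   path (then `design` must be supplied for [read_growth_curves()]).
#' @param design Design tibble when `datasets` is a CSV path.
#' @param cfg A [fit_config].
#' @param n_boot Bootstrap draws; 0 skips the bootstrap (no `ci95` in the
#'   report).
#' @param seed Seed for the bootstrap resampling.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fit (and bootstrap) objects and file
#'   paths.
#' @rdname pipelines
#' @export
pipeline_fit <- function(datasets, design = scenario_presets(),
                         cfg = fit_config(), n_boot = 0, seed = 1L,
                         out_dir = ".") {
  if (is.character(datasets)) {
    datasets <- read_growth_curves(datasets, design)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bs <- NULL
  if (n_boot > 0) {
    bs <- bootstrap_cis(datasets, cfg, n_boot = n_boot, seed = seed)
    fit <- bs$point
  } else {
    fit <- run_three_stage_fit(datasets, cfg)
  }
  cfg_hash <- config_hash(list(cfg = unclass(cfg), n_boot = n_boot,
                               mixes = names(datasets)))
  stage_report <- function(s) {
    rep <- list(estimates = as.list(s$estimates),
                bounds = s$bounds,
                rss = s$rss, aic = s$aic, bic = s$bic,
                n_obs = s$n_obs, n_params = s$n_params)
    if (!is.null(s$ci95)) {
      rep$ci95 <- lapply(rownames(s$ci95), function(p) {
        list(parameter = p, lower = s$ci95[p, 1], upper = s$ci95[p, 2])
      })
    }
    rep
  }
  report <- list(
    seed = seed, config_hash = cfg_hash, n_boot = n_boot,
    stage1 = stage_report(fit$stage1),
    stage2 = stage_report(fit$stage2),
    stage3 = stage_report(fit$stage3)
  )
  paths <- list(report = file.path(out_dir, "fit_report.json"),
                parameters = file.path(out_dir, "fit_parameters.csv"))
  write_json(report, paths$report)
  utils::write.csv(fit$table, paths$parameters, row.names = FALSE)
  invisible(list(fit = fit, bootstrap = bs, paths = paths))
}

#' Run the single-cell pipeline and write records and statistics
#'
#' Filters tracks, estimates growth rates, summarizes conditions and runs
#' the replicate-means two-way ANOVA with Tukey HSD; writes the per-track
#' records CSV and a JSON stats report (summaries, ANOVA table, Tukey
#' pairs, rejection tally, seed, config hash).
#'
#' @param tracks Tibble of track frames, or a track CSV path.
#' @param filter_cfg A [track_filter_config].
#' @param seed Seed recorded in the report (this pipeline stage is
#'   deterministic given the tracks).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the records, summaries, test tables and
#'   file paths.
#' @rdname pipelines
#' @export
pipeline_tracks <- function(tracks, filter_cfg = track_filter_config(),
                            seed = 1L, out_dir = ".") {
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flt <- filter_tracks(tracks, filter_cfg)
  if (flt$tally[["retained"]] == 0) {
    stop("no tracks survived filtering; rejection tally: ",
         paste(sprintf("%s=%d", names(flt$tally), flt$tally),
               collapse = ", "), call. = FALSE)
  }
  summ <- summarize_conditions(flt$records)
  anova_tbl <- replicate_means_anova(summ$replicate_means)
  tukey_tbl <- tukey_hsd(summ$replicate_means)
  cfg_hash <- config_hash(unclass(filter_cfg))

  paths <- list(records = file.path(out_dir, "growth_rate_records.csv"),
                stats = file.path(out_dir, "single_cell_stats.json"))
  utils::write.csv(flt$records, paths$records, row.names = FALSE)
  write_json(list(
    seed = seed, config_hash = cfg_hash,
    rejection_tally = as.list(flt$tally),
    condition_summary = summ$condition_summary,
    replicate_means = summ$replicate_means,
    anova = as.data.frame(anova_tbl),
    tukey = tukey_tbl
  ), paths$stats)
  invisible(list(records = flt$records, tally = flt$tally,
                 summary = summ, anova = anova_tbl, tukey = tukey_tbl,
                 paths = paths))
}
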