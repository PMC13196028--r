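#' Batch-culture noise model
#'
#' Observation model for synthetic replicate growth curves: each replicate
#' reading is the noiseless model OD times a lognormal factor
#' `exp(N(0, od_cv))`, i.e. errors scale multiplicatively with the signal.
#' Defaults emulate the batch experiments: four biological replicates
#' sampled hourly.
#'
#' @param od_cv Multiplicative lognormal sigma per observation (default
#'   0.05; for small values this is the coefficient of variation, with a
#'   relative mean bias of about `od_cv^2 / 2`).
#' @param n_replicates Number of replicate cultures (default 4).
#' @param sampling_interval Sampling interval in hours (default 1).
#' @param t_end End of the sampled time course in hours (default 10).
#' @return An object of class `batch_noise_model`.
#' @export
batch_noise_model <- function(od_cv = 0.05, n_replicates = 4,
                              sampling_interval = 1, t_end = 10) {
  if (od_cv < 0) stop("`od_cv` must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(od_cv = od_cv, n_replicates = as.integer(n_replicates),
                 sampling_interval = sampling_interval, t_end = t_end),
            class = "batch_noise_model")
}

#' Batch-culture scenario presets
#'
#' The six population designs of the batch experiments: mixed WT/TS cultures
#' at a total initial OD600 of 0.01 (100WT, 73WT-27TS, 19WT-81TS, 100TS)
#' plus WT-only controls at reduced inoculum matching the WT fractions of
#' the mixes (73WT at 0.0073, 19WT at 0.0019).
#'
#' @return A tibble with columns `mix_label`, `wt_fraction`, `ts_fraction`,
#'   `initial_od`.
#' @export
scenario_presets <- function() {
  tibble::tibble(
    mix_label = c("100WT", "73WT", "19WT", "73WT-27TS", "19WT-81TS",
                  "100TS"),
    wt_fraction = c(1, 1, 1, 0.73, 0.19, 0),
    ts_fraction = c(0, 0, 0, 0.27, 0.81, 1),
    initial_od = c(0.01, 0.0073, 0.0019, 0.01, 0.01, 0.01)
  )
}

#' Generate one synthetic replicate growth-curve dataset
#'
#' Simulates the consumer-resource model for a given inoculum design,
#' samples the OD observable on the experimental time grid and draws
#' replicate observations under the multiplicative lognormal noise model.
#'
#' @param params A [model_params] object.
#' @param mix_label,wt_fraction,ts_fraction,initial_od Inoculum design (see
#'   [scenario_presets()]).
#' @param noise A [batch_noise_model].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param glucose_od Glucose pool available at t = 0 in OD-equivalent units.
#'   The default follows the convention saturation OD minus initial OD of
#'   the matched WT-only culture, with saturation OD 0.5 for 0.1% glucose.
#' @return A [growth_dataset].
#' @export
generate_batch_dataset <- function(params, mix_label, wt_fraction,
                                   ts_fraction, initial_od,
                                   noise = batch_noise_model(), seed = 1L,
                                   glucose_od = 0.5 - initial_od) {
  stopifnot(inherits(params, "model_params"),
            inherits(noise, "batch_noise_model"))
  times <- seq(0, noise$t_end, by = noise$sampling_interval)
  init <- initial_state(B_WT0 = wt_fraction * initial_od,
                        TS0 = ts_fraction * initial_od,
                        C_g0 = glucose_od)
  grid <- sort(unique(c(seq(0, noise$t_end, length.out = 601), times)))
  traj <- simulate_lysis(params, init, times = grid)
  od <- stats::approx(traj$time, traj$od, xout = times)$y
  reps <- with_seed(seed, {
    matrix(od, nrow = length(times), ncol = noise$n_replicates) *
      exp(matrix(stats::rnorm(length(times) * noise$n_replicates,
                              sd = noise$od_cv),
                 nrow = length(times)))
  })
  growth_dataset(mix_label, wt_fraction, ts_fraction, initial_od,
                 times = times, replicates = reps)
}

#' Generate the full synthetic growth-curve suite
#'
#' One [growth_dataset] per preset design (or a custom design table), with
#' per-mix seeds derived deterministically from `seed`.
#'
#' @param params A [model_params] object.
#' @param noise A [batch_noise_model].
#' @param seed Integer master seed.
#' @param designs Design tibble as returned by [scenario_presets()].
#' @return A named list of [growth_dataset]s.
#' @export
generate_growth_curve_suite <- function(params = default_model_params(),
                                        noise = batch_noise_model(),
                                        seed = 1L,
                                        designs = scenario_presets()) {
  out <- lapply(seq_len(nrow(designs)), function(i) {
    d <- designs[i, ]
    generate_batch_dataset(params, d$mix_label, d$wt_fraction,
                           d$ts_fraction, d$initial_od, noise,
                           seed = seed + i)
  })
  stats::setNames(out, designs$mix_label)
}

#' Specification of a synthetic mother-machine cohort
#'
#' Describes the single-cell observation process the generator emulates:
#' chamber slots imaged every `frame_interval` minutes for `duration_h`
#' hours, cells elongating exponentially from a birth length and dividing
#' (length halving) at a fixed threshold length, multiplicative measurement
#' noise on observed length, and a fraction of slots that drift past the
#' chamber-exit threshold late in the movie. Each division starts a new cell
#' and hence a new track id, and the new cell's true growth rate is drawn
#' afresh from the condition distribution (normal, truncated at 0) —
#' the distribution describes between-cell variability, so rates are not
#' heritable along a lineage slot and the pooled mean over tracks is an
#' unbiased estimate of the condition mean. Default condition means and SDs
#' mirror the reported supernatant experiment (WT-sn 0.54 +/- 0.09,
#' WT-TS-sn 0.61 +/- 0.09, TS-sn 0.62 +/- 0.10 h^-1, four biological
#' replicates), and the default slot count yields on the order of 2,500
#' analyzable cell tracks per condition and replicate, matching the reported
#' cohort sizes (about 10^4 cells per condition).
#'
#' @param conditions Tibble with columns `condition`, `mean_rate`,
#'   `sd_rate` (h^-1).
#' @param n_cells Chamber slots per condition x replicate; each slot yields
#'   roughly `1 + duration_h * mean_rate / log(2)` cell tracks.
#' @param n_replicates Biological replicates per condition.
#' @param frame_interval Minutes between frames (default 5).
#' @param duration_h Movie duration in hours (default 6).
#' @param length_noise_cv Multiplicative lognormal sigma on observed length.
#' @param birth_length,division_length Birth and division lengths (um).
#' @param exit_fraction Fraction of slots whose x-position crosses the exit
#'   threshold in the last third of the movie.
#' @param replicate_sd SD of an additive per-replicate rate offset
#'   (default 0: replicates are exchangeable).
#' @return An object of class `track_cohort_spec`.
#' @export
track_cohort_spec <- function(conditions = tibble::tibble(
                                condition = c("WT-sn", "WT-TS-sn", "TS-sn"),
                                mean_rate = c(0.54, 0.61, 0.62),
                                sd_rate = c(0.09, 0.09, 0.10)
                              ),
                              n_cells = 450, n_replicates = 4,
                              frame_interval = 5, duration_h = 6,
                              length_noise_cv = 0.02,
                              birth_length = 1.5, division_length = 3,
                              exit_fraction = 0.05, replicate_sd = 0) {
  stopifnot(all(c("condition", "mean_rate", "sd_rate") %in%
                  names(conditions)))
  if (any(conditions$mean_rate <= 0) || any(conditions$sd_rate < 0)) {
    stop("condition mean rates must be > 0 and SDs >= 0", call. = FALSE)
  }
  if (division_length <= birth_length) {
    stop("`division_length` must exceed `birth_length`", call. = FALSE)
  }
  if (duration_h <= 0 || frame_interval <= 0) {
    stop("`duration_h` and `frame_interval` must be > 0", call. = FALSE)
  }
  structure(
    list(conditions = tibble::as_tibble(conditions),
         n_cells = as.integer(n_cells),
         n_replicates = as.integer(n_replicates),
         frame_interval = frame_interval, duration_h = duration_h,
         length_noise_cv = length_noise_cv, birth_length = birth_length,
         division_length = division_length, exit_fraction = exit_fraction,
         replicate_sd = replicate_sd),
    class = "track_cohort_spec"
  )
}

# frames for one chamber slot: a sequence of cells, each growing
# exponentially at its own rate and dividing exactly at the threshold
# length; `rates` supplies one rate per successive cell (only the leading
# ones are used within the movie)
slot_frames <- function(rates, t_min, birth_length, division_length) {
  n_seg <- length(rates)
  start_len <- c(birth_length, rep(division_length / 2, n_seg - 1))
  # division times (min): cell j lives log(division/start)/rate hours
  lifespans <- log(division_length / start_len) / rates * 60
  bounds <- c(0, cumsum(lifespans))
  seg <- findInterval(t_min, bounds, rightmost.closed = FALSE)
  seg[seg > n_seg] <- n_seg  # unreachable if enough rates supplied
  len <- start_len[seg] *
    exp(rates[seg] * (t_min - bounds[seg]) / 60)
  list(segment = seg, length = len, rate = rates[seg])
}

#' Generate a synthetic mother-machine track cohort
#'
#' Draws per-cell true growth rates from the condition distributions and
#' emits observed track frames under the [track_cohort_spec] observation
#' process, in the same layout consumed by [filter_tracks()].
#'
#' @param spec A [track_cohort_spec].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A tibble of frames with columns `track_id`, `condition`,
#'   `replicate`, `time_min`, `length_um`, `x_um`.
#' @export
generate_track_cohort <- function(spec = track_cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "track_cohort_spec"))
  t_min <- seq(0, spec$duration_h * 60, by = spec$frame_interval)
  n_f <- length(t_min)
  with_seed(seed, {
    per_cond <- lapply(seq_len(nrow(spec$conditions)), function(ci) {
      cond <- spec$conditions$condition[ci]
      mu <- spec$conditions$mean_rate[ci]
      s <- spec$conditions$sd_rate[ci]
      per_rep <- lapply(seq_len(spec$n_replicates), function(ri) {
        rep_off <- if (spec$replicate_sd > 0) {
          stats::rnorm(1, 0, spec$replicate_sd)
        } else 0
        # enough successive cells per slot to cover the movie even for
        # fast-growing draws
        n_seg <- ceiling(spec$duration_h * (mu + rep_off + 5 * s) /
                           log(2)) + 2L
        cells <- lapply(seq_len(spec$n_cells), function(cell) {
          # truncated-normal true rates, one per successive cell in the slot
          r <- stats::rnorm(n_seg, mu + rep_off, s)
          while (any(r <= 0)) {
            r[r <= 0] <- stats::rnorm(sum(r <= 0), mu + rep_off, s)
          }
          sf <- slot_frames(r, t_min, spec$birth_length,
                            spec$division_length)
          obs_len <- sf$length *
            if (spec$length_noise_cv > 0) {
              exp(stats::rnorm(n_f, sd = spec$length_noise_cv))
            } else 1
          exits <- stats::runif(1) < spec$exit_fraction
          x <- rep(stats::runif(1, 2, 15), n_f)
          if (exits) {
            late <- t_min > t_min[n_f] * 2 / 3
            x[late] <- x[late] + seq_len(sum(late)) * 2 + 10
          }
          tibble::tibble(
            track_id = sprintf("%s_r%d_c%d_s%d", cond, ri, cell,
                               sf$segment),
            condition = cond, replicate = paste0("rep", ri),
            time_min = t_min, length_um = obs_len, x_um = x
          )
        })
        dplyr::bind_rows(cells)
      })
      dplyr::bind_rows(per_rep)
    })
    dplyr::bind_rows(per_cond)
  })
}

#' Write track frames to CSV
#'
#' @param tracks Tibble of track frames (see [generate_track_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}
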