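#' Quality-filter configuration for mother-machine tracks
#'
#' Thresholds of the single-cell pipeline: tracks must be observed in at
#' least `min_frames` frames, stay clear of the chamber exit (cells drifting
#' past `x_max` towards the main channel produce artifactual negative rates),
#' and yield a log-linear fit with `r2 >= r2_min`. Only the final
#' `analysis_window_h` hours of an experiment are analyzed.
#'
#' @param min_frames Minimum number of frames per track (default 7).
#' @param r2_min Minimum squared Pearson correlation of the log-length fit
#'   (default 0.95).
#' @param x_max Chamber-exit threshold on the x-coordinate (um), measured
#'   from the closed end of the chamber. Default 20 um, i.e. 80% of a 25 um
#'   chamber.
#' @param analysis_window_h Final hours of the experiment retained
#'   (default 6).
#' @return An object of class `track_filter_config`.
#' @export
track_filter_config <- function(min_frames = 7, r2_min = 0.95, x_max = 20,
                                analysis_window_h = 6) {
  if (min_frames < 2) stop("`min_frames` must be >= 2", call. = FALSE)
  if (r2_min <= 0 || r2_min > 1) stop("`r2_min` must be in (0, 1]",
                                      call. = FALSE)
  structure(list(min_frames = as.integer(min_frames), r2_min = r2_min,
                 x_max = x_max, analysis_window_h = analysis_window_h),
            class = "track_filter_config")
}

# closed-form OLS of ln(length) on time in hours; r2 as squared Pearson
# correlation (equals R^2 for OLS with intercept). A zero-variance response
# (constant length) is a perfect flat fit: slope 0, r2 1.
ols_log_length <- function(time_min, length_um) {
  if (length(time_min) < 2) {
    stop("need at least 2 frames to estimate a growth rate", call. = FALSE)
  }
  if (any(length_um <= 0)) {
    stop("cell lengths must be positive", call. = FALSE)
  }
  t_h <- time_min / 60
  y <- log(length_um)
  tc <- t_h - mean(t_h)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  syy <- sum(yc^2)
  slope <- sum(tc * yc) / sxx
  r2 <- if (syy == 0) 1 else (sum(tc * yc)^2) / (sxx * syy)
  c(rate = slope, r2 = r2, n_frames = length(t_h))
}

#' Single-cell growth rate from one track
#'
#' Assuming exponential elongation, the growth rate is the slope of an
#' ordinary least-squares regression (with intercept) of log cell length on
#' time. Frame times in minutes are converted to hours so rates come out in
#' h^-1.
#'
#' @param track Data frame with columns `time_min` and `length_um` for one
#'   cell track (at least 2 frames, positive lengths).
#' @return Named numeric vector `c(rate, r2, n_frames)`.
#' @examples
#' tr <- data.frame(time_min = seq(0, 60, 5),
#'                  length_um = 1.5 * exp(0.6 * seq(0, 60, 5) / 60))
#' estimate_track_growth_rate(tr)  # rate 0.6, r2 1
#' @export
estimate_track_growth_rate <- function(track) {
  stopifnot(all(c("time_min", "length_um") %in% names(track)))
  ols_log_length(track$time_min, track$length_um)
}

#' Filter mother-machine tracks and estimate growth rates
#'
#' Applies the pipeline's quality filters in a fixed order — analysis-window
#' crop, minimum frame count, chamber-exit exclusion, log-length fit,
#' minimum r2 — and records exactly one (first-failing) rejection reason per
#' track.
#'
#' @param tracks Tibble/data frame of frames with columns `track_id`,
#'   `condition`, `replicate`, `time_min`, `length_um`, `x_um`.
#' @param cfg A [track_filter_config].
#' @return A list with `records` (one row per track: `track_id`,
#'   `condition`, `replicate`, `rate`, `r2`, `n_frames`, `rejected_reason`
#'   of `none | short_track | chamber_exit | low_r2`) and `tally` (named
#'   rejection counts including `retained`).
#' @export
filter_tracks <- function(tracks, cfg = track_filter_config()) {
  stopifnot(all(c("track_id", "condition", "replicate", "time_min",
                  "length_um", "x_um") %in% names(tracks)))
  tracks <- tibble::as_tibble(tracks)
  if (nrow(tracks) == 0) {
    rec <- tibble::tibble(track_id = character(), condition = character(),
                          replicate = character(), rate = numeric(),
                          r2 = numeric(), n_frames = integer(),
                          rejected_reason = character())
    return(list(records = rec,
                tally = c(retained = 0L, short_track = 0L,
                          chamber_exit = 0L, low_r2 = 0L)))
  }
  t_cut <- max(tracks$time_min) - cfg$analysis_window_h * 60
  cropped <- dplyr::filter(tracks, .data$time_min >= t_cut)

  records <- cropped |>
    dplyr::group_by(.data$track_id, .data$condition, .data$replicate) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      .fit = list({
        n <- dplyr::n()
        if (n < cfg$min_frames) {
          list(rate = NA_real_, r2 = NA_real_, n_frames = n,
               reason = "short_track")
        } else if (any(.data$x_um > cfg$x_max)) {
          list(rate = NA_real_, r2 = NA_real_, n_frames = n,
               reason = "chamber_exit")
        } else {
          f <- ols_log_length(.data$time_min, .data$length_um)
          list(rate = f[["rate"]], r2 = f[["r2"]], n_frames = n,
               reason = if (f[["r2"]] < cfg$r2_min) "low_r2" else "none")
        }
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider(".fit") |>
    dplyr::rename(rejected_reason = "reason") |>
    dplyr::mutate(n_frames = as.integer(.data$n_frames))

  tally <- c(
    retained = sum(records$rejected_reason == "none"),
    short_track = sum(records$rejected_reason == "short_track"),
    chamber_exit = sum(records$rejected_reason == "chamber_exit"),
    low_r2 = sum(records$rejected_reason == "low_r2")
  )
  list(records = records, tally = tally)
}

#' Summarize growth rates per condition and replicate
#'
#' Pools retained single-cell rates per condition (mean, sample SD, count)
#' and tabulates per-(condition, replicate) means — the replicate-means table
#' on which the downstream two-way ANOVA operates. A single observation has
#' SD 0 by convention.
#'
#' @param records Growth-rate records from [filter_tracks()]; rejected rows
#'   are ignored.
#' @return A list with tibbles `condition_summary` (`condition`, `n`,
#'   `mean_rate`, `sd_rate`) and `replicate_means` (`condition`, `replicate`,
#'   `n`, `mean_rate`).
#' @export
summarize_conditions <- function(records) {
  kept <- dplyr::filter(records, .data$rejected_reason == "none")
  if (nrow(kept) == 0) {
    stop("no retained growth-rate records to summarize", call. = FALSE)
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  condition_summary <- kept |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean_rate = mean(.data$rate),
                     sd_rate = sd0(.data$rate), .groups = "drop")
  replicate_means <- kept |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(n = dplyr::n(), mean_rate = mean(.data$rate),
                     .groups = "drop")
  list(condition_summary = condition_summary,
       replicate_means = replicate_means)
}

check_replicate_means <- function(replicate_means) {
  stopifnot(all(c("condition", "replicate", "mean_rate") %in%
                  names(replicate_means)))
  d <- tibble::as_tibble(replicate_means)
  tab <- table(d$condition, d$replicate)
  if (any(tab != 1)) {
    stop("replicate-means table must be complete: exactly one mean per ",
         "condition x replicate cell", call. = FALSE)
  }
  d$condition <- factor(d$condition)
  d$replicate <- factor(d$replicate)
  d
}

#' Two-way ANOVA on replicate means
#'
#' Additive fixed-effects two-factor ANOVA (condition + biological
#' replicate, no interaction) on the table of per-replicate mean growth
#' rates — inference is at the level of biological replicates, not of
#' individual cells.
#'
#' @param replicate_means Tibble with columns `condition`, `replicate`,
#'   `mean_rate`, complete over conditions x replicates (>= 2 levels each).
#' @return A tibble ANOVA table (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`) with the fitted `aov` object attached as
#'   attribute `"aov"`.
#' @export
replicate_means_anova <- function(replicate_means) {
  d <- check_replicate_means(replicate_means)
  if (nlevels(d$condition) < 2 || nlevels(d$replicate) < 2) {
    stop("need >= 2 conditions and >= 2 replicates", call. = FALSE)
  }
  fit <- stats::aov(mean_rate ~ condition + replicate, data = d)
  s <- summary(fit)[[1]]
  out <- tibble::tibble(
    term = trimws(rownames(s)),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    statistic = s$`F value`,
    p.value = s$`Pr(>F)`
  )
  attr(out, "aov") <- fit
  out
}

#' Tukey HSD pairwise comparisons between conditions
#'
#' All-pairs post hoc comparison of condition means using the studentized
#' range distribution, with the residual mean square of the additive two-way
#' ANOVA on replicate means.
#'
#' @inheritParams replicate_means_anova
#' @return A tibble with columns `contrast`, `estimate`, `conf.low`,
#'   `conf.high`, `adj.p.value`.
#' @export
tukey_hsd <- function(replicate_means) {
  d <- check_replicate_means(replicate_means)
  if (nlevels(d$condition) < 2) {
    stop("Tukey HSD needs >= 2 conditions", call. = FALSE)
  }
  fit <- stats::aov(mean_rate ~ condition + replicate, data = d)
  tk <- stats::TukeyHSD(fit, which = "condition")$condition
  tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}

#' Doubling time of an exponentially growing cell
#'
#' @param rate Growth rate in h^-1, `> 0`.
#' @return Doubling time in minutes: `60 * log(2) / rate`.
#' @examples
#' doubling_time(0.54)  # ~77 min
#' doubling_time(0.61)  # ~68 min
#' @export
doubling_time <- function(rate) {
  if (any(rate <= 0)) stop("`rate` must be > 0", call. = FALSE)
  60 * log(2) / rate
}

#' Percent change between two growth rates
#'
#' @param rate_ref Reference rate (h^-1), `> 0`.
#' @param rate_new New rate (h^-1).
#' @return Percent change `100 * (rate_new - rate_ref) / rate_ref`.
#' @examples
#' percent_change(0.54, 0.61)  # ~13%
#' @export
percent_change <- function(rate_ref, rate_new) {
  if (any(rate_ref <= 0)) stop("`rate_ref` must be > 0", call. = FALSE)
  100 * (rate_new - rate_ref) / rate_ref
}

#' Read mother-machine tracks from CSV
#'
#' Expects columns `track_id,condition,replicate,time_min,length_um,x_um`.
#'
#' @param path CSV file path.
#' @return A tibble of track frames.
#' @export
read_tracks <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("track_id", "condition", "replicate", "time_min", "length_um",
            "x_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("track CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
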