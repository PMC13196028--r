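#' Replicate growth-curve dataset for one population mix
#'
#' Container for an OD600 time series of one WT/TS mix measured in several
#' biological replicates, together with the inoculum composition. Per-time
#' replicate means and standard deviations are derived on construction; these
#' are what the weighted least-squares fit consumes.
#'
#' @param mix_label Text label, e.g. `"100WT"` or `"19WT-81TS"`.
#' @param wt_fraction,ts_fraction Fractions of the initial OD contributed by
#'   WT and TS lysogens; must sum to 1.
#' @param initial_od Total initial OD600 of the culture.
#' @param times Observation times (h), strictly increasing.
#' @param replicates Numeric matrix of positive OD600 readings, one row per
#'   time point and one column per replicate.
#'
#' @return An object of class `growth_dataset`.
#' @examples
#' growth_dataset("100WT", 1, 0, 0.01, times = 0:3,
#'                replicates = cbind(c(.01, .02, .04, .08),
#'                                   c(.011, .019, .041, .079)))
#' @export
growth_dataset <- function(mix_label, wt_fraction, ts_fraction, initial_od,
                           times, replicates) {
  if (abs(wt_fraction + ts_fraction - 1) > 1e-8) {
    stop("`wt_fraction` + `ts_fraction` must equal 1", call. = FALSE)
  }
  if (wt_fraction < 0 || ts_fraction < 0 || initial_od <= 0) {
    stop("fractions must be >= 0 and `initial_od` > 0", call. = FALSE)
  }
  replicates <- as.matrix(replicates)
  times <- as.numeric(times)
  if (length(times) != nrow(replicates)) {
    stop("`times` length must match rows of `replicates`", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(replicates)) || any(replicates <= 0)) {
    stop("all replicate OD readings must be positive", call. = FALSE)
  }
  colnames(replicates) <- paste0("rep", seq_len(ncol(replicates)))
  structure(
    list(
      mix_label = as.character(mix_label),
      wt_fraction = wt_fraction,
      ts_fraction = ts_fraction,
      initial_od = initial_od,
      times = times,
      replicates = replicates,
      od_mean = rowMeans(replicates),
      od_sd = apply(replicates, 1, function(r) {
        if (length(r) > 1) stats::sd(r) else 0
      })
    ),
    class = "growth_dataset"
  )
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf(
    "<growth_dataset> %s: %d time points x %d replicates, WT %g / TS %g, OD0 %g\n",
    x$mix_label, length(x$times), ncol(x$replicates),
    x$wt_fraction, x$ts_fraction, x$initial_od))
  invisible(x)
}

#' @describeIn growth_dataset Long tidy view (`mix`, `time_h`, `replicate`,
#'   `od`).
#' @param x A `growth_dataset`.
#' @param ... Unused.
#' @export
tidy.growth_dataset <- function(x, ...) {
  tibble::tibble(
    mix = x$mix_label,
    time_h = rep(x$times, ncol(x$replicates)),
    replicate = rep(colnames(x$replicates), each = length(x$times)),
    od = as.vector(x$replicates)
  )
}

#' Read growth-curve datasets from CSV
#'
#' Accepts the long dialect `mix,time_h,replicate,od` (canonical) or the wide
#' dialect `mix,time_h,rep1..repN`, auto-detected from the header. Inoculum
#' composition is supplied through a `design` table because it is not part of
#' the OD file.
#'
#' @param path CSV file path.
#' @param design Data frame with columns `mix_label`, `wt_fraction`,
#'   `ts_fraction`, `initial_od`, one row per mix present in the file (see
#'   [scenario_presets()]).
#'
#' @return A named list of [growth_dataset] objects.
#' @export
read_growth_curves <- function(path, design) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("mix", "time_h") %in% names(df))) {
    stop("growth-curve CSV must contain `mix` and `time_h` columns",
         call. = FALSE)
  }
  if (all(c("replicate", "od") %in% names(df))) {
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(df),
      id_cols = c("mix", "time_h"),
      names_from = "replicate", values_from = "od"
    )
  } else {
    rep_cols <- grep("^rep", names(df), value = TRUE)
    if (length(rep_cols) == 0) {
      stop("growth-curve CSV must be long (`replicate`,`od`) or wide (rep1..N)",
           call. = FALSE)
    }
    wide <- tibble::as_tibble(df[, c("mix", "time_h", rep_cols)])
  }
  design <- tibble::as_tibble(design)
  mixes <- unique(wide$mix)
  missing_design <- setdiff(mixes, design$mix_label)
  if (length(missing_design) > 0) {
    stop("design table missing mixes: ",
         paste(missing_design, collapse = ", "), call. = FALSE)
  }
  out <- lapply(mixes, function(m) {
    sub <- dplyr::arrange(dplyr::filter(wide, .data$mix == m), .data$time_h)
    d <- design[design$mix_label == m, ]
    reps <- as.matrix(sub[, setdiff(names(sub), c("mix", "time_h"))])
    growth_dataset(m, d$wt_fraction, d$ts_fraction, d$initial_od,
                   times = sub$time_h, replicates = reps)
  })
  stats::setNames(out, mixes)
}

#' Write growth-curve datasets to long CSV
#'
#' @param datasets A list of [growth_dataset] objects.
#' @param path Output CSV path (long dialect `mix,time_h,replicate,od`).
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(datasets, path) {
  long <- dplyr::bind_rows(lapply(datasets, tidy))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
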