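#' Construct a FRET trace object
#'
#' A time-stamped FRET ratio signal together with its stimulus events and
#' strain label. Events are additions/removals of attractant at known
#' times; event times must be covered by the time axis, sorted, and
#' alternate add/remove. The strain label selects the zero-activity
#' duration cap used by [removal_peak()] (114 s for `"wild-type"`, 257 s
#' for `"tar-only"`).
#'
#' @param data Data frame with columns `t_s` (strictly increasing, s) and
#'   `ratio` (arbitrary units).
#' @param events Data frame with columns `t_s`, `kind` (`"add"`/`"remove"`)
#'   and `L_mM`.
#' @param strain Strain label, `"tar-only"` (default) or `"wild-type"` (any
#'   other label gets no duration cap).
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(data, events, strain = "tar-only") {
  data <- as_tibble(data)
  events <- as_tibble(events)
  if (!all(c("t_s", "ratio") %in% names(data))) {
    abort("`data` must have columns `t_s` and `ratio`.")
  }
  if (!all(c("t_s", "kind", "L_mM") %in% names(events))) {
    abort("`events` must have columns `t_s`, `kind`, `L_mM`.")
  }
  if (is.unsorted(data$t_s, strictly = TRUE)) {
    abort("Trace times must be strictly increasing.")
  }
  if (nrow(events) > 0) {
    if (is.unsorted(events$t_s)) abort("Event times must be sorted.")
    if (!all(events$kind %in% c("add", "remove"))) {
      abort('Event kinds must be "add" or "remove".')
    }
    if (any(diff(match(events$kind, c("add", "remove"))) == 0)) {
      abort("Events must alternate add/remove.")
    }
    if (min(events$t_s) < min(data$t_s) || max(events$t_s) > max(data$t_s)) {
      abort("The trace time axis must cover all event times.")
    }
  }
  structure(list(data = data, events = events, strain = strain),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %d samples over %.0f s, %d events, strain = %s\n",
              nrow(x$data), diff(range(x$data$t_s)), nrow(x$events), x$strain))
  invisible(x)
}

# default saturating-concentration threshold, mM (above the dose-response
# saturation point of ~30 uM MeAsp)
.sat_threshold_mM <- 0.03

# index of the first add event at a saturating concentration
.saturating_add <- function(trace, sat_threshold = .sat_threshold_mM) {
  idx <- which(trace$events$kind == "add" & trace$events$L_mM >= sat_threshold)
  if (length(idx) == 0) {
    abort("Trace contains no saturating addition event; cannot calibrate.")
  }
  idx[1]
}

# centered rolling mean; edges (partial windows) are NA
.rolling_mean <- function(x, width = 21) {
  if (length(x) < width) return(mean(x))
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

# robust plateau extrema: the extremum of a rolling mean resists isolated
# noise spikes without the systematic ~2-sigma bias a raw order statistic
# picks up on long windows
.robust_min <- function(x, width = 21) min(.rolling_mean(x, width), na.rm = TRUE)
.robust_max <- function(x, width = 21) max(.rolling_mean(x, width), na.rm = TRUE)

# window statistics used by the calibration: F_pre is the mean over the
# pre-stimulus window, F_sat a robust minimum over the saturating-stimulus
# window
.calibration_anchors <- function(trace, sat_threshold = .sat_threshold_mM) {
  d <- trace$data
  ev <- trace$events
  i_sat <- .saturating_add(trace, sat_threshold)
  t_add <- ev$t_s[i_sat]
  later_removes <- ev$t_s[ev$kind == "remove" & ev$t_s > t_add]
  t_rem <- if (length(later_removes)) later_removes[1] else max(d$t_s)
  first_event <- if (nrow(ev)) min(ev$t_s) else max(d$t_s)
  F_pre <- mean(d$ratio[d$t_s < first_event])
  F_sat <- .robust_min(d$ratio[d$t_s > t_add & d$t_s <= t_rem])
  if (!is.finite(F_pre) || !is.finite(F_sat)) {
    abort("Calibration windows are empty.")
  }
  if (F_pre <= F_sat) {
    abort("Calibration error: pre-stimulus FRET does not exceed the saturated value.")
  }
  list(F_pre = F_pre, F_sat = F_sat, t_add = t_add, t_rem = t_rem)
}

#' Calibrate a FRET trace to kinase activity
#'
#' Converts the raw ratio to activity using the pre-stimulus value and the
#' (robust) minimum after a saturating addition, which correspond to
#' activities `a0` and 0: `a(t) = a0 (F(t) - F_sat) / (F_pre - F_sat)`.
#' The transform is affine-invariant: shifting or rescaling the raw ratio
#' leaves the activity unchanged. Calibrated activities outside
#' `[-0.05, 1.05]` are tolerated (noise) but logged with a warning.
#'
#' @param trace A [fret_trace()] object containing a saturating addition.
#' @param a0 Pre-stimulus activity (from [extract_a0()] on a full add /
#'   adapt / remove cycle).
#' @param sat_threshold Concentration (mM) above which an addition counts
#'   as saturating.
#' @return The trace `data` tibble with an added `activity` column.
#' @export
calibrate_activity <- function(trace, a0, sat_threshold = .sat_threshold_mM) {
  stopifnot(inherits(trace, "fret_trace"))
  if (a0 <= 0 || a0 > 1) abort("`a0` must lie in (0, 1].")
  anchors <- .calibration_anchors(trace, sat_threshold)
  out <- trace$data |>
    mutate(activity = a0 * (.data$ratio - anchors$F_sat) /
             (anchors$F_pre - anchors$F_sat))
  n_out <- sum(out$activity < -0.05 | out$activity > 1.05)
  if (n_out > 0) {
    warn(sprintf("%d calibrated activity sample(s) outside [-0.05, 1.05].", n_out))
  }
  out
}

#' Extract the pre-stimulus activity from a full stimulus cycle
#'
#' A full cycle -- saturating addition, full adaptation, removal -- spans
#' the activity range 0 to 1: activity is 0 while the saturating stimulus
#' is present and peaks at 1 right after removal. The pre-stimulus
#' activity is then `a0 = (F_pre - F_sat) / (F_peak - F_sat)`.
#'
#' @param trace A [fret_trace()] with a saturating add and a later remove.
#' @param peak_window Seconds after removal searched for the peak.
#' @param sat_threshold Saturating-concentration threshold, mM.
#' @return The pre-stimulus activity `a0` in (0, 1\].
#' @export
extract_a0 <- function(trace, peak_window = 100,
                       sat_threshold = .sat_threshold_mM) {
  stopifnot(inherits(trace, "fret_trace"))
  anchors <- .calibration_anchors(trace, sat_threshold)
  d <- trace$data
  post <- d$ratio[d$t_s > anchors$t_rem & d$t_s <= anchors$t_rem + peak_window]
  if (length(post) == 0) abort("No samples after the removal event.")
  F_peak <- .robust_max(post)
  if (F_peak <= anchors$F_sat) abort("Removal peak does not exceed the saturated value.")
  a0 <- (anchors$F_pre - anchors$F_sat) / (F_peak - anchors$F_sat)
  if (a0 >= 0.999) {
    warn("a0 ~ 1: removal peak does not exceed the pre-stimulus level; suspicious.")
  }
  a0
}

#' Adapted steady-state activity before a removal event
#'
#' Mean calibrated activity over a trailing window before the removal
#' event, the operational definition of the adapted activity `a*`. A
#' linear drift above `slope_threshold` over the window raises a warning
#' (steady state not reached).
#'
#' @param trace A [fret_trace()] object.
#' @param a0 Pre-stimulus activity for calibration.
#' @param event_index Row index into `trace$events` of the removal event
#'   (default: the last removal).
#' @param window Window length, s (default 100).
#' @param slope_threshold Drift tolerance, 1/s (default 1e-4).
#' @inheritParams calibrate_activity
#' @return The adapted activity `a*`.
#' @export
adapted_activity <- function(trace, a0, event_index = NULL, window = 100,
                             slope_threshold = 1e-4,
                             sat_threshold = .sat_threshold_mM) {
  stopifnot(inherits(trace, "fret_trace"))
  removes <- which(trace$events$kind == "remove")
  if (length(removes) == 0) abort("Trace has no removal event.")
  event_index <- event_index %||% removes[length(removes)]
  if (!(event_index %in% removes)) abort("`event_index` is not a removal event.")
  t_rem <- trace$events$t_s[event_index]
  cal <- calibrate_activity(trace, a0, sat_threshold)
  win <- cal |> filter(.data$t_s >= t_rem - window, .data$t_s < t_rem)
  if (nrow(win) < 3) abort("Steady-state window contains too few samples.")
  slope <- unname(coef(lm(activity ~ t_s, data = win))["t_s"])
  if (abs(slope) > slope_threshold) {
    warn(sprintf("Activity drifts at %.2g /s over the steady-state window (> %g /s).",
                 slope, slope_threshold))
  }
  mean(win$activity)
}

#' Post-removal activity peak and zero-activity duration
#'
#' Finds the maximum calibrated activity within a window after a removal
#' event (the recovery peak `a_r`), and the duration for which activity
#' stayed at approximately zero before the removal (the zero-activity
#' duration `delta_t` of the assay). Warns when `a_r >= 0.9` (outside the
#' assay validity range) or when `delta_t` exceeds the strain's cap
#' (114 s wild-type, 257 s Tar-only).
#'
#' @inheritParams adapted_activity
#' @param window Post-removal search window, s.
#' @param zero_threshold Activity below this counts as zero (default 0.02).
#' @return A one-row tibble: `a_r`, `t_peak`, `delta_t`.
#' @export
removal_peak <- function(trace, a0, event_index = NULL, window = 150,
                         zero_threshold = 0.02,
                         sat_threshold = .sat_threshold_mM) {
  stopifnot(inherits(trace, "fret_trace"))
  removes <- which(trace$events$kind == "remove")
  if (length(removes) == 0) abort("Trace has no removal event.")
  event_index <- event_index %||% removes[length(removes)]
  if (!(event_index %in% removes)) abort("`event_index` is not a removal event.")
  t_rem <- trace$events$t_s[event_index]
  cal <- calibrate_activity(trace, a0, sat_threshold)
  post <- cal |> filter(.data$t_s > t_rem, .data$t_s <= t_rem + window)
  if (nrow(post) == 0) abort("No samples after the removal event.")
  i_peak <- which.max(post$activity)
  a_r <- post$activity[i_peak]
  pre <- cal |> filter(.data$t_s < t_rem) |> arrange(.data$t_s)
  above <- which(pre$activity >= zero_threshold)
  i_zero <- if (length(above)) max(above) + 1L else 1L
  t_zero_start <- if (i_zero <= nrow(pre)) pre$t_s[i_zero] else t_rem
  delta_t <- t_rem - t_zero_start
  caps <- c("wild-type" = 114, "tar-only" = 257)
  cap <- caps[trace$strain]
  if (!is.na(cap) && delta_t > cap) {
    warn(sprintf("Zero-activity duration %.0f s exceeds the %s cap of %g s.",
                 delta_t, trace$strain, cap))
  }
  if (a_r >= 0.9) {
    warn("a_r >= 0.9: outside the validity range of the zero-activity assay.")
  }
  tibble(a_r = a_r, t_peak = post$t_s[i_peak], delta_t = delta_t)
}

#' Adaptation-precision pairs and their slope
#'
#' For a set of step-response results, computes for each step the
#' ligand-dependent free energy `fL` from the dose and the
#' methylation-dependent free energy `fm` from the inverted adapted
#' activity, and fits the linear relation `fm ~ fL` by OLS. Perfect
#' adaptation gives slope -1; the tethered-CheR mechanism gives a slope of
#' magnitude ~0.92--0.93 for Tar.
#'
#' @param steps Data frame with columns `L_mM` and `a_star`, one row per
#'   step-response experiment (at least 3 distinct doses).
#' @param mwc An [mwc_params()] object.
#' @return A list with `pairs` (tibble `L_mM`, `a_star`, `m`, `fm`, `fL`),
#'   `slope`, `slope_se`, `intercept` and `fit` (the `lm`).
#' @export
precision_pairs <- function(steps, mwc = mwc_params()) {
  steps <- as_tibble(steps)
  if (!all(c("L_mM", "a_star") %in% names(steps))) {
    abort("`steps` must have columns `L_mM` and `a_star`.")
  }
  if (length(unique(steps$L_mM)) < 3) {
    abort("At least 3 steps at distinct doses are required.")
  }
  pairs <- steps |>
    mutate(
      m = invert_activity(.data$a_star, .data$L_mM, mwc),
      fm = methylation_free_energy(.data$m, mwc),
      fL = ligand_free_energy(.data$L_mM, mwc)
    )
  fit <- lm(fm ~ fL, data = pairs)
  s <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  list(pairs = pairs,
       slope = unname(coef(fit)["fL"]),
       slope_se = s["fL", "Std. Error"],
       intercept = unname(coef(fit)["(Intercept)"]),
       fit = fit)
}
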