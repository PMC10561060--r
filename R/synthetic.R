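#' Ground truth for synthetic experiments
#'
#' Bundles everything the synthetic-experiment generators need: the MWC
#' receptor parameters, the TPM tether parameters, the linear site-distance
#' geometry, the adaptation rate constants, the measurement-noise level and
#' the affine map from activity to the recorded FRET-style ratio. Every
#' generator is a pure function of `(truth, protocol, seed)`.
#'
#' Unless `kin` is supplied, the demethylation rate `kB` is derived from the
#' requested pre-stimulus activity `a0`: at the unstimulated steady state
#' `kR(m_pre) (1 - a0) = kB d(a0)` with `d` the variant's demethylation
#' activity dependence, and `m_pre` the MWC inversion of `a0` at `L = 0`.
#' The TPM encounter factor modulates `kR` via [make_tpm_modifier()].
#'
#' The affine ratio map is `ratio = offset + gain * a` with additive iid
#' Gaussian noise of standard deviation `noise_sd` (default 2% of the full
#' FRET range `gain`), so the pre-stimulus FRET exceeds the saturated
#' value, matching the calibration convention of [calibrate_activity()].
#'
#' @param mwc An [mwc_params()] object.
#' @param tpm A [tpm_params()] object (ground-truth `x0`).
#' @param geometry A `geometry_fit` or named list/vector with `k`, `R0`.
#' @param a0 Pre-stimulus activity the unstimulated steady state should sit
#'   at.
#' @param kR0 Methylation rate constant at `m = 0`, 1/s.
#' @param variant Demethylation variant, `"linear"` or `"cubic"`.
#' @param kin Optional explicit [adaptation_params()]; overrides the
#'   `a0`-derived rates.
#' @param noise_sd Ratio-scale Gaussian noise sd.
#' @param ratio_offset,ratio_gain Affine activity-to-ratio map.
#' @param sampling_dt Sampling interval, s.
#' @param seed Default seed recorded in the truth and used by generators.
#' @return An object of class `ground_truth` with the above fields plus the
#'   derived `m_pre` and `kin`.
#' @export
ground_truth <- function(mwc = mwc_params(), tpm = tpm_params(),
                         geometry = fit_site_distance(), a0 = 0.35,
                         kR0 = 0.002, variant = c("linear", "cubic"),
                         kin = NULL, noise_sd = 0.004,
                         ratio_offset = 0.8, ratio_gain = 0.2,
                         sampling_dt = 1, seed = 1L) {
  variant <- match.arg(variant)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (ratio_gain <= 0) abort("`ratio_gain` must be > 0.")
  k <- if (inherits(geometry, "geometry_fit")) geometry$k else geometry[["k"]]
  R0 <- if (inherits(geometry, "geometry_fit")) geometry$R0 else geometry[["R0"]]
  truth <- structure(
    list(mwc = mwc, tpm = tpm, k = k, R0 = R0, a0 = a0, variant = variant,
         noise_sd = noise_sd, ratio_offset = ratio_offset,
         ratio_gain = ratio_gain, sampling_dt = sampling_dt,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
  modifier <- make_tpm_modifier(truth)
  if (is.null(kin)) {
    if (a0 <= 0 || a0 >= 1) abort("`a0` must lie strictly in (0, 1).")
    m_pre <- invert_activity(a0, 0, mwc)
    demeth <- switch(variant, linear = a0, cubic = a0^3)
    kB <- kR0 * modifier(m_pre) * (1 - a0) / demeth
    kin <- adaptation_params(kR = kR0, kB = kB, variant = variant)
  } else {
    # steady state of the supplied rates under the TPM modifier
    g <- function(m) {
      a <- receptor_activity(m, 0, mwc)
      methylation_rate(a, m, kin, kR_modifier = modifier(m))
    }
    m_pre <- uniroot(g, c(1e-9, 4 - 1e-9), tol = 1e-12)$root
    truth$a0 <- receptor_activity(m_pre, 0, mwc)
  }
  truth$kin <- kin
  truth$m_pre <- m_pre
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> a0 = %.3f, m_pre = %.3f, kR0 = %.4g /s, kB = %.4g /s (%s)\n",
    x$a0, x$m_pre, x$kin$kR, x$kin$kB, x$variant))
  cat(sprintf("  x0 = %.3g nm, R(m) = %.3g m + %.3g nm, noise sd = %.3g, seed = %d\n",
              x$tpm$x0, x$k, x$R0, x$noise_sd, x$seed))
  invisible(x)
}

#' TPM modifier of the methylation rate
#'
#' The methylation rate is proportional to the local CheR concentration at
#' the next site to be methylated, i.e. to the translated-Gaussian density
#' at `R(m) = k m + R0`:
#' `kR(m) = kR0 * exp(-3 (R(m) - x0)^2 / (2 L_total b)) / normaliser`,
#' with the normaliser chosen so the modifier equals 1 at `m = 0`. With a
#' flat geometry (`k = 0`) the modifier is identically 1.
#'
#' @param truth A [ground_truth()] object.
#' @return A function of `m` returning the dimensionless modifier.
#' @export
make_tpm_modifier <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  k <- truth$k; R0 <- truth$R0; tpm <- truth$tpm
  norm <- tpm_density(R0, tpm) / tpm$c
  function(m) (tpm_density(k * m + R0, tpm) / tpm$c) / norm
}

# simulate a protocol under the truth and wrap the noisy affine-mapped
# activity as a fret_trace; hidden truth goes into attr(trace, "truth")
.render_trace <- function(truth, protocol, events, t_end, seed, strain) {
  traj <- simulate_adaptation(protocol, truth$mwc, truth$kin,
                              m_init = truth$m_pre,
                              rate_modifier = make_tpm_modifier(truth),
                              t_end = t_end, dt_out = truth$sampling_dt)
  ratio <- withr::with_seed(seed, {
    truth$ratio_offset + truth$ratio_gain * traj$a +
      rnorm(nrow(traj), sd = truth$noise_sd)
  })
  trace <- fret_trace(tibble(t_s = traj$t_s, ratio = ratio), events, strain)
  attr(trace, "truth") <- list(trajectory = traj, a0 = truth$a0,
                               m_pre = truth$m_pre, seed = seed)
  trace
}

#' Generate a synthetic step-response experiment
#'
#' Simulates the add/adapt/remove protocol of a step-response experiment
#' under the TPM-modulated adaptation dynamics, maps activity to a
#' FRET-style ratio with the truth's affine transform and Gaussian noise,
#' and returns a [fret_trace()]. When `calibration_pulse` is `TRUE` and the
#' step dose itself is not saturating, a short saturating pulse is appended
#' after recovery so the trace can be calibrated on its own.
#'
#' The hidden ground truth (noise-free trajectory, `a0`, `m_pre`, seed) is
#' attached as `attr(trace, "truth")`; no estimator in the package reads
#' it.
#'
#' @param truth A [ground_truth()] object.
#' @param L_step Step concentration, mM.
#' @param t_add Time of addition, s.
#' @param duration_add Duration of the step, s.
#' @param t_recover Recovery time after removal before the calibration
#'   pulse, s.
#' @param calibration_pulse Append a saturating pulse (`L_sat`,
#'   `duration_sat`) for self-calibration.
#' @param L_sat,duration_sat Saturating-pulse concentration (mM) and
#'   duration (s).
#' @param t_post Trailing time after the last event, s.
#' @param seed Seed for the measurement noise; defaults to the truth's.
#' @param strain Strain label for the trace.
#' @return A [fret_trace()] with hidden-truth attribute.
#' @export
generate_step_experiment <- function(truth, L_step, t_add = 200,
                                     duration_add = 900, t_recover = 300,
                                     calibration_pulse = TRUE, L_sat = 0.25,
                                     duration_sat = 120, t_post = 100,
                                     seed = NULL, strain = "tar-only") {
  stopifnot(inherits(truth, "ground_truth"))
  if (L_step < 0) abort("`L_step` must be >= 0.")
  seed <- seed %||% truth$seed
  t_rem <- t_add + duration_add
  protocol <- tibble(t_s = c(0, t_add, t_rem), L_mM = c(0, L_step, 0))
  events <- tibble(t_s = c(t_add, t_rem), kind = c("add", "remove"),
                   L_mM = c(L_step, 0))
  if (calibration_pulse && L_step < .sat_threshold_mM) {
    t_sat <- t_rem + t_recover
    protocol <- bind_rows(protocol,
                          tibble(t_s = c(t_sat, t_sat + duration_sat),
                                 L_mM = c(L_sat, 0)))
    events <- bind_rows(events,
                        tibble(t_s = c(t_sat, t_sat + duration_sat),
                               kind = c("add", "remove"),
                               L_mM = c(L_sat, 0)))
  }
  .render_trace(truth, protocol, events, max(protocol$t_s) + t_post, seed,
                strain)
}

#' Generate synthetic zero-activity assays
#'
#' One trace per requested zero-activity duration: a saturating stimulus is
#' added at `t_pre` and removed after `delta_t` seconds, during which the
#' activity is pinned at ~0 and the methylation level integrates the
#' TPM-modulated rate `kR(m)`; the recovery peak after removal encodes the
#' accrued methylation.
#'
#' @param truth A [ground_truth()] object.
#' @param delta_t_list Zero-activity durations, s (> 0).
#' @param L_sat Saturating concentration, mM; must give an initial activity
#'   below 1e-3 at the truth's pre-stimulus state.
#' @param t_pre Pre-stimulus recording time, s.
#' @param t_post Post-removal recording time, s.
#' @param seed Base seed; trace `i` uses `seed + i - 1`.
#' @param strain Strain label.
#' @return A list of [fret_trace()] objects (hidden-truth attributes as in
#'   [generate_step_experiment()]).
#' @export
generate_zero_activity_assay <- function(truth, delta_t_list, L_sat = 0.25,
                                         t_pre = 200, t_post = 300,
                                         seed = NULL, strain = "tar-only") {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(delta_t_list <= 0)) abort("Zero-activity durations must be > 0.")
  a_at_sat <- receptor_activity(truth$m_pre, L_sat, truth$mwc)
  if (a_at_sat > 1e-3) {
    abort(sprintf("L_sat = %g mM is not saturating (initial activity %.3g).",
                  L_sat, a_at_sat))
  }
  seed <- seed %||% truth$seed
  imap(as.list(delta_t_list), function(dt, i) {
    t_rem <- t_pre + dt
    protocol <- tibble(t_s = c(0, t_pre, t_rem), L_mM = c(0, L_sat, 0))
    events <- tibble(t_s = c(t_pre, t_rem), kind = c("add", "remove"),
                     L_mM = c(L_sat, 0))
    .render_trace(truth, protocol, events, t_rem + t_post, seed + i - 1L,
                  strain)
  })
}

#' Generate a synthetic dose-response table
#'
#' Instantaneous MWC responses at the truth's pre-stimulus methylation
#' level, with Gaussian noise on the activity scale. Used to exercise
#' [fit_cluster_size()].
#'
#' @param truth A [ground_truth()] object.
#' @param doses Dose grid, mM (non-empty, >= 0).
#' @param noise_sd_activity Activity-scale noise sd; defaults to the
#'   truth's ratio-scale noise divided by the ratio gain.
#' @param seed Seed for the noise.
#' @return A tibble with columns `dose_mM` and `activity`.
#' @export
generate_dose_response <- function(truth, doses,
                                   noise_sd_activity = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(doses) == 0) abort("`doses` must be non-empty.")
  if (any(doses < 0)) abort("Doses must be >= 0.")
  noise_sd_activity <- noise_sd_activity %||%
    (truth$noise_sd / truth$ratio_gain)
  seed <- seed %||% truth$seed
  a <- receptor_activity(truth$m_pre, doses, truth$mwc)
  a_obs <- withr::with_seed(seed, a + rnorm(length(doses), sd = noise_sd_activity))
  tibble(dose_mM = doses, activity = a_obs)
}
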