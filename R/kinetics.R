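#' Adaptation kinetics parameters
#'
#' Rate constants for the canonical adaptation model in which the
#' methyltransferase CheR works on inactive receptors and the methylesterase
#' CheB on active ones: `dm/dt = kR * (1 - a) - kB * a` (linear variant) or
#' `dm/dt = kR * (1 - a) - kB * a^3` (cubic variant, a stronger activity
#' dependence of demethylation). An optional scarce-sites correction
#' multiplies each rate by `M / (M + M_sat)`, where `M` is the number of
#' sites still available for that reaction (`4 - m` for methylation, `m` for
#' demethylation).
#'
#' Absolute rates in 1/s are not pinned down by steady-state measurements;
#' the defaults put step adaptation on a several-hundred-second timescale
#' and keep the zero-activity assay inside its validity caps (see the
#' methods vignette) and are freely overridable.
#'
#' @param kR Methylation rate constant, 1/s (>= 0).
#' @param kB Demethylation rate constant, 1/s (>= 0).
#' @param variant `"linear"` or `"cubic"` demethylation activity dependence.
#' @param M_sat Scarce-sites constant (sites); `NULL` disables the correction.
#' @return An object of class `adaptation_params`.
#' @export
adaptation_params <- function(kR = 0.002, kB = 0.0037, variant = c("linear", "cubic"),
                              M_sat = NULL) {
  variant <- match.arg(variant)
  if (kR < 0 || kB < 0) abort("`kR` and `kB` must be >= 0.")
  if (kR == 0 && kB == 0) abort("At least one of `kR`, `kB` must be positive.")
  if (!is.null(M_sat) && M_sat < 0) abort("`M_sat` must be >= 0.")
  structure(list(kR = kR, kB = kB, variant = variant, M_sat = M_sat),
            class = "adaptation_params")
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat(sprintf("<adaptation_params> kR = %.4g /s, kB = %.4g /s, variant = %s%s\n",
              x$kR, x$kB, x$variant,
              if (is.null(x$M_sat)) "" else sprintf(", M_sat = %g", x$M_sat)))
  invisible(x)
}

#' Net methylation rate
#'
#' `dm/dt` at a given activity and methylation level under an
#' [adaptation_params()] set (see there for the variants and the
#' scarce-sites correction).
#'
#' @param a Activity in \[0, 1\].
#' @param m Methylation level; only used by the scarce-sites correction.
#' @param params An [adaptation_params()] object.
#' @param kR_modifier Optional multiplicative modifier of `kR` (already
#'   evaluated at the current state), e.g. a TPM encounter factor.
#' @return Net rate in 1/s.
#' @export
methylation_rate <- function(a, m = NA_real_, params = adaptation_params(),
                             kR_modifier = 1) {
  if (any(a < 0 | a > 1)) abort("`a` must lie in [0, 1].")
  kR <- params$kR * kR_modifier
  kB <- params$kB
  if (!is.null(params$M_sat)) {
    if (any(is.na(m))) abort("Scarce-sites correction requires `m`.")
    mc <- pmin(pmax(m, 0), 4)
    kR <- kR * (4 - mc) / ((4 - mc) + params$M_sat)
    kB <- kB * mc / (mc + params$M_sat)
  }
  demeth <- switch(params$variant, linear = a, cubic = a^3)
  kR * (1 - a) - kB * demeth
}

#' Steady-state adapted activity
#'
#' Solves `dm/dt = 0` for the activity. Linear variant:
#' `a* = kR / (kR + kB)` in closed form. Cubic variant: the unique root in
#' (0, 1) of `a^3 / (1 - a) = kR / kB`, located by bracketed root finding
#' (the left-hand side increases strictly from 0 to infinity).
#'
#' @param params An [adaptation_params()] object (`kB > 0`; `kB = 0` returns
#'   1 with a warning).
#' @param kR_modifier Optional multiplicative modifier of `kR`.
#' @return Activity `a*` in (0, 1\].
#' @export
steady_state_activity <- function(params = adaptation_params(), kR_modifier = 1) {
  kR <- params$kR * kR_modifier
  kB <- params$kB
  if (kB == 0) {
    warn("kB = 0: activity saturates, returning a* = 1.")
    return(1)
  }
  if (kR == 0) return(0)
  if (params$variant == "linear") return(kR / (kR + kB))
  r <- kR / kB
  uniroot(function(a) a^3 / (1 - a) - r, lower = 1e-12, upper = 1 - 1e-12,
          tol = 1e-14)$root
}

#' Simulate adaptation to a piecewise-constant stimulus protocol
#'
#' Integrates `dm/dt = kR(m) * (1 - a) - kB * a^p` coupled to the MWC
#' activity `a(m, L(t))`, with the ligand concentration held
#' piecewise-constant between protocol events. Integration restarts at every
#' protocol switch so the discontinuity in `L` never straddles a solver
#' step. `m` is clamped to the physical range \[0, 4\] (sites are finite);
#' the fitting-side inversion [invert_activity()] deliberately is not.
#'
#' @param protocol Data frame with columns `t_s` (strictly increasing event
#'   times, the first being the start of the simulation) and `L_mM` (the
#'   concentration that applies from that time on).
#' @param mwc An [mwc_params()] object.
#' @param kin An [adaptation_params()] object.
#' @param m_init Initial methylation level (finite).
#' @param rate_modifier Optional function of `m` returning a multiplicative
#'   modifier of `kR` (e.g. from [make_tpm_modifier()]).
#' @param t_end End time of the simulation, s; defaults to the last protocol
#'   time plus 300 s.
#' @param dt_out Output sampling interval, s.
#' @param atol,rtol Absolute/relative integrator tolerances.
#' @return A tibble with columns `t_s`, `L_mM`, `m`, `a`.
#' @examples
#' proto <- tibble::tibble(t_s = c(0, 200, 1100), L_mM = c(0, 0.025, 0))
#' traj <- simulate_adaptation(proto, mwc_params(), adaptation_params(),
#'                             m_init = 1)
#' @export
simulate_adaptation <- function(protocol, mwc, kin, m_init,
                                rate_modifier = NULL, t_end = NULL,
                                dt_out = 1, atol = 1e-9, rtol = 1e-7) {
  protocol <- as_tibble(protocol)
  if (!all(c("t_s", "L_mM") %in% names(protocol))) {
    abort("`protocol` must have columns `t_s` and `L_mM`.")
  }
  if (is.unsorted(protocol$t_s, strictly = TRUE)) {
    abort("Protocol times must be strictly increasing.")
  }
  if (!is.finite(m_init)) abort("`m_init` must be finite.")
  t_end <- t_end %||% (max(protocol$t_s) + 300)
  if (t_end <= max(protocol$t_s)) abort("`t_end` must exceed the last event time.")
  mod_fun <- rate_modifier %||% function(m) 1

  deriv <- function(t, state, parms) {
    m <- min(max(state[["m"]], 0), 4)
    a <- receptor_activity(m, parms$L, mwc)
    dm <- methylation_rate(a, m, kin, kR_modifier = mod_fun(m))
    # reflecting boundaries: no flux out of [0, 4]
    if (state[["m"]] >= 4 && dm > 0) dm <- 0
    if (state[["m"]] <= 0 && dm < 0) dm <- 0
    list(dm)
  }

  starts <- protocol$t_s
  ends <- c(protocol$t_s[-1], t_end)
  m_cur <- min(max(m_init, 0), 4)
  pieces <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    times <- unique(c(seq(starts[i], ends[i], by = dt_out), ends[i]))
    sol <- tryCatch(
      deSolve::lsoda(c(m = m_cur), times, deriv, parms = list(L = protocol$L_mM[i]),
                     atol = atol, rtol = rtol),
      warning = function(w) {
        abort(sprintf("ODE integration failed on segment %d (t = %g..%g s): %s",
                      i, starts[i], ends[i], conditionMessage(w)))
      }
    )
    m_seg <- pmin(pmax(sol[, "m"], 0), 4)
    pieces[[i]] <- tibble(
      t_s = sol[, "time"], L_mM = protocol$L_mM[i], m = m_seg,
      a = receptor_activity(m_seg, protocol$L_mM[i], mwc)
    )
    m_cur <- m_seg[length(m_seg)]
    # drop the duplicated segment-boundary sample of the next piece
    if (i < nrow(protocol)) pieces[[i]] <- pieces[[i]][-nrow(pieces[[i]]), ]
  }
  bind_rows(pieces)
}

#' Average net methylation rate from a zero-activity assay
#'
#' In the zero-activity assay a saturating attractant step pins the kinase
#' activity at zero for a duration `delta_t` while CheR methylates freely;
#' the activity peak `a_r` right after stimulus removal is converted to the
#' recovery methylation level `m_r` via the MWC inversion, and the average
#' net rate is `(m_r - m_pre) / delta_t`.
#'
#' @param m_pre Pre-stimulus methylation level.
#' @param a_r Peak activity after removal, in (0, 1). Values >= 0.9 are
#'   outside the assay's validity range and raise a warning.
#' @param delta_t Zero-activity duration, s (> 0).
#' @param mwc An [mwc_params()] object.
#' @return A one-row tibble: `delta_t`, `a_r`, `m_r`, `rate` (1/s).
#' @export
zero_activity_rate <- function(m_pre, a_r, delta_t, mwc = mwc_params()) {
  if (any(delta_t <= 0)) abort("`delta_t` must be > 0.")
  if (any(a_r <= 0 | a_r >= 1)) abort("`a_r` must lie strictly in (0, 1).")
  if (any(a_r >= 0.9)) {
    warn("a_r >= 0.9: outside the validity range of the zero-activity assay.")
  }
  m_r <- invert_activity(a_r, L = 0, params = mwc)
  tibble(delta_t = delta_t, a_r = a_r, m_r = m_r,
         rate = (m_r - m_pre) / delta_t)
}
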