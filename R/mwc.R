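#' MWC receptor-cluster parameters
#'
#' Parameter set for the two-state Monod-Wyman-Changeux (MWC) model of a
#' chemoreceptor cluster. A cluster of `N` receptors is jointly active with
#' probability `a = 1 / (1 + exp(N * (fm + fL)))`, where
#' `fm = alpha * (m - m0)` is the methylation-dependent free energy and
#' `fL = log((1 + L/Koff) / (1 + L/Kon))` is the ligand-dependent free energy
#' (both in units of kT). Defaults are the MeAsp/Tar values used throughout:
#' the cluster size `N = 8.7` extracted for the Tar-only strain, with
#' `alpha = -1.875`, `m0 = 1`, `Koff = 0.0182` mM and `Kon = 3` mM fixed from
#' prior dose-response work.
#'
#' @param N Receptor-cluster size (dimensionless, > 0).
#' @param alpha Free energy per methyl group, kT; negative (methylation
#'   activates the kinase).
#' @param m0 Methylation offset (dimensionless).
#' @param Koff Inactive-state dissociation constant, mM (> 0).
#' @param Kon Active-state dissociation constant, mM (> `Koff`); `Kon > Koff`
#'   is the attractant convention, giving `fL >= 0` increasing in `L`.
#' @return An object of class `mwc_params`.
#' @examples
#' p <- mwc_params()
#' receptor_activity(m = 1, L = 0, params = p)
#' @export
mwc_params <- function(N = 8.7, alpha = -1.875, m0 = 1, Koff = 0.0182, Kon = 3) {
  if (!is.numeric(N) || N <= 0) abort("`N` must be > 0.")
  if (Koff <= 0) abort("`Koff` must be > 0.")
  if (Kon <= Koff) abort("`Kon` must exceed `Koff` (attractant convention).")
  structure(
    list(N = N, alpha = alpha, m0 = m0, Koff = Koff, Kon = Kon),
    class = "mwc_params"
  )
}

#' @export
print.mwc_params <- function(x, ...) {
  cat("<mwc_params> N =", x$N, " alpha =", x$alpha, " m0 =", x$m0,
      " Koff =", x$Koff, "mM  Kon =", x$Kon, "mM\n")
  invisible(x)
}

#' Ligand-dependent free energy
#'
#' `fL = log((1 + L/Koff) / (1 + L/Kon))`, in kT. Zero at `L = 0`, strictly
#' increasing in `L`, saturating at `log(Kon/Koff)`.
#'
#' @param L Ligand concentration, mM (vectorised, >= 0).
#' @param params An [mwc_params()] object.
#' @return Free energy in kT, same length as `L`.
#' @export
ligand_free_energy <- function(L, params = mwc_params()) {
  if (any(L < 0)) abort("Ligand concentration `L` must be >= 0.")
  log1p(L / params$Koff) - log1p(L / params$Kon)
}

#' Methylation-dependent free energy
#'
#' `fm = alpha * (m - m0)`, in kT; linear in the methylation level `m` and
#' decreasing for `alpha < 0`. `m` is not restricted to the physical range
#' 0--4 here: fitted values may fall slightly outside it.
#'
#' @param m Methylation level (vectorised).
#' @inheritParams ligand_free_energy
#' @return Free energy in kT.
#' @export
methylation_free_energy <- function(m, params = mwc_params()) {
  params$alpha * (m - params$m0)
}

#' Receptor-kinase activity of an MWC cluster
#'
#' `a = 1 / (1 + exp(N * (fm + fL)))`, evaluated with a numerically stable
#' logistic so that exponents up to several hundred in magnitude do not
#' overflow. Strictly increasing in `m` (for `alpha < 0`) and strictly
#' decreasing in `L`.
#'
#' @inheritParams methylation_free_energy
#' @param L Ligand concentration, mM (>= 0).
#' @return Activity in (0, 1).
#' @export
receptor_activity <- function(m, L = 0, params = mwc_params()) {
  f <- methylation_free_energy(m, params) + ligand_free_energy(L, params)
  plogis(-params$N * f)
}

#' Invert activity to methylation level
#'
#' Exact algebraic inverse of [receptor_activity()] at known ligand
#' concentration: `m = m0 + (log((1 - a)/a) / N - fL) / alpha`. Used to read
#' methylation levels off measured activities. The result is not clamped to
#' the physical range; a warning is raised when `m` falls outside
#' `[-0.2, 4.2]`, which usually indicates a calibration problem upstream.
#'
#' @param a Activity, strictly inside (0, 1) (vectorised).
#' @param L Ligand concentration, mM, at which `a` was observed.
#' @inheritParams ligand_free_energy
#' @return Methylation level(s).
#' @export
invert_activity <- function(a, L = 0, params = mwc_params()) {
  if (any(a <= 0 | a >= 1)) {
    abort("`a` must lie strictly in (0, 1): the free energy is infinite at 0 or 1.")
  }
  fL <- ligand_free_energy(L, params)
  m <- params$m0 + (-qlogis(a) / params$N - fL) / params$alpha
  out_of_range <- m < -0.2 | m > 4.2
  if (any(out_of_range)) {
    warn(sprintf(
      "%d inverted methylation level(s) outside [-0.2, 4.2] (range %.3g..%.3g).",
      sum(out_of_range), min(m), max(m)
    ))
  }
  m
}

#' Fit the MWC cluster size to a dose-response table
#'
#' Unweighted nonlinear least squares of the MWC activity curve to measured
#' (dose, activity) pairs, estimating the cluster size `N` and the
#' pre-stimulus methylation level `m_pre` jointly while `alpha`, `m0`,
#' `Koff`, `Kon` stay fixed at their calibrated values.
#'
#' @param data Data frame with columns `dose_mM` and `activity`.
#' @param params An [mwc_params()] whose `alpha`, `m0`, `Koff`, `Kon` are
#'   held fixed; its `N` seeds the optimiser.
#' @param start Optional named list/vector with starting values `N`, `m_pre`.
#' @return An object of class `mwc_fit` with elements `N`, `m_pre`,
#'   `se` (named standard errors), `rss`, `converged`, `fit` (the underlying
#'   `nls` object) and `data`. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' p <- mwc_params(N = 8.7)
#' doses <- 10^seq(-3, 0, length.out = 12)
#' dr <- tibble::tibble(dose_mM = doses,
#'                      activity = receptor_activity(1, doses, p))
#' fit_cluster_size(dr, p)
#' @export
fit_cluster_size <- function(data, params = mwc_params(), start = NULL) {
  data <- as_tibble(data)
  if (!all(c("dose_mM", "activity") %in% names(data))) {
    abort("`data` must have columns `dose_mM` and `activity`.")
  }
  if (length(unique(data$dose_mM)) < 4) {
    abort("At least 4 distinct dose points spanning the transition are required.")
  }
  start <- start %||% list(N = params$N, m_pre = params$m0)
  model_a <- function(dose, N, m_pre) {
    fm <- params$alpha * (m_pre - params$m0)
    fL <- log1p(dose / params$Koff) - log1p(dose / params$Kon)
    plogis(-N * (fm + fL))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      activity ~ model_a(dose_mM, N, m_pre),
      data = data, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(N = NA_real_, m_pre = NA_real_, se = c(N = NA_real_, m_pre = NA_real_),
           rss = NA_real_, converged = FALSE, message = conditionMessage(fit),
           fit = NULL, data = data, params = params),
      class = "mwc_fit"
    ))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(
    list(N = unname(est["N"]), m_pre = unname(est["m_pre"]),
         se = c(N = unname(se["N"]), m_pre = unname(se["m_pre"])),
         rss = sum(stats::resid(fit)^2), converged = fit$convInfo$isConv,
         message = fit$convInfo$stopMessage, fit = fit, data = data,
         params = params),
    class = "mwc_fit"
  )
}

#' @export
print.mwc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mwc_fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<mwc_fit> N = %.3f (se %.3f), m_pre = %.3f (se %.3f), rss = %.3g\n",
              x$N, x$se["N"], x$m_pre, x$se["m_pre"], x$rss))
  invisible(x)
}

#' @export
tidy.mwc_fit <- function(x, ...) {
  tibble(
    term = c("N", "m_pre"),
    estimate = c(x$N, x$m_pre),
    std.error = unname(x$se[c("N", "m_pre")])
  )
}

#' @export
glance.mwc_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data), converged = x$converged)
}
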