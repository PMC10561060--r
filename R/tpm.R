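#' Tethered-particle-motion parameters
#'
#' Parameters of the translated-Gaussian positional density of a tethered
#' enzyme. A freely jointed chain of contour length `L_total` and Kuhn
#' length `b` has a Gaussian end-to-end density with variance
#' `L_total * b / 3` per axis; volume exclusion by the chain and the wall
#' shifts the peak of the tethered ball's radial position to a translation
#' `x0`. Defaults are the wild-type Tar values: `L_total = 12.24` nm
#' (34 residues x 0.36 nm), `b = 0.76` nm (twice the 0.38 nm persistence
#' length), and the fitted `x0 = 10.5` nm.
#'
#' @param L_total Contour length, nm (> 0).
#' @param b Kuhn length, nm (> 0).
#' @param x0 Peak translation, nm (>= 0).
#' @param c Amplitude of the ratio model (dimensionless, > 0).
#' @return An object of class `tpm_params`.
#' @export
tpm_params <- function(L_total = 12.24, b = 0.76, x0 = 10.5, c = 1) {
  if (L_total <= 0 || b <= 0) abort("`L_total` and `b` must be > 0.")
  if (x0 < 0) abort("`x0` must be >= 0.")
  if (c <= 0) abort("`c` must be > 0.")
  structure(list(L_total = L_total, b = b, x0 = x0, c = c), class = "tpm_params")
}

#' @export
print.tpm_params <- function(x, ...) {
  cat(sprintf("<tpm_params> L_total = %.3g nm, b = %.3g nm, x0 = %.3g nm, c = %.3g\n",
              x$L_total, x$b, x$x0, x$c))
  invisible(x)
}

#' Gaussian chain end-to-end density (unnormalised)
#'
#' `exp(-3 R^2 / (2 L_total b))`: the ideal-chain density of the end-to-end
#' distance, symmetric and maximal at `R = 0`.
#'
#' @param R Distance from the tethering point, nm (vectorised).
#' @param L_total Contour length, nm (> 0).
#' @param b Kuhn length, nm (> 0).
#' @return Unnormalised density.
#' @export
chain_end_pdf <- function(R, L_total = 12.24, b = 0.76) {
  if (L_total <= 0 || b <= 0) abort("`L_total` and `b` must be > 0.")
  exp(-3 * R^2 / (2 * L_total * b))
}

#' Translated-Gaussian density of the tethered enzyme
#'
#' `c * exp(-3 (R - x0)^2 / (2 L_total b))`: the positional density of the
#' tethered ball, maximal at `R = x0`. Because the peak sits beyond the most
#' distant methylation site, the site-encounter rate decays along the
#' Gaussian tail as sites get closer to the tether.
#'
#' @param R Distance from the tethering point, nm (vectorised).
#' @param params A [tpm_params()] object.
#' @return Density (amplitude `c` at `R = x0`).
#' @export
tpm_density <- function(R, params = tpm_params()) {
  params$c * exp(-3 * (R - params$x0)^2 / (2 * params$L_total * params$b))
}

#' Fit the TPM model to steady-state activity ratios
#'
#' Nonlinear least squares of the translated-Gaussian model to measured
#' steady-state activity ratios at known site distances:
#' `ratio(R) = c * exp(-3 (R - x0)^2 / (2 L_total b))`, with `L_total` and
#' `b` fixed and `(c, x0)` free. For the linear adaptation variant the ratio
#' is `a*/(1 - a*)`; for the cubic variant it is `a*^3/(1 - a*)`. The loss
#' is unweighted on the ratio scale by default; set `log_loss = TRUE` to fit
#' on the log-ratio scale instead.
#'
#' @param data Data frame with columns `R_nm` and `ratio` (> 0); at least 3
#'   distinct `R_nm` values.
#' @param L_total,b Fixed chain parameters, nm.
#' @param variant `"linear"` or `"cubic"`; recorded in the result (the ratio
#'   column is assumed to already be on the variant's scale).
#' @param log_loss Fit on the log-ratio scale (default `FALSE`).
#' @param start Optional named list with starting values `c`, `x0`; the
#'   default starts `x0` at `max(R) + 2` nm.
#' @return An object of class `tpm_fit` with elements `c`, `x0`, `se`,
#'   `rss`, `converged`, `flagged` (TRUE when `x0` falls outside
#'   `[0, 3 L_total]`), `variant`, `fit`, `data`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(R_nm = c(6.75, 5.7, 4.65, 3.45),
#'                     ratio = tpm_density(c(6.75, 5.7, 4.65, 3.45),
#'                                         tpm_params(c = 2)))
#' fit_tpm(d)
#' @export
fit_tpm <- function(data, L_total = 12.24, b = 0.76,
                    variant = c("linear", "cubic"), log_loss = FALSE,
                    start = NULL) {
  variant <- match.arg(variant)
  data <- as_tibble(data)
  if (!all(c("R_nm", "ratio") %in% names(data))) {
    abort("`data` must have columns `R_nm` and `ratio`.")
  }
  if (any(data$ratio <= 0) || any(data$R_nm <= 0)) {
    abort("`ratio` and `R_nm` must be positive.")
  }
  if (length(unique(data$R_nm)) < 3) {
    abort("At least 3 distinct `R_nm` values are required.")
  }
  x0_start <- max(data$R_nm) + 2
  start <- start %||% list(
    c = max(data$ratio) / chain_end_pdf(max(data$R_nm) - x0_start, L_total, b),
    x0 = x0_start
  )
  Lb2 <- 2 * L_total * b
  form <- if (log_loss) {
    log(ratio) ~ log(c) - 3 * (R_nm - x0)^2 / Lb2
  } else {
    ratio ~ c * exp(-3 * (R_nm - x0)^2 / Lb2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    abort(sprintf("TPM fit did not converge: %s", conditionMessage(fit)))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  flagged <- est[["x0"]] < 0 || est[["x0"]] > 3 * L_total
  if (flagged) warn(sprintf("Fitted x0 = %.3g nm outside [0, %g] nm.",
                            est[["x0"]], 3 * L_total))
  structure(
    list(c = unname(est["c"]), x0 = unname(est["x0"]),
         se = c(c = unname(se["c"]), x0 = unname(se["x0"])),
         rss = sum(stats::resid(fit)^2), converged = fit$convInfo$isConv,
         flagged = flagged, variant = variant, L_total = L_total, b = b,
         fit = fit, data = data),
    class = "tpm_fit"
  )
}

#' @export
print.tpm_fit <- function(x, ...) {
  cat(sprintf(
    "<tpm_fit %s> c = %.4g (se %.2g), x0 = %.4g nm (se %.2g), rss = %.3g%s\n",
    x$variant, x$c, x$se["c"], x$x0, x$se["x0"], x$rss,
    if (x$flagged) "  [x0 out of range]" else ""))
  invisible(x)
}

#' @export
tidy.tpm_fit <- function(x, ...) {
  tibble(term = c("c", "x0"), estimate = c(x$c, x$x0),
         std.error = unname(x$se[c("c", "x0")]))
}

#' @export
glance.tpm_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data), converged = x$converged,
         flagged = x$flagged, variant = x$variant)
}

#' Site encounter probabilities of the tethered enzyme
#'
#' Normalises the translated-Gaussian density over a set of site distances:
#' `P_i = density(R_i) / sum_j density(R_j)`. Independent of the amplitude
#' `c`. At the Tar site distances with the fitted `x0 = 10.5` nm this
#' reproduces the encounter-matched probabilities
#' (0.781, 0.186, 0.031, 0.003).
#'
#' @param distances Site distances `R_i` in nm, in methylation order.
#' @param params A [tpm_params()] object.
#' @return Numeric vector of probabilities summing to 1.
#' @examples
#' encounter_probabilities(tar_site_distances()$R_nm)
#' @export
encounter_probabilities <- function(distances, params = tpm_params()) {
  if (length(distances) < 1) abort("At least one distance is required.")
  d <- tpm_density(distances, params)
  d / sum(d)
}

#' Fit the chain-length dependence of the translation x0
#'
#' Ordinary least squares of the fitted translation `x0` against tether
#' residue count, `x0 = slope * n_residues + intercept`. The published fit
#' over the four Tar constructs gives a slope of about 0.128 nm per residue
#' and an intercept of about 6.0 nm (of the order of the CheR molecule
#' size).
#'
#' @param data Data frame with columns `n_residues` and `x0_nm`; at least 2
#'   distinct lengths.
#' @return An object of class `chainlength_fit` with `slope`, `intercept`,
#'   `se`, `fit`, `data`. Methods: [tidy()], [glance()].
#' @export
fit_x0_vs_chain_length <- function(data) {
  data <- as_tibble(data)
  if (!all(c("n_residues", "x0_nm") %in% names(data))) {
    abort("`data` must have columns `n_residues` and `x0_nm`.")
  }
  if (length(unique(data$n_residues)) < 2) {
    abort("At least two distinct chain lengths are required.")
  }
  fit <- lm(x0_nm ~ n_residues, data = data)
  s <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  structure(
    list(slope = unname(coef(fit)["n_residues"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         se = c(slope = s["n_residues", "Std. Error"],
                intercept = s["(Intercept)", "Std. Error"]),
         fit = fit, data = data),
    class = "chainlength_fit"
  )
}

#' @export
print.chainlength_fit <- function(x, ...) {
  cat(sprintf("<chainlength_fit> x0 = %.4g nm/aa * n + %.4g nm (se %.2g, %.2g)\n",
              x$slope, x$intercept, x$se["slope"], x$se["intercept"]))
  invisible(x)
}

#' @export
tidy.chainlength_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         std.error = unname(x$se[c("slope", "intercept")]))
}

#' @export
glance.chainlength_fit <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, n = nrow(x$data))
}

#' Closed-form quadratic relation between ligand and methylation free energy
#'
#' Combining the MWC steady-state condition
#' `log(a*/(1-a*)) = -N (fm + fL)` with the TPM ratio model and the linear
#' site-distance relation `R = k m + R0` yields a quadratic relation
#' `fL = q2 fm^2 + q1 fm + f0` with
#' `q2 = 3 k^2 / (2 L_total b alpha^2 N)` and
#' `q1 = -1 + 3 (k/alpha) (R0 + k m0 - x0) / (L_total b N)`. Perfect
#' adaptation corresponds to `q2 = 0, q1 = -1`; with the Tar parameters the
#' coefficients are approximately 0.006 and -1.07, i.e. a nearly linear
#' relation of slope magnitude 1/1.07 = 0.93 between `fm` and `fL`.
#'
#' @param mwc An [mwc_params()] object (`alpha != 0`, `N > 0`).
#' @param geometry Either a `geometry_fit` or a named vector/list with `k`
#'   and `R0` (nm).
#' @param tpm A [tpm_params()] object.
#' @return A tibble with columns `q2`, `q1` and `implied_slope`, the slope
#'   `dfm/dfL` of the linearised relation at `fm = 0` (i.e. `1/q1`).
#' @examples
#' fl_fm_relation()
#' @export
fl_fm_relation <- function(mwc = mwc_params(), geometry = fit_site_distance(),
                           tpm = tpm_params()) {
  if (mwc$alpha == 0) abort("`alpha` must be nonzero.")
  k <- if (inherits(geometry, "geometry_fit")) geometry$k else geometry[["k"]]
  R0 <- if (inherits(geometry, "geometry_fit")) geometry$R0 else geometry[["R0"]]
  Lb <- tpm$L_total * tpm$b
  q2 <- 3 * k^2 / (2 * Lb * mwc$alpha^2 * mwc$N)
  q1 <- -1 + 3 * (k / mwc$alpha) * (R0 + k * mwc$m0 - tpm$x0) / (Lb * mwc$N)
  tibble(q2 = q2, q1 = q1, implied_slope = 1 / q1)
}
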