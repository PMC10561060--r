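#' Plot a FRET trace
#'
#' Raw ratio against time with stimulus additions/removals marked as
#' vertical lines.
#'
#' @param object A [fret_trace()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_trace <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_s, y = .data$ratio)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_vline(data = object$events,
                        ggplot2::aes(xintercept = .data$t_s,
                                     linetype = .data$kind),
                        colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "FRET ratio (a.u.)",
                  title = sprintf("FRET trace (%s)", object$strain)) +
    ggplot2::theme_minimal()
}

#' Plot a TPM fit
#'
#' Measured steady-state ratios against site distance with the fitted
#' translated-Gaussian curve.
#'
#' @param object A `tpm_fit` from [fit_tpm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tpm_fit <- function(object, ...) {
  grid <- tibble(R_nm = seq(min(object$data$R_nm) * 0.8,
                            max(object$data$R_nm) * 1.1, length.out = 200))
  grid$ratio <- object$c *
    exp(-3 * (grid$R_nm - object$x0)^2 / (2 * object$L_total * object$b))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$R_nm, y = .data$ratio)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "site distance R (nm)",
                  y = if (object$variant == "linear") "a*/(1-a*)" else "a*^3/(1-a*)",
                  title = sprintf("TPM fit: x0 = %.2f nm", object$x0)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated adaptation trajectory
#'
#' Activity and methylation level against time for a trajectory from
#' [simulate_adaptation()].
#'
#' @param trajectory A tibble with columns `t_s`, `m`, `a` (and `L_mM`).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  long <- trajectory |>
    select("t_s", "m", "a") |>
    tidyr::pivot_longer(c("m", "a"), names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(a = "activity a", m = "methylation m"))) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot multisite saturation curves
#'
#' `P(m = n)` against `theta` (log scale) for each case of a
#' [scan_cases()] table, the saturation counterpart of a dose-response
#' curve.
#'
#' @param scan A tibble from [scan_cases()].
#' @return A ggplot object.
#' @export
plot_saturation_curves <- function(scan) {
  pm_top <- rev(grep("^pm[0-9]+$", names(scan), value = TRUE))[1]
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$theta, y = .data[[pm_top]],
                                     colour = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(theta), y = "P(all sites methylated)") +
    ggplot2::theme_minimal()
}
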