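#' End-to-end synthetic step-response pipeline
#'
#' Runs the full analysis chain on synthetic data: generate a saturating
#' full cycle and extract the pre-stimulus activity `a0`; generate one
#' step-response experiment per dose and extract the adapted activity `a*`;
#' invert each `a*` to a methylation level and a site distance via the
#' linear geometry; fit the translated-Gaussian TPM model to the
#' steady-state ratios to recover `(c, x0)`; and fit the `fm`--`fL`
#' precision relation. Only the generators see the hidden truth; every
#' estimate comes from the trace-processing chain.
#'
#' @param truth A [ground_truth()] object.
#' @param doses Step doses, mM (at least 3 distinct).
#' @param duration_add Step duration, s; long enough for the slowest dose
#'   to reach steady state.
#' @param seed Base seed; trace `i` uses `seed + i`.
#' @param variant Adaptation variant used for the ratio transform in the
#'   TPM fit; defaults to the truth's.
#' @return A list of class `tpm_pipeline`: `a0` (estimate), `steps`
#'   (per-dose tibble with `L_mM`, `a_star`, `m`, `R_nm`, `ratio`),
#'   `tpm_fit` (a [fit_tpm()] result), `x0`, `precision` (from
#'   [precision_pairs()]) and `slope`.
#' @examples
#' \donttest{
#' truth <- ground_truth(noise_sd = 0)
#' run_tpm_pipeline(truth, doses = c(0.005, 0.025, 0.1), duration_add = 3000)
#' }
#' @export
run_tpm_pipeline <- function(truth, doses = c(0.005, 0.01, 0.025, 0.1, 0.25),
                             duration_add = 8000, seed = NULL,
                             variant = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(unique(doses)) < 3) abort("At least 3 distinct doses are required.")
  seed <- seed %||% truth$seed
  variant <- variant %||% truth$variant

  # a0 from a full saturating cycle: add, adapt long, remove
  cycle <- generate_step_experiment(truth, L_step = 0.25, t_add = 200,
                                    duration_add = 2000,
                                    calibration_pulse = FALSE,
                                    t_post = 150, seed = seed)
  a0_hat <- extract_a0(cycle)

  steps <- imap(as.list(sort(doses)), function(L, i) {
    tr <- generate_step_experiment(truth, L_step = L, t_add = 200,
                                   duration_add = duration_add,
                                   seed = seed + i)
    a_star <- suppressWarnings(
      adapted_activity(tr, a0 = a0_hat, event_index = 2)
    )
    tibble(L_mM = L, a_star = a_star)
  }) |> list_rbind()

  prec <- precision_pairs(steps, truth$mwc)
  steps <- prec$pairs |>
    mutate(R_nm = truth$k * .data$m + truth$R0,
           ratio = switch(variant,
                          linear = .data$a_star / (1 - .data$a_star),
                          cubic = .data$a_star^3 / (1 - .data$a_star)))
  fit <- fit_tpm(steps[c("R_nm", "ratio")], L_total = truth$tpm$L_total,
                 b = truth$tpm$b, variant = variant)
  structure(
    list(a0 = a0_hat, steps = steps, tpm_fit = fit, x0 = fit$x0,
         precision = prec, slope = prec$slope, truth_seed = seed),
    class = "tpm_pipeline"
  )
}

#' @export
print.tpm_pipeline <- function(x, ...) {
  cat(sprintf("<tpm_pipeline> %d doses: a0 = %.3f, x0 = %.3f nm, fm~fL slope = %.4f\n",
              nrow(x$steps), x$a0, x$x0, x$slope))
  invisible(x)
}

#' Fit report for a TPM dataset
#'
#' Convenience wrapper running [fit_tpm()] on a ratio table and returning a
#' tidy one-row summary alongside the fit object.
#'
#' @inheritParams fit_tpm
#' @return A list with `fit` (the `tpm_fit`) and `summary` (one-row tibble
#'   with `c`, `x0`, their standard errors, `rss`, `variant`).
#' @export
tpm_fit_report <- function(data, L_total = 12.24, b = 0.76,
                           variant = c("linear", "cubic")) {
  variant <- match.arg(variant)
  fit <- fit_tpm(data, L_total = L_total, b = b, variant = variant)
  list(fit = fit,
       summary = tibble(c = fit$c, c_se = unname(fit$se["c"]),
                        x0_nm = fit$x0, x0_se = unname(fit$se["x0"]),
                        rss = fit$rss, variant = variant))
}
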