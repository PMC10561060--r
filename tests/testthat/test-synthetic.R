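test_that("ground truth derives self-consistent rates from a0", {
  truth <- ground_truth(noise_sd = 0)
  expect_equal(receptor_activity(truth$m_pre, 0, truth$mwc), truth$a0,
               tolerance = 1e-9)
  mod <- make_tpm_modifier(truth)
  # steady state: kR(m_pre) (1 - a0) = kB a0
  expect_equal(truth$kin$kR * mod(truth$m_pre) * (1 - truth$a0),
               truth$kin$kB * truth$a0, tolerance = 1e-9)
  # explicit kin: m_pre found by root finding instead
  truth2 <- ground_truth(kin = adaptation_params(kR = 0.002, kB = 0.004),
                         noise_sd = 0)
  mod2 <- make_tpm_modifier(truth2)
  a2 <- receptor_activity(truth2$m_pre, 0, truth2$mwc)
  expect_equal(truth2$kin$kR * mod2(truth2$m_pre) * (1 - a2),
               truth2$kin$kB * a2, tolerance = 1e-8)
})

test_that("the TPM rate modifier mirrors the encounter geometry", {
  truth <- ground_truth(noise_sd = 0)
  mod <- make_tpm_modifier(truth)
  expect_equal(mod(0), 1)
  # decreasing in m: the tether geometry keeps R(m) < x0 throughout
  m <- seq(0, 4, by = 0.25)
  expect_true(all(diff(mod(m)) < 0))
  # at site positions the modifier is proportional to the encounter weights
  g <- tar_site_distances()
  m_sites <- (g$R_nm - truth$R0) / truth$k
  w <- mod(m_sites)
  P <- encounter_probabilities(g$R_nm, truth$tpm)
  expect_equal(w / sum(w), P, tolerance = 1e-12)
  # flat geometry: modifier identically one
  flat <- ground_truth(geometry = c(k = 0, R0 = 5), noise_sd = 0)
  expect_equal(make_tpm_modifier(flat)(m), rep(1, length(m)))
})

test_that("generators are pure functions of truth and seed", {
  truth <- ground_truth()
  tr1 <- generate_step_experiment(truth, 0.025, seed = 99)
  tr2 <- generate_step_experiment(truth, 0.025, seed = 99)
  expect_identical(tr1$data, tr2$data)
  tr3 <- generate_step_experiment(truth, 0.025, seed = 100)
  expect_false(identical(tr1$data$ratio, tr3$data$ratio))
  dr1 <- generate_dose_response(truth, c(0.01, 0.1), seed = 4)
  dr2 <- generate_dose_response(truth, c(0.01, 0.1), seed = 4)
  expect_identical(dr1, dr2)
})

test_that("noise-free step experiments are recovered exactly downstream", {
  truth <- ground_truth(noise_sd = 0)
  tr <- generate_step_experiment(truth, L_step = 0.005, duration_add = 1500)
  # the sub-saturating step gets a trailing saturating calibration pulse
  expect_equal(nrow(tr$events), 4)
  a_star <- suppressWarnings(adapted_activity(tr, a0 = truth$a0, event_index = 2))
  hidden <- attr(tr, "truth")$trajectory
  a_true <- hidden$a[hidden$t_s == 1699]
  expect_equal(a_star, a_true, tolerance = 1e-3)
  # a saturating step needs no extra pulse
  tr_sat <- generate_step_experiment(truth, L_step = 0.25, duration_add = 600)
  expect_equal(nrow(tr_sat$events), 2)
})

test_that("zero-activity assays read back the generating rate curve", {
  truth <- ground_truth(noise_sd = 0)
  dts <- c(40, 100, 160, 220)
  traces <- generate_zero_activity_assay(truth, dts)
  res <- purrr::map(traces, removal_peak, a0 = truth$a0) |> purrr::list_rbind()
  expect_equal(res$delta_t, dts)
  rates <- zero_activity_rate(truth$m_pre, res$a_r, res$delta_t, truth$mwc)
  # rate decreases with the recovered methylation level
  expect_true(all(diff(rates$rate) < 0))
  # oracle: direct quadrature of dm/dt = kR(m) from m_pre over delta_t
  mod <- make_tpm_modifier(truth)
  for (i in seq_along(dts)) {
    m_oracle <- truth$m_pre
    dt <- 0.01
    for (s in seq(0, dts[i] - dt, by = dt)) {
      m_oracle <- m_oracle + dt * truth$kin$kR * mod(m_oracle)
    }
    expect_equal(rates$m_r[i], m_oracle, tolerance = 5e-3)
    # and the mean rate tracks the generating kR * modifier at m_r
    expect_lt(abs(rates$rate[i] / (truth$kin$kR * mod(rates$m_r[i])) - 1), 0.15)
  }
  # a wild-type-like flat geometry keeps the rate nearly constant
  flat <- ground_truth(geometry = c(k = 0, R0 = 7.86), noise_sd = 0,
                       kR0 = 0.0007)
  traces_f <- generate_zero_activity_assay(flat, dts, strain = "wild-type")
  # durations beyond the 114 s wild-type cap warn by design
  res_f <- suppressWarnings(
    purrr::map(traces_f, removal_peak, a0 = flat$a0) |> purrr::list_rbind()
  )
  rates_f <- zero_activity_rate(flat$m_pre, res_f$a_r, res_f$delta_t, flat$mwc)
  spread_wt <- diff(range(rates_f$rate)) / mean(rates_f$rate)
  expect_lt(spread_wt, 0.05)
  # a non-saturating concentration is rejected
  expect_error(generate_zero_activity_assay(truth, 100, L_sat = 0.001),
               "not saturating")
})

test_that("dose-response generation feeds the cluster-size fit", {
  truth <- ground_truth(noise_sd = 0)
  doses <- 10^seq(-2.3, -0.3, length.out = 12)
  dr <- generate_dose_response(truth, doses)
  expect_equal(dr$activity, receptor_activity(truth$m_pre, doses, truth$mwc))
  f <- fit_cluster_size(dr, mwc_params(N = 5))
  expect_equal(f$N, truth$mwc$N, tolerance = 1e-6)
  expect_error(generate_dose_response(truth, numeric(0)), "non-empty")
})
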