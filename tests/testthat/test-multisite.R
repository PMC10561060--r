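cases <- standard_cases()

test_that("stationary distribution equals the birth-death null-space oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    P <- rexp(n); P <- P / sum(P)
    theta <- 10^runif(1, -2, 3)
    cs <- multisite_case(P)
    expect_equal(stationary_distribution(theta, cs),
                 bd_stationary_oracle(theta, P), tolerance = 1e-12)
  }
})

test_that("stationary distribution handles the dose limits", {
  c1 <- cases$case1
  expect_equal(stationary_distribution(0, c1), c(1, 0, 0, 0, 0))
  expect_equal(stationary_distribution(1e12, c1), c(0, 0, 0, 0, 1),
               tolerance = 1e-9)
  expect_error(stationary_distribution(-1, c1), ">= 0")
  # rows of a vectorised call are normalised
  pm <- stationary_distribution(c(0.1, 1, 10, 100), c1)
  expect_equal(rowSums(pm), rep(1, 4), tolerance = 1e-12)
})

test_that("case probabilities are validated and renormalised defensively", {
  expect_warning(cs <- multisite_case(c(0.5, 0.5, 0.1)), "renormalising")
  expect_equal(sum(cs$P), 1)
  expect_error(multisite_case(c(-0.1, 1.1)), "non-negative")
})

test_that("the saturated probability is the equal-weight fifth at theta = 4", {
  # case 1 at theta = 4: all unnormalised weights equal 1
  expect_equal(pm_saturated(4, cases$case1), 1 / 5, tolerance = 1e-12)
  expect_equal(pm_saturated(0, cases$case1), 0)
  # strictly increasing in theta
  th <- 10^seq(-2, 4, length.out = 100)
  expect_true(all(diff(pm_saturated(th, cases$case4)) > 0))
})

test_that("threshold doses invert the saturation curve", {
  for (cs in cases) {
    for (target in c(0.1, 0.5, 0.9)) {
      th <- theta_at_saturation(target, cs)
      expect_equal(pm_saturated(th, cs), target, tolerance = 1e-9)
    }
  }
  expect_error(theta_at_saturation(0, cases$case1), "strictly in")
})

test_that("threshold doses and Hill coefficients match the published table", {
  rep <- multisite_report(cases)
  # theta_0.1: published 3.0, 5.3, 3.2, 65.6 (case 2 is a known ~2% print
  # deviation: computed ~5.2); asserted per element within 3%
  expect_true(all(abs(rep$theta_01 / c(3.0, 5.3, 3.2, 65.6) - 1) < 0.03))
  # Hill coefficients: published 1.7, 1.3, 2.2, 1.1, within 3%
  expect_true(all(abs(rep$hill / c(1.7, 1.3, 2.2, 1.1) - 1) < 0.03))
  # mean methylation at threshold: published 1.4, 2.2, 0.9, 2.8, within 3%
  expect_true(all(abs(rep$m_01 / c(1.4, 2.2, 0.9, 2.8) - 1) < 0.03))
  # published rankings
  expect_true(rep$theta_01[4] > rep$theta_01[2])
  expect_true(rep$theta_01[2] > max(rep$theta_01[c(1, 3)]))
  expect_true(all(diff(rep$hill[c(4, 2, 1, 3)]) > 0))
})

test_that("a single-site system is an exact hyperbola with H = 1", {
  cs1 <- multisite_case(1)
  # pm1 = theta / (1 + theta): brute-force thresholds 1/9 and 9
  expect_equal(theta_at_saturation(0.1, cs1), 1 / 9, tolerance = 1e-9)
  expect_equal(theta_at_saturation(0.9, cs1), 9, tolerance = 1e-9)
  expect_equal(hill_coefficient(cs1), 1, tolerance = 1e-9)
})

test_that("moments behave and the mean is monotone in theta", {
  ms0 <- mean_and_sigma(0, cases$case1)
  expect_equal(ms0$mean_m, 0)
  expect_equal(ms0$sigma_m, 0)
  th <- 10^seq(-2, 4, length.out = 200)
  ms <- mean_and_sigma(th, cases$case4)
  expect_true(all(diff(ms$mean_m) > 0))
  expect_true(all(ms$mean_m >= 0 & ms$mean_m <= 4))
  # target -> 1 pushes the threshold mean toward 4
  expect_gt(m_threshold(cases$case1, target = 0.999), 3.9)
})

test_that("the matched case is sharply peaked at mid-range methylation", {
  # solve theta so that <m> = 2 for case 4, then inspect the distribution
  th2 <- uniroot(function(lt) mean_and_sigma(exp(lt), cases$case4)$mean_m - 2,
                 c(-5, 15), tol = 1e-12)$root
  pm <- stationary_distribution(exp(th2), cases$case4)
  expect_equal(which.max(pm), 3)          # peak at m = 2
  expect_lt(pm[1], 0.02)                  # near-zero at m = 0 (computed 0.019)
  expect_lt(pm[5], 0.01)                  # near-zero at m = 4 (computed 0.008)
  # an order of magnitude below the boundary mass of the other cases
  for (other in cases[c("case1", "case2", "case3")]) {
    th_o <- uniroot(function(lt) mean_and_sigma(exp(lt), other)$mean_m - 2,
                    c(-5, 15), tol = 1e-12)$root
    pm_o <- stationary_distribution(exp(th_o), other)
    expect_gt(pm_o[1], 4 * pm[1])
    expect_gt(pm_o[5], 4 * pm[5])
  }
  # case 3 spreads more than case 4 at every mean level
  for (mbar in c(0.5, 1, 2, 3, 3.5)) {
    s <- vapply(cases[c("case3", "case4")], function(cs) {
      th <- uniroot(function(lt) mean_and_sigma(exp(lt), cs)$mean_m - mbar,
                    c(-10, 20), tol = 1e-12)$root
      mean_and_sigma(exp(th), cs)$sigma_m
    }, numeric(1))
    expect_gt(s[["case3"]], s[["case4"]])
  }
})

test_that("scan_cases tabulates normalised distributions for plotting", {
  scan <- scan_cases(10^seq(-1, 3, length.out = 41), cases)
  expect_equal(nrow(scan), 4 * 41)
  pm_cols <- paste0("pm", 0:4)
  expect_true(all(pm_cols %in% names(scan)))
  expect_equal(rowSums(as.matrix(scan[pm_cols])), rep(1, nrow(scan)),
               tolerance = 1e-12)
  expect_error(scan_cases(1, list()), "at least one")
  # a five-site geometry-driven case works through the same machinery
  P5 <- encounter_probabilities(tsr_site_distances()$R_nm,
                                tpm_params(L_total = contour_length(30)))
  cs5 <- multisite_case(P5, "Tsr five-site")
  scan5 <- scan_cases(c(1, 10, 100), cs5)
  expect_true("pm5" %in% names(scan5))
  expect_equal(rowSums(as.matrix(scan5[paste0("pm", 0:5)])), rep(1, 3),
               tolerance = 1e-12)
})
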