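test_that("noiseless planted breakpoints are recovered to grid resolution", {
  tr <- make_heating_trace(psi = 45)
  fit <- fit_tcrit(tr)
  expect_lt(abs(fit$t_crit - 45), 0.1 + 1e-9)
  expect_gt(abs(fit$slope_fast), abs(fit$slope_slow))
  expect_false(fit$slow_fast_warning)
})

test_that("a pure straight line yields no breakpoint", {
  temp <- seq(20, 65, by = 0.1)
  tr <- list(sample_id = "line", species_id = "spA", treatment = "control",
             direction = "heating", temperature = temp,
             f0 = 1 + 0.01 * (temp - 20))
  expect_error(fit_tcrit(tr), "no breakpoint")
})

test_that("breakpoints survive realistic noise and converge as noise vanishes", {
  withr::with_seed(89, {
    errs_by_sd <- vapply(c(0.05, 0.01, 0.001), function(sdv) {
      mean(abs(vapply(1:20, function(i) {
        fit_tcrit(make_heating_trace(psi = 45, noise_sd = sdv,
                                     s_slow = 0.002, s_fast = 0.08))$t_crit
      }, numeric(1)) - 45))
    }, numeric(1))
  })
  expect_true(all(diff(errs_by_sd) < 0))   # estimator consistency
  expect_lt(errs_by_sd[3], 0.1 + 1e-9)
  withr::with_seed(97, {
    errs <- vapply(1:30, function(i) {
      abs(fit_tcrit(make_heating_trace(psi = 45, noise_sd = 0.02,
                                       s_slow = 0.002,
                                       s_fast = 0.08))$t_crit - 45)
    }, numeric(1))
  })
  expect_gte(mean(errs < 0.5), 0.95)
})

test_that("refining the breakpoint grid never worsens the fit", {
  withr::with_seed(101, {
    tr <- make_heating_trace(psi = 43.17, noise_sd = 0.02, s_slow = 0.002,
                             s_fast = 0.08)
  })
  rss_coarse <- fit_tcrit(tr, grid_step = 0.2)$rss
  rss_fine <- fit_tcrit(tr, grid_step = 0.1)$rss
  rss_finer <- fit_tcrit(tr, grid_step = 0.05)$rss
  expect_lte(rss_fine, rss_coarse + 1e-9)
  expect_lte(rss_finer, rss_fine + 1e-9)
})

test_that("breakpoints are equivariant under temperature shifts", {
  withr::with_seed(103, {
    tr <- make_heating_trace(psi = 45, noise_sd = 0.01, s_slow = 0.002,
                             s_fast = 0.08)
  })
  shift <- 4
  tr2 <- tr; tr2$temperature <- tr$temperature + shift
  expect_equal(fit_tcrit(tr2)$t_crit, fit_tcrit(tr)$t_crit + shift,
               tolerance = 1e-6)
})

test_that("cooling ramps are analyzed on the negated axis", {
  temp <- seq(20, -25, by = -0.1)
  f0 <- 1 + 0.08 * pmax(-temp - 8, 0)  # fast rise below -8 degrees C
  tr <- list(sample_id = "c1", species_id = "spA", treatment = "control",
             direction = "cooling", temperature = temp, f0 = f0)
  expect_lt(abs(fit_tcrit(tr)$t_crit - (-8)), 0.1 + 1e-9)
})

test_that("Tmax is the smoothed F0 argmax with the documented tie and edge rules", {
  tr <- make_heating_trace(psi = 45, peak = 55, s_slow = 0.002, s_fast = 0.08)
  expect_equal(extract_tmax(tr)$t_max, 55, tolerance = 0.2)

  # two equal maxima at 54 and 56: tie resolves toward Tcrit's side (54)
  temp <- seq(20, 65, by = 0.5)
  f0 <- 1 + 0.05 * pmax(temp - 45, 0)
  f0 <- f0 - 0.1 * pmax(temp - 54, 0) + 0.1 * pmax(temp - 55, 0)
  f0[temp > 56] <- f0[temp > 56] - 0.2 * (temp[temp > 56] - 56)
  tie <- list(sample_id = "tie", species_id = "spA", treatment = "control",
              direction = "heating", temperature = temp, f0 = f0)
  expect_equal(f0[temp == 54], f0[temp == 56])  # the construction really is tied
  expect_equal(extract_tmax(tie, smoothing_window = 1)$t_max, 54)

  rising <- make_heating_trace(psi = 45)  # monotone to the last point
  expect_warning(out <- extract_tmax(rising), "endpoint")
  expect_true(out$endpoint_flag)
})

test_that("acclimation deltas follow the arm-difference sign conventions", {
  traits <- data.frame(
    sample_id = paste0("s", 1:8),
    species_id = "spA",
    treatment = c("hot", "hot", "control", "control",
                  "cold", "cold", "control", "control"),
    direction = c(rep("heating", 4), rep("cooling", 4)),
    t_crit = c(48, 48, 45, 45, -6, -6, -9, -9),
    t_max = c(56, 56, 53, 53, -13, -13, -16, -16))
  d <- acclimation_deltas(traits)
  expect_equal(d$delta[d$trait == "Tcrit_hot"], 3)    # gained heat tolerance
  expect_equal(d$delta[d$trait == "Tcrit_cold"], 3)   # toward 0: worsened cold
  expect_equal(d$delta[d$trait == "Tmax_hot"], 3)
  expect_equal(d$delta[d$trait == "Tmax_cold"], 3)

  # equal means give zero delta; a missing arm drops the species with warning
  traits0 <- traits; traits0$t_crit[1:2] <- 45; traits0$t_max[1:2] <- 53
  d0 <- acclimation_deltas(traits0)
  expect_equal(d0$delta[d0$trait == "Tcrit_hot"], 0)
  no_cold <- traits[traits$treatment != "cold", ]
  warns <- capture_warnings(d2 <- acclimation_deltas(no_cold))
  expect_length(warns, 2)  # both cold traits reported missing
  expect_match(warns, "missing an arm", all = TRUE)
  expect_false("Tcrit_cold" %in% d2$trait)
})

test_that("trace QC deduplicates temperatures and rejects short traces", {
  tr <- make_heating_trace(psi = 45)
  tr$temperature <- c(tr$temperature, tr$temperature[100])
  tr$f0 <- c(tr$f0, tr$f0[100] + 0.5)
  fit <- fit_tcrit(tr)  # duplicate averaged away, still fits
  expect_lt(abs(fit$t_crit - 45), 0.2)
  short <- list(sample_id = "s", species_id = "spA", treatment = "control",
                direction = "heating", temperature = 1:10, f0 = rep(1, 10))
  expect_error(fit_tcrit(short), "20 usable points")
})
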