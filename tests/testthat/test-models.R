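# metadata for the full 20-species, 188-library design
full_design_metadata <- function() {
  sp <- thermoresp:::default_species_design()
  do.call(rbind, lapply(seq_len(nrow(sp)), function(i)
    thermoresp:::species_library_plan(sp[i, ])))
}

test_that("the treatment mixed model reports the residual df convention", {
  md <- full_design_metadata()
  expect_equal(nrow(md), 188)
  withr::with_seed(61, {
    u <- stats::setNames(rnorm(20, 0, 1), unique(md$species_id))
    y <- u[md$species_id] + 0.5 * (md$treatment == "hot") + rnorm(188)
  })
  fit <- fit_treatment_lmm(data.frame(estimate = unname(y),
                                      library_id = md$library_id), md)
  # 188 obs - 20 species - (3 levels - 1) = 166
  expect_equal(unique(fit$contrasts$df), 166)
  expect_equal(fit$n_species, 20)
  expect_setequal(fit$contrasts$contrast, c("cold", "hot"))
  expect_true(fit$icc > 0 && fit$icc < 1)
  expect_equal(fit$icc,
               fit$sigma2_species / (fit$sigma2_species + fit$sigma2_residual))
  # Satterthwaite mode yields positive, non-integer-constrained df
  fit2 <- fit_treatment_lmm(data.frame(estimate = unname(y),
                                       library_id = md$library_id), md,
                            df_mode = "satterthwaite")
  expect_true(all(fit2$contrasts$df > 0))
  expect_equal(fit2$contrasts$estimate, fit$contrasts$estimate)
})

test_that("with no species variance the contrasts equal OLS group-mean differences", {
  md <- full_design_metadata()
  withr::with_seed(67, {
    y <- 2 + 1.5 * (md$treatment == "hot") - 0.7 * (md$treatment == "cold") +
      rnorm(188, sd = 0.3)
  })
  fit <- fit_treatment_lmm(data.frame(estimate = y, library_id = md$library_id),
                           md)
  # independent OLS oracle with the same control reference level
  dat <- data.frame(y = y, treatment = factor(md$treatment,
                                              c("control", "cold", "hot")))
  ols <- stats::lm(y ~ treatment, data = dat)
  expect_equal(stats::setNames(fit$contrasts$estimate, NULL),
               unname(stats::coef(ols)[c("treatmentcold", "treatmenthot")]),
               tolerance = 1e-6)
  expect_true(fit$singular)
  expect_equal(fit$icc, 0)  # collapsed species component is reported as 0
})

test_that("t statistics are invariant under affine response rescaling", {
  md <- full_design_metadata()
  withr::with_seed(71, {
    u <- stats::setNames(rnorm(20), unique(md$species_id))
    y <- u[md$species_id] + (md$treatment == "hot") + rnorm(188)
  })
  resp <- data.frame(estimate = unname(y), library_id = md$library_id)
  f1 <- fit_treatment_lmm(resp, md)
  resp2 <- resp; resp2$estimate <- 100 * resp2$estimate + 7
  f2 <- fit_treatment_lmm(resp2, md)
  expect_equal(f1$contrasts$t, f2$contrasts$t, tolerance = 1e-6)
  expect_equal(f1$icc, f2$icc, tolerance = 1e-6)
  expect_equal(f1$marginal_r2, f2$marginal_r2, tolerance = 1e-6)
})

test_that("mixed-model variance components recover planted values", {
  # planted species SD^2 = 1, residual SD^2 = 3 -> ICC = 0.25
  md <- full_design_metadata()
  withr::with_seed(73, {
    iccs <- replicate(30, {
      u <- stats::setNames(rnorm(20, 0, 1), unique(md$species_id))
      y <- u[md$species_id] + rnorm(188, 0, sqrt(3))
      fit_treatment_lmm(data.frame(estimate = unname(y),
                                   library_id = md$library_id), md)$icc
    })
  })
  expect_lt(abs(mean(iccs) - 0.25), 0.05)
})

test_that("the mixed model rejects degenerate designs", {
  md1 <- make_metadata(treatments = c("control", "cold", "hot"))
  expect_error(fit_treatment_lmm(
    data.frame(estimate = 1:3, library_id = md1$library_id), md1), "2 species")
  md2 <- rbind(make_metadata("spA", rep("control", 3)),
               make_metadata("spB", rep("control", 3)))
  expect_error(fit_treatment_lmm(
    data.frame(estimate = rnorm(6), library_id = md2$library_id), md2),
    "treatment")
})

test_that("biome models match the OLS oracle and handle exact fits", {
  fc_eq <- data.frame(species_id = paste0("sp", 1:6), estimate = rep(0.4, 6))
  biomes <- stats::setNames(rep(c("arid", "alpine", "temperate"), each = 2),
                            paste0("sp", 1:6))
  f0 <- suppressWarnings(fit_biome_lm(fc_eq, biomes))  # zero-residual edge case
  expect_equal(f0$r_squared, 0)
  expect_equal(f0$p_value, 1)

  fc_exact <- data.frame(species_id = paste0("sp", 1:6),
                         estimate = rep(c(-1, 0, 1), each = 2))
  f1 <- suppressWarnings(fit_biome_lm(fc_exact, biomes))
  expect_equal(f1$r_squared, 1)

  withr::with_seed(79, {
    fc <- data.frame(species_id = paste0("sp", 1:6),
                     estimate = rnorm(6) + rep(c(0, 0.5, 1), each = 2))
  })
  f2 <- fit_biome_lm(fc, biomes)
  oracle <- summary(stats::lm(fc$estimate ~ factor(rep(c("arid", "alpine",
                                                         "temperate"), each = 2))))
  expect_equal(f2$r_squared, oracle$r.squared)
  expect_equal(f2$p_value,
               unname(stats::pf(oracle$fstatistic[1], oracle$fstatistic[2],
                                oracle$fstatistic[3], lower.tail = FALSE)))
  expect_equal(f2$groups$mean[f2$groups$biome == "arid"],
               mean(fc$estimate[1:2]))

  one_biome <- stats::setNames(rep("arid", 6), paste0("sp", 1:6))
  expect_error(fit_biome_lm(fc, one_biome), "2 biomes")
  # a single-species biome is flagged, not dropped
  biomes2 <- stats::setNames(c("arid", rep("alpine", 5)), paste0("sp", 1:6))
  f3 <- fit_biome_lm(fc, biomes2)
  expect_equal(f3$flagged_biomes, "arid")
})

test_that("acclimation models report slope inference and FC summaries", {
  fc <- data.frame(species_id = paste0("sp", 1:8),
                   estimate = seq(-0.7, 0.7, length.out = 8))
  acc <- data.frame(species_id = paste0("sp", 1:8),
                    delta = 3 + 2 * fc$estimate)  # perfectly collinear
  fit <- suppressWarnings(fit_acclimation_lm(acc, fc, trait = "Tcrit_hot",
                                             set_id = "GO:0000001", min_n = 12))
  expect_equal(fit$adj_r_squared, 1)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(fit$slope, 2)
  expect_equal(fit$fc_median, median(fc$estimate))
  expect_equal(fit$fc_min, -0.7); expect_equal(fit$fc_max, 0.7)
  expect_equal(fit$min_n, 12)

  const_fc <- data.frame(species_id = paste0("sp", 1:8), estimate = rep(0.2, 8))
  expect_error(fit_acclimation_lm(acc, const_fc), "constant")
  expect_error(fit_acclimation_lm(acc[1:3, ], fc[1:3, ]), "4 species")
})

test_that("regression slope confidence intervals reach nominal coverage", {
  # planted slope at the study's species count; 95% CI coverage over replicates
  withr::with_seed(83, {
    hits <- replicate(500, {
      fc <- data.frame(species_id = paste0("sp", 1:20), estimate = rnorm(20, 0, 0.4))
      acc <- data.frame(species_id = paste0("sp", 1:20),
                        delta = 1.5 * fc$estimate + rnorm(20, 0, 1))
      fit <- fit_acclimation_lm(acc, fc)
      ci <- stats::confint(fit$fit)["estimate", ]
      ci[1] <= 1.5 && 1.5 <= ci[2]
    })
  })
  expect_gte(mean(hits), 0.94 - 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("result ranking is stable, directional and tie-broken by set id", {
  res <- data.frame(set_id = c("GO:3", "GO:1", "GO:2", "GO:4"),
                    adj_r_squared = c(0.1, 0.4, 0.2, 0.4),
                    t = c(1, -3, 2, 0.5),
                    p_value = c(0.5, 0.01, 0.2, 0.01))
  by_r2 <- rank_results(res, by = "adj_r2")
  expect_equal(by_r2$set_id, c("GO:1", "GO:4", "GO:2", "GO:3"))  # tie -> lexicographic
  by_t <- rank_results(res, by = "t")
  expect_equal(by_t$set_id[1], "GO:1")  # |t| descending
  by_p <- rank_results(res, by = "p", top_k = 2, fdr = TRUE)
  expect_equal(nrow(by_p), 2)
  expect_true("p_adjust" %in% names(by_p))
})
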