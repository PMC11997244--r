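test_that("boot-strapped median handles the degenerate and exact cases", {
  expect_equal(bootstrap_median(rep(3.7, 6), 3, 100, seed = 1), 3.7)
  # subset = full set: every resample is the sample median
  expect_equal(bootstrap_median(1:5, 5, 100, seed = 1), 3)
  expect_error(bootstrap_median(1:4, 5, 100, seed = 1), "infeasible")
  expect_error(bootstrap_median(c(1, NA, 3), 2, 10, seed = 1), "finite")
})

test_that("Monte-Carlo estimate agrees with the exhaustive subset-median oracle", {
  # {1..5} choose 3: medians of the 10 subsets average exactly 3.0
  expect_equal(exact_subset_median_mean(1:5, 3), 3)
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(3:8, 1)
      k <- sample(seq_len(min(n - 1, 5)), 1)
      vals <- rnorm(n, sd = 5)
      exact <- exact_subset_median_mean(vals, k)
      # exact SD of the subset-median distribution for the MC tolerance
      meds <- apply(utils::combn(n, k), 2, function(ix) median(vals[ix]))
      se <- sd(meds) / sqrt(10000)
      mc <- bootstrap_median(vals, k, 10000, seed = i)
      expect_lt(abs(mc - exact), max(3 * se, 1e-12))
    }
  })
})

test_that("estimates are deterministic, bounded and permutation invariant", {
  withr::with_seed(23, v <- rexp(15, 0.2))
  a <- bootstrap_median(v, 7, 500, seed = 99)
  expect_identical(a, bootstrap_median(v, 7, 500, seed = 99))
  expect_gte(a, min(v)); expect_lte(a, max(v))
  # estimate variance shrinks roughly like 1/B
  est <- function(B, seeds) vapply(seeds, function(s)
    bootstrap_median(v, 7, B, seed = s), numeric(1))
  v_small <- var(est(100, 1:40))
  v_large <- var(est(1600, 41:80))
  expect_lt(v_large, v_small / 4)  # 16x resamples, allow generous slack
})

test_that("per-library GO expression summaries are seeded per (term, species)", {
  m <- matrix(rep(c(2, 8), each = 12), nrow = 12,
              dimnames = list(paste0("g", 1:12), c("spA_L1", "spA_L2")))
  expr <- list(spA = make_expr(m))
  md <- make_metadata(treatments = c("control", "hot"),
                      library_ids = c("spA_L1", "spA_L2"))
  catalog <- structure(list(
    go_table = data.frame(set_id = "GO:0000001", set_type = "go",
                          species_id = "spA", n_members = 12L,
                          retained = TRUE, subset_size = 9L),
    go_members = list(`GO:0000001` = list(spA = paste0("g", 1:12))),
    og_table = NULL, og_members = list(), species_universe = "spA"),
    class = "geneset_catalog")
  out <- go_expression_per_library(expr, catalog, md, n_resamples = 100, seed = 1)
  expect_equal(out$estimate, c(2, 8))  # constant member TPMs pass through
  out2 <- go_expression_per_library(expr, catalog, md, n_resamples = 100, seed = 1)
  expect_identical(out, out2)

  # two terms: each term's estimate is unchanged when the other is removed,
  # because substreams are keyed by (seed, term, species)
  withr::with_seed(31, m2 <- matrix(rexp(24, 0.1), nrow = 12,
                                    dimnames = dimnames(m)))
  expr2 <- list(spA = make_expr(m2))
  cat2 <- catalog
  cat2$go_table <- rbind(cat2$go_table,
                         data.frame(set_id = "GO:0000002", set_type = "go",
                                    species_id = "spA", n_members = 6L,
                                    retained = TRUE, subset_size = 4L))
  cat2$go_members$`GO:0000002` <- list(spA = paste0("g", 1:6))
  both <- go_expression_per_library(expr2, cat2, md, n_resamples = 200, seed = 5)
  only1 <- go_expression_per_library(expr2, catalog, md, n_resamples = 200, seed = 5)
  expect_equal(both$estimate[both$set_id == "GO:0000001"], only1$estimate)

  bad_cat <- catalog
  bad_cat$go_members$`GO:0000001`$spA <- c(paste0("g", 1:12), "missing_gene")
  expect_error(go_expression_per_library(expr, bad_cat, md, 10, seed = 1),
               "missing")
})

test_that("species-level FC summaries recover planted medians", {
  fc <- data.frame(species_id = "spA", gene_id = paste0("g", 1:3),
                   contrast = "HvsN", log2fc = c(-1, 0, 1))
  catalog <- structure(list(
    go_table = data.frame(set_id = "GO:0000001", set_type = "go",
                          species_id = "spA", n_members = 3L,
                          retained = TRUE, subset_size = 3L),
    go_members = list(`GO:0000001` = list(spA = paste0("g", 1:3))),
    og_table = NULL, og_members = list(), species_universe = "spA"),
    class = "geneset_catalog")
  out <- go_fc_per_species(fc, catalog, n_resamples = 50, seed = 2)
  expect_equal(out$estimate[out$contrast == "HvsN"], 0)  # symmetric full set

  # a planted shifted median is recovered within Monte-Carlo tolerance
  withr::with_seed(41, {
    fc2 <- data.frame(species_id = "spA", gene_id = paste0("g", 1:40),
                      contrast = "HvsN", log2fc = rnorm(40, mean = 0.8, sd = 0.3))
  })
  cat2 <- catalog
  cat2$go_table$n_members <- 40L
  cat2$go_table$subset_size <- 30L
  cat2$go_members$`GO:0000001`$spA <- paste0("g", 1:40)
  out2 <- go_fc_per_species(fc2, cat2, n_resamples = 2000, seed = 3)
  expect_lt(abs(out2$estimate[out2$contrast == "HvsN"] - 0.8), 0.15)
})

test_that("orthogroup summaries are member means per library", {
  m <- matrix(c(2, 4, 10, 20), nrow = 2, byrow = FALSE,
              dimnames = list(c("g1", "g2"), c("spA_L1", "spA_L2")))
  catalog <- structure(list(
    go_table = NULL, go_members = list(),
    og_table = data.frame(set_id = "OG0000001", set_type = "orthogroup",
                          species_id = "spA", n_members = 2L, retained = TRUE,
                          n_present = 1L, n_expressed = 1L),
    og_members = list(OG0000001 = list(spA = c("g1", "g2"))),
    species_universe = "spA"), class = "geneset_catalog")
  out <- orthogroup_expression(list(spA = make_expr(m)), catalog,
                               make_metadata(treatments = c("control", "hot"),
                                             library_ids = c("spA_L1", "spA_L2")))
  expect_equal(out$estimate, c(3, 15))
})

test_that("z-scaling and group summaries follow their closed forms", {
  expect_equal(zscale(c(1, 2, 3)), c(-1, 0, 1))  # sample-SD convention
  withr::with_seed(53, x <- rnorm(10))
  expect_equal(zscale(5 * x + 2), zscale(x))     # affine invariance
  expect_error(zscale(rep(1, 5)), "distinct")

  summaries <- data.frame(set_id = "GO:0000001",
                          library_id = paste0("spA_L", 1:3),
                          species_id = "spA", estimate = c(2, 4, 9))
  md <- make_metadata(treatments = c("control", "control", "hot"))
  out <- treatment_group_summary(summaries, md, grouping = "treatment")
  ctl <- out[out$group == "control", ]
  expect_equal(ctl$mean, 3); expect_equal(ctl$se, 1); expect_equal(ctl$n, 2)
  expect_true(is.na(out$se[out$group == "hot"]))  # single-member group
})
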