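# Model fits: treatment mixed models with variance partitioning, biome linear
# models on species-level fold changes, and acclimation-association models.

#' Treatment linear mixed model with variance partitioning
#'
#' Fits `estimate ~ treatment + (1 | species_id)` by REML for one gene set,
#' with control as the reference level, and reports the cold and hot contrast
#' estimates with t statistics and p values, the species and residual
#' variance components, the ICC (proportion of variance between species) and
#' the marginal R2 of the treatment fixed effect.
#'
#' The default degrees of freedom convention is `n_obs - n_species -
#' (n_treatment_levels - 1)` — 166 for the full 188-library, 20-species,
#' 3-treatment design — with `df_mode = "satterthwaite"` available as an
#' alternative.
#'
#' @param responses data.frame with columns `estimate` and `library_id` (one
#'   row per library) for a single gene set.
#' @param metadata library metadata supplying `species_id` and `treatment`
#'   per library.
#' @param df_mode `"residual"` (default) or `"satterthwaite"`.
#' @param set_id optional gene-set label carried into the result.
#' @return a `thermo_lmm` object: list with `set_id`, `contrasts` (data.frame
#'   with estimate, se, t, df, p per contrast), `sigma2_species`,
#'   `sigma2_residual`, `icc`, `marginal_r2`, `n_obs`, `n_species`,
#'   `singular`.
#' @export
fit_treatment_lmm <- function(responses, metadata,
                              df_mode = c("residual", "satterthwaite"),
                              set_id = NA_character_) {
  df_mode <- match.arg(df_mode)
  dat <- responses
  idx <- match(dat$library_id, metadata$library_id)
  if (anyNA(idx)) stop_data("responses contain libraries absent from metadata")
  dat$species_id <- metadata$species_id[idx]
  dat$treatment <- factor(as.character(metadata$treatment[idx]),
                          levels = TREATMENT_LEVELS)
  n_species <- length(unique(dat$species_id))
  if (n_species < 2L)
    stop_data("mixed model needs >= 2 species (ICC undefined with %d)", n_species)
  if (length(unique(dat$treatment)) < 2L)
    stop_data("mixed model needs >= 2 treatment arms")
  fit <- suppressMessages(lme4::lmer(
    estimate ~ treatment + (1 | species_id), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_sp <- vc$vcov[vc$grp == "species_id"]
  sigma2_res <- vc$vcov[vc$grp == "Residual"]
  icc <- if (sigma2_sp + sigma2_res > 0) sigma2_sp / (sigma2_sp + sigma2_res) else 0
  if (singular) icc <- 0

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(dat)
  n_lev <- nlevels(droplevels(dat$treatment))
  keep <- grep("^treatment", names(beta))
  est <- beta[keep]; se <- se[keep]
  tval <- est / se
  if (df_mode == "residual") {
    dfree <- rep(n_obs - n_species - (n_lev - 1L), length(est))
  } else {
    lt <- lmerTest::as_lmerModLmerTest(fit)
    cs <- stats::coef(summary(lt))
    dfree <- cs[grep("^treatment", rownames(cs)), "df"]
  }
  pval <- 2 * stats::pt(-abs(tval), dfree)

  # marginal R2: fixed-effect fitted variance over total (Nakagawa-style)
  fitted_fix <- as.vector(stats::model.matrix(fit) %*% beta)
  var_fix <- stats::var(fitted_fix)
  marginal_r2 <- var_fix / (var_fix + sigma2_sp + sigma2_res)

  structure(list(
    set_id = set_id,
    contrasts = data.frame(
      contrast = sub("^treatment", "", names(est)),
      estimate = unname(est), se = unname(se), t = unname(tval),
      df = unname(dfree), p = unname(pval), stringsAsFactors = FALSE),
    sigma2_species = sigma2_sp, sigma2_residual = sigma2_res,
    icc = icc, marginal_r2 = marginal_r2,
    n_obs = n_obs, n_species = n_species, singular = singular,
    df_mode = df_mode
  ), class = "thermo_lmm")
}

#' @export
print.thermo_lmm <- function(x, ...) {
  cat(sprintf("Treatment mixed model%s: %d libraries, %d species\n",
              if (is.na(x$set_id)) "" else paste0(" [", x$set_id, "]"),
              x$n_obs, x$n_species))
  print(x$contrasts, row.names = FALSE, digits = 4)
  cat(sprintf("ICC = %.3f  marginal R2 = %.3f  (sigma2_sp = %.4g, sigma2_res = %.4g)%s\n",
              x$icc, x$marginal_r2, x$sigma2_species, x$sigma2_residual,
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}

#' @export
coef.thermo_lmm <- function(object, ...) {
  stats::setNames(object$contrasts$estimate, object$contrasts$contrast)
}

#' Biome linear model on species-level fold changes
#'
#' Fits `fc ~ biome` (fixed-effect one-way model) across species for one gene
#' set and contrast, reporting the multiple R2, the overall F-test p value,
#' and per-biome group means with standard errors.
#'
#' @param species_fc data.frame with `species_id` and `estimate` (one
#'   species-level fold change per species).
#' @param biomes named character vector or data.frame mapping species to
#'   biome.
#' @param set_id,contrast labels carried into the result.
#' @return a `biome_lm` object: list with `r_squared`, `p_value`, `groups`
#'   (mean/se/n per biome), `fit` (the underlying `lm`), plus labels.
#' @export
fit_biome_lm <- function(species_fc, biomes, set_id = NA_character_,
                         contrast = NA_character_) {
  if (is.data.frame(biomes))
    biomes <- stats::setNames(as.character(biomes$biome), biomes$species_id)
  dat <- species_fc
  dat$biome <- factor(biomes[dat$species_id], levels = BIOME_LEVELS)
  if (anyNA(dat$biome)) stop_data("species without biome assignment")
  dat$biome <- droplevels(dat$biome)
  if (nlevels(dat$biome) < 2L)
    stop_data("biome model needs >= 2 biomes")
  counts <- table(dat$biome)
  flagged <- names(counts)[counts < 2L]
  fit <- stats::lm(estimate ~ biome, data = dat)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  if (sm$r.squared < .Machine$double.eps^0.5 && is.na(p)) p <- 1
  groups <- do.call(rbind, lapply(levels(dat$biome), function(b) {
    v <- dat$estimate[dat$biome == b]
    data.frame(biome = b, mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(set_id = set_id, contrast = contrast,
                 r_squared = sm$r.squared, p_value = p,
                 groups = groups, flagged_biomes = flagged,
                 n_species = nrow(dat), fit = fit),
            class = "biome_lm")
}

#' @export
print.biome_lm <- function(x, ...) {
  cat(sprintf("Biome model%s%s: R2 = %.3f, p = %.4g (n = %d species)\n",
              if (is.na(x$set_id)) "" else paste0(" [", x$set_id, "]"),
              if (is.na(x$contrast)) "" else paste0(" ", x$contrast),
              x$r_squared, x$p_value, x$n_species))
  print(x$groups, row.names = FALSE, digits = 4)
  if (length(x$flagged_biomes))
    cat("single-species biome(s):", paste(x$flagged_biomes, collapse = ", "), "\n")
  invisible(x)
}

#' Acclimation association linear model
#'
#' Regresses a per-species thermal-tolerance acclimation delta on the
#' species-level fold change of one gene set (`acclimation ~ FC`), reporting
#' the slope t statistic and p value, the adjusted R2, the minimum member
#' count behind the fold-change summaries, and the median/min/max fold change
#' across species.
#'
#' @param acclimation data.frame with `species_id` and `delta` (trait units,
#'   degrees C).
#' @param species_fc data.frame with `species_id` and `estimate` (log2 FC).
#' @param trait label, e.g. `"Tcrit_hot"`.
#' @param set_id gene-set label.
#' @param min_n minimum member-gene count for the set (from the catalog).
#' @return an `acclimation_lm` object with `adj_r_squared`, `t`, `p_value`,
#'   `slope`, `n_species`, `min_n`, `fc_median`, `fc_min`, `fc_max`, `fit`.
#' @export
fit_acclimation_lm <- function(acclimation, species_fc,
                               trait = NA_character_, set_id = NA_character_,
                               min_n = NA_integer_) {
  dat <- merge(acclimation, species_fc, by = "species_id")
  if (nrow(dat) < 4L)
    stop_data("acclimation model needs >= 4 species with both trait and FC (got %d)",
              nrow(dat))
  if (stats::sd(dat$estimate) == 0)
    stop_data("fold changes are constant across species; slope undefined")
  fit <- stats::lm(delta ~ estimate, data = dat)
  cs <- stats::coef(summary(fit))
  structure(list(trait = trait, set_id = set_id,
                 slope = cs["estimate", "Estimate"],
                 t = cs["estimate", "t value"],
                 p_value = cs["estimate", "Pr(>|t|)"],
                 adj_r_squared = summary(fit)$adj.r.squared,
                 n_species = nrow(dat), min_n = min_n,
                 fc_median = stats::median(dat$estimate),
                 fc_min = min(dat$estimate), fc_max = max(dat$estimate),
                 fit = fit),
            class = "acclimation_lm")
}

#' @export
print.acclimation_lm <- function(x, ...) {
  cat(sprintf("Acclimation model%s ~ %s: adj R2 = %.3f, t = %.2f, p = %.4g (n = %d)\n",
              if (is.na(x$trait)) "" else paste0(" ", x$trait),
              if (is.na(x$set_id)) "FC" else x$set_id,
              x$adj_r_squared, x$t, x$p_value, x$n_species))
  invisible(x)
}

#' Rank fitted results
#'
#' Stable sort of a results table: descending adjusted R2 or |t|, or
#' ascending p, with ties broken by `set_id` so output is deterministic. An
#' optional Benjamini-Hochberg FDR column can be added (off by default; with
#' few species the emphasis is on effect sizes rather than corrected p
#' values).
#'
#' @param results data.frame containing the `by` column and `set_id`.
#' @param by `"adj_r2"`, `"t"` or `"p"` (column names `adj_r_squared`, `t`,
#'   `p_value`).
#' @param top_k optionally keep only the first `top_k` rows.
#' @param fdr add a `p_adjust` BH column.
#' @return the reordered data.frame.
#' @export
rank_results <- function(results, by = c("adj_r2", "t", "p"), top_k = NULL,
                         fdr = FALSE) {
  by <- match.arg(by)
  col <- switch(by, adj_r2 = "adj_r_squared", t = "t", p = "p_value")
  if (!col %in% names(results))
    stop_data("results lack column '%s' needed to rank by %s", col, by)
  key <- switch(by, adj_r2 = -results[[col]], t = -abs(results[[col]]),
                p = results[[col]])
  out <- results[order(key, results$set_id), , drop = FALSE]
  if (fdr && "p_value" %in% names(out))
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

# flatten a list of thermo_lmm fits into the lmm_results table
lmm_results_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(set_id = f$set_id,
               contrast = f$contrasts$contrast,
               estimate = f$contrasts$estimate,
               t = f$contrasts$t, df = f$contrasts$df, p = f$contrasts$p,
               sigma2_species = f$sigma2_species,
               sigma2_residual = f$sigma2_residual,
               icc = f$icc, marginal_r2 = f$marginal_r2,
               n_obs = f$n_obs, n_species = f$n_species,
               singular = f$singular, stringsAsFactors = FALSE)
  }))
}
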