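# The boot-strapped median gene-set summarizer and related summaries.

#' Boot-strapped median of a value set
#'
#' Draws `n_resamples` random subsets of size `subset_size` (without
#' replacement by default) from `values`, takes the median of each subset,
#' and returns the mean of the resampled medians. With `subset_size ==
#' length(values)` every subset is the full set and the statistic is exactly
#' the sample median. Deterministic given `seed`.
#'
#' @param values numeric vector (finite).
#' @param subset_size subset size, `1 <= subset_size <= length(values)`.
#' @param n_resamples number of resamples, default 1000.
#' @param seed integer seed for this draw.
#' @param replace draw subsets with replacement instead (sensitivity mode).
#' @return the boot-strapped median (numeric scalar).
#' @export
bootstrap_median <- function(values, subset_size, n_resamples = 1000, seed,
                             replace = FALSE) {
  n <- length(values)
  if (subset_size < 1 || (!replace && subset_size > n))
    stop_data("subset_size %d infeasible for %d values", subset_size, n)
  if (any(!is.finite(values))) stop_data("bootstrap_median needs finite values")
  if (!replace && subset_size == n) return(stats::median(values))
  with_substream(as.integer(seed),
                 cpp_boot_median(values, as.integer(subset_size),
                                 as.integer(n_resamples), replace))
}

#' Exhaustive mean of subset medians
#'
#' Enumerates every size-`k` subset of `values` and averages their medians:
#' the exact expectation that [bootstrap_median()] estimates by Monte Carlo.
#' Intended for small inputs (test oracle); cost is `choose(n, k)`.
#'
#' @param values numeric vector.
#' @param k subset size.
#' @return exact expected subset median.
#' @export
exact_subset_median_mean <- function(values, k) {
  n <- length(values)
  stopifnot(k >= 1, k <= n)
  idx <- utils::combn(n, k)
  mean(apply(idx, 2, function(i) stats::median(values[i])))
}

#' Boot-strapped GO expression per library
#'
#' For every retained GO term and every library, computes the boot-strapped
#' median TPM of the term's member genes in that library. Each (term,
#' species) pair uses its own RNG substream derived from the master seed, so
#' estimates do not depend on processing order.
#'
#' @param exprs named list of `species_expression`, one per species.
#' @param catalog a `geneset_catalog`.
#' @param metadata library metadata.
#' @param n_resamples resamples per estimate, default 1000.
#' @param seed master seed.
#' @return data.frame: `set_id`, `species_id`, `library_id`, `estimate`,
#'   `subset_size`, `n_resamples`, `seed`.
#' @export
go_expression_per_library <- function(exprs, catalog, metadata,
                                      n_resamples = 1000, seed) {
  rows <- list()
  for (term in sort(names(catalog$go_members))) {
    k <- catalog_subset_size(catalog, term)
    for (sp in names(catalog$go_members[[term]])) {
      genes <- catalog$go_members[[term]][[sp]]
      expr <- exprs[[sp]]
      if (is.null(expr) || !all(genes %in% rownames(expr$tpm)))
        stop_data("catalog members of %s missing from expression matrix of %s",
                  term, sp)
      sub <- expr$tpm[genes, , drop = FALSE]
      sub_seed <- substream_seed(seed, term, sp)
      for (j in seq_len(ncol(sub))) {
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = term, species_id = sp, library_id = colnames(sub)[j],
          estimate = bootstrap_median(sub[, j], k, n_resamples,
                                      seed = substream_seed(sub_seed, colnames(sub)[j])),
          subset_size = k, n_resamples = n_resamples, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Boot-strapped GO fold change per species
#'
#' For every retained GO term, species and contrast, computes the
#' boot-strapped median of the member genes' log2 fold changes. Genes with
#' missing fold changes (infinite ratios under a zero pseudocount) are
#' excluded; the subset size is capped at the number of usable members.
#'
#' @param fold_changes data.frame from [log2_fold_change()] (all species and
#'   contrasts row-bound).
#' @param catalog a `geneset_catalog`.
#' @param n_resamples resamples per estimate, default 1000.
#' @param seed master seed.
#' @return data.frame: `set_id`, `species_id`, `contrast`, `estimate`,
#'   `subset_size`, `n_resamples`, `seed`.
#' @export
go_fc_per_species <- function(fold_changes, catalog, n_resamples = 1000, seed) {
  fc_key <- split(fold_changes,
                  list(fold_changes$species_id, fold_changes$contrast),
                  drop = TRUE)
  rows <- list()
  for (term in sort(names(catalog$go_members))) {
    k0 <- catalog_subset_size(catalog, term)
    for (sp in names(catalog$go_members[[term]])) {
      genes <- catalog$go_members[[term]][[sp]]
      for (contrast in c("HvsN", "CvsN")) {
        block <- fc_key[[paste(sp, contrast, sep = ".")]]
        if (is.null(block)) next
        vals <- block$log2fc[match(genes, block$gene_id)]
        if (anyNA(vals)) vals <- vals[!is.na(vals)]
        if (!length(vals))
          stop_data("no usable fold changes for %s in %s", term, sp)
        k <- min(k0, length(vals))
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = term, species_id = sp, contrast = contrast,
          estimate = bootstrap_median(vals, k, n_resamples,
                                      seed = substream_seed(seed, term, sp, contrast)),
          subset_size = k, n_resamples = n_resamples, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean orthogroup expression per library
#'
#' Mean TPM of an orthogroup's expressed member genes, per library. The mean
#' (not a boot-strapped median) is used because many orthogroups have a
#' single member gene in some species.
#'
#' @param exprs named list of `species_expression`.
#' @param catalog a `geneset_catalog`.
#' @param metadata library metadata.
#' @return data.frame: `set_id`, `species_id`, `library_id`, `estimate`.
#' @export
orthogroup_expression <- function(exprs, catalog, metadata) {
  rows <- list()
  for (og in sort(names(catalog$og_members))) {
    for (sp in names(catalog$og_members[[og]])) {
      genes <- catalog$og_members[[og]][[sp]]
      expr <- exprs[[sp]]
      if (is.null(expr) || !all(genes %in% rownames(expr$tpm)))
        stop_data("catalog members of %s missing from expression matrix of %s",
                  og, sp)
      sub <- expr$tpm[genes, , drop = FALSE]
      est <- colMeans(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = og, species_id = sp, library_id = names(est),
        estimate = unname(est), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-scale a value vector
#'
#' Centers to mean 0 and scales to SD 1 (sample SD, n - 1 denominator).
#' Used to make expression trends comparable across gene sets before group
#' means are plotted.
#'
#' @param values numeric vector with at least two distinct values.
#' @return scaled vector.
#' @export
zscale <- function(values) {
  if (length(unique(values[is.finite(values)])) < 2L)
    stop_data("zscale needs at least two distinct values (zero variance)")
  (values - mean(values)) / stats::sd(values)
}

#' Group mean and standard error summaries
#'
#' Summarizes gene-set estimates by treatment, or by biome x treatment for
#' species-level fold changes. `SE = SD / sqrt(n)`; single-member groups
#' report a missing SE.
#'
#' @param summaries data.frame with `set_id`, `estimate` and either
#'   `library_id` + `species_id` (expression level) or `species_id` +
#'   `contrast` (fold-change level).
#' @param metadata library metadata.
#' @param grouping `"treatment"` (expression per library, grouped by its
#'   library's arm) or `"biome_treatment"` (species-level fold changes
#'   grouped by the species' biome and the contrast).
#' @param scale z-scale estimates within each set before summarizing.
#' @return data.frame with one row per (set, group): `set_id`, grouping
#'   columns, `mean`, `se`, `n`.
#' @export
treatment_group_summary <- function(summaries, metadata,
                                    grouping = c("treatment", "biome_treatment"),
                                    scale = FALSE) {
  grouping <- match.arg(grouping)
  df <- summaries
  if (grouping == "treatment") {
    df$group <- as.character(metadata$treatment[match(df$library_id,
                                                      metadata$library_id)])
  } else {
    sp_biome <- unique(metadata[, c("species_id", "biome")])
    df$group <- paste(as.character(sp_biome$biome[match(df$species_id,
                                                        sp_biome$species_id)]),
                      df$contrast, sep = ":")
  }
  if (anyNA(df$group)) stop_data("summaries contain units absent from metadata")
  rows <- list()
  for (set in sort(unique(df$set_id))) {
    block <- df[df$set_id == set, , drop = FALSE]
    vals <- block$estimate
    if (scale) vals <- zscale(vals)
    for (g in sort(unique(block$group))) {
      v <- vals[block$group == g]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = set, group = g, mean = mean(v),
        se = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
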