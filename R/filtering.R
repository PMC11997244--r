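# Expression filtering and log2 fold-change contrasts.

#' Filter genes on mean expression
#'
#' Retains the genes of a species whose mean TPM across all of that species'
#' libraries (all treatments pooled) is at or above `threshold`. The default
#' of 10 TPM focuses the analysis on consistently expressed, well-assembled
#' genes.
#'
#' @param expr a `species_expression`.
#' @param threshold TPM threshold (inclusive), default 10.
#' @return a `retained_gene_set`: list with `species_id`, `gene_ids`,
#'   `mean_tpm` (named), `threshold`.
#' @export
filter_low_expression <- function(expr, threshold = 10) {
  stopifnot(inherits(expr, "species_expression"))
  if (threshold < 0) stop_config("threshold must be non-negative")
  means <- rowMeans(expr$tpm)
  keep <- means >= threshold
  if (!any(keep))
    stop_data("no genes of %s pass the mean TPM >= %g filter",
              expr$species_id, threshold)
  structure(list(species_id = expr$species_id,
                 gene_ids = rownames(expr$tpm)[keep],
                 mean_tpm = means[keep],
                 threshold = threshold),
            class = "retained_gene_set")
}

#' Per-treatment mean expression
#'
#' Arithmetic mean TPM per retained gene for each treatment arm of a species.
#' Arms with a single library return that library's values unchanged.
#'
#' @param expr a `species_expression`.
#' @param retained a `retained_gene_set` for the same species.
#' @param metadata library metadata (from [read_metadata()]).
#' @return a `treatment_means`: list with `species_id` and matrix `means`
#'   (retained genes x treatments).
#' @export
treatment_means <- function(expr, retained, metadata) {
  stopifnot(inherits(expr, "species_expression"),
            inherits(retained, "retained_gene_set"),
            identical(expr$species_id, retained$species_id))
  md <- metadata[metadata$species_id == expr$species_id, , drop = FALSE]
  md <- md[md$library_id %in% colnames(expr$tpm), , drop = FALSE]
  sub <- expr$tpm[retained$gene_ids, , drop = FALSE]
  means <- matrix(NA_real_, nrow = nrow(sub), ncol = length(TREATMENT_LEVELS),
                  dimnames = list(rownames(sub), TREATMENT_LEVELS))
  for (tr in TREATMENT_LEVELS) {
    libs <- md$library_id[md$treatment == tr]
    if (!length(libs))
      stop_data("species %s has no libraries for treatment '%s'",
                expr$species_id, tr)
    means[, tr] <- rowMeans(sub[, libs, drop = FALSE])
  }
  structure(list(species_id = expr$species_id, means = means),
            class = "treatment_means")
}

#' Log2 fold change of treatment versus control means
#'
#' Computes `log2((mean_treatment + pseudocount) / (mean_control +
#' pseudocount))` per retained gene, for the hot-versus-control (`HvsN`) or
#' cold-versus-control (`CvsN`) contrast. The pseudocount (default 0.5 TPM)
#' keeps fold changes finite for genes with a zero mean in one arm; with
#' `pseudocount = 0` infinite values are returned as `NA` and excluded
#' downstream.
#'
#' @param means a `treatment_means`.
#' @param contrast `"HvsN"` or `"CvsN"`.
#' @param pseudocount non-negative TPM offset, default 0.5.
#' @return data.frame with columns `species_id`, `gene_id`, `contrast`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(means, contrast = c("HvsN", "CvsN"),
                             pseudocount = 0.5) {
  stopifnot(inherits(means, "treatment_means"))
  contrast <- match.arg(contrast)
  if (pseudocount < 0) stop_config("pseudocount must be non-negative")
  num_arm <- if (contrast == "HvsN") "hot" else "cold"
  fc <- log2((means$means[, num_arm] + pseudocount) /
               (means$means[, "control"] + pseudocount))
  fc[!is.finite(fc)] <- NA_real_
  data.frame(species_id = means$species_id,
             gene_id = rownames(means$means),
             contrast = contrast,
             log2fc = unname(fc),
             stringsAsFactors = FALSE)
}
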