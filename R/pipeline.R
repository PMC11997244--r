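# End-to-end pipeline driver: configuration validation, stage orchestration,
# result tables, retention log and run manifest.

pipeline_defaults <- function() {
  list(
    input_dir = NULL, output_dir = NULL,
    tpm_threshold = 10, min_genes = 10, subset_fraction = 0.75,
    n_resamples = 1000, presence_min = 15, expressed_min = 12,
    pseudocount = 0.5, seed = NULL,
    df_mode = "residual", go_scope = "per_species",
    grid_step = 0.1, smoothing_window = 5
  )
}

#' Validate a pipeline configuration
#'
#' Merges a raw configuration (a named list, or a YAML file read with
#' [read_pipeline_config()]) with the documented defaults, rejecting unknown
#' keys and reporting all type/range violations at once. A seed is mandatory
#' whenever any resampling will be performed.
#'
#' @param raw named list of configuration values.
#' @return a validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(raw = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop_config("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$tpm_threshold) && cfg$tpm_threshold >= 0,
      "tpm_threshold must be a non-negative number")
  chk(num1(cfg$min_genes) && cfg$min_genes >= 1, "min_genes must be >= 1")
  chk(num1(cfg$subset_fraction) && cfg$subset_fraction > 0 &&
        cfg$subset_fraction <= 1, "subset_fraction must be in (0, 1]")
  chk(num1(cfg$n_resamples) && cfg$n_resamples >= 1, "n_resamples must be >= 1")
  chk(num1(cfg$presence_min) && cfg$presence_min >= 1, "presence_min must be >= 1")
  chk(num1(cfg$expressed_min) && cfg$expressed_min >= 1, "expressed_min must be >= 1")
  chk(num1(cfg$pseudocount) && cfg$pseudocount >= 0,
      "pseudocount must be non-negative")
  chk(num1(cfg$grid_step) && cfg$grid_step > 0, "grid_step must be positive")
  chk(num1(cfg$smoothing_window) && cfg$smoothing_window >= 1,
      "smoothing_window must be >= 1")
  chk(cfg$df_mode %in% c("residual", "satterthwaite"),
      "df_mode must be 'residual' or 'satterthwaite'")
  chk(cfg$go_scope %in% c("per_species", "total"),
      "go_scope must be 'per_species' or 'total'")
  if (length(problems))
    stop_config("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  if (cfg$tpm_threshold == 0)
    warn_data("tpm_threshold = 0: expression filtering is disabled")
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file; an empty file yields all defaults (a
#'   seed must then be supplied some other way).
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, thermoresp_error = function(e) {
    stop_data("[stage %s] %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input reading, expression filtering and
#' fold changes, gene-set catalog construction, boot-strapped summaries,
#' mixed/biome/acclimation models, and (when traces are present) thermal
#' trait extraction — writing every result table, a retention log and a JSON
#' run manifest to `output_dir`. Repeated runs with the same inputs and seed
#' produce byte-identical tables.
#'
#' The expected `input_dir` layout is the one written by
#' [write_synthetic_bundle()]: `metadata.csv`, `expression/<sp>_tpm.tsv`,
#' `annotations/<sp>_trinotate.tsv`, `Orthogroups.tsv` and optionally
#' `traces.csv`.
#'
#' @param config a `pipeline_config` from [validate_config()], with
#'   `input_dir` and `output_dir` set.
#' @return invisibly, a named list of all result data.frames.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop_config("input_dir and output_dir are required")
  if (is.null(config$seed) && config$n_resamples > 0)
    stop_config("seed is required when resampling is enabled")
  in_dir <- config$input_dir
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- io stage ---------------------------------------------------------
  metadata <- run_stage("io", read_metadata(file.path(in_dir, "metadata.csv")))
  expr_files <- list.files(file.path(in_dir, "expression"),
                           pattern = "_tpm\\.tsv$", full.names = TRUE)
  if (!length(expr_files)) stop_data("[stage io] no expression tables found in %s", in_dir)
  species <- sub("_tpm\\.tsv$", "", basename(expr_files))
  exprs <- run_stage("io", {
    out <- lapply(seq_along(expr_files), function(i)
      read_tpm_matrix(expr_files[i], species[i]))
    names(out) <- species
    out
  })
  missing_sp <- setdiff(metadata$species_id, species)
  if (length(missing_sp))
    stop_data("[stage io] metadata species without expression tables: %s",
              paste(missing_sp, collapse = ", "))
  annotations <- run_stage("io", {
    out <- lapply(species, function(sp)
      read_trinotate_go(file.path(in_dir, "annotations",
                                  paste0(sp, "_trinotate.tsv")), sp))
    names(out) <- species
    out
  })
  orthogroups <- run_stage("io", read_orthogroups(
    file.path(in_dir, "Orthogroups.tsv"), known_species = species))

  # --- filtering stage --------------------------------------------------
  retained <- run_stage("filtering", {
    out <- lapply(exprs, filter_low_expression, threshold = config$tpm_threshold)
    names(out) <- names(exprs)
    out
  })
  means <- run_stage("filtering", lapply(species, function(sp)
    treatment_means(exprs[[sp]], retained[[sp]], metadata)))
  names(means) <- species
  fold_changes <- run_stage("filtering", do.call(rbind, unlist(
    lapply(means, function(m) list(
      log2_fold_change(m, "HvsN", pseudocount = config$pseudocount),
      log2_fold_change(m, "CvsN", pseudocount = config$pseudocount))),
    recursive = FALSE)))

  # --- genesets stage ---------------------------------------------------
  catalog <- run_stage("genesets", {
    go_sets <- build_go_sets(annotations, retained)
    build_catalog(go_sets, orthogroups, retained, species,
                  min_genes = config$min_genes,
                  subset_fraction = config$subset_fraction,
                  presence_min = config$presence_min,
                  expressed_min = config$expressed_min,
                  go_scope = config$go_scope)
  })
  for (term in unique(catalog$go_table$set_id)) {
    kept <- catalog$go_table$retained[catalog$go_table$set_id == term][1]
    min_count <- min(catalog$go_table$n_members[catalog$go_table$set_id == term])
    log_add("go %s %s (min members across species = %d, rule >= %d)",
            term, if (kept) "retained" else "dropped", min_count, config$min_genes)
  }
  og_t <- catalog$og_table
  for (og in names(orthogroups)) {
    if (!og %in% og_t$set_id) {
      log_add("orthogroup %s dropped (present in %d species, rule >= %d)",
              og, length(orthogroups[[og]]), config$presence_min)
    } else {
      row <- og_t[og_t$set_id == og, ][1, ]
      log_add("orthogroup %s %s (present %d, expressed %d, rule >= %d)",
              og, if (row$retained) "retained" else "dropped",
              row$n_present, row$n_expressed, config$expressed_min)
    }
  }

  # --- bootstrap stage --------------------------------------------------
  go_expr_boot <- run_stage("bootstrap", go_expression_per_library(
    exprs, catalog, metadata, n_resamples = config$n_resamples,
    seed = config$seed))
  go_fc_boot <- run_stage("bootstrap", go_fc_per_species(
    fold_changes, catalog, n_resamples = config$n_resamples,
    seed = config$seed))
  og_expr <- run_stage("bootstrap", orthogroup_expression(exprs, catalog, metadata))
  grp_treatment <- run_stage("bootstrap", treatment_group_summary(
    go_expr_boot, metadata, grouping = "treatment", scale = TRUE))
  grp_biome <- run_stage("bootstrap", treatment_group_summary(
    go_fc_boot, metadata, grouping = "biome_treatment"))

  # --- models stage -----------------------------------------------------
  lmm_fits <- run_stage("models", {
    fits <- list()
    for (term in sort(unique(go_expr_boot$set_id))) {
      block <- go_expr_boot[go_expr_boot$set_id == term, ]
      fits[[term]] <- fit_treatment_lmm(block, metadata,
                                        df_mode = config$df_mode,
                                        set_id = term)
    }
    for (og in sort(unique(og_expr$set_id))) {
      block <- og_expr[og_expr$set_id == og, ]
      fits[[og]] <- fit_treatment_lmm(block, metadata,
                                      df_mode = config$df_mode, set_id = og)
    }
    fits
  })
  lmm_results <- lmm_results_table(lmm_fits)

  sp_biome <- unique(data.frame(species_id = metadata$species_id,
                                biome = as.character(metadata$biome),
                                stringsAsFactors = FALSE))
  biome_results <- run_stage("models", do.call(rbind, unlist(
    lapply(sort(unique(go_fc_boot$set_id)), function(term) {
      lapply(c("HvsN", "CvsN"), function(ctr) {
        block <- go_fc_boot[go_fc_boot$set_id == term &
                              go_fc_boot$contrast == ctr, ]
        fit <- fit_biome_lm(block, sp_biome, set_id = term, contrast = ctr)
        data.frame(set_id = term, contrast = ctr, r_squared = fit$r_squared,
                   p_value = fit$p_value, n_species = fit$n_species,
                   stringsAsFactors = FALSE)
      })
    }), recursive = FALSE)))

  # --- thermal stage (optional) ----------------------------------------
  traits <- deltas <- acc_results <- NULL
  traces_path <- file.path(in_dir, "traces.csv")
  if (file.exists(traces_path)) {
    traces <- run_stage("thermal", read_traces(traces_path))
    traits <- run_stage("thermal", thermal_traits(
      traces, grid_step = config$grid_step,
      smoothing_window = config$smoothing_window))
    deltas <- run_stage("thermal", acclimation_deltas(traits))
    min_n_of <- function(term)
      min(catalog$go_table$n_members[catalog$go_table$set_id == term])
    trait_contrast <- c(Tcrit_hot = "HvsN", Tmax_hot = "HvsN",
                        Tcrit_cold = "CvsN", Tmax_cold = "CvsN")
    acc_rows <- list()
    for (trait in names(trait_contrast)) {
      acc <- deltas[deltas$trait == trait, c("species_id", "delta")]
      if (nrow(acc) < 4L) next
      for (term in sort(unique(go_fc_boot$set_id))) {
        block <- go_fc_boot[go_fc_boot$set_id == term &
                              go_fc_boot$contrast == trait_contrast[[trait]], ]
        fit <- run_stage("models", fit_acclimation_lm(
          acc, block[, c("species_id", "estimate")], trait = trait,
          set_id = term, min_n = min_n_of(term)))
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          set_id = term, trait = trait, min_n = fit$min_n,
          adj_r_squared = fit$adj_r_squared, t = fit$t,
          p_value = fit$p_value, n_species = fit$n_species,
          fc_median = fit$fc_median, fc_min = fit$fc_min,
          fc_max = fit$fc_max, stringsAsFactors = FALSE)
      }
    }
    acc_results <- do.call(rbind, acc_rows)
    # ordered by trait then descending adjusted R2, as in the result tables
    acc_results <- do.call(rbind, lapply(names(trait_contrast), function(tr)
      rank_results(acc_results[acc_results$trait == tr, ], by = "adj_r2")))
    rownames(acc_results) <- NULL
  } else {
    log_add("thermal stage skipped: no traces.csv in %s", in_dir)
  }

  # --- outputs ----------------------------------------------------------
  retained_tab <- do.call(rbind, lapply(retained, function(r)
    data.frame(species_id = r$species_id, gene_id = r$gene_ids,
               mean_tpm = unname(r$mean_tpm), stringsAsFactors = FALSE)))
  catalog_tab <- rbind(
    catalog$go_table[, c("set_id", "set_type", "species_id", "n_members",
                         "retained", "subset_size")],
    cbind(catalog$og_table[, c("set_id", "set_type", "species_id",
                               "n_members", "retained")],
          subset_size = NA_integer_))
  tables <- list(
    retained_genes = retained_tab,
    fold_changes = fold_changes,
    geneset_catalog = catalog_tab,
    go_expression_boot = go_expr_boot,
    go_fc_boot = go_fc_boot,
    orthogroup_expression = og_expr,
    group_summary_treatment = grp_treatment,
    group_summary_biome = grp_biome,
    lmm_results = lmm_results,
    biome_results = biome_results,
    thermal_traits = traits,
    acclimation_deltas = deltas,
    acclimation_results = acc_results
  )
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    write_result_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  inputs <- c(metadata = file.path(in_dir, "metadata.csv"),
              stats::setNames(expr_files, paste0("expression_", species)),
              orthogroups = file.path(in_dir, "Orthogroups.tsv"))
  if (file.exists(traces_path)) inputs <- c(inputs, traces = traces_path)
  params <- config[setdiff(names(config), c("seed", "input_dir", "output_dir"))]
  write_manifest(inputs, params, config$seed,
                 file.path(out_dir, "manifest.json"))
  invisible(tables)
}
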