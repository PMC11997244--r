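# Synthetic multi-species RNA-seq and fluorescence-ramp generator with known
# ground truth. The default configuration reproduces the study design the
# analysis targets: 20 species from three biomes, 188 libraries with
# unbalanced arms (including n = 1 arms), planted GO-term effects on the
# log2-TPM scale, orthogroups present in subsets of species, and two-segment
# fluorescence ramps with known breakpoints.

# Default species design: 20 species, 7 alpine / 7 arid / 6 temperate, with
# per-arm library counts summing to 188 (including the n = 1 arms).
default_species_design <- function() {
  data.frame(
    species_id = sprintf("sp%02d", 1:20),
    biome = c(rep("alpine", 7), rep("arid", 7), rep("temperate", 6)),
    n_control = c(2, 4, 4, 4, 1, 4, 4, 1, 1, 3, 4, 3, 2, 4, 4, 3, 4, 3, 3, 3),
    n_cold    = c(2, 4, 3, 4, 1, 3, 3, 1, 1, 3, 4, 4, 2, 4, 3, 4, 4, 4, 3, 4),
    n_hot     = c(3, 4, 4, 4, 2, 4, 4, 1, 1, 3, 4, 4, 1, 4, 4, 4, 4, 4, 3, 4),
    stringsAsFactors = FALSE
  )
}

# Planted GO-term catalog. Effects are log2-TPM shifts applied to member
# genes under the named treatment, possibly differing by biome. Terms with
# qualifying = FALSE are distractors that must fail the retention rule.
default_go_catalog <- function() {
  b <- function(arid, alpine, temperate)
    c(arid = arid, alpine = alpine, temperate = temperate)
  list(
    list(id = "GO:2000001", n_members = 12, qualifying = TRUE,
         beta_hot = b(1.0, 1.0, 1.0), beta_cold = b(0, 0, 0)),
    list(id = "GO:2000002", n_members = 20, qualifying = TRUE,
         beta_hot = b(0.9, 0.9, 0.9), beta_cold = b(0.1, 0.1, 0.1)),
    list(id = "GO:2000003", n_members = 15, qualifying = TRUE,
         beta_hot = b(0, 0, 0), beta_cold = b(0.7, 0.7, 0.7)),
    list(id = "GO:2000004", n_members = 30, qualifying = TRUE,
         beta_hot = b(0, 0, 0), beta_cold = b(-0.8, -0.8, -0.8)),
    list(id = "GO:2000005", n_members = 18, qualifying = TRUE,  # arid-weak heat response
         beta_hot = b(0.3, 1.0, 1.0), beta_cold = b(0, 0, 0)),
    list(id = "GO:2000006", n_members = 16, qualifying = TRUE,  # alpine-weak cold response
         beta_hot = b(0, 0, 0), beta_cold = b(-0.6, -0.1, -0.6)),
    list(id = "GO:2000007", n_members = 25, qualifying = TRUE,
         beta_hot = b(0, 0, 0), beta_cold = b(0, 0, 0)),
    list(id = "GO:2000008", n_members = 10, qualifying = TRUE,  # boundary count
         beta_hot = b(0, 0, 0), beta_cold = b(0, 0, 0)),
    list(id = "GO:2000009", n_members = 12, qualifying = FALSE, # 9 members in sp01
         beta_hot = b(0, 0, 0), beta_cold = b(0, 0, 0), short_species = "first")
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic data
#' generator. Defaults reproduce the targeted study design (20 species in
#' three biomes, 188 libraries with unbalanced arms); the variance components
#' place 45% of library-level log2 expression variance between species
#' (`true ICC = sigma_sp^2 / (sigma_sp^2 + sigma_lib^2) = 0.45`).
#'
#' @param species data.frame with `species_id`, `biome`, `n_control`,
#'   `n_cold`, `n_hot`.
#' @param n_genes genes per species (expressed + low).
#' @param frac_low fraction of genes planted below the 10-TPM filter.
#' @param go_catalog list of planted GO terms (see source for the entry
#'   shape).
#' @param n_orthogroups_pass,n_fail_presence,n_fail_expressed planted
#'   orthogroup counts: qualifying, failing the presence stage, failing the
#'   expression stage.
#' @param sigma_sp,sigma_lib,sigma_gene SDs (log2 units) of the species
#'   random intercept, the library-level residual, and gene-level noise.
#' @param tcrit_hot_mean,tcrit_hot_sd population mean and between-species SD
#'   of the control-arm heating Tcrit (degrees C).
#' @param delta_tcrit_hot,delta_tmax_hot,delta_tcrit_cold,delta_tmax_cold
#'   planted acclimation deltas (treatment arm minus control, degrees C).
#' @param trace_noise_sd Gaussian noise SD on F0 (fluorescence units).
#' @param plants_per_combo fluorescence replicates per species x arm.
#' @param log_interval_s ramp logging cadence in seconds.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(species = default_species_design(),
                              n_genes = 2000,
                              frac_low = 0.25,
                              go_catalog = default_go_catalog(),
                              n_orthogroups_pass = 5,
                              n_fail_presence = 2,
                              n_fail_expressed = 2,
                              sigma_sp = sqrt(0.45),
                              sigma_lib = sqrt(0.55),
                              sigma_gene = 0.3,
                              tcrit_hot_mean = 45, tcrit_hot_sd = 2,
                              delta_tcrit_hot = 2.5, delta_tmax_hot = 2.0,
                              delta_tcrit_cold = 1.5, delta_tmax_cold = 1.0,
                              trace_noise_sd = 0.02,
                              plants_per_combo = 5,
                              log_interval_s = 5) {
  cfg <- list(species = species, n_genes = as.integer(n_genes),
              frac_low = frac_low, go_catalog = go_catalog,
              n_orthogroups_pass = n_orthogroups_pass,
              n_fail_presence = n_fail_presence,
              n_fail_expressed = n_fail_expressed,
              sigma_sp = sigma_sp, sigma_lib = sigma_lib,
              sigma_gene = sigma_gene,
              tcrit_hot_mean = tcrit_hot_mean, tcrit_hot_sd = tcrit_hot_sd,
              delta_tcrit_hot = delta_tcrit_hot, delta_tmax_hot = delta_tmax_hot,
              delta_tcrit_cold = delta_tcrit_cold, delta_tmax_cold = delta_tmax_cold,
              trace_noise_sd = trace_noise_sd,
              plants_per_combo = as.integer(plants_per_combo),
              log_interval_s = log_interval_s)
  need <- c("species_id", "biome", "n_control", "n_cold", "n_hot")
  if (!all(need %in% names(species)))
    stop_config("species design needs columns: %s", paste(need, collapse = ", "))
  if (any(species[, c("n_control", "n_cold", "n_hot")] < 1))
    stop_config("every species needs >= 1 library per arm")
  if (frac_low < 0 || frac_low >= 1) stop_config("frac_low must be in [0, 1)")
  if (sigma_sp < 0 || sigma_lib <= 0 || sigma_gene < 0)
    stop_config("variance components must be non-negative (sigma_lib > 0)")
  n_member_total <- sum(vapply(go_catalog, function(t) t$n_members, numeric(1)))
  n_expressed <- round((1 - frac_low) * n_genes)
  if (n_member_total + 50 > n_expressed)
    stop_config("n_genes too small for the GO catalog (%d members, %d expressed genes)",
                n_member_total, n_expressed)
  structure(cfg, class = "sim_config")
}

# per-library treatment vector for one species row
species_library_plan <- function(row) {
  tr <- rep(TREATMENT_LEVELS, times = c(row$n_control, row$n_cold, row$n_hot))
  data.frame(
    library_id = sprintf("%s_L%02d", row$species_id, seq_along(tr)),
    species_id = row$species_id, treatment = tr, biome = row$biome,
    stringsAsFactors = FALSE)
}

#' Generate synthetic expression data
#'
#' Simulates TPM matrices for every species in the design. For gene `g`
#' (member of term `k`) in species `s`, library `l` under treatment `tau`:
#' `log2 TPM = mu_g + u_s + beta[k, tau, biome(s)] + e_l + eps_gl`, with
#' `u_s ~ N(0, sigma_sp^2)` (species random intercept), `e_l ~ N(0,
#' sigma_lib^2)` (library-level residual) and `eps_gl ~ N(0, sigma_gene^2)`
#' (gene-level noise). Non-member genes have no treatment effect; a planted
#' fraction of genes sits well below the 10-TPM retention filter.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `exprs` (named list of `species_expression`),
#'   `metadata` (library data.frame), `gene_plan` (per-species gene roles)
#'   and `truth` (planted ground truth).
#' @export
generate_expression <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  sp_tab <- config$species
  n_genes <- config$n_genes
  n_low <- round(config$frac_low * n_genes)
  n_expressed <- n_genes - n_low
  catalog <- config$go_catalog

  metadata <- do.call(rbind, lapply(seq_len(nrow(sp_tab)), function(i)
    species_library_plan(sp_tab[i, ])))
  metadata$treatment <- factor(metadata$treatment, levels = TREATMENT_LEVELS)
  metadata$biome <- factor(metadata$biome, levels = BIOME_LEVELS)

  with_substream(substream_seed(seed, "expression"), {
    exprs <- list()
    gene_plan <- list()
    u_sp <- stats::rnorm(nrow(sp_tab), 0, config$sigma_sp)
    # GO-member baselines are shared across species (orthologous processes
    # keep comparable expression levels), so the planted species variance is
    # the only between-species component in gene-set median summaries
    mu_members <- lapply(catalog, function(term)
      6 + stats::rexp(term$n_members, rate = 1 / 1.5))
    names(mu_members) <- vapply(catalog, function(t) t$id, character(1))
    for (i in seq_len(nrow(sp_tab))) {
      sp <- sp_tab$species_id[i]
      biome <- sp_tab$biome[i]
      md <- metadata[metadata$species_id == sp, ]
      gene_ids <- sprintf("%s_g%04d", sp, seq_len(n_genes))
      # gene roles: GO members first (disjoint blocks), background, then low
      role <- rep("background", n_genes)
      term_of <- rep(NA_character_, n_genes)
      pos <- 1L
      for (term in catalog) {
        n_mem <- term$n_members
        if (identical(term$short_species, "first") && i == 1L)
          n_mem <- n_mem - 3L  # drops this species below the retention minimum
        idx <- seq(pos, length.out = n_mem)
        role[idx] <- "go_member"
        term_of[idx] <- term$id
        pos <- pos + n_mem
      }
      if (n_low > 0L) role[seq(n_expressed + 1L, n_genes)] <- "low"
      # baselines: expressed genes >= 64 TPM with a heavy right tail so the
      # species random intercept cannot drag them under the 10-TPM filter;
      # low genes planted at 0.25-1.4 TPM, safely below it
      mu <- numeric(n_genes)
      mu[role != "low"] <- 6 + stats::rexp(n_expressed, rate = 1 / 1.5)
      for (term in catalog) {
        sel <- which(term_of == term$id)
        if (length(sel)) mu[sel] <- mu_members[[term$id]][seq_along(sel)]
      }
      if (n_low > 0L) mu[role == "low"] <- stats::runif(n_low, -2, 0.5)

      tpm <- matrix(0, n_genes, nrow(md),
                    dimnames = list(gene_ids, md$library_id))
      for (j in seq_len(nrow(md))) {
        tau <- as.character(md$treatment[j])
        beta <- numeric(n_genes)
        if (tau != "control") {
          for (term in catalog) {
            sel <- which(term_of == term$id)
            if (!length(sel)) next
            bvec <- if (tau == "hot") term$beta_hot else term$beta_cold
            beta[sel] <- bvec[[biome]]
          }
        }
        e_l <- stats::rnorm(1, 0, config$sigma_lib)
        eps <- stats::rnorm(n_genes, 0, config$sigma_gene)
        tpm[, j] <- 2^(mu + u_sp[i] + beta + e_l + eps)
      }
      exprs[[sp]] <- new_species_expression(sp, tpm)
      gene_plan[[sp]] <- data.frame(gene_id = gene_ids, role = role,
                                    term = term_of, stringsAsFactors = FALSE)
    }

    qualifying <- vapply(Filter(function(t) isTRUE(t$qualifying), catalog),
                         function(t) t$id, character(1))
    truth <- list(
      n_expressed = n_expressed, n_low = n_low,
      qualifying_terms = sort(qualifying),
      beta = catalog,
      sigma_sp2 = config$sigma_sp^2, sigma_lib2 = config$sigma_lib^2,
      true_icc = config$sigma_sp^2 / (config$sigma_sp^2 + config$sigma_lib^2),
      u_species = stats::setNames(u_sp, sp_tab$species_id)
    )
    list(exprs = exprs, metadata = metadata, gene_plan = gene_plan,
         truth = truth)
  })
}

#' Generate synthetic annotations and orthogroups
#'
#' Builds per-species biological-process GO annotations consistent with the
#' planted term memberships (plus distractor cellular_component entries), and
#' an orthogroup map with planted retention outcomes: qualifying orthogroups
#' (present in >= 15 species and expressed in >= 12 after the TPM filter),
#' orthogroups failing the presence stage, and orthogroups failing the
#' expression stage (present widely but backed by low-expression genes in too
#' many species).
#'
#' @param config a `sim_config`.
#' @param dataset output of [generate_expression()].
#' @param seed integer seed.
#' @return list with `annotations` (named list of `annotation_table`),
#'   `orthogroups` (mapping as from [read_orthogroups()]) and `truth`
#'   (planted orthogroup outcomes).
#' @export
generate_annotations <- function(config, dataset, seed) {
  stopifnot(inherits(config, "sim_config"))
  plan <- dataset$gene_plan
  species <- names(plan)
  n_sp <- length(species)
  annotations <- lapply(species, function(sp) {
    p <- plan[[sp]]
    members <- p[p$role == "go_member", ]
    go <- stats::setNames(as.list(members$term), members$gene_id)
    structure(list(species_id = sp, go = lapply(go, identity)),
              class = "annotation_table")
  })
  names(annotations) <- species

  presence_min <- 15L
  if (n_sp < presence_min) presence_min <- max(2L, ceiling(0.75 * n_sp))
  expressed_min <- min(12L, n_sp)

  with_substream(substream_seed(seed, "orthogroups"), {
    og_list <- list()
    og_truth <- list()
    pick_genes <- function(sp, role_wanted, n) {
      pool <- plan[[sp]]$gene_id[plan[[sp]]$role == role_wanted]
      sample(pool, n)
    }
    og_counter <- 0L
    add_og <- function(n_present, n_expressed_sp, outcome) {
      og_counter <<- og_counter + 1L
      og_id <- sprintf("OG%07d", og_counter)
      present_sp <- sample(species, n_present)
      expressed_sp <- sample(present_sp, n_expressed_sp)
      row <- list()
      for (sp in present_sp) {
        n_mem <- sample(1:3, 1)
        row[[sp]] <- if (sp %in% expressed_sp)
          pick_genes(sp, "background", n_mem)
        else pick_genes(sp, "low", n_mem)
      }
      og_list[[og_id]] <<- row
      og_truth[[og_id]] <<- outcome
    }
    for (i in seq_len(config$n_orthogroups_pass))
      add_og(min(n_sp, presence_min + 1L), min(n_sp, expressed_min + 1L), "pass")
    for (i in seq_len(config$n_fail_presence))
      add_og(presence_min - 1L, presence_min - 1L, "fail_presence")
    for (i in seq_len(config$n_fail_expressed))
      add_og(min(n_sp, presence_min + 1L), expressed_min - 1L, "fail_expressed")
    truth <- list(orthogroup_outcomes = unlist(og_truth),
                  n_pass = config$n_orthogroups_pass,
                  presence_min = presence_min, expressed_min = expressed_min)
    list(annotations = annotations, orthogroups = og_list, truth = truth)
  })
}

# piecewise F0 ramp: slow rise to psi, fast rise to the peak, then decay
trace_f0 <- function(temp, psi, peak, base = 0.2, s_slow = 0.002,
                     s_fast = 0.08, s_decay = 0.04) {
  f <- base + s_slow * (temp - temp[1])
  f <- f + s_fast * pmax(temp - psi, 0)
  f - (s_fast + s_decay) * pmax(temp - peak, 0)
}

#' Generate synthetic fluorescence-ramp traces
#'
#' Heating ramps (20 to 65 C at 30 C/h) for the control and hot arms and
#' cooling ramps (20 to -25 C at 15 C/h) for the control and cold arms, with
#' the configured logging cadence, two-segment rise plus post-peak decay, and
#' Gaussian noise. True per-species breakpoints (Tcrit) and peaks (Tmax) are
#' returned as ground truth; the planted acclimation deltas shift the
#' treatment arms relative to control.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return list with `traces` (list as from [read_traces()]) and `truth`
#'   (per species x arm true traits and per-species deltas).
#' @export
generate_traces <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  sp_tab <- config$species
  dt <- config$log_interval_s / 3600  # hours per log step
  heat_temp <- seq(20, 65, by = 30 * dt)
  cool_temp <- seq(20, -25, by = -15 * dt)
  with_substream(substream_seed(seed, "traces"), {
    traces <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(sp_tab))) {
      sp <- sp_tab$species_id[i]
      tcrit_hot_ctl <- stats::rnorm(1, config$tcrit_hot_mean, config$tcrit_hot_sd)
      tmax_hot_ctl <- tcrit_hot_ctl + 8
      tcrit_cold_ctl <- stats::rnorm(1, -8, 1.5)
      tmin_cold_ctl <- tcrit_cold_ctl - 7
      arms <- list(
        list(treatment = "control", direction = "heating",
             psi = tcrit_hot_ctl, peak = tmax_hot_ctl),
        list(treatment = "hot", direction = "heating",
             psi = tcrit_hot_ctl + config$delta_tcrit_hot,
             peak = tmax_hot_ctl + config$delta_tmax_hot),
        list(treatment = "control", direction = "cooling",
             psi = tcrit_cold_ctl, peak = tmin_cold_ctl),
        list(treatment = "cold", direction = "cooling",
             psi = tcrit_cold_ctl + config$delta_tcrit_cold,
             peak = tmin_cold_ctl + config$delta_tmax_cold))
      for (arm in arms) {
        heating <- arm$direction == "heating"
        temp <- if (heating) heat_temp else cool_temp
        axis_temp <- if (heating) temp else -temp
        f_clean <- trace_f0(axis_temp, psi = if (heating) arm$psi else -arm$psi,
                            peak = if (heating) arm$peak else -arm$peak)
        for (r in seq_len(config$plants_per_combo)) {
          sample_id <- sprintf("%s_%s_%s_r%d", sp, arm$direction,
                               arm$treatment, r)
          traces[[sample_id]] <- list(
            sample_id = sample_id, species_id = sp,
            treatment = arm$treatment, direction = arm$direction,
            temperature = temp,
            f0 = pmax(f_clean + stats::rnorm(length(temp), 0,
                                             config$trace_noise_sd), 0))
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          species_id = sp, treatment = arm$treatment,
          direction = arm$direction, t_crit = arm$psi, t_max = arm$peak,
          stringsAsFactors = FALSE)
      }
    }
    truth <- list(
      traits = do.call(rbind, truth_rows),
      deltas = list(Tcrit_hot = config$delta_tcrit_hot,
                    Tmax_hot = config$delta_tmax_hot,
                    Tcrit_cold = config$delta_tcrit_cold,
                    Tmax_cold = config$delta_tmax_cold))
    list(traces = traces, truth = truth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs the expression, annotation/orthogroup and fluorescence generators
#' under one master seed and returns everything the pipeline consumes along
#' with the planted ground truth.
#'
#' @param config a `sim_config`.
#' @param seed master seed.
#' @param traces generate fluorescence traces too (default TRUE).
#' @return a `sim_dataset` list: `exprs`, `metadata`, `annotations`,
#'   `orthogroups`, `traces` (or NULL), `truth`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed,
                             traces = TRUE) {
  ex <- generate_expression(config, seed)
  an <- generate_annotations(config, ex, seed)
  tr <- if (traces) generate_traces(config, seed) else NULL
  structure(list(
    exprs = ex$exprs, metadata = ex$metadata, gene_plan = ex$gene_plan,
    annotations = an$annotations, orthogroups = an$orthogroups,
    traces = tr$traces,
    truth = c(ex$truth, an$truth, if (!is.null(tr)) list(thermal = tr$truth)),
    config = config
  ), class = "sim_dataset")
}

#' Write a synthetic dataset as an on-disk input bundle
#'
#' Writes every external input format the pipeline reads: `metadata.csv`,
#' `expression/<species>_tpm.tsv` (generic TPM matrices),
#' `annotations/<species>_trinotate.tsv` (Trinotate-dialect reports),
#' `Orthogroups.tsv`, `traces.csv` (when present) and `ground_truth.json`.
#' All files are plain text; the layout is what [run_pipeline()] expects as
#' its `input_dir`.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(file.path(dir, "expression"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  md <- dataset$metadata
  md$treatment <- as.character(md$treatment)
  md$biome <- as.character(md$biome)
  utils::write.table(md, file.path(dir, "metadata.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  for (sp in names(dataset$exprs))
    write_tpm_matrix(dataset$exprs[[sp]],
                     file.path(dir, "expression", paste0(sp, "_tpm.tsv")))
  for (sp in names(dataset$annotations)) {
    ann <- dataset$annotations[[sp]]$go
    gene_ids <- names(ann)
    cells <- vapply(seq_along(ann), function(i) {
      terms <- ann[[i]]
      paste(sprintf("%s^biological_process^synthetic process %s", terms, terms),
            collapse = "`")
    }, character(1))
    # a cellular_component entry per row exercises the branch filter
    cells <- paste0(cells, "`GO:0005737^cellular_component^cytoplasm")
    df <- data.frame("#gene_id" = gene_ids, gene_ontology_BLASTX = cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "annotations",
                                     paste0(sp, "_trinotate.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  species <- names(dataset$exprs)
  og <- dataset$orthogroups
  og_df <- data.frame(Orthogroup = names(og), stringsAsFactors = FALSE)
  for (sp in species)
    og_df[[sp]] <- vapply(og, function(row)
      paste(row[[sp]] %||% character(0), collapse = ", "), character(1))
  utils::write.table(og_df, file.path(dir, "Orthogroups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$traces)) {
    tr_df <- do.call(rbind, lapply(dataset$traces, function(tr)
      data.frame(sample_id = tr$sample_id, species_id = tr$species_id,
                 treatment = tr$treatment, direction = tr$direction,
                 temperature_C = tr$temperature, f0 = tr$f0,
                 stringsAsFactors = FALSE)))
    utils::write.table(tr_df, file.path(dir, "traces.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- dataset$truth
  truth$u_species <- as.list(truth$u_species)
  jsonlite::write_json(
    list(qualifying_terms = truth$qualifying_terms,
         n_expressed = truth$n_expressed, n_low = truth$n_low,
         true_icc = truth$true_icc,
         orthogroup_outcomes = as.list(truth$orthogroup_outcomes)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
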