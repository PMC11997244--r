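# Shared fixture builders: all fixtures are constructed in code.

# tiny expression object from a matrix
make_expr <- function(m, species_id = "spA") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0(species_id, "_L", seq_len(ncol(m)))
  thermoresp:::new_species_expression(species_id, m)
}

make_metadata <- function(species_id = "spA", treatments, biome = "arid",
                          library_ids = NULL) {
  if (is.null(library_ids))
    library_ids <- paste0(species_id, "_L", seq_along(treatments))
  data.frame(library_id = library_ids, species_id = species_id,
             treatment = factor(treatments,
                                levels = c("control", "cold", "hot")),
             biome = factor(biome, levels = c("arid", "alpine", "temperate")),
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# 6-species down-scaled simulation config used by pipeline-level tests
small_sim_config <- function(n_genes = 400, plants_per_combo = 2, ...) {
  sp <- thermoresp:::default_species_design()[c(1, 2, 8, 9, 15, 16), ]
  sp$biome <- rep(c("alpine", "arid", "temperate"), each = 2)
  simulation_config(species = sp, n_genes = n_genes,
                    plants_per_combo = plants_per_combo, ...)
}

# synthetic two-segment heating trace
make_heating_trace <- function(psi = 45, peak = NULL, noise_sd = 0,
                               from = 20, to = 65, step = 0.1,
                               s_slow = 0, s_fast = 0.5, sample_id = "tr1",
                               species_id = "spA", treatment = "control") {
  temp <- seq(from, to, by = step)
  f0 <- 1 + s_slow * (temp - from) + s_fast * pmax(temp - psi, 0)
  if (!is.null(peak)) f0 <- f0 - (s_fast + 0.1) * pmax(temp - peak, 0)
  if (noise_sd > 0) f0 <- f0 + rnorm(length(temp), 0, noise_sd)
  list(sample_id = sample_id, species_id = species_id, treatment = treatment,
       direction = "heating", temperature = temp, f0 = f0)
}
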