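# Readers and writers for the external table formats consumed by the pipeline:
# library metadata CSV, RSEM .genes.results, generic TPM matrices, Trinotate
# annotation reports, OrthoFinder Orthogroups.tsv, and tidy TSV outputs.

TREATMENT_LEVELS <- c("control", "cold", "hot")
BIOME_LEVELS <- c("arid", "alpine", "temperate")

#' Read library metadata
#'
#' Reads the library metadata CSV describing each sequencing library: which
#' species it came from, which temperature treatment arm it belongs to
#' (control, cold or hot) and the species' biome of origin (arid, alpine or
#' temperate). Treatment and biome values are case-folded to lowercase.
#'
#' @param path path to a CSV with header columns `library_id`, `species_id`,
#'   `treatment`, `biome`.
#' @return a data.frame with one row per library; `treatment` and `biome` are
#'   factors with fixed level sets.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("library_id", "species_id", "treatment", "biome")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_data("metadata file %s is missing column(s): %s", path,
              paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop_data("metadata file %s has no rows", path)
  dup <- df$library_id[duplicated(df$library_id)]
  if (length(dup))
    stop_data("duplicate library_id in metadata: %s",
              paste(unique(dup), collapse = ", "))
  df$treatment <- tolower(df$treatment)
  df$biome <- tolower(df$biome)
  bad_tr <- which(!df$treatment %in% TREATMENT_LEVELS)
  if (length(bad_tr))
    stop_data("unknown treatment '%s' in metadata row %d",
              df$treatment[bad_tr[1]], bad_tr[1])
  bad_bi <- which(!df$biome %in% BIOME_LEVELS)
  if (length(bad_bi))
    stop_data("unknown biome '%s' in metadata row %d", df$biome[bad_bi[1]], bad_bi[1])
  df$treatment <- factor(df$treatment, levels = TREATMENT_LEVELS)
  df$biome <- factor(df$biome, levels = BIOME_LEVELS)
  df[required]
}

#' Read one RSEM `.genes.results` file
#'
#' Extracts gene-level TPM values from an RSEM quantification output. Only the
#' `gene_id` and `TPM` columns are used.
#'
#' @param path path to the tab-separated RSEM output.
#' @param library_id library identifier to attach to the values.
#' @return a data.frame with columns `gene_id`, `library_id`, `tpm`.
#' @export
read_rsem_genes <- function(path, library_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "TPM") %in% names(df)))
    stop_data("%s is not an RSEM genes.results file: needs gene_id and TPM columns",
              path)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop_data("gene_id repeated in %s: %s", path, paste(unique(dup), collapse = ", "))
  tpm <- as.numeric(df$TPM)
  if (anyNA(tpm)) stop_data("non-numeric TPM values in %s", path)
  if (any(tpm < 0)) stop_data("negative TPM values in %s", path)
  data.frame(gene_id = df$gene_id, library_id = library_id, tpm = tpm,
             stringsAsFactors = FALSE)
}

#' Assemble a species expression matrix from per-library vectors
#'
#' Column-binds per-library TPM vectors (as returned by [read_rsem_genes()])
#' into one genes x libraries matrix for a species. All libraries must share
#' an identical gene universe, as guaranteed when RSEM quantifies every
#' library against the same de novo assembly.
#'
#' @param vectors list of data.frames from [read_rsem_genes()].
#' @param species_id species identifier.
#' @return a `species_expression` object: list with `species_id`, numeric
#'   matrix `tpm` (rownames = gene ids, colnames = library ids).
#' @export
assemble_species_matrix <- function(vectors, species_id) {
  if (length(vectors) == 0L) stop_data("no libraries supplied for %s", species_id)
  genes <- vectors[[1]]$gene_id
  for (v in vectors[-1]) {
    if (!setequal(v$gene_id, genes)) {
      nd <- length(setdiff(genes, v$gene_id)) + length(setdiff(v$gene_id, genes))
      stop_data("gene universes differ across libraries of %s (%d genes not shared)",
                species_id, nd)
    }
  }
  tpm <- vapply(vectors, function(v) v$tpm[match(genes, v$gene_id)],
                numeric(length(genes)))
  tpm <- matrix(tpm, nrow = length(genes),
                dimnames = list(genes, vapply(vectors, function(v) v$library_id[1],
                                              character(1))))
  new_species_expression(species_id, tpm)
}

new_species_expression <- function(species_id, tpm) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (anyDuplicated(rownames(tpm)))
    stop_data("duplicate gene ids in expression matrix for %s", species_id)
  if (any(tpm < 0)) stop_data("negative TPM in expression matrix for %s", species_id)
  structure(list(species_id = species_id, tpm = tpm),
            class = "species_expression")
}

#' @export
print.species_expression <- function(x, ...) {
  cat(sprintf("<species_expression> %s: %d genes x %d libraries\n",
              x$species_id, nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Read a generic TPM matrix TSV
#'
#' Accepts the matrix dialect: a `gene_id` column followed by one numeric
#' column per library. Auto-detected alongside RSEM files by
#' [read_species_expression()].
#'
#' @param path path to the TSV.
#' @param species_id species identifier.
#' @return a `species_expression` object.
#' @export
read_tpm_matrix <- function(path, species_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop_data("%s: generic TPM matrix must have gene_id as first column", path)
  if (ncol(df) < 2L) stop_data("%s: TPM matrix has no library columns", path)
  if (anyDuplicated(df$gene_id))
    stop_data("duplicate gene_id in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_data("non-numeric TPM values in %s", path)
  rownames(m) <- df$gene_id
  new_species_expression(species_id, m)
}

#' Read species expression from a file, auto-detecting the dialect
#'
#' RSEM `.genes.results` files (detected by their `TPM` header column) hold a
#' single library and need `library_id`; anything else with a leading
#' `gene_id` column is treated as a generic TPM matrix.
#'
#' @param path input path.
#' @param species_id species identifier.
#' @param library_id library id, required only for the RSEM dialect.
#' @return `species_expression` for the matrix dialect; a per-library
#'   data.frame for the RSEM dialect.
#' @export
read_species_expression <- function(path, species_id, library_id = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if ("TPM" %in% header) {
    if (is.null(library_id))
      stop_data("%s looks like RSEM output; library_id is required", path)
    read_rsem_genes(path, library_id)
  } else {
    read_tpm_matrix(path, species_id)
  }
}

#' Write a species expression matrix as a generic TPM TSV
#'
#' @param expr a `species_expression`.
#' @param path output path.
#' @return `path`, invisibly. Round-trips bit-exactly through
#'   [read_tpm_matrix()] (values are written with full precision).
#' @export
write_tpm_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read biological-process GO annotations from a Trinotate report
#'
#' Scans a Trinotate-style annotation report for GO columns, keeps
#' biological_process entries only, and unions terms across rows (transcripts)
#' and across GO-bearing columns for each gene. GO cells contain
#' backtick-separated entries of the form `GO:nnnnnnn^branch^name`.
#'
#' @param path path to the tab-separated report. Must contain a `#gene_id` or
#'   `gene_id` column; every column whose name contains `gene_ontology` (case
#'   insensitive) is parsed.
#' @param species_id species identifier.
#' @return an `annotation_table`: list with `species_id` and `go`, a named
#'   list gene_id -> character vector of BP GO ids.
#' @export
read_trinotate_go <- function(path, species_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  gene_col <- intersect(c("#gene_id", "gene_id"), names(df))
  if (!length(gene_col))
    stop_data("%s: no gene_id column found in Trinotate report", path)
  go_cols <- grep("gene_ontology", names(df), ignore.case = TRUE, value = TRUE)
  if (!length(go_cols))
    stop_data("%s: no gene_ontology columns found in Trinotate report", path)
  genes <- df[[gene_col[1]]]
  go <- list()
  n_malformed <- 0L
  for (col in go_cols) {
    cells <- df[[col]]
    for (i in seq_along(cells)) {
      cell <- cells[i]
      if (is.na(cell) || cell == "." || cell == "") next
      entries <- strsplit(cell, "`", fixed = TRUE)[[1]]
      parts <- strsplit(entries, "^", fixed = TRUE)
      for (p in parts) {
        if (length(p) < 2L || !grepl("^GO:[0-9]{7}$", p[1])) {
          n_malformed <- n_malformed + 1L
          next
        }
        if (p[2] == "biological_process") {
          g <- genes[i]
          go[[g]] <- c(go[[g]], p[1])
        }
      }
    }
  }
  if (n_malformed > 0L)
    warn_data("%s: skipped %d malformed GO entries", path, n_malformed)
  if (!length(go))
    stop_data("%s: no biological_process GO annotations found", path)
  go <- lapply(go, function(x) sort(unique(x)))
  structure(list(species_id = species_id, go = go), class = "annotation_table")
}

#' Read an OrthoFinder Orthogroups.tsv
#'
#' First column is the orthogroup id; remaining columns are species, with
#' cells holding comma-separated gene lists (possibly empty). Species columns
#' not present in `known_species` (when given) are dropped with a warning;
#' empty cells mean the species is absent from that orthogroup.
#'
#' @param path path to the TSV.
#' @param known_species optional character vector of valid species ids.
#' @return named list: orthogroup id -> named list (species -> character
#'   vector of gene ids). Orthogroups with zero species are retained (they are
#'   removed later by the presence filter).
#' @export
read_orthogroups <- function(path, known_species = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop_data("%s: Orthogroups table needs species columns", path)
  og_ids <- df[[1]]
  if (anyDuplicated(og_ids))
    stop_data("duplicate orthogroup id in %s: %s", path,
              paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "))
  sp_cols <- names(df)[-1]
  if (!is.null(known_species)) {
    unknown <- setdiff(sp_cols, known_species)
    if (length(unknown)) {
      warn_data("%s: ignoring unknown species column(s): %s", path,
                paste(unknown, collapse = ", "))
      sp_cols <- setdiff(sp_cols, unknown)
    }
  }
  out <- vector("list", length(og_ids))
  names(out) <- og_ids
  for (i in seq_along(og_ids)) {
    row <- list()
    for (sp in sp_cols) {
      cell <- df[i, sp]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      genes <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      genes <- genes[nzchar(genes)]
      if (length(genes)) row[[sp]] <- genes
    }
    out[[i]] <- row
  }
  out
}

#' Write a tidy result table
#'
#' Plain TSV writer used for every pipeline output table; fixed formatting so
#' repeated runs are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records input file checksums, parameters and the master seed so a run can
#' be reproduced and verified.
#'
#' @param inputs named character vector of input paths.
#' @param params named list of parameters.
#' @param seed integer master seed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(inputs, params, seed, path) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(unname(inputs))) else list()
  if (length(inputs)) names(checksums) <- names(inputs)
  manifest <- list(
    package = "thermoresp",
    version = as.character(utils::packageVersion("thermoresp")),
    seed = seed,
    parameters = params,
    input_checksums = checksums
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
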