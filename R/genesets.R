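# Gene-set construction: per-species GO term membership, retention rules, the
# boot-strap subset-size rule, and the two-stage orthogroup filter.

#' Build raw GO term gene sets
#'
#' Maps each biological-process GO term to its member genes per species,
#' restricted to retained (expression-filtered) genes. A gene contributes to
#' every GO term it carries.
#'
#' @param annotations named list of `annotation_table`s, one per species.
#' @param retained named list of `retained_gene_set`s for the same species.
#' @return named list: GO id -> named list (species -> character vector of
#'   member gene ids).
#' @export
build_go_sets <- function(annotations, retained) {
  missing <- setdiff(names(annotations), names(retained))
  if (length(missing))
    stop_data("species with annotations but no retained gene set: %s",
              paste(missing, collapse = ", "))
  sets <- list()
  for (sp in names(annotations)) {
    ann <- annotations[[sp]]$go
    keep_genes <- intersect(names(ann), retained[[sp]]$gene_ids)
    for (g in keep_genes) {
      for (term in ann[[g]]) {
        sets[[term]][[sp]] <- c(sets[[term]][[sp]], g)
      }
    }
  }
  lapply(sets, function(by_sp) lapply(by_sp, sort))
}

#' Apply the GO term retention rule
#'
#' A biological-process term is kept when it has at least `min_genes`
#' annotated (and retained) member genes in every species of the universe
#' (`scope = "per_species"`, the default), so that the cross-species minimum
#' member count — which sets the boot-strap subset size — is bounded below.
#' `scope = "total"` instead requires the summed count to reach `min_genes`.
#'
#' @param go_sets raw sets from [build_go_sets()].
#' @param species_universe character vector of all study species.
#' @param min_genes minimum member count, default 10.
#' @param scope `"per_species"` or `"total"`.
#' @param subset_fraction subsampling fraction passed to [subset_size()].
#' @return data.frame with one row per (term, species): `set_id`, `set_type`,
#'   `species_id`, `n_members`, `retained`, `subset_size`; only retained terms
#'   carry a subset size.
#' @export
retain_go_terms <- function(go_sets, species_universe, min_genes = 10,
                            scope = c("per_species", "total"),
                            subset_fraction = 0.75) {
  scope <- match.arg(scope)
  if (min_genes < 1) stop_config("min_genes must be >= 1")
  rows <- list()
  n_retained <- 0L
  for (term in sort(names(go_sets))) {
    counts <- vapply(species_universe, function(sp)
      length(go_sets[[term]][[sp]] %||% character(0)), integer(1))
    keep <- if (scope == "per_species") all(counts >= min_genes)
            else sum(counts) >= min_genes
    size <- if (keep) subset_size(counts, fraction = subset_fraction) else NA_integer_
    if (keep) n_retained <- n_retained + 1L
    rows[[term]] <- data.frame(set_id = term, set_type = "go",
                               species_id = species_universe,
                               n_members = unname(counts),
                               retained = keep, subset_size = size,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_retained == 0L)
    stop_data("no GO terms pass the >= %d members per species rule", min_genes)
  out
}

#' Boot-strap subset size for a gene set
#'
#' The subset size is `fraction` (default 75%) of the minimum member count
#' across species, rounded half-up to the nearest whole integer and floored
#' at 1. Using the cross-species minimum controls for unequal numbers of
#' expressed and annotated genes per species.
#'
#' @param member_counts integer vector of per-species member counts.
#' @param fraction subsampling fraction in (0, 1].
#' @return integer subset size.
#' @export
subset_size <- function(member_counts, fraction = 0.75) {
  if (fraction <= 0 || fraction > 1) stop_config("fraction must be in (0, 1]")
  if (!length(member_counts) || any(member_counts < 1))
    stop_data("subset_size needs positive member counts in every species")
  max(1L, as.integer(round_half_up(fraction * min(member_counts))))
}

#' Two-stage orthogroup retention filter
#'
#' Stage 1 keeps orthogroups present (at least one gene, before the
#' expression filter) in at least `presence_min` species. Stage 2 intersects
#' memberships with the retained gene sets and keeps orthogroups still
#' expressed in at least `expressed_min` species. Both counts are reported.
#'
#' @param orthogroups mapping from [read_orthogroups()].
#' @param retained named list of `retained_gene_set`s.
#' @param presence_min stage-1 species count, default 15.
#' @param expressed_min stage-2 species count, default 12.
#' @return list with `table` (one row per (orthogroup, species) for stage-1
#'   survivors: `set_id`, `set_type`, `species_id`, `n_members`, `retained`,
#'   `n_present`, `n_expressed`) and `members` (retained orthogroup ->
#'   species -> expressed member genes).
#' @export
retain_orthogroups <- function(orthogroups, retained,
                               presence_min = 15, expressed_min = 12) {
  rows <- list()
  members <- list()
  n_kept <- 0L
  for (og in names(orthogroups)) {
    by_sp <- orthogroups[[og]]
    n_present <- length(by_sp)
    if (n_present < presence_min) next
    expressed <- list()
    for (sp in names(by_sp)) {
      if (is.null(retained[[sp]])) next
      genes <- intersect(by_sp[[sp]], retained[[sp]]$gene_ids)
      if (length(genes)) expressed[[sp]] <- genes
    }
    n_expressed <- length(expressed)
    keep <- n_expressed >= expressed_min
    if (keep) {
      n_kept <- n_kept + 1L
      members[[og]] <- expressed
    }
    sp_all <- union(names(by_sp), names(expressed))
    rows[[og]] <- data.frame(
      set_id = og, set_type = "orthogroup", species_id = sp_all,
      n_members = vapply(sp_all, function(sp)
        length(expressed[[sp]] %||% character(0)), integer(1)),
      retained = keep, n_present = n_present, n_expressed = n_expressed,
      stringsAsFactors = FALSE)
  }
  if (n_kept == 0L)
    warn_data("no orthogroups pass the presence >= %d / expressed >= %d filter",
              presence_min, expressed_min)
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(0), set_type = character(0),
               species_id = character(0), n_members = integer(0),
               retained = logical(0), n_present = integer(0),
               n_expressed = integer(0))
  rownames(table) <- NULL
  list(table = table, members = members)
}

#' Assemble the gene-set catalog
#'
#' Combines GO retention, subset sizes and orthogroup retention into the
#' catalog consumed by the boot-strap and modelling stages.
#'
#' @param go_sets raw GO sets from [build_go_sets()].
#' @param orthogroups orthogroup mapping from [read_orthogroups()].
#' @param retained named list of `retained_gene_set`s.
#' @param species_universe character vector of study species.
#' @param min_genes,subset_fraction,presence_min,expressed_min filter
#'   parameters (see the individual rules).
#' @param go_scope retention scope passed to [retain_go_terms()].
#' @return a `geneset_catalog`: list with `go_table`, `go_members` (retained
#'   terms only), `og_table`, `og_members`, `species_universe`, and the
#'   parameters used.
#' @export
build_catalog <- function(go_sets, orthogroups, retained, species_universe,
                          min_genes = 10, subset_fraction = 0.75,
                          presence_min = 15, expressed_min = 12,
                          go_scope = "per_species") {
  go_table <- retain_go_terms(go_sets, species_universe, min_genes = min_genes,
                              scope = go_scope, subset_fraction = subset_fraction)
  kept_terms <- unique(go_table$set_id[go_table$retained])
  og <- retain_orthogroups(orthogroups, retained,
                           presence_min = presence_min,
                           expressed_min = expressed_min)
  structure(list(
    go_table = go_table,
    go_members = go_sets[kept_terms],
    og_table = og$table,
    og_members = og$members,
    species_universe = species_universe,
    params = list(min_genes = min_genes, subset_fraction = subset_fraction,
                  presence_min = presence_min, expressed_min = expressed_min,
                  go_scope = go_scope)
  ), class = "geneset_catalog")
}

#' @export
print.geneset_catalog <- function(x, ...) {
  cat(sprintf("<geneset_catalog> %d retained GO terms, %d retained orthogroups, %d species\n",
              length(x$go_members), length(x$og_members),
              length(x$species_universe)))
  invisible(x)
}

# subset size lookup for one retained term
catalog_subset_size <- function(catalog, term) {
  s <- catalog$go_table$subset_size[catalog$go_table$set_id == term][1]
  if (is.na(s)) stop_data("term %s is not retained in the catalog", term)
  s
}
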