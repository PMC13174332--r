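#' Define a taxonomy mode
#'
#' A mode is a named cell and/or gene subset of a base taxonomy, stored as
#' boolean masks in the taxonomy's unstructured slot rather than as a copy
#' of the data. Cell selectors may be cell set accessions or labels (the
#' union of their memberships) or explicit cell ids; gene selectors are gene
#' ids. An omitted selector means "all".
#'
#' @param taxonomy An `ait_taxonomy`.
#' @param name Mode name, unique within the taxonomy.
#' @param cell_sets Cell set accessions or labels selecting cells.
#' @param cells Explicit cell ids (combined with `cell_sets` by union).
#' @param genes Gene ids for a gene panel mode.
#' @param description Free-text description.
#' @return The taxonomy with the mode registered; base data unchanged.
#' @export
define_mode <- function(taxonomy, name, cell_sets = NULL, cells = NULL,
                        genes = NULL, description = "") {
  stopifnot(inherits(taxonomy, "ait_taxonomy"), is.character(name), nzchar(name))
  if (name %in% names(taxonomy$modes)) {
    abort(sprintf("mode '%s' already defined", name))
  }
  cell_ids <- taxonomy$obs$cell_id
  gene_ids <- taxonomy$var$gene_id

  cell_mask <- rep(TRUE, length(cell_ids))
  if (!is.null(cell_sets) || !is.null(cells)) {
    selected <- character()
    if (!is.null(cell_sets)) {
      cs <- cellsets(taxonomy$hierarchy)
      for (s in cell_sets) {
        hit <- cs$accession[cs$accession == s | cs$label == s]
        if (length(hit) == 0) abort(sprintf("unknown cell set '%s'", s))
        selected <- union(selected, unlist(lapply(hit, cellset_membership,
                                                  hierarchy = taxonomy$hierarchy)))
      }
    }
    if (!is.null(cells)) {
      unknown <- setdiff(cells, cell_ids)
      if (length(unknown) > 0) {
        abort(sprintf("unknown cell id(s): %s", paste(head(unknown, 10), collapse = ", ")))
      }
      selected <- union(selected, cells)
    }
    cell_mask <- cell_ids %in% selected
  }

  gene_mask <- rep(TRUE, length(gene_ids))
  if (!is.null(genes)) {
    unknown <- setdiff(genes, gene_ids)
    if (length(unknown) > 0) {
      abort(sprintf("unknown gene id(s): %s", paste(head(unknown, 10), collapse = ", ")))
    }
    gene_mask <- gene_ids %in% genes
  }

  if (!any(cell_mask)) abort("mode selects no cells")
  if (!any(gene_mask)) abort("mode selects no genes")

  taxonomy$modes[[name]] <- list(
    name = name, cell_mask = cell_mask, gene_mask = gene_mask,
    description = description
  )
  taxonomy
}

#' Apply a taxonomy mode
#'
#' Materializes the derived taxonomy for a registered mode. The hierarchy is
#' pruned to the selected cells. When the cell subset changes, statistics,
#' markers and the dendrogram are recomputed on the subset (means over fewer
#' cells change); when only genes are masked, statistics are sliced from the
#' base (means over fewer genes do not change), markers are filtered to
#' surviving genes, and the dendrogram is rebuilt over the surviving marker
#' union. The base taxonomy is never mutated.
#'
#' @param taxonomy An `ait_taxonomy`.
#' @param name Registered mode name.
#' @param config Build configuration used for any recomputation.
#' @return A derived `ait_taxonomy` (with an empty mode registry).
#' @export
apply_mode <- function(taxonomy, name, config = ait_build_config()) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  mode <- taxonomy$modes[[name]]
  if (is.null(mode)) abort(sprintf("unknown mode '%s'", name))

  cell_ids <- taxonomy$obs$cell_id[mode$cell_mask]
  gene_ids <- taxonomy$var$gene_id[mode$gene_mask]
  cells_change <- !all(mode$cell_mask)
  genes_change <- !all(mode$gene_mask)

  hierarchy <- if (cells_change) {
    prune_hierarchy(taxonomy$hierarchy, cell_ids)
  } else {
    taxonomy$hierarchy
  }
  obs <- taxonomy$obs[mode$cell_mask, , drop = FALSE]
  var <- taxonomy$var[mode$gene_mask, , drop = FALSE]
  X <- if (!is.null(taxonomy$X)) taxonomy$X[mode$cell_mask, mode$gene_mask, drop = FALSE]
  counts <- if (!is.null(taxonomy$counts)) taxonomy$counts[mode$cell_mask, mode$gene_mask, drop = FALSE]

  stats <- NULL
  if (!is.null(taxonomy$stats)) {
    if (cells_change) {
      if (is.null(X)) abort("cell-subset modes need the expression matrix to recompute stats")
      stats <- compute_cluster_stats(X, hierarchy)
      stats <- select_markers(stats, hierarchy, config)
    } else {
      stats <- slice_stats_genes(taxonomy$stats, gene_ids)
    }
  }
  dendro <- if (!is.null(stats)) build_dendrogram(stats, hierarchy, config)

  out <- new_ait_taxonomy(
    taxonomy_id = taxonomy$taxonomy_id, X = X, counts = counts, obs = obs,
    var = var, hierarchy = hierarchy, stats = stats, dendrogram = dendro,
    modes = list(), cas_json = if (cells_change) NULL else taxonomy$cas_json,
    schema_version = taxonomy$schema_version
  )
  attr(out, "applied_mode") <- name
  if (!cells_change && !genes_change) {
    # identity mode: derived equals base apart from the mode registry
    out$stats <- taxonomy$stats
    out$dendrogram <- taxonomy$dendrogram
  }
  out
}

slice_stats_genes <- function(stats, gene_ids) {
  stats$means <- lapply(stats$means, function(m) m[, intersect(colnames(m), gene_ids), drop = FALSE])
  stats$fractions <- lapply(stats$fractions, function(m) m[, intersect(colnames(m), gene_ids), drop = FALSE])
  stats$markers <- lapply(stats$markers, function(g) intersect(g, gene_ids))
  stats$node_markers <- lapply(stats$node_markers, function(g) intersect(g, gene_ids))
  stats$marker_union <- lex_sort(unique(unlist(stats$node_markers, use.names = FALSE)))
  stats
}

#' List registered modes
#'
#' @param taxonomy An `ait_taxonomy`.
#' @return Tibble `name`, `n_cells`, `n_genes`, `description` (empty when no
#'   modes are registered).
#' @export
list_modes <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  if (length(taxonomy$modes) == 0) {
    return(tibble(name = character(), n_cells = integer(),
                  n_genes = integer(), description = character()))
  }
  bind_rows(lapply(taxonomy$modes, function(m) {
    tibble(name = m$name, n_cells = sum(m$cell_mask),
           n_genes = sum(m$gene_mask), description = m$description)
  }))
}
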