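#' Build configuration
#'
#' Fixed-policy knobs for taxonomy building. Normalization is log2(CPM + 1)
#' (counts per million, scale 1e6, log base 2, pseudocount 1); dendrograms
#' use average linkage on 1 - Pearson correlation. Both are part of the
#' format's reproducibility contract and are not configurable.
#'
#' @param markers_per_node Maximum markers retained per child set at each
#'   node (default 20).
#' @param min_fraction_diff Minimum difference in fraction-of-cells-expressing
#'   between a child and its best sibling for a gene to be marker-eligible
#'   (default 0.2).
#' @param seed Integer seed routed to any stochastic step (the default
#'   pipeline is fully deterministic; the seed is recorded for provenance).
#' @return A list of class `ait_build_config`.
#' @export
ait_build_config <- function(markers_per_node = 20L, min_fraction_diff = 0.2,
                             seed = 1L) {
  stopifnot(markers_per_node >= 1, min_fraction_diff >= 0, min_fraction_diff <= 1)
  structure(
    list(
      normalization = "log2cpm", scale = 1e6, pseudocount = 1,
      markers_per_node = as.integer(markers_per_node),
      min_fraction_diff = min_fraction_diff,
      linkage = "average", distance = "1 - Pearson correlation",
      seed = as.integer(seed)
    ),
    class = "ait_build_config"
  )
}

#' Library-size normalization to log2(CPM + 1)
#'
#' @param counts Cell x gene count matrix (dense or `Matrix` sparse), cell
#'   ids as rownames, gene ids as colnames. Cells with zero total counts get
#'   all-zero normalized values.
#' @return Matrix of the same shape and type family with normalized values.
#'   Zeros map to zeros, so sparsity is preserved.
#' @export
normalize_log2cpm <- function(counts) {
  check_counts_matrix(counts)
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1  # empty cells stay all-zero
  if (inherits(counts, "CsparseMatrix")) {
    out <- counts
    cell_of_entry <- out@i + 1L
    out@x <- log2(out@x / lib[cell_of_entry] * 1e6 + 1)
    out
  } else {
    counts <- as_matrix(counts)
    log2(counts / lib * 1e6 + 1)
  }
}

#' Precomputed per-cell-set statistics
#'
#' For every cell set at every level of the hierarchy: the mean normalized
#' expression of each gene over member cells, the fraction of member cells
#' with a nonzero value, and the member count. These are the quantities that
#' downstream mapping uses in place of the full matrix.
#'
#' @param norm_matrix Cell x gene matrix of normalized (log2 CPM + 1) values.
#' @param hierarchy A valid [ait_hierarchy()] whose cells are exactly the
#'   matrix rows.
#' @return A list of class `ait_stats`: `cell_sets` (tibble), `means` and
#'   `fractions` (per-level matrices, cell sets x genes, rownames =
#'   accessions), plus empty marker slots filled by [select_markers()].
#' @export
compute_cluster_stats <- function(norm_matrix, hierarchy) {
  stopifnot(inherits(hierarchy, "ait_hierarchy"))
  asn <- hierarchy$assignments
  if (!setequal(rownames(norm_matrix), asn$cell_id)) {
    abort(sprintf("matrix rows (%d cells) do not match hierarchy cells (%d)",
                  nrow(norm_matrix), nrow(asn)))
  }
  norm_matrix <- norm_matrix[asn$cell_id, , drop = FALSE]
  cs <- cellsets(hierarchy)
  means <- list(); fractions <- list()
  for (lv in hierarchy$levels) {
    sets <- cs[cs$level == lv, ]
    grp <- match(asn[[lv]], sets$label)
    ind <- Matrix::sparseMatrix(i = grp, j = seq_len(nrow(asn)), x = 1,
                                dims = c(nrow(sets), nrow(asn)))
    m <- as.matrix(ind %*% norm_matrix) / sets$n_cells
    f <- as.matrix(ind %*% (norm_matrix > 0)) / sets$n_cells
    dimnames(m) <- dimnames(f) <- list(sets$accession, colnames(norm_matrix))
    means[[lv]] <- m
    fractions[[lv]] <- f
  }
  structure(
    list(levels = hierarchy$levels, cell_sets = cs, means = means,
         fractions = fractions, markers = list(), node_markers = list(),
         marker_union = character()),
    class = "ait_stats"
  )
}

#' @export
print.ait_stats <- function(x, ...) {
  cat(sprintf("<precomputed stats> %d cell sets over %d level(s); %d genes\n",
              nrow(x$cell_sets), length(x$levels), ncol(x$means[[1]])))
  if (length(x$marker_union) > 0) {
    cat(sprintf("  markers: %d nodes, union of %d genes\n",
                length(x$node_markers), length(x$marker_union)))
  }
  invisible(x)
}

#' Tidy view of precomputed statistics
#'
#' @param x An `ait_stats` object.
#' @param ... Unused.
#' @return Long tibble with one row per (cell set, gene):
#'   `accession`, `level`, `gene_id`, `mean`, `fraction_nonzero`.
#' @export
tidy.ait_stats <- function(x, ...) {
  purrr::map_dfr(x$levels, function(lv) {
    m <- x$means[[lv]]
    tibble(
      accession = rep(rownames(m), times = ncol(m)),
      level = lv,
      gene_id = rep(colnames(m), each = nrow(m)),
      mean = as.vector(m),
      fraction_nonzero = as.vector(x$fractions[[lv]])
    )
  })
}

#' One-vs-sibling marker selection
#'
#' At every node of the hierarchy with at least two children (including the
#' implicit root above the coarsest level), each child is scored against its
#' siblings: a gene is eligible when the child's fraction-of-cells-expressing
#' exceeds the best sibling's by at least `min_fraction_diff`, and eligible
#' genes are ranked by the difference between the child's mean and the
#' maximum sibling mean on the normalized scale (positive scores only; ties
#' broken by lexicographic gene id). Up to `markers_per_node` genes are kept
#' per child; a node's marker set is the union over its children. Nodes with
#' a single child get empty lists.
#'
#' @param stats An [compute_cluster_stats()] result.
#' @param hierarchy The matching [ait_hierarchy()].
#' @param config An [ait_build_config()].
#' @return `stats` with `markers` (per cell set: its own ranked marker list),
#'   `node_markers` (per internal node accession and `"root"`: union over
#'   children) and `marker_union` filled in.
#' @export
select_markers <- function(stats, hierarchy, config = ait_build_config()) {
  cs <- stats$cell_sets
  markers <- setNames(vector("list", nrow(cs)), cs$accession)
  node_markers <- list()

  # sibling groups: children of the implicit root, then of each internal set
  groups <- list(list(node = "root", level = stats$levels[1],
                      children = cs$accession[cs$level == stats$levels[1]]))
  if (length(stats$levels) > 1) {
    for (k in 2:length(stats$levels)) {
      lv <- stats$levels[k]
      kids <- cs[cs$level == lv, ]
      for (p in lex_sort(unique(kids$parent_accession))) {
        groups <- c(groups, list(list(
          node = p, level = lv,
          children = kids$accession[kids$parent_accession == p]
        )))
      }
    }
  }

  for (g in groups) {
    if (length(g$children) < 2) {
      node_markers[[g$node]] <- character()
      for (child in g$children) markers[[child]] <- character()
      next
    }
    m <- stats$means[[g$level]][g$children, , drop = FALSE]
    f <- stats$fractions[[g$level]][g$children, , drop = FALSE]
    node_set <- character()
    for (i in seq_along(g$children)) {
      sib_m <- apply(m[-i, , drop = FALSE], 2, max)
      sib_f <- apply(f[-i, , drop = FALSE], 2, max)
      score <- m[i, ] - sib_m
      eligible <- (f[i, ] - sib_f) >= config$min_fraction_diff & score > 0
      genes <- colnames(m)[eligible]
      if (length(genes) > 0) {
        ord <- lex_order(-score[eligible], genes)
        genes <- genes[ord][seq_len(min(config$markers_per_node, length(genes)))]
      }
      markers[[g$children[i]]] <- genes
      node_set <- union(node_set, genes)
    }
    node_markers[[g$node]] <- lex_sort(node_set)
  }

  stats$markers <- markers
  stats$node_markers <- node_markers
  stats$marker_union <- lex_sort(unique(unlist(node_markers, use.names = FALSE)))
  stats
}

#' Centroid dendrogram over leaf cell sets
#'
#' Agglomerative tree (average linkage, distance = 1 - Pearson correlation)
#' over the finest-level cell set mean profiles, restricted to the union of
#' all selected markers (all genes when no markers are available). Leaves
#' are processed in accession order so the result is deterministic; leaf
#' order is the left-to-right traversal of the tree.
#'
#' @param stats An `ait_stats` object (markers optional).
#' @param hierarchy The matching [ait_hierarchy()].
#' @param config An [ait_build_config()].
#' @return Nested list tree; internal nodes are `list(height, children)`,
#'   leaves are `list(label)` where `label` is the leaf set's label.
#' @export
build_dendrogram <- function(stats, hierarchy, config = ait_build_config()) {
  leaf_level <- stats$levels[length(stats$levels)]
  m <- stats$means[[leaf_level]]
  cs <- stats$cell_sets
  labels <- setNames(cs$label, cs$accession)[rownames(m)]
  genes <- stats$marker_union
  if (length(genes) >= 2) m <- m[, genes, drop = FALSE]
  if (nrow(m) == 1) {
    return(list(label = unname(labels[1])))
  }
  ord <- lex_order(rownames(m))
  m <- m[ord, , drop = FALSE]
  labels <- labels[ord]
  cors <- suppressWarnings(cor(t(m)))
  cors[!is.finite(cors)] <- 0
  hc <- hclust(as.dist(1 - cors), method = "average")
  hclust_to_nested(hc, unname(labels))
}

hclust_to_nested <- function(hc, labels) {
  build <- function(i) {
    if (i < 0) return(list(label = labels[-i]))
    row <- hc$merge[i, ]
    list(height = unname(hc$height[i]), children = list(build(row[1]), build(row[2])))
  }
  build(nrow(hc$merge))
}

#' Left-to-right leaf order of a nested dendrogram
#' @param tree A nested tree from [build_dendrogram()].
#' @return Character vector of leaf labels.
#' @export
dendrogram_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, dendrogram_leaves), use.names = FALSE)
}

#' Assemble a taxonomy from raw inputs
#'
#' The build entry point: validates the hierarchy, normalizes counts to
#' log2(CPM + 1), computes per-cell-set statistics, selects one-vs-sibling
#' markers per node, and builds the leaf dendrogram. Deterministic given the
#' config seed (the default pipeline has no stochastic step).
#'
#' @param counts Cell x gene count matrix (rownames cell ids, colnames gene
#'   ids; dense or sparse).
#' @param cell_metadata Data frame keyed by `cell_id` (optional columns).
#' @param gene_metadata Data frame keyed by `gene_id`.
#' @param assignments Assignment data frame (`cell_id` + one column per
#'   level, coarsest first) or an [ait_hierarchy()].
#' @param taxonomy_id Identifier recorded in the file and used as accession
#'   prefix.
#' @param config An [ait_build_config()].
#' @return An object of class `ait_taxonomy`.
#' @examples
#' counts <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' asn <- tibble::tibble(cell_id = c("c1", "c2"), cluster = c("K1", "K2"))
#' tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "toy")
#' glance(tax)
#' @export
build_taxonomy <- function(counts, cell_metadata = NULL, gene_metadata = NULL,
                           assignments, taxonomy_id = "taxonomy",
                           config = ait_build_config()) {
  check_counts_matrix(counts)
  if (anyDuplicated(rownames(counts))) abort("duplicate cell ids in counts")
  if (anyDuplicated(colnames(counts))) abort("duplicate gene ids in counts")

  if (inherits(assignments, "ait_hierarchy")) {
    hierarchy <- ait_hierarchy(assignments$assignments, assignments$levels, taxonomy_id)
  } else {
    hierarchy <- ait_hierarchy(assignments, id_prefix = taxonomy_id)
  }
  rep <- validate_hierarchy(hierarchy)
  if (!is_conformant(rep)) {
    abort(c("hierarchy fails validation; findings:",
            stats::setNames(utils::head(rep$message, 10), rep("x", min(10, nrow(rep))))))
  }
  if (!setequal(hierarchy$assignments$cell_id, rownames(counts))) {
    abort(sprintf("assignments cover %d cells but counts have %d rows (ids differ)",
                  nrow(hierarchy$assignments), nrow(counts)))
  }
  counts <- counts[hierarchy$assignments$cell_id, , drop = FALSE]

  obs <- tibble(cell_id = rownames(counts))
  obs <- left_join(obs, hierarchy$assignments, by = "cell_id")
  if (!is.null(cell_metadata)) {
    cm <- as_tibble(cell_metadata)
    if (!"cell_id" %in% names(cm)) abort("`cell_metadata` must have a `cell_id` column")
    obs <- left_join(obs, cm, by = "cell_id")
  }
  var <- tibble(gene_id = colnames(counts))
  if (!is.null(gene_metadata)) {
    gm <- as_tibble(gene_metadata)
    if (!"gene_id" %in% names(gm)) abort("`gene_metadata` must have a `gene_id` column")
    var <- left_join(var, gm, by = "gene_id")
  }

  X <- normalize_log2cpm(counts)
  stats <- compute_cluster_stats(X, hierarchy)
  stats <- select_markers(stats, hierarchy, config)
  dendro <- build_dendrogram(stats, hierarchy, config)

  new_ait_taxonomy(
    taxonomy_id = taxonomy_id, X = X, counts = counts, obs = obs, var = var,
    hierarchy = hierarchy, stats = stats, dendrogram = dendro
  )
}

new_ait_taxonomy <- function(taxonomy_id, X = NULL, counts = NULL, obs, var,
                             hierarchy, stats = NULL, dendrogram = NULL,
                             modes = list(), cas_json = NULL,
                             schema_version = AIT_SCHEMA_VERSION) {
  structure(
    list(
      taxonomy_id = taxonomy_id, schema_version = schema_version,
      X = X, counts = counts, obs = obs, var = var, hierarchy = hierarchy,
      stats = stats, dendrogram = dendrogram, modes = modes, cas_json = cas_json
    ),
    class = "ait_taxonomy"
  )
}

# dialect version written into files by this implementation
AIT_SCHEMA_VERSION <- "1.0.0"

#' @export
print.ait_taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy '%s'> schema %s\n", x$taxonomy_id, x$schema_version))
  cat(sprintf("  %d cells x %d genes (%s)\n", nrow(x$obs), nrow(x$var),
              if (is.null(x$X)) "lightweight: no matrix" else "normalized matrix present"))
  print(x$hierarchy)
  cat(sprintf("  stats: %s | dendrogram: %s | CAS: %s | modes: %d\n",
              if (is.null(x$stats)) "absent" else "present",
              if (is.null(x$dendrogram)) "absent" else "present",
              if (is.null(x$cas_json)) "absent" else "embedded",
              length(x$modes)))
  invisible(x)
}

#' @export
tidy.ait_taxonomy <- function(x, ...) {
  cellsets(x$hierarchy)
}

#' @export
glance.ait_taxonomy <- function(x, ...) {
  tibble(
    taxonomy_id = x$taxonomy_id,
    schema_version = x$schema_version,
    n_cells = nrow(x$obs),
    n_genes = nrow(x$var),
    n_levels = length(x$hierarchy$levels),
    n_cell_sets = nrow(cellsets(x$hierarchy)),
    has_matrix = !is.null(x$X),
    has_stats = !is.null(x$stats),
    has_cas = !is.null(x$cas_json),
    n_modes = length(x$modes)
  )
}
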