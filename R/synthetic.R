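#' Simulation configuration
#'
#' Parameters of the synthetic hierarchically clustered scRNA-seq generator.
#' Defaults produce a 3-class x 3-subclass x 3-cluster taxonomy (27 leaf
#' clusters, 50 cells each, 1350 cells) over 300 genes, with 10 planted
#' marker genes per tree node elevated by 3 log2 units, negative-binomial
#' counts (gene dispersion 0.5) and lognormal library sizes
#' (meanlog 9.2, sdlog 0.3; median ~9900 counts per cell).
#'
#' @param n_classes,subclasses_per_class,clusters_per_subclass Tree shape.
#' @param cells_per_cluster Cells per leaf cluster.
#' @param n_genes Number of genes.
#' @param markers_per_node Planted markers per tree node.
#' @param log2_fc Planted marker elevation in log2 units.
#' @param baseline_mean Relative expression of non-marker genes.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param library_meanlog,library_sdlog Lognormal library-size parameters
#'   (natural-log scale).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A list of class `ait_sim_config`.
#' @export
ait_sim_config <- function(n_classes = 3L, subclasses_per_class = 3L,
                           clusters_per_subclass = 3L, cells_per_cluster = 50L,
                           n_genes = 300L, markers_per_node = 10L,
                           log2_fc = 3.0, baseline_mean = 1.0,
                           dispersion = 0.5, library_meanlog = 9.2,
                           library_sdlog = 0.3, seed = 1L) {
  sizes <- c(n_classes, subclasses_per_class, clusters_per_subclass,
             cells_per_cluster, n_genes, markers_per_node)
  if (any(sizes <= 0)) abort("all size parameters must be positive")
  if (baseline_mean <= 0 || dispersion <= 0) abort("baseline_mean and dispersion must be positive")
  structure(as.list(environment()), class = "ait_sim_config")
}

#' Simulate a hierarchically clustered single-cell dataset
#'
#' Generates a cell x gene count matrix with planted hierarchical structure:
#' a balanced class/subclass/cluster tree in which every node carries a set
#' of planted marker genes whose relative expression is elevated by
#' `log2_fc` in all cells of that node's subtree. Counts are negative
#' binomial around cell-specific means obtained by scaling each cell's
#' relative expression profile to a lognormal library size. Marker genes are
#' assigned so that sibling nodes never share a marker (genes may be reused
#' across unrelated subtrees when the gene pool is smaller than the total
#' number of marker slots; unused genes are preferred).
#'
#' @param config An [ait_sim_config()].
#' @return A list with `counts` (dense integer-valued matrix), `cell_metadata`
#'   and `gene_metadata` tibbles, `assignments` (cell_id, class, subclass,
#'   cluster), and `truth`: the generator's ground truth (`tree` tibble of
#'   nodes with parents, `markers` named list node -> planted genes,
#'   `profiles` cluster x gene matrix of relative expression, plus the
#'   config).
#' @examples
#' sim <- simulate_taxonomy_dataset(ait_sim_config(n_genes = 60, cells_per_cluster = 5))
#' dim(sim$counts)
#' @export
simulate_taxonomy_dataset <- function(config = ait_sim_config()) {
  stopifnot(inherits(config, "ait_sim_config"))
  withr::with_seed(config$seed, simulate_taxonomy_dataset_impl(config))
}

simulate_taxonomy_dataset_impl <- function(config) {
  nodes <- sim_tree(config)
  markers <- sim_assign_markers(nodes, config)

  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  clusters <- nodes$node[nodes$level == "cluster"]
  profiles <- matrix(config$baseline_mean, nrow = length(clusters),
                     ncol = config$n_genes, dimnames = list(clusters, gene_ids))
  for (cl in clusters) {
    lineage <- c(cl, nodes$parent[nodes$node == cl],
                 nodes$parent[nodes$node == nodes$parent[nodes$node == cl]])
    planted <- unique(unlist(markers[lineage], use.names = FALSE))
    profiles[cl, planted] <- profiles[cl, planted] * 2^config$log2_fc
  }

  n_cells <- length(clusters) * config$cells_per_cluster
  cell_cluster <- rep(clusters, each = config$cells_per_cluster)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  counts <- sim_counts(profiles, cell_cluster, config)
  dimnames(counts) <- list(cell_ids, gene_ids)

  parent_of <- setNames(nodes$parent, nodes$node)
  assignments <- tibble(
    cell_id = cell_ids,
    class = unname(parent_of[parent_of[cell_cluster]]),
    subclass = unname(parent_of[cell_cluster]),
    cluster = cell_cluster
  )

  list(
    counts = counts,
    cell_metadata = tibble(cell_id = cell_ids,
                           library_size = unname(Matrix::rowSums(counts))),
    gene_metadata = tibble(gene_id = gene_ids),
    assignments = assignments,
    truth = list(tree = nodes, markers = markers, profiles = profiles,
                 config = config)
  )
}

sim_tree <- function(config) {
  rows <- list()
  for (a in seq_len(config$n_classes)) {
    cls <- sprintf("C%d", a)
    rows <- c(rows, list(tibble(node = cls, level = "class", parent = NA_character_)))
    for (b in seq_len(config$subclasses_per_class)) {
      sub <- sprintf("%s.S%d", cls, b)
      rows <- c(rows, list(tibble(node = sub, level = "subclass", parent = cls)))
      for (d in seq_len(config$clusters_per_subclass)) {
        rows <- c(rows, list(tibble(node = sprintf("%s.K%d", sub, d),
                                    level = "cluster", parent = sub)))
      }
    }
  }
  bind_rows(rows)
}

# Sibling-disjoint planted markers. Children of one parent draw from a shared
# pool excluding their ancestors' markers; genes not yet used anywhere are
# preferred so reuse only happens when slots exceed the gene pool.
sim_assign_markers <- function(nodes, config) {
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  usage <- setNames(integer(length(gene_ids)), gene_ids)
  markers <- list()
  ancestors <- function(node) {
    out <- character()
    while (!is.na(node)) {
      out <- c(out, node)
      node <- nodes$parent[nodes$node == node]
    }
    out
  }
  parents <- c(NA_character_, unique(nodes$parent[!is.na(nodes$parent)]))
  for (p in parents) {
    kids <- nodes$node[if (is.na(p)) is.na(nodes$parent) else !is.na(nodes$parent) & nodes$parent == p]
    excl <- if (is.na(p)) character() else unique(unlist(markers[ancestors(p)], use.names = FALSE))
    taken_in_group <- character()
    for (kid in kids) {
      avail <- setdiff(gene_ids, c(excl, taken_in_group))
      if (length(avail) < config$markers_per_node) {
        abort("gene pool too small for sibling-disjoint marker assignment")
      }
      # fresh genes first, then least-reused
      avail <- avail[order(usage[avail], sample.int(length(avail)))]
      chosen <- avail[seq_len(config$markers_per_node)]
      markers[[kid]] <- lex_sort(chosen)
      usage[chosen] <- usage[chosen] + 1L
      taken_in_group <- c(taken_in_group, chosen)
    }
  }
  markers
}

sim_counts <- function(profiles, cell_cluster, config,
                       extra_dispersion = 0) {
  n_cells <- length(cell_cluster)
  n_genes <- ncol(profiles)
  # lognormal sequencing depths, median-normalized: the distribution sets the
  # relative per-cell scale factor; `baseline_mean` is the NB mean of an
  # unelevated gene in a median-depth cell
  depth <- rlnorm(n_cells, config$library_meanlog, config$library_sdlog)
  s <- depth / exp(config$library_meanlog)
  mu <- profiles[cell_cluster, , drop = FALSE] * s
  size <- 1 / (config$dispersion + extra_dispersion)
  counts <- matrix(rnbinom(n_cells * n_genes, size = size, mu = as.vector(mu)),
                   nrow = n_cells, ncol = n_genes)
  storage.mode(counts) <- "double"
  counts
}

#' Simulate held-out query cells from an existing truth
#'
#' Draws new cells from the generator's per-cluster models, optionally with
#' extra negative-binomial dispersion (`noise_scale` is added to the config's
#' dispersion), and returns their true cluster labels.
#'
#' @param truth The `truth` component of [simulate_taxonomy_dataset()].
#' @param n_per_cluster New cells per cluster (0 gives an empty result).
#' @param noise_scale Extra dispersion added to the generative model
#'   (0 = same model as the reference cells).
#' @param seed Integer seed.
#' @param clusters Clusters to draw from (default all).
#' @return List with `counts` (cells x genes) and `true_labels` tibble
#'   (`cell_id`, `cluster`, `subclass`, `class`).
#' @export
simulate_query_cells <- function(truth, n_per_cluster = 20L, noise_scale = 0,
                                 seed = 1L, clusters = NULL) {
  stopifnot(is.list(truth), !is.null(truth$profiles))
  all_clusters <- rownames(truth$profiles)
  clusters <- clusters %||% all_clusters
  unknown <- setdiff(clusters, all_clusters)
  if (length(unknown) > 0) {
    abort(sprintf("unknown cluster(s): %s", paste(unknown, collapse = ", ")))
  }
  if (n_per_cluster == 0) {
    return(list(
      counts = matrix(0, 0, ncol(truth$profiles),
                      dimnames = list(NULL, colnames(truth$profiles))),
      true_labels = tibble(cell_id = character(), cluster = character(),
                           subclass = character(), class = character())
    ))
  }
  withr::with_seed(seed, {
    cell_cluster <- rep(clusters, each = n_per_cluster)
    counts <- sim_counts(truth$profiles, cell_cluster, truth$config,
                         extra_dispersion = noise_scale)
    cell_ids <- sprintf("query%05d", seq_along(cell_cluster))
    dimnames(counts) <- list(cell_ids, colnames(truth$profiles))
    parent_of <- setNames(truth$tree$parent, truth$tree$node)
    list(
      counts = counts,
      true_labels = tibble(
        cell_id = cell_ids,
        cluster = cell_cluster,
        subclass = unname(parent_of[cell_cluster]),
        class = unname(parent_of[parent_of[cell_cluster]])
      )
    )
  })
}

#' Simulate a canonical biospecimen provenance chain
#'
#' Produces the canonical entity chain for one assay class, with identifiers
#' generated by [make_nhash_id()]. With `with_optionals = TRUE` the optional
#' entities (slab, enriched cell sample, amplified cDNA, where the class
#' permits them) are included. The result validates cleanly under
#' [validate_chain()].
#'
#' @param assay_class One of `"dissociated"`, `"multiome_like"`,
#'   `"seq_spatial"`, `"img_spatial"`.
#' @param with_optionals Include optional entities.
#' @param seed Integer seed (salts the identifiers).
#' @return Entity tibble as accepted by [validate_chain()].
#' @export
simulate_provenance_chain <- function(assay_class = "dissociated",
                                      with_optionals = FALSE, seed = 1L) {
  grammar <- assay_grammar(assay_class)  # errors on unknown class
  salt <- as.character(seed)
  seq_types <- grammar$sequence
  if (!with_optionals) seq_types <- setdiff(seq_types, grammar$optional)

  rows <- list()
  prev_id <- NULL
  for (tp in seq_types) {
    id <- make_nhash_id(tp, prev_id %||% "", paste0("sim-", tp), salt)
    parents <- if (is.null(prev_id)) character() else prev_id
    attributes <- list()
    if (tp == "SC") {
      su_id <- make_nhash_id("SU", "", "sim-SU", salt)
      rows <- c(rows, list(tibble(
        id = su_id, type = "SU", parents = list(character()),
        process = "substrate preparation", attributes = list(list())
      )))
      parents <- c(parents, su_id)
    }
    if (tp == "BC" && assay_class == "img_spatial") attributes$analog <- TRUE
    rows <- c(rows, list(tibble(
      id = id, type = tp, parents = list(parents),
      process = default_process_label(tp), attributes = list(attributes)
    )))
    prev_id <- id
  }

  entities <- bind_rows(rows)

  # multiome-like: two libraries (RNA + chromatin) from the one barcoded
  # sample, pooled at the end
  if (assay_class == "multiome_like") {
    bc_id <- entities$id[entities$type == "BC"]
    anchor <- if ("AC" %in% entities$type) entities$id[entities$type == "AC"] else bc_id
    entities <- entities[!entities$type %in% c("LI", "LA", "LP"), ]
    la_ids <- character()
    for (mod in c("atac", "rna")) {
      li <- make_nhash_id("LI", anchor, paste0("sim-LI-", mod), salt)
      la <- make_nhash_id("LA", li, paste0("sim-LA-", mod), salt)
      entities <- bind_rows(entities,
        tibble(id = li, type = "LI", parents = list(anchor),
               process = default_process_label("LI"),
               attributes = list(list(modality = mod))),
        tibble(id = la, type = "LA", parents = list(li),
               process = default_process_label("LA"),
               attributes = list(list(modality = mod))))
      la_ids <- c(la_ids, la)
    }
    lp <- make_nhash_id("LP", paste(la_ids, collapse = ","), "sim-LP", salt)
    entities <- bind_rows(entities,
      tibble(id = lp, type = "LP", parents = list(la_ids),
             process = default_process_label("LP"), attributes = list(list())))
  }
  entities
}

default_process_label <- function(type) {
  c(DO = "donor enrollment", SL = "slab sectioning", RI = "region dissection",
    TI = "tissue sampling", SC = "cryosectioning", DC = "dissociation",
    EC = "cell enrichment", BC = "barcoding chemistry", AC = "cDNA amplification",
    LI = "library construction", LA = "library aliquoting", LP = "library pooling",
    SU = "substrate preparation")[[type]]
}
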