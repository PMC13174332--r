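#' Map query cells onto a taxonomy (flat correlation)
#'
#' Normalizes the query counts exactly as the builder does (log2 CPM + 1)
#' and correlates each query cell with every finest-level cell set mean over
#' the genes shared between the query and the taxonomy's marker union (all
#' taxonomy genes when no markers are stored). Each cell is assigned to the
#' best-correlated leaf; ties break to the lowest accession. A query cell
#' with constant expression over the shared genes has no defined correlation
#' and is assigned the first leaf with score 0 and flag
#' `"constant_query"`.
#'
#' @param taxonomy An `ait_taxonomy` with precomputed stats.
#' @param query_counts Query cell x gene count matrix (rownames cell ids).
#' @param query_genes Gene ids of the query columns (default: colnames).
#' @return A tibble of class `ait_mapping`: `cell_id`, `accession`, `label`,
#'   `score`, `path` and `path_scores` (list-columns root -> leaf),
#'   `confidence` (`NA` until [bootstrap_confidence()]), `flag`.
#' @export
map_flat <- function(taxonomy, query_counts, query_genes = colnames(query_counts)) {
  prep <- prepare_query(taxonomy, query_counts, query_genes)
  leaf_level <- taxonomy$stats$levels[length(taxonomy$stats$levels)]
  res <- correlate_assign(prep$qnorm, taxonomy$stats$means[[leaf_level]], prep$genes)
  cs <- cellsets(taxonomy$hierarchy)
  label_of <- setNames(cs$label, cs$accession)
  out <- tibble(
    cell_id = rownames(prep$qnorm),
    accession = res$accession,
    label = unname(label_of[res$accession]),
    score = res$score,
    path = lapply(res$accession, function(a) accession_path(cs, a)),
    path_scores = lapply(res$score, function(s) s),
    confidence = NA_real_,
    flag = res$flag
  )
  new_ait_mapping(out, method = "flat", genes = prep$genes)
}

#' Map query cells onto a taxonomy (hierarchical descent)
#'
#' Greedy root-to-leaf descent: at each node the query cell is correlated
#' with the node's children over that node's marker-union genes (restricted
#' to genes shared with the query), and descends into the best-correlated
#' child until a finest-level set is reached. When a node's markers share no
#' genes with the query, all shared genes are used at that node and the cell
#' is flagged `"marker_fallback"`. A one-level taxonomy reduces to
#' [map_flat()].
#'
#' @inheritParams map_flat
#' @return An `ait_mapping` tibble; `path` and `path_scores` hold the
#'   accessions and per-step correlations from the coarsest level down.
#' @export
map_hierarchical <- function(taxonomy, query_counts, query_genes = colnames(query_counts)) {
  prep <- prepare_query(taxonomy, query_counts, query_genes)
  st <- taxonomy$stats
  if (length(st$node_markers) == 0) {
    abort("taxonomy stats lack per-node markers; rebuild with select_markers()")
  }
  cs <- cellsets(taxonomy$hierarchy)
  n <- nrow(prep$qnorm)
  n_levels <- length(st$levels)
  assigned <- rep("root", n)
  paths <- replicate(n, character(), simplify = FALSE)
  path_scores <- replicate(n, numeric(), simplify = FALSE)
  flags <- rep(NA_character_, n)

  for (k in seq_len(n_levels)) {
    lv <- st$levels[k]
    kids_tab <- cs[cs$level == lv, ]
    for (node in unique(assigned)) {
      idx <- which(assigned == node)
      children <- if (node == "root") kids_tab$accession else
        kids_tab$accession[kids_tab$parent_accession == node]
      if (length(children) == 1) {
        for (i in idx) {
          paths[[i]] <- c(paths[[i]], children)
          path_scores[[i]] <- c(path_scores[[i]], NA_real_)
        }
        assigned[idx] <- children
        next
      }
      node_genes <- intersect(st$node_markers[[node]] %||% character(), prep$genes)
      fallback <- length(node_genes) == 0
      if (fallback) node_genes <- prep$genes
      res <- correlate_assign(prep$qnorm[idx, , drop = FALSE],
                              st$means[[lv]][children, , drop = FALSE], node_genes)
      for (j in seq_along(idx)) {
        i <- idx[j]
        paths[[i]] <- c(paths[[i]], res$accession[j])
        path_scores[[i]] <- c(path_scores[[i]], res$score[j])
        if (fallback) flags[i] <- "marker_fallback"
        if (!is.na(res$flag[j])) flags[i] <- res$flag[j]
      }
      assigned[idx] <- res$accession
    }
  }

  label_of <- setNames(cs$label, cs$accession)
  out <- tibble(
    cell_id = rownames(prep$qnorm),
    accession = assigned,
    label = unname(label_of[assigned]),
    score = vapply(path_scores, function(s) s[length(s)], numeric(1)),
    path = paths,
    path_scores = path_scores,
    confidence = NA_real_,
    flag = flags
  )
  new_ait_mapping(out, method = "hierarchical", genes = prep$genes)
}

#' Bootstrap confidence for cell type assignments
#'
#' Re-runs the chosen mapper `n_boot` times, each time on a random subsample
#' of the shared marker-union genes (a fraction `subsample`, drawn without
#' replacement), and reports for each query cell the fraction of bootstrap
#' assignments that agree with the full-marker assignment.
#'
#' @inheritParams map_flat
#' @param method `"flat"` or `"hierarchical"`.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param subsample Fraction of marker genes retained per replicate.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return The full-gene `ait_mapping` with the `confidence` column filled.
#' @export
bootstrap_confidence <- function(taxonomy, query_counts,
                                 query_genes = colnames(query_counts),
                                 method = c("hierarchical", "flat"),
                                 n_boot = 100L, subsample = 0.7, seed = 1L) {
  method <- match.arg(method)
  if (n_boot < 1) abort("`n_boot` must be at least 1")
  stopifnot(subsample > 0, subsample <= 1)
  mapper <- if (method == "flat") map_flat else map_hierarchical
  full <- mapper(taxonomy, query_counts, query_genes)
  genes <- attr(full, "genes")
  n_take <- ceiling(subsample * length(genes))
  hits <- integer(nrow(full))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      keep <- sample(genes, n_take)
      qc <- query_counts[, match(keep, query_genes), drop = FALSE]
      bt <- mapper(taxonomy, qc, keep)
      hits <- hits + as.integer(bt$accession == full$accession)
    }
  })
  full$confidence <- hits / n_boot
  full
}

# --- internals ---------------------------------------------------------------

prepare_query <- function(taxonomy, query_counts, query_genes) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  if (is.null(taxonomy$stats)) abort("taxonomy has no precomputed stats; run build_taxonomy()")
  if (is.null(dim(query_counts))) abort("`query_counts` must be a cell x gene matrix")
  if (length(query_genes) != ncol(query_counts)) {
    abort("`query_genes` must have one entry per query matrix column")
  }
  colnames(query_counts) <- query_genes
  if (is.null(rownames(query_counts))) {
    rownames(query_counts) <- sprintf("query%05d", seq_len(nrow(query_counts)))
  }
  ref_genes <- taxonomy$stats$marker_union
  if (length(ref_genes) == 0) ref_genes <- colnames(taxonomy$stats$means[[1]])
  genes <- intersect(ref_genes, query_genes)
  if (length(genes) == 0) {
    abort(sprintf(
      "no overlap between query genes (%d) and taxonomy mapping genes (%d)",
      length(query_genes), length(ref_genes)))
  }
  qnorm <- normalize_log2cpm(query_counts)
  list(qnorm = as_matrix(qnorm), genes = genes)
}

# Pearson correlation of each query row against each centroid row over
# `genes`; argmax with ties to the lowest accession (row order of centroids
# is sorted by accession).
correlate_assign <- function(qnorm, centroids, genes) {
  centroids <- centroids[lex_order(rownames(centroids)), genes, drop = FALSE]
  q <- qnorm[, genes, drop = FALSE]
  cors <- suppressWarnings(cor(t(q), t(centroids)))
  flag <- rep(NA_character_, nrow(q))
  constant <- !is.finite(matrixStats_rowSds(q))
  bad <- apply(!is.finite(cors), 1, all)
  cors[!is.finite(cors)] <- 0
  pick <- max.col(cors, ties.method = "first")
  score <- cors[cbind(seq_len(nrow(cors)), pick)]
  flag[bad | constant] <- "constant_query"
  score[bad] <- 0
  list(accession = rownames(centroids)[pick], score = score, flag = flag)
}

# sd per row without the matrixStats dependency; returns NaN for constant rows
matrixStats_rowSds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  out <- sqrt(v)
  out[v == 0] <- NaN
  out
}

accession_path <- function(cs, accession) {
  path <- accession
  repeat {
    p <- cs$parent_accession[cs$accession == path[1]]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

new_ait_mapping <- function(tbl, method, genes) {
  class(tbl) <- unique(c("ait_mapping", class(tbl)))
  attr(tbl, "method") <- method
  attr(tbl, "genes") <- genes
  tbl
}

#' @export
glance.ait_mapping <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_cells = nrow(x),
    n_genes_used = length(attr(x, "genes")),
    mean_score = mean(x$score),
    mean_confidence = if (all(is.na(x$confidence))) NA_real_ else mean(x$confidence),
    n_flagged = sum(!is.na(x$flag))
  )
}

#' Write a mapping result
#'
#' Writes the per-cell assignments as TSV (`cell_id`, `leaf`, `label`,
#' `path` joined by `"/"`, `score`, `confidence`, `flag`) and optionally as
#' JSON alongside.
#'
#' @param mapping An `ait_mapping`.
#' @param path Output TSV path.
#' @param json Also write `<path>.json`.
#' @export
write_mapping <- function(mapping, path, json = FALSE) {
  flat <- tibble(
    cell_id = mapping$cell_id,
    leaf = mapping$accession,
    label = mapping$label,
    path = vapply(mapping$path, paste, character(1), collapse = "/"),
    score = mapping$score,
    confidence = mapping$confidence,
    flag = mapping$flag
  )
  readr::write_tsv(flat, path, progress = FALSE)
  if (json) {
    jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
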