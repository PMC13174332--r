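# Independent oracles: deliberately naive implementations used to check the
# package's vectorized paths.

# group means / nonzero fractions by explicit per-set loops over the
# assignment table
naive_group_stats <- function(norm, assignments, level) {
  labels <- sort(unique(assignments[[level]]), method = "radix")
  means <- matrix(NA_real_, length(labels), ncol(norm),
                  dimnames = list(labels, colnames(norm)))
  fracs <- means
  for (lb in labels) {
    cells <- assignments$cell_id[assignments[[level]] == lb]
    sub <- norm[cells, , drop = FALSE]
    means[lb, ] <- colMeans(sub)
    fracs[lb, ] <- colMeans(sub > 0)
  }
  list(means = means, fractions = fracs)
}

# per-cell, per-leaf correlation loop; ties to the first (lowest) accession
naive_nearest_centroid <- function(qnorm, centroids, genes) {
  centroids <- centroids[sort(rownames(centroids), method = "radix"), genes, drop = FALSE]
  acc <- character(nrow(qnorm)); sc <- numeric(nrow(qnorm))
  for (i in seq_len(nrow(qnorm))) {
    cors <- numeric(nrow(centroids))
    for (j in seq_len(nrow(centroids))) {
      cors[j] <- suppressWarnings(stats::cor(qnorm[i, genes], centroids[j, ]))
    }
    cors[!is.finite(cors)] <- 0
    k <- which.max(cors)
    acc[i] <- rownames(centroids)[k]
    sc[i] <- cors[k]
  }
  list(accession = acc, score = sc)
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# cut a nested binary dendrogram into k groups by splitting the k-1 highest
# internal nodes
cut_nested <- function(tree, k) {
  heights <- collect_heights(tree)
  thr <- sort(heights, decreasing = TRUE)[k - 1]
  groups <- list()
  descend <- function(node) {
    if (is.null(node$label) && node$height >= thr) {
      for (ch in node$children) descend(ch)
    } else {
      groups[[length(groups) + 1]] <<- dendrogram_leaves(node)
    }
  }
  descend(tree)
  membership <- integer()
  for (i in seq_along(groups)) {
    membership[groups[[i]]] <- i
  }
  membership
}

collect_heights <- function(tree) {
  if (!is.null(tree$label)) return(numeric())
  c(tree$height, unlist(lapply(tree$children, collect_heights)))
}

# single-edit chain mutation harness: each mutant makes exactly one edit that
# breaks the grammar of `assay_class`
chain_mutations <- function(entities, assay_class, n = 50, seed = 1) {
  grammar_forbidden <- c(dissociated = "SC", multiome_like = "SC",
                         seq_spatial = "EC", img_spatial = "LI")
  withr::with_seed(seed, {
    muts <- list()
    non_do <- which(entities$type != "DO" & entities$type != "SU")
    kinds <- c("retype_forbidden", "orphan", "extra_parent", "swap_types",
               "duplicate_stage")
    ki <- 0L
    while (length(muts) < n) {
      ki <- ki + 1L
      kind <- kinds[(ki - 1L) %% length(kinds) + 1L]
      i <- sample(non_do, 1)
      e <- entities
      desc <- kind
      if (kind == "retype_forbidden") {
        e$type[i] <- grammar_forbidden[[assay_class]]
      } else if (kind == "orphan") {
        e$parents[[i]] <- character()
      } else if (kind == "extra_parent") {
        others <- setdiff(e$id[e$type %in% c("DO", "RI", "TI")], c(e$id[i], e$parents[[i]]))
        if (length(others) == 0) next
        if (e$type[i] %in% c("LP", "SC")) next  # these legitimately multi-parent
        e$parents[[i]] <- c(e$parents[[i]], others[1])
      } else if (kind == "swap_types") {
        p <- e$parents[[i]]
        p <- p[e$type[match(p, e$id)] != "SU"]
        if (length(p) != 1) next
        j <- match(p, e$id)
        if (e$type[j] == "DO") next  # donors stay donors
        tmp <- e$type[i]; e$type[i] <- e$type[j]; e$type[j] <- tmp
      } else if (kind == "duplicate_stage") {
        if (assay_class == "multiome_like" && e$type[i] %in% c("LI", "LA")) next
        dup <- entities[i, ]
        dup$id <- paste0(dup$id, "-dup")
        e <- rbind(e, dup)
      }
      muts[[length(muts) + 1]] <- list(entities = e, edit = desc,
                                       target = entities$id[i])
    }
    muts
  })
}
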