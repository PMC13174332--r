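test_that("log2 CPM normalization matches the closed form and is invertible", {
  counts <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  asn <- tibble::tibble(cell_id = c("c1", "c2"), cluster = c("K1", "K2"))
  tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "t2")

  expect_equal(tax$stats$means$cluster["t2:0001", "g1"], log2(1e6 * 10 / 10 + 1))
  expect_equal(unname(tax$stats$fractions$cluster),
               matrix(c(1, 0, 0, 1), 2, byrow = TRUE))

  # invertible up to library size for integer counts
  cm <- toy_counts()
  norm <- normalize_log2cpm(cm)
  lib <- rowSums(cm)
  back <- (2^norm - 1) * lib / 1e6
  expect_equal(back, cm, tolerance = 1e-12)

  # sparse and dense agree, zeros stay zero
  sp <- Matrix::Matrix(cm, sparse = TRUE)
  expect_equal(as.matrix(normalize_log2cpm(sp)), norm)
  expect_equal(norm == 0, cm == 0)
})

test_that("a single all-cells cluster degenerates gracefully", {
  counts <- toy_counts()
  asn <- tibble::tibble(cell_id = rownames(counts), cluster = "K1")
  tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "one")
  expect_equal(nrow(tax$stats$means$cluster), 1)
  expect_equal(tax$dendrogram, list(label = "K1"))
  expect_equal(tax$stats$markers[["one:0001"]], character())
  expect_equal(tax$stats$marker_union, character())
})

test_that("cluster stats equal a naive group-by loop within 1e-10", {
  sim <- synth_dataset()
  cells <- sim$assignments$cell_id[1:500]
  counts <- sim$counts[cells, 1:100]
  asn <- sim$assignments[sim$assignments$cell_id %in% cells, ]
  h <- ait_hierarchy(asn)
  norm <- normalize_log2cpm(counts)
  st <- compute_cluster_stats(norm, h)
  cs <- cellsets(h)
  for (lv in h$levels) {
    oracle <- naive_group_stats(norm, asn, lv)
    labels <- cs$label[cs$level == lv]
    expect_lt(max(abs(st$means[[lv]] - oracle$means[labels, ])), 1e-10)
    expect_lt(max(abs(st$fractions[[lv]] - oracle$fractions[labels, ])), 1e-10)
  }
  # n_cells bookkeeping at the leaf level
  leaf <- st$cell_sets[st$cell_sets$level == "cluster", ]
  expect_equal(leaf$n_cells,
               unname(as.integer(table(asn$cluster)[leaf$label])))
})

test_that("parent means are the n-weighted average of child means", {
  tax <- synth_taxonomy()
  st <- tax$stats
  cs <- st$cell_sets
  subs <- cs[cs$level == "subclass", ]
  for (i in seq_len(nrow(subs))) {
    kids <- cs[!is.na(cs$parent_accession) & cs$parent_accession == subs$accession[i], ]
    w <- kids$n_cells / sum(kids$n_cells)
    expect_equal(st$means$subclass[subs$accession[i], ],
                 colSums(st$means$cluster[kids$accession, , drop = FALSE] * w),
                 tolerance = 1e-10)
  }
})

test_that("marker selection honors the fraction gate and sibling contrast", {
  # gene expressed only in K1 becomes K1's top marker
  counts <- matrix(c(50, 5, 5, 0, 5, 5,
                     40, 6, 4, 0, 4, 6,
                     0, 5, 5, 30, 5, 5,
                     0, 4, 6, 45, 6, 4),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(sprintf("c%d", 1:4), sprintf("g%d", 1:6)))
  asn <- tibble::tibble(cell_id = sprintf("c%d", 1:4),
                        cluster = c("K1", "K1", "K2", "K2"))
  tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "mk")
  cs <- cellsets(tax$hierarchy)
  k1 <- cs$accession[cs$label == "K1"]
  k2 <- cs$accession[cs$label == "K2"]
  expect_equal(tax$stats$markers[[k1]][1], "g1")
  expect_equal(tax$stats$markers[[k2]][1], "g4")

  # identical profiles: nothing passes the fraction gate
  counts2 <- counts[c(1, 2, 1, 2), ]
  rownames(counts2) <- sprintf("c%d", 1:4)
  tax2 <- build_taxonomy(counts2, assignments = asn, taxonomy_id = "mk2")
  expect_equal(tax2$stats$marker_union, character())
})

test_that("planted markers are recovered at >= 90% per node", {
  sim <- synth_dataset()
  tax <- synth_taxonomy()
  cs <- cellsets(tax$hierarchy)
  rec <- vapply(seq_len(nrow(cs)), function(i) {
    mean(sim$truth$markers[[cs$label[i]]] %in% tax$stats$markers[[cs$accession[i]]])
  }, numeric(1))
  expect_gte(min(rec), 0.9)
})

test_that("marker lists are invariant under gene-order permutation", {
  counts <- toy_counts()
  asn <- toy_assignments()
  tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "perm")
  perm <- withr::with_seed(3, sample(ncol(counts)))
  tax_p <- build_taxonomy(counts[, perm], assignments = asn, taxonomy_id = "perm")
  expect_equal(tax_p$stats$markers, tax$stats$markers)
  expect_equal(tax_p$stats$node_markers, tax$stats$node_markers)
})

test_that("stats on a cell subset match a rebuild on the subsetted matrix", {
  sim <- synth_dataset()
  tax <- synth_taxonomy()
  keep <- withr::with_seed(11, sample(rownames(sim$counts), 400))
  h_sub <- prune_hierarchy(tax$hierarchy, keep)
  st_sub <- compute_cluster_stats(normalize_log2cpm(sim$counts[keep, ]), h_sub)
  asn_sub <- sim$assignments[sim$assignments$cell_id %in% keep, ]
  rebuilt <- build_taxonomy(sim$counts[keep, ], assignments = asn_sub,
                            taxonomy_id = tax$taxonomy_id)
  for (lv in h_sub$levels) {
    expect_lt(max(abs(st_sub$means[[lv]] - rebuilt$stats$means[[lv]])), 1e-10)
  }
})

test_that("dendrogram structure follows the correlation-linkage definition", {
  # two leaves: single merge, tie-broken accession order
  counts <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  asn <- tibble::tibble(cell_id = c("c1", "c2"), cluster = c("A1", "A2"))
  tax <- build_taxonomy(counts, assignments = asn, taxonomy_id = "d2")
  expect_equal(dendrogram_leaves(tax$dendrogram), c("A1", "A2"))
  expect_length(collect_heights(tax$dendrogram), 1)

  # three leaves: the most correlated pair merges first
  counts3 <- matrix(c(10, 9, 0, 1,
                      9, 10, 1, 0,
                      0, 1, 10, 9),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("c1", "c2", "c3"), sprintf("g%d", 1:4)))
  asn3 <- tibble::tibble(cell_id = c("c1", "c2", "c3"),
                         cluster = c("A1", "A2", "A3"))
  tax3 <- build_taxonomy(counts3, assignments = asn3, taxonomy_id = "d3")
  # A1,A2 are near-identical; first merge (lowest internal node) pairs them
  grp <- cut_nested(tax3$dendrogram, 2)
  expect_equal(grp[["A1"]], grp[["A2"]])
  expect_false(grp[["A3"]] == grp[["A1"]])
})

test_that("dendrogram cuts recover the planted class and subclass partitions", {
  sim <- synth_dataset()
  tax <- synth_taxonomy()
  leaves <- dendrogram_leaves(tax$dendrogram)
  expect_setequal(leaves, rownames(sim$truth$profiles))
  truth_parent <- stats::setNames(sim$truth$tree$parent, sim$truth$tree$node)
  for (k in c(3, 9)) {
    got <- cut_nested(tax$dendrogram, k)
    planted <- if (k == 3) truth_parent[truth_parent[names(got)]] else truth_parent[names(got)]
    expect_equal(adjusted_rand(got, planted), 1)
  }
})

test_that("axis mismatches and invalid hierarchies are rejected with context", {
  counts <- toy_counts()
  asn <- toy_assignments()
  expect_error(build_taxonomy(counts[1:3, ], assignments = asn, taxonomy_id = "x"),
               "3")
  bad <- asn; bad$cluster[1] <- ""
  expect_error(build_taxonomy(counts, assignments = bad, taxonomy_id = "x"),
               "missing label")
})
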