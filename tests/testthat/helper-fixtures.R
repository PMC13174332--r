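# Shared fixtures, built in code. The synthetic taxonomy is cached per test
# run because several files exercise it.

toy_assignments <- function() {
  tibble::tibble(
    cell_id = c("c1", "c2", "c3", "c4"),
    class = c("A", "A", "A", "B"),
    cluster = c("A1", "A1", "A2", "B1")
  )
}

toy_counts <- function() {
  m <- matrix(
    c(10, 0, 0, 2, 0, 0,
      8, 1, 0, 0, 3, 0,
      0, 9, 0, 1, 0, 2,
      0, 0, 12, 0, 0, 5),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("c1", "c2", "c3", "c4"), sprintf("g%d", 1:6))
  )
  m
}

toy_taxonomy <- function() {
  build_taxonomy(toy_counts(), assignments = toy_assignments(),
                 taxonomy_id = "toy")
}

.fixture_cache <- new.env(parent = emptyenv())

synth_dataset <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_taxonomy_dataset(ait_sim_config())
  }
  .fixture_cache$sim
}

synth_taxonomy <- function() {
  if (is.null(.fixture_cache$tax)) {
    sim <- synth_dataset()
    .fixture_cache$tax <- build_taxonomy(
      sim$counts, sim$cell_metadata, sim$gene_metadata, sim$assignments,
      taxonomy_id = "synth"
    )
  }
  .fixture_cache$tax
}

# single-cell-per-cluster taxonomy: each leaf centroid is exactly one cell's
# normalized profile, so a copied cell maps back with correlation 1
singleton_taxonomy <- function() {
  counts <- matrix(
    c(20, 1, 0, 0, 0, 0,
      0, 0, 18, 2, 0, 0,
      0, 1, 0, 0, 25, 3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), sprintf("g%d", 1:6))
  )
  asn <- tibble::tibble(cell_id = c("s1", "s2", "s3"),
                        cluster = c("K1", "K2", "K3"))
  build_taxonomy(counts, assignments = asn, taxonomy_id = "single")
}
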