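local_h5ad <- function(tax, ..., envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".h5ad", .local_envir = envir)
  write_ait(tax, path, ...)
  path
}

test_that("a minimal taxonomy round-trips field-for-field", {
  tax <- toy_taxonomy()
  path <- local_h5ad(tax)
  back <- read_ait(path)
  expect_equal(back, tax)
  expect_identical(back$X, tax$X)          # matrices bit-exact
  expect_identical(back$counts, tax$counts)
})

test_that("lightweight files drop matrices but keep every other component", {
  tax <- synth_taxonomy()
  full <- local_h5ad(tax)
  light <- local_h5ad(tax, include_matrix = FALSE)
  expect_lt(file.size(light), file.size(full))
  back <- read_ait(light)
  expect_null(back$X)
  expect_null(back$counts)
  expect_equal(back$stats, tax$stats)
  expect_equal(back$dendrogram, tax$dendrogram)
  expect_equal(back$hierarchy, tax$hierarchy)
})

test_that("a taxonomy with CAS and modes survives uns nesting round trip", {
  tax <- synth_taxonomy()
  tax <- embed_cas(tax, annotations_to_cas(tax))
  tax <- define_mode(tax, "neurons", cell_sets = c("C1", "C2"),
                     description = "two classes")
  tax <- define_mode(tax, "panel", genes = colnames(tax$counts)[1:25],
                     description = "spatial panel")
  path <- local_h5ad(tax)
  back <- read_ait(path)
  expect_equal(back, tax)
  expect_identical(back$cas_json, tax$cas_json)
})

test_that("files without the AIT block or with future versions are rejected", {
  plain <- withr::local_tempfile(fileext = ".h5ad")
  rhdf5::h5createFile(plain)
  rhdf5::h5write(matrix(1:4, 2), plain, "X")
  rhdf5::h5closeAll()
  expect_error(read_ait(plain), "not an AIT file")
  expect_error(read_ait(withr::local_tempfile(fileext = ".h5ad")), "does not exist")

  future <- local_h5ad(toy_taxonomy())
  rhdf5::h5delete(future, "uns/AIT/schema_version")
  fid <- rhdf5::H5Fopen(future)
  rhdf5::h5write("99.0.0", fid, "uns/AIT/schema_version", variableLengthString = TRUE)
  rhdf5::H5Fclose(fid)
  expect_error(read_ait(future), "newer than supported")
})

test_that("deleted optional components read back as absent, never fabricated", {
  path <- local_h5ad(synth_taxonomy())
  rhdf5::h5delete(path, "uns/AIT/stats")
  rhdf5::h5closeAll()
  back <- read_ait(path)
  expect_null(back$stats)
  rep <- validate_ait(path)
  expect_true(is_conformant(rep))
  expect_true("missing_stats" %in% rep$code[rep$severity == "RECOMMENDED"])
})

test_that("builder output is conformant and validation findings are deterministic", {
  path <- local_h5ad(synth_taxonomy())
  rep <- validate_ait(path)
  expect_equal(sum(rep$severity == "MUST"), 0)
  expect_identical(validate_ait(path), rep)
})

test_that("each schema mutation triggers exactly its own finding", {
  make_file <- function() {
    tax <- synth_taxonomy()
    tax <- embed_cas(tax, annotations_to_cas(tax))
    path <- tempfile(fileext = ".h5ad")
    write_ait(tax, path)
    path
  }
  rewrite_string <- function(path, name, value) {
    rhdf5::h5delete(path, name)
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5write(value, fid, name, variableLengthString = TRUE)
    rhdf5::H5Fclose(fid)
  }
  mutations <- list(
    list(code = "missing_schema_version", severity = "MUST",
         mutate = function(p) rhdf5::h5delete(p, "uns/AIT/schema_version")),
    list(code = "schema_version_not_semver", severity = "MUST",
         mutate = function(p) rewrite_string(p, "uns/AIT/schema_version", "v1-final")),
    list(code = "missing_taxonomy_id", severity = "MUST",
         mutate = function(p) rhdf5::h5delete(p, "uns/AIT/taxonomy_id")),
    list(code = "no_level_columns", severity = "MUST",
         mutate = function(p) rhdf5::h5delete(p, "obs/cluster")),
    list(code = "duplicate_cell_id", severity = "MUST",
         mutate = function(p) {
           ids <- as.character(rhdf5::h5read(p, "obs/_index"))
           ids[2] <- ids[1]
           rewrite_string(p, "obs/_index", ids)
         }),
    list(code = "hierarchy_partition_missing_label", severity = "MUST",
         mutate = function(p) {
           x <- as.character(rhdf5::h5read(p, "obs/cluster"))
           x[5] <- ""
           rewrite_string(p, "obs/cluster", x)
         }),
    list(code = "hierarchy_nesting_multiple_parents", severity = "MUST",
         mutate = function(p) {
           x <- as.character(rhdf5::h5read(p, "obs/class"))
           x[1] <- "C2"
           rewrite_string(p, "obs/class", x)
         }),
    list(code = "cas_unparseable", severity = "MUST",
         mutate = function(p) rewrite_string(p, "uns/cell_annotation_schema", "{oops")),
    list(code = "missing_dendrogram", severity = "RECOMMENDED",
         mutate = function(p) rhdf5::h5delete(p, "uns/AIT/dendrogram")),
    list(code = "missing_stats", severity = "RECOMMENDED",
         mutate = function(p) rhdf5::h5delete(p, "uns/AIT/stats")),
    list(code = "missing_cas", severity = "RECOMMENDED",
         mutate = function(p) rhdf5::h5delete(p, "uns/cell_annotation_schema")),
    list(code = "ontology_terms_unpopulated", severity = "RECOMMENDED",
         mutate = function(p) invisible(p))  # builder CAS carries no terms yet
  )
  for (m in mutations) {
    path <- make_file()
    m$mutate(path)
    rhdf5::h5closeAll()
    rep <- validate_ait(path)
    hit <- rep[rep$code == m$code, ]
    expect_equal(nrow(hit), 1, label = m$code)
    expect_equal(hit$severity, m$severity, label = m$code)
    # no unexpected MUST findings ride along for RECOMMENDED mutations
    if (m$severity == "RECOMMENDED") expect_true(is_conformant(rep))
    file.remove(path)
  }
})

test_that("conformance is monotone in recommended content", {
  tax <- synth_taxonomy()
  bare <- tax
  bare$stats <- NULL; bare$dendrogram <- NULL
  p1 <- local_h5ad(bare)
  p2 <- local_h5ad(tax)
  p3 <- local_h5ad(embed_cas(tax, annotations_to_cas(tax)))
  musts <- vapply(c(p1, p2, p3), function(p) sum(validate_ait(p)$severity == "MUST"),
                  numeric(1))
  recs <- vapply(c(p1, p2, p3), function(p) sum(validate_ait(p)$severity == "RECOMMENDED"),
                 numeric(1))
  expect_equal(unname(musts), c(0, 0, 0))
  expect_true(all(diff(recs) <= 0))
})

test_that("strip_matrix preserves annotations, is idempotent, and still maps", {
  sim <- synth_dataset()
  tax <- synth_taxonomy()
  full <- local_h5ad(tax)
  light <- withr::local_tempfile(fileext = ".h5ad")
  strip_matrix(full, light)
  lt <- read_ait(light)
  expect_null(lt$X)
  expect_equal(lt$stats, tax$stats)
  expect_true(is_conformant(validate_ait(light)))

  light2 <- withr::local_tempfile(fileext = ".h5ad")
  strip_matrix(light, light2)
  expect_equal(read_ait(light2), lt)

  # a lightweight taxonomy still answers queries from its stats alone
  q <- simulate_query_cells(sim$truth, n_per_cluster = 2, seed = 8)
  res <- map_hierarchical(lt, q$counts)
  expect_gte(mean(res$label == q$true_labels$cluster), 0.95)

  # refuses to strip a broken file
  broken <- local_h5ad(toy_taxonomy())
  rhdf5::h5delete(broken, "uns/AIT/taxonomy_id")
  rhdf5::h5closeAll()
  expect_error(strip_matrix(broken, withr::local_tempfile()), "non-conformant")
})

test_that("writing refuses an invalid hierarchy with its report", {
  tax <- toy_taxonomy()
  tax$hierarchy$assignments$cluster[2] <- "B1"  # breaks nesting
  expect_error(write_ait(tax, withr::local_tempfile(fileext = ".h5ad")),
               "invalid hierarchy")
})
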