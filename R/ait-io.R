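#' Write a taxonomy to a single-file AIT (h5ad) container
#'
#' Serializes an `ait_taxonomy` into an AnnData-compatible HDF5 file:
#' normalized expression in `X`, raw counts in `layers/counts`, cell
#' metadata plus one column per hierarchy level in `obs`, gene metadata in
#' `var`, and all taxonomy components (schema version, taxonomy id, level
#' order, cell sets, precomputed statistics, markers, dendrogram, modes)
#' under `uns/AIT`, with any embedded CAS document as a canonical JSON
#' string under `uns/cell_annotation_schema`. With
#' `include_matrix = FALSE` a "lightweight" file is written: matrices are
#' omitted but every other component round-trips.
#'
#' @param taxonomy An `ait_taxonomy`; its hierarchy must validate.
#' @param path Output `.h5ad` path (overwritten if present).
#' @param include_matrix Write `X` and `layers/counts`.
#' @return `path`, invisibly.
#' @export
write_ait <- function(taxonomy, path, include_matrix = TRUE) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  rep <- validate_hierarchy(taxonomy$hierarchy)
  if (!is_conformant(rep)) {
    abort(c("refusing to write a taxonomy with an invalid hierarchy; findings:",
            setNames(head(rep$message, 10), rep("x", min(10, nrow(rep))))))
  }
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) abort(sprintf("cannot create file '%s'", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  h5_attr(fid, "encoding-type", "anndata")
  h5_attr(fid, "encoding-version", "0.1.0")

  if (include_matrix && !is.null(taxonomy$X)) {
    h5_write_matrix(fid, "X", as_matrix(taxonomy$X))
  }
  rhdf5::h5createGroup(fid, "layers"); h5_mark_dict(fid, "layers")
  if (include_matrix && !is.null(taxonomy$counts)) {
    h5_write_matrix(fid, "layers/counts", as_matrix(taxonomy$counts))
  }

  h5_write_dataframe(fid, "obs", taxonomy$obs[, setdiff(names(taxonomy$obs), "cell_id")],
                     taxonomy$obs$cell_id)
  h5_write_dataframe(fid, "var", taxonomy$var[, setdiff(names(taxonomy$var), "gene_id")],
                     taxonomy$var$gene_id)

  rhdf5::h5createGroup(fid, "uns"); h5_mark_dict(fid, "uns")
  rhdf5::h5createGroup(fid, "uns/AIT"); h5_mark_dict(fid, "uns/AIT")
  h5_write_string(fid, "uns/AIT/schema_version", taxonomy$schema_version)
  h5_write_string(fid, "uns/AIT/taxonomy_id", taxonomy$taxonomy_id)
  h5_write_string_array(fid, "uns/AIT/levels", taxonomy$hierarchy$levels)

  cs <- cellsets(taxonomy$hierarchy)
  cs$parent_accession[is.na(cs$parent_accession)] <- ""
  h5_write_dataframe(fid, "uns/AIT/cell_sets",
                     cs[, c("label", "level", "parent_accession", "n_cells")],
                     cs$accession)

  if (!is.null(taxonomy$stats)) {
    rhdf5::h5createGroup(fid, "uns/AIT/stats"); h5_mark_dict(fid, "uns/AIT/stats")
    rhdf5::h5createGroup(fid, "uns/AIT/stats/means"); h5_mark_dict(fid, "uns/AIT/stats/means")
    rhdf5::h5createGroup(fid, "uns/AIT/stats/fractions"); h5_mark_dict(fid, "uns/AIT/stats/fractions")
    for (lv in taxonomy$stats$levels) {
      h5_write_matrix(fid, paste0("uns/AIT/stats/means/", lv), taxonomy$stats$means[[lv]])
      h5_write_matrix(fid, paste0("uns/AIT/stats/fractions/", lv), taxonomy$stats$fractions[[lv]])
    }
    h5_write_string(fid, "uns/AIT/stats/markers_json", markers_to_json(taxonomy$stats))
  }
  if (!is.null(taxonomy$dendrogram)) {
    h5_write_string(fid, "uns/AIT/dendrogram",
                    as.character(jsonlite::toJSON(taxonomy$dendrogram,
                                                  auto_unbox = TRUE, digits = NA)))
  }
  rhdf5::h5createGroup(fid, "uns/AIT/modes"); h5_mark_dict(fid, "uns/AIT/modes")
  for (m in taxonomy$modes) {
    g <- paste0("uns/AIT/modes/", m$name)
    rhdf5::h5createGroup(fid, g); h5_mark_dict(fid, g)
    h5_write_num_array(fid, paste0(g, "/cell_mask"), as.integer(m$cell_mask))
    h5_write_num_array(fid, paste0(g, "/gene_mask"), as.integer(m$gene_mask))
    h5_write_string(fid, paste0(g, "/description"), m$description)
  }
  if (!is.null(taxonomy$cas_json)) {
    h5_write_string(fid, "uns/cell_annotation_schema", taxonomy$cas_json)
  }
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a taxonomy from an AIT (h5ad) container
#'
#' Reconstructs the full `ait_taxonomy` from a file written by
#' [write_ait()]. Absent optional components (matrices, stats, dendrogram,
#' CAS, modes) come back as `NULL`/empty, never fabricated. A file without
#' a `uns/AIT` block is rejected as not an AIT file; a file whose schema
#' major version is newer than this implementation supports raises a
#' version error.
#'
#' @param path Path to an `.h5ad` file.
#' @return An `ait_taxonomy`.
#' @export
read_ait <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  entries <- paste0(sub("^/$", "", contents$group), "/", contents$name)
  has <- function(e) e %in% entries

  if (!has("/uns/AIT")) {
    abort(sprintf("'%s' is not an AIT file (no uns/AIT block)", path))
  }
  version <- h5_read_scalar(path, "uns/AIT/schema_version")
  major <- suppressWarnings(as.integer(sub("\\..*$", "", version)))
  supported <- as.integer(sub("\\..*$", "", AIT_SCHEMA_VERSION))
  if (!is.na(major) && major > supported) {
    abort(sprintf("file schema version %s is newer than supported (%s)",
                  version, AIT_SCHEMA_VERSION))
  }
  taxonomy_id <- h5_read_scalar(path, "uns/AIT/taxonomy_id")
  levels <- as.character(rhdf5::h5read(path, "uns/AIT/levels"))

  obs <- h5_read_dataframe(path, "obs", "cell_id")
  var <- h5_read_dataframe(path, "var", "gene_id")

  X <- NULL
  if (has("/X")) X <- h5_read_matrix(path, "X", obs$cell_id, var$gene_id)
  counts <- NULL
  if (has("/layers/counts")) counts <- h5_read_matrix(path, "layers/counts", obs$cell_id, var$gene_id)

  asn <- obs[, c("cell_id", levels)]
  hierarchy <- ait_hierarchy(asn, levels, taxonomy_id)

  stats <- NULL
  if (has("/uns/AIT/stats")) {
    cs <- cellsets(hierarchy)
    means <- list(); fractions <- list()
    for (lv in levels) {
      acc <- cs$accession[cs$level == lv]
      means[[lv]] <- h5_read_matrix(path, paste0("uns/AIT/stats/means/", lv), acc, var$gene_id)
      fractions[[lv]] <- h5_read_matrix(path, paste0("uns/AIT/stats/fractions/", lv), acc, var$gene_id)
    }
    stats <- structure(
      list(levels = levels, cell_sets = cs, means = means, fractions = fractions,
           markers = list(), node_markers = list(), marker_union = character()),
      class = "ait_stats"
    )
    if (has("/uns/AIT/stats/markers_json")) {
      stats <- markers_from_json(stats, h5_read_scalar(path, "uns/AIT/stats/markers_json"))
    }
  }

  dendro <- NULL
  if (has("/uns/AIT/dendrogram")) {
    dendro <- jsonlite::fromJSON(h5_read_scalar(path, "uns/AIT/dendrogram"),
                                 simplifyVector = FALSE)
  }

  modes <- list()
  if (has("/uns/AIT/modes")) {
    mode_names <- contents$name[contents$group == "/uns/AIT/modes"]
    for (nm in lex_sort(mode_names)) {
      g <- paste0("uns/AIT/modes/", nm)
      modes[[nm]] <- list(
        name = nm,
        cell_mask = as.logical(rhdf5::h5read(path, paste0(g, "/cell_mask"))),
        gene_mask = as.logical(rhdf5::h5read(path, paste0(g, "/gene_mask"))),
        description = h5_read_scalar(path, paste0(g, "/description"))
      )
    }
  }

  cas_json <- NULL
  if (has("/uns/cell_annotation_schema")) {
    cas_json <- h5_read_scalar(path, "uns/cell_annotation_schema")
  }

  new_ait_taxonomy(
    taxonomy_id = taxonomy_id, X = X, counts = counts, obs = obs, var = var,
    hierarchy = hierarchy, stats = stats, dendrogram = dendro, modes = modes,
    cas_json = cas_json, schema_version = version
  )
}

#' Validate an AIT file against the schema's normative keywords
#'
#' Runs the conformance checks on a file without fully loading it. `MUST`
#' checks: the `uns/AIT` block exists; `schema_version` is present and a
#' semantic version; `taxonomy_id` is present; at least one hierarchy level
#' column is present in `obs`; cell ids are unique; the hierarchy
#' invariants hold. `RECOMMENDED` checks: dendrogram present; precomputed
#' stats present; a CAS document is embedded; ontology terms are populated
#' in the embedded CAS. The file is conformant iff there are zero `MUST`
#' findings; the report is deterministic.
#'
#' @param path Path to an `.h5ad` file.
#' @return An [validation_report()]. An unreadable container is a
#'   structural error, not a finding.
#' @export
validate_ait <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (!isTRUE(rhdf5::H5Fis_hdf5(path))) {
    abort(sprintf("'%s' is not a readable HDF5 container", path))
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  entries <- paste0(sub("^/$", "", contents$group), "/", contents$name)
  has <- function(e) e %in% entries
  f <- list()
  add <- function(severity, code, pth, message) {
    f[[length(f) + 1]] <<- finding(severity, code, pth, message)
  }

  if (!has("/uns/AIT")) {
    add("MUST", "missing_ait_block", "uns/AIT", "file has no uns/AIT block: not an AIT file")
    return(bind_findings(!!!f))
  }

  if (!has("/uns/AIT/schema_version")) {
    add("MUST", "missing_schema_version", "uns/AIT/schema_version", "schema_version is absent")
  } else {
    v <- h5_read_scalar(path, "uns/AIT/schema_version")
    if (!grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", v)) {
      add("MUST", "schema_version_not_semver", "uns/AIT/schema_version",
          sprintf("'%s' is not a semantic version", v))
    }
  }
  if (!has("/uns/AIT/taxonomy_id")) {
    add("MUST", "missing_taxonomy_id", "uns/AIT/taxonomy_id", "taxonomy_id is absent")
  }

  obs_cols <- contents$name[contents$group == "/obs"]
  levels <- character()
  if (has("/uns/AIT/levels")) {
    levels <- as.character(rhdf5::h5read(path, "uns/AIT/levels"))
  }
  present_levels <- intersect(levels, obs_cols)
  if (length(present_levels) == 0) {
    add("MUST", "no_level_columns", "obs",
        "no hierarchy level column found in obs (uns/AIT/levels must name obs columns)")
  } else if (length(setdiff(levels, obs_cols)) > 0) {
    add("MUST", "no_level_columns", "obs",
        sprintf("level column(s) missing from obs: %s",
                paste(setdiff(levels, obs_cols), collapse = ", ")))
  }

  cell_ids <- tryCatch(as.character(rhdf5::h5read(path, "obs/_index")), error = function(e) character())
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup) > 0) {
    add("MUST", "duplicate_cell_id", paste0("obs/_index/", dup[1]),
        sprintf("duplicate cell id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }

  if (length(present_levels) == length(levels) && length(levels) > 0 &&
      length(dup) == 0 && length(cell_ids) > 0) {
    asn <- tibble(cell_id = cell_ids)
    for (lv in levels) asn[[lv]] <- as.character(rhdf5::h5read(path, paste0("obs/", lv)))
    hrep <- validate_hierarchy(asn, levels)
    for (i in seq_len(nrow(hrep))) {
      add("MUST", paste0("hierarchy_", hrep$code[i]), hrep$path[i], hrep$message[i])
    }
  }

  if (!has("/uns/AIT/dendrogram")) {
    add("RECOMMENDED", "missing_dendrogram", "uns/AIT/dendrogram", "no dendrogram stored")
  }
  if (!has("/uns/AIT/stats")) {
    add("RECOMMENDED", "missing_stats", "uns/AIT/stats", "no precomputed statistics stored")
  }
  if (!has("/uns/cell_annotation_schema")) {
    add("RECOMMENDED", "missing_cas", "uns/cell_annotation_schema",
        "no Cell Annotation Schema document embedded")
  } else {
    cas <- tryCatch(cas_from_json(h5_read_scalar(path, "uns/cell_annotation_schema")),
                    error = function(e) NULL)
    if (is.null(cas)) {
      add("MUST", "cas_unparseable", "uns/cell_annotation_schema",
          "embedded CAS document does not parse")
    } else if (all(is.na(cas$annotations$cell_ontology_term_id))) {
      add("RECOMMENDED", "ontology_terms_unpopulated", "uns/cell_annotation_schema",
          "no cell ontology term ids populated in the embedded CAS")
    }
  }

  if (length(f) == 0) validation_report() else bind_findings(!!!f)
}

#' Strip expression matrices from an AIT file
#'
#' Produces a "lightweight" copy of a valid AIT file with `X` and all
#' layers removed and every other component intact; conformance is
#' preserved, and stripping an already-light file is idempotent.
#'
#' @param path_in Input AIT file (must be conformant).
#' @param path_out Output path.
#' @return `path_out`, invisibly.
#' @export
strip_matrix <- function(path_in, path_out) {
  rep <- validate_ait(path_in)
  if (!is_conformant(rep)) {
    abort(c(sprintf("refusing to strip non-conformant file '%s'; findings:", path_in),
            setNames(head(rep$message, 10), rep("x", min(10, nrow(rep))))))
  }
  tax <- read_ait(path_in)
  write_ait(tax, path_out, include_matrix = FALSE)
}

# --- low-level h5ad helpers --------------------------------------------------

h5_attr <- function(obj, name, val) {
  rhdf5::h5writeAttribute(val, obj, name, variableLengthString = TRUE,
                          asScalar = length(val) == 1L)
}

h5_mark_dict <- function(fid, name) {
  g <- rhdf5::H5Gopen(fid, name)
  h5_attr(g, "encoding-type", "dict")
  h5_attr(g, "encoding-version", "0.1.0")
  rhdf5::H5Gclose(g)
}

h5_mark_dataset <- function(fid, name, type) {
  o <- rhdf5::H5Dopen(fid, name)
  h5_attr(o, "encoding-type", type)
  h5_attr(o, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(o)
}

# dense cells x genes matrix, stored so h5py sees shape (nrow, ncol)
h5_write_matrix <- function(fid, name, mat) {
  rhdf5::h5write(t(unname(as_matrix(mat))), fid, name)
  h5_mark_dataset(fid, name, "array")
}

h5_read_matrix <- function(path, name, row_ids, col_ids) {
  m <- t(rhdf5::h5read(path, name))
  dimnames(m) <- list(row_ids, col_ids)
  m
}

h5_write_string <- function(fid, name, x) {
  # single strings go in as 1-element string arrays (rhdf5 has no scalar
  # string dataset); readers treat length-1 arrays as scalars
  rhdf5::h5write(x, fid, name, variableLengthString = TRUE)
  h5_mark_dataset(fid, name, "string-array")
}

h5_write_string_array <- function(fid, name, x) {
  rhdf5::h5write(x, fid, name, variableLengthString = TRUE)
  h5_mark_dataset(fid, name, "string-array")
}

h5_write_num_array <- function(fid, name, x) {
  rhdf5::h5write(x, fid, name)
  h5_mark_dataset(fid, name, "array")
}

h5_read_scalar <- function(path, name) {
  as.character(rhdf5::h5read(path, name))[1]
}

h5_write_dataframe <- function(fid, name, df, index) {
  rhdf5::h5createGroup(fid, name)
  g <- rhdf5::H5Gopen(fid, name)
  h5_attr(g, "encoding-type", "dataframe")
  h5_attr(g, "encoding-version", "0.2.0")
  h5_attr(g, "_index", "_index")
  cols <- names(df)
  if (length(cols) == 0) {
    # zero-column frame: empty numeric attribute, as h5py writes it
    rhdf5::h5writeAttribute(numeric(0), g, "column-order")
  } else {
    rhdf5::h5writeAttribute(as.array(cols), g, "column-order", variableLengthString = TRUE)
  }
  rhdf5::H5Gclose(g)
  h5_write_string_array(fid, paste0(name, "/_index"), index)
  for (cn in cols) {
    x <- df[[cn]]
    target <- paste0(name, "/", cn)
    if (is.character(x) || is.factor(x)) {
      h5_write_string_array(fid, target, as.character(x))
    } else if (is.integer(x)) {
      rhdf5::h5write(x, fid, target)
      h5_mark_dataset(fid, target, "array")
    } else {
      h5_write_num_array(fid, target, as.numeric(x))
    }
  }
}

h5_read_dataframe <- function(path, name, index_name) {
  attrs <- rhdf5::h5readAttributes(path, name)
  cols <- as.character(attrs[["column-order"]])
  out <- tibble(!!index_name := as.character(rhdf5::h5read(path, paste0(name, "/_index"))))
  for (cn in cols) {
    x <- rhdf5::h5read(path, paste0(name, "/", cn))
    if (is.array(x)) x <- as.vector(x)
    if (is.raw(x)) x <- as.integer(x)
    out[[cn]] <- x
  }
  out
}

markers_to_json <- function(stats) {
  as.character(jsonlite::toJSON(list(
    markers = lapply(stats$markers, as.list),
    node_markers = lapply(stats$node_markers, as.list),
    marker_union = as.list(stats$marker_union)
  ), auto_unbox = TRUE))
}

markers_from_json <- function(stats, json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  stats$markers <- lapply(doc$markers, function(g) as.character(unlist(g)))
  stats$node_markers <- lapply(doc$node_markers, function(g) as.character(unlist(g)))
  stats$marker_union <- as.character(unlist(doc$marker_union))
  stats
}
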