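#' Cell Annotation Schema documents
#'
#' A CAS document carries nested cell type annotations: *labelsets* (one per
#' hierarchy level, with integer ranks, 0 = coarsest) and *annotations* (one
#' per cell set, with its label, accession, optional parent accession,
#' optional ontology term, free-text rationale, and marker gene evidence).
#'
#' @param labelsets Tibble with `name`, `rank` (integer), `description`.
#' @param annotations Tibble with `labelset`, `cell_label`,
#'   `cell_set_accession`, and optionally `parent_cell_set_accession`,
#'   `cell_ontology_term_id`, `cell_ontology_term`, `rationale`,
#'   `marker_gene_evidence` (list-column of gene ids).
#' @return An object of class `cas_document`.
#' @export
cas_document <- function(labelsets, annotations) {
  labelsets <- as_tibble(labelsets)
  annotations <- as_tibble(annotations)
  stopifnot(all(c("name", "rank") %in% names(labelsets)),
            all(c("labelset", "cell_label", "cell_set_accession") %in% names(annotations)))
  if (!"description" %in% names(labelsets)) labelsets$description <- ""
  for (col in c("parent_cell_set_accession", "cell_ontology_term_id",
                "cell_ontology_term", "rationale")) {
    if (!col %in% names(annotations)) annotations[[col]] <- NA_character_
  }
  if (!"marker_gene_evidence" %in% names(annotations)) {
    annotations$marker_gene_evidence <- rep(list(character()), nrow(annotations))
  }
  labelsets$rank <- as.integer(labelsets$rank)
  key <- paste(annotations$labelset, annotations$cell_label)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (labelset, cell_label) pair(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (anyDuplicated(annotations$cell_set_accession)) {
    abort("cell set accessions must be unique within a CAS document")
  }
  structure(list(labelsets = labelsets, annotations = annotations),
            class = "cas_document")
}

#' @export
print.cas_document <- function(x, ...) {
  cat(sprintf("<CAS document> %d labelset(s), %d annotation(s)\n",
              nrow(x$labelsets), nrow(x$annotations)))
  invisible(x)
}

#' Derive a CAS document from a taxonomy's hierarchy
#'
#' Produces one labelset per hierarchy level (rank = level index, 0 =
#' coarsest) and one annotation per cell set, with parent links mirroring
#' the hierarchy tree. When the taxonomy carries precomputed statistics,
#' each annotation's `marker_gene_evidence` is filled from the cell set's
#' selected markers.
#'
#' @param taxonomy An `ait_taxonomy` (valid hierarchy).
#' @return A [cas_document()].
#' @export
annotations_to_cas <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  h <- taxonomy$hierarchy
  cs <- cellsets(h)
  labelsets <- tibble(
    name = h$levels,
    rank = seq_along(h$levels) - 1L,
    description = sprintf("cell sets at level '%s'", h$levels)
  )
  markers <- if (!is.null(taxonomy$stats)) taxonomy$stats$markers else list()
  annotations <- tibble(
    labelset = cs$level,
    cell_label = cs$label,
    cell_set_accession = cs$accession,
    parent_cell_set_accession = cs$parent_accession,
    cell_ontology_term_id = NA_character_,
    cell_ontology_term = NA_character_,
    rationale = NA_character_,
    marker_gene_evidence = lapply(cs$accession, function(a) markers[[a]] %||% character())
  )
  cas_document(labelsets, annotations)
}

#' Reconstruct a hierarchy from a CAS document
#'
#' Given per-cell assignments at the finest labelset, derives the coarser
#' level labels by following the document's parent accession links and
#' returns a full hierarchy. Dangling parent accessions, cycles in the
#' parent links, and cells with unknown finest labels are errors.
#'
#' @param cas A [cas_document()].
#' @param cell_assignments Data frame with `cell_id` and a column named like
#'   the finest labelset (or a 2-column frame `cell_id`, `label`).
#' @param id_prefix Accession prefix for the rebuilt hierarchy; defaults to
#'   the prefix of the document's accessions.
#' @return An [ait_hierarchy()].
#' @export
cas_to_annotations <- function(cas, cell_assignments, id_prefix = NULL) {
  stopifnot(inherits(cas, "cas_document"))
  ls_ordered <- cas$labelsets[order(cas$labelsets$rank), ]
  levels <- ls_ordered$name
  finest <- levels[length(levels)]
  ann <- cas$annotations

  dangling <- setdiff(ann$parent_cell_set_accession[!is.na(ann$parent_cell_set_accession)],
                      ann$cell_set_accession)
  if (length(dangling) > 0) {
    abort(sprintf("dangling parent accession(s): %s", paste(dangling, collapse = ", ")))
  }

  parent_of <- setNames(ann$parent_cell_set_accession, ann$cell_set_accession)
  label_of <- setNames(ann$cell_label, ann$cell_set_accession)
  level_of <- setNames(ann$labelset, ann$cell_set_accession)

  # cycle check on parent links
  for (a in ann$cell_set_accession) {
    seen <- character(); cur <- a
    while (!is.na(cur)) {
      if (cur %in% seen) abort(sprintf("cycle in parent links involving '%s'", cur))
      seen <- c(seen, cur)
      cur <- unname(parent_of[cur])
    }
  }

  ca <- as_tibble(cell_assignments)
  if (!"cell_id" %in% names(ca)) abort("`cell_assignments` must have a `cell_id` column")
  label_col <- if (finest %in% names(ca)) finest else setdiff(names(ca), "cell_id")[1]
  fine_ann <- ann[ann$labelset == finest, ]
  acc_of_label <- setNames(fine_ann$cell_set_accession, fine_ann$cell_label)
  unknown <- setdiff(ca[[label_col]], fine_ann$cell_label)
  if (length(unknown) > 0) {
    abort(sprintf("cell label(s) not in finest labelset '%s': %s",
                  finest, paste(head(unknown, 10), collapse = ", ")))
  }

  cols <- list(cell_id = ca$cell_id)
  acc <- unname(acc_of_label[ca[[label_col]]])
  chain <- list()
  cur <- acc
  for (lv in rev(levels)) {
    if (any(is.na(cur)) || any(level_of[cur] != lv)) {
      abort(sprintf("parent chain does not reach labelset '%s' for every cell", lv))
    }
    chain[[lv]] <- unname(label_of[cur])
    cur <- unname(parent_of[cur])
  }
  for (lv in levels) cols[[lv]] <- chain[[lv]]
  asn <- as_tibble(cols)

  if (is.null(id_prefix)) {
    id_prefix <- sub(":[^:]*$", "", ann$cell_set_accession[1])
  }
  h <- ait_hierarchy(asn, levels, id_prefix)
  rep <- validate_hierarchy(h)
  if (!is_conformant(rep)) {
    abort("reconstructed assignments do not form a valid hierarchy")
  }
  h
}

#' Syntactic validation of ontology term references
#'
#' Every non-empty `cell_ontology_term_id` must be a CURIE matching
#' `^[A-Za-z]+:[0-9]{7}$` with a prefix from the allowed set (by default
#' only `CL`, the Cell Ontology). Ontology terms are optional, so
#' violations are `RECOMMENDED`-severity findings. No network lookup of
#' term existence is attempted.
#'
#' @param cas A [cas_document()].
#' @param allowed_prefixes Allowed CURIE prefixes.
#' @return An [validation_report()].
#' @export
validate_ontology_terms <- function(cas, allowed_prefixes = c("CL")) {
  stopifnot(inherits(cas, "cas_document"))
  terms <- cas$annotations$cell_ontology_term_id
  acc <- cas$annotations$cell_set_accession
  f <- list()
  for (i in seq_along(terms)) {
    t <- terms[i]
    if (is.na(t) || !nzchar(t)) next
    if (!grepl("^[A-Za-z]+:[0-9]{7}$", t)) {
      f <- c(f, list(finding("RECOMMENDED", "ontology_term_pattern", acc[i],
                             sprintf("'%s' is not a CURIE of the form PREFIX:0000000", t))))
    } else {
      prefix <- sub(":.*$", "", t)
      if (!prefix %in% allowed_prefixes) {
        f <- c(f, list(finding("RECOMMENDED", "ontology_term_prefix", acc[i],
                               sprintf("prefix '%s' not in allowed set {%s}", prefix,
                                       paste(allowed_prefixes, collapse = ", ")))))
      }
    }
  }
  if (length(f) == 0) validation_report() else bind_findings(!!!f)
}

#' Embed / extract a CAS document in a taxonomy
#'
#' `embed_cas()` stores the document, canonically serialized (sorted keys,
#' UTF-8, no insignificant whitespace), in the taxonomy's unstructured slot;
#' the document's accessions must match the taxonomy's cell sets exactly.
#' `extract_cas()` parses it back; extract-after-embed is byte-identical
#' under canonical serialization.
#'
#' @param taxonomy An `ait_taxonomy`.
#' @param cas A [cas_document()].
#' @return `embed_cas()`: the taxonomy with `cas_json` set;
#'   `extract_cas()`: a [cas_document()].
#' @export
embed_cas <- function(taxonomy, cas) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"), inherits(cas, "cas_document"))
  tax_acc <- cellsets(taxonomy$hierarchy)$accession
  cas_acc <- cas$annotations$cell_set_accession
  only_tax <- setdiff(tax_acc, cas_acc)
  only_cas <- setdiff(cas_acc, tax_acc)
  if (length(only_tax) > 0 || length(only_cas) > 0) {
    abort(sprintf(
      "CAS accessions do not match taxonomy cell sets (only in taxonomy: %s; only in CAS: %s)",
      paste(only_tax, collapse = ", ") , paste(only_cas, collapse = ", ")))
  }
  taxonomy$cas_json <- cas_to_json(cas)
  taxonomy
}

#' @rdname embed_cas
#' @export
extract_cas <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "ait_taxonomy"))
  if (is.null(taxonomy$cas_json)) abort("taxonomy has no embedded CAS document")
  cas_from_json(taxonomy$cas_json)
}

#' Canonical JSON serialization of a CAS document
#'
#' @param cas A [cas_document()].
#' @return A single JSON string (canonical form: sorted keys, no
#'   insignificant whitespace).
#' @export
cas_to_json <- function(cas) {
  stopifnot(inherits(cas, "cas_document"))
  drop_na <- function(x) {
    x[!vapply(x, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  }
  doc <- list(
    labelsets = lapply(seq_len(nrow(cas$labelsets)), function(i) {
      list(name = cas$labelsets$name[i], rank = cas$labelsets$rank[i],
           description = cas$labelsets$description[i])
    }),
    annotations = lapply(seq_len(nrow(cas$annotations)), function(i) {
      a <- cas$annotations[i, ]
      drop_na(list(
        labelset = a$labelset, cell_label = a$cell_label,
        cell_set_accession = a$cell_set_accession,
        parent_cell_set_accession = a$parent_cell_set_accession,
        cell_ontology_term_id = a$cell_ontology_term_id,
        cell_ontology_term = a$cell_ontology_term,
        rationale = a$rationale,
        marker_gene_evidence = if (length(a$marker_gene_evidence[[1]]) > 0)
          as.list(a$marker_gene_evidence[[1]]) else NULL
      ))
    })
  )
  as.character(canonical_json(doc))
}

#' @rdname cas_to_json
#' @param json CAS JSON string (or path to a `.json` file).
#' @export
cas_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  labelsets <- bind_rows(lapply(doc$labelsets, function(l) {
    tibble(name = l$name, rank = as.integer(l$rank),
           description = l$description %||% "")
  }))
  annotations <- bind_rows(lapply(doc$annotations, function(a) {
    # exact [[-access: $ would partial-match cell_ontology_term to _term_id
    tibble(
      labelset = a[["labelset"]], cell_label = a[["cell_label"]],
      cell_set_accession = a[["cell_set_accession"]],
      parent_cell_set_accession = a[["parent_cell_set_accession"]] %||% NA_character_,
      cell_ontology_term_id = a[["cell_ontology_term_id"]] %||% NA_character_,
      cell_ontology_term = a[["cell_ontology_term"]] %||% NA_character_,
      rationale = a[["rationale"]] %||% NA_character_,
      marker_gene_evidence = list(unlist(a[["marker_gene_evidence"]]) %||% character())
    )
  }))
  cas_document(labelsets, annotations)
}

#' Write / read a standalone CAS JSON file
#' @param cas A [cas_document()].
#' @param path Output `.json` path.
#' @export
write_cas_json <- function(cas, path) {
  writeLines(cas_to_json(cas), path, useBytes = TRUE)
  invisible(path)
}
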