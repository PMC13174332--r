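#' Biospecimen entity types and visualization levels
#'
#' The assay-agnostic provenance model types every physical sample in a
#' single-cell or spatial experiment with a two-letter code: DO donor, SL
#' slab or brain segment, RI region of interest, TI tissue sample, SC tissue
#' section or cryosection, DC dissociated cell sample, EC enriched cell
#' sample, BC barcoded cell sample, AC amplified cDNA, LI library, LA
#' library aliquot, LP library pool, plus SU for the slide/coverslip
#' substrate a section is mounted on. Entities are displayed in eleven
#' ordered columns from donor (level 1) through library pool (level 11);
#' SC and DC are assay-specific alternatives sharing level 5, and SU
#' attaches at level 5 without a column of its own.
#'
#' @return `entity_types()`: tibble with `code`, `label`, `level`,
#'   `own_column`. `provenance_levels()`: the eleven-row level table with
#'   `level` and the codes displayed in that column.
#' @examples
#' provenance_levels()
#' @export
entity_types <- function() {
  tibble(
    code = c("DO", "SL", "RI", "TI", "SC", "DC", "SU", "EC", "BC", "AC", "LI", "LA", "LP"),
    label = c("donor", "slab or brain segment", "region of interest",
              "tissue sample", "tissue section or cryosection",
              "dissociated cell sample", "substrate", "enriched cell sample",
              "barcoded cell sample", "amplified cDNA", "library",
              "library aliquot", "library pool"),
    level = c(1L, 2L, 3L, 4L, 5L, 5L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
    own_column = c(rep(TRUE, 6), FALSE, rep(TRUE, 6))
  )
}

#' @rdname entity_types
#' @export
provenance_levels <- function() {
  et <- entity_types()
  et <- et[et$own_column, ]
  out <- et |>
    group_by(.data$level) |>
    summarise(codes = paste(.data$code, collapse = "|"), .groups = "drop") |>
    arrange(.data$level)
  out
}

#' Deterministic biospecimen identifier
#'
#' Generates an opaque identifier `<CODE>-<10-char base32 digest>` from the
#' parent identifier, a local name, and a salt (SHA-256, first 50 bits,
#' RFC 4648 base32 alphabet). The same inputs always give the same id. This
#' is an internal identifier scheme in the spirit of consortium biospecimen
#' identifiers; the production format is not public.
#'
#' @param type_code Entity type code (see [entity_types()]).
#' @param parent_id Parent identifier ("" for roots).
#' @param local_name Local name of the sample.
#' @param salt Namespace salt.
#' @return Identifier string.
#' @examples
#' make_nhash_id("DO", "", "donor7", "s")
#' @export
make_nhash_id <- function(type_code, parent_id = "", local_name = "", salt = "") {
  et <- entity_types()
  if (!type_code %in% et$code) {
    abort(sprintf("unknown entity type code '%s'", type_code))
  }
  hex <- digest::digest(paste(parent_id, local_name, salt, sep = "|"),
                        algo = "sha256", serialize = FALSE)
  paste0(type_code, "-", hex_to_base32(hex, 10L))
}

hex_to_base32 <- function(hex, n_chars) {
  alphabet <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ234567", "")[[1]]
  need_bits <- n_chars * 5L
  nibbles <- strtoi(strsplit(substr(hex, 1, ceiling(need_bits / 4)), "")[[1]], 16L)
  bits <- as.vector(t(sapply(nibbles, function(v) as.integer(intToBits(v))[4:1])))
  bits <- bits[seq_len(need_bits)]
  idx <- colSums(matrix(bits, nrow = 5) * c(16L, 8L, 4L, 2L, 1L)) + 1L
  paste(alphabet[idx], collapse = "")
}

# Chain grammar per assay class: ordered type sequence, optional subset,
# forbidden types, and whether library branching (several LI/LA lineages
# from one barcoded sample) is allowed.
assay_grammar <- function(assay_class) {
  grammars <- list(
    dissociated = list(
      sequence = c("DO", "SL", "RI", "TI", "DC", "EC", "BC", "AC", "LI", "LA", "LP"),
      optional = c("SL", "EC", "AC"),
      forbidden = c("SC", "SU"),
      needs_substrate = FALSE, branching = FALSE, terminal = "LP"
    ),
    multiome_like = list(
      sequence = c("DO", "SL", "RI", "TI", "DC", "EC", "BC", "AC", "LI", "LA", "LP"),
      optional = c("SL", "EC", "AC"),
      forbidden = c("SC", "SU"),
      needs_substrate = FALSE, branching = TRUE, terminal = "LP"
    ),
    seq_spatial = list(
      sequence = c("DO", "SL", "RI", "TI", "SC", "BC", "AC", "LI", "LA", "LP"),
      optional = c("SL", "AC"),
      forbidden = c("EC", "DC"),
      needs_substrate = TRUE, branching = FALSE, terminal = "LP"
    ),
    img_spatial = list(
      sequence = c("DO", "SL", "RI", "TI", "SC", "BC"),
      optional = c("SL"),
      forbidden = c("EC", "DC", "AC", "LI", "LA", "LP"),
      needs_substrate = TRUE, branching = FALSE, terminal = "BC"
    )
  )
  if (!assay_class %in% names(grammars)) {
    abort(sprintf("unknown assay class '%s' (known: %s)", assay_class,
                  paste(names(grammars), collapse = ", ")))
  }
  grammars[[assay_class]]
}

#' Assay classes with a defined provenance grammar
#' @return Character vector of class names.
#' @export
assay_classes <- function() {
  c("dissociated", "multiome_like", "seq_spatial", "img_spatial")
}

normalize_entities <- function(entities) {
  if (!is.data.frame(entities)) abort("`entities` must be a data frame")
  needed <- c("id", "type")
  miss <- setdiff(needed, names(entities))
  if (length(miss) > 0) abort(sprintf("entity table lacks column(s): %s", paste(miss, collapse = ", ")))
  entities <- as_tibble(entities)
  if (!"parents" %in% names(entities)) entities$parents <- list(character())
  if (!"process" %in% names(entities)) entities$process <- NA_character_
  if (!"attributes" %in% names(entities)) entities$attributes <- list(list())
  entities$parents <- lapply(entities$parents, function(p) as.character(p[!is.na(p) & nzchar(p)]))
  if (anyDuplicated(entities$id)) {
    abort(sprintf("duplicate entity id(s): %s",
                  paste(unique(entities$id[duplicated(entities$id)]), collapse = ", ")))
  }
  all_parents <- unique(unlist(entities$parents, use.names = FALSE))
  dangling <- setdiff(all_parents, entities$id)
  if (length(dangling) > 0) {
    abort(sprintf("dangling parent id(s): %s", paste(dangling, collapse = ", ")))
  }
  entities
}

#' Validate a provenance chain against an assay-class grammar
#'
#' Checks a set of typed biospecimen entities against the canonical chain of
#' one assay class: required types present, forbidden types absent (e.g. no
#' enriched cell sample in sequencing-based spatial assays), parent types in
#' chain order with no required type skipped, single parent except the
#' library pool (many aliquot parents) and the section's substrate
#' attachment, and no unexpected duplicate stages. An empty report means the
#' chain matches the grammar.
#'
#' @param entities Entity data frame: columns `id`, `type`, `parents`
#'   (list-column of parent ids), `process`, optional `attributes`
#'   (list-column). See also [read_chain_json()] / [read_chain_tsv()].
#' @param assay_class One of [assay_classes()].
#' @return An [validation_report()]. Structural problems (duplicate ids,
#'   dangling parent references) raise errors instead.
#' @export
validate_chain <- function(entities, assay_class) {
  grammar <- assay_grammar(assay_class)
  entities <- normalize_entities(entities)
  et <- entity_types()
  f <- list()
  add <- function(code, path, message) {
    f[[length(f) + 1]] <<- finding("MUST", code, path, message)
  }

  unknown <- entities$id[!entities$type %in% et$code]
  for (id in unknown) {
    add("unknown_type", id, sprintf("entity '%s' has unknown type '%s'",
                                    id, entities$type[entities$id == id]))
  }
  known <- entities[entities$type %in% et$code, ]

  forbidden <- c(grammar$forbidden, if (!grammar$needs_substrate) "SU")
  for (i in which(known$type %in% forbidden)) {
    add("forbidden_type", known$id[i],
        sprintf("type '%s' is forbidden in assay class '%s'", known$type[i], assay_class))
  }

  required <- setdiff(grammar$sequence, grammar$optional)
  for (tp in setdiff(required, known$type)) {
    add("missing_required", tp,
        sprintf("required type '%s' is absent from the chain", tp))
  }
  if (grammar$needs_substrate && !"SU" %in% known$type) {
    add("missing_required", "SU", "substrate (SU) is required for spatial chains")
  }

  # duplicate stages: each sequence type appears once, except library
  # branching in multiome-like chains (several LI/LA from one barcoded sample)
  dup_ok <- if (grammar$branching) c("LI", "LA") else character()
  tab <- table(known$type)
  for (tp in names(tab)[tab > 1]) {
    if (tp %in% dup_ok) next
    add("duplicate_type", tp,
        sprintf("type '%s' appears %d times; one expected", tp, tab[[tp]]))
  }

  pos <- setNames(seq_along(grammar$sequence), grammar$sequence)
  type_of <- setNames(known$type, known$id)
  for (i in seq_len(nrow(known))) {
    id <- known$id[i]; tp <- known$type[i]
    parents <- known$parents[[i]]
    ptypes <- unname(type_of[parents])
    su_parents <- parents[ptypes == "SU"]
    chain_parents <- parents[ptypes != "SU"]
    cptypes <- ptypes[ptypes != "SU"]

    if (tp == "SU") {
      if (length(parents) > 0) add("order_violation", id, "substrate (SU) must have no parents")
      next
    }
    if (length(su_parents) > 0 && tp != "SC") {
      add("order_violation", id,
          sprintf("entity '%s' of type '%s' may not attach to a substrate", id, tp))
    }
    if (tp == "SC" && grammar$needs_substrate && length(su_parents) != 1) {
      add("missing_parent", id, "section (SC) must attach to exactly one substrate (SU)")
    }

    if (tp == "DO") {
      if (length(chain_parents) > 0) add("order_violation", id, "donor (DO) must have no parents")
      next
    }
    if (length(chain_parents) == 0) {
      add("orphan_entity", id,
          sprintf("entity '%s' of type '%s' has no parent", id, tp))
      next
    }
    if (tp == "LP") {
      bad <- cptypes[cptypes != "LA"]
      if (length(bad) > 0) {
        add("order_violation", id,
            sprintf("library pool parents must be aliquots (LA); found %s", paste(bad, collapse = ", ")))
      }
      next
    }
    if (length(chain_parents) > 1) {
      add("multi_parent", id,
          sprintf("entity '%s' of type '%s' has %d parents; one expected",
                  id, tp, length(chain_parents)))
      next
    }
    ptype <- cptypes[1]
    if (!tp %in% names(pos) || !ptype %in% names(pos)) next
    if (pos[[ptype]] >= pos[[tp]]) {
      add("order_violation", id,
          sprintf("'%s' (%s) cannot derive from '%s' (%s): wrong chain order",
                  id, tp, chain_parents[1], ptype))
    } else if (pos[[tp]] - pos[[ptype]] > 1) {
      skipped <- grammar$sequence[(pos[[ptype]] + 1):(pos[[tp]] - 1)]
      skipped <- skipped[!skipped %in% grammar$optional]
      if (length(skipped) > 0) {
        add("order_violation", id,
            sprintf("'%s' (%s) derives from '%s' (%s), skipping required stage(s) %s",
                    id, tp, chain_parents[1], ptype, paste(skipped, collapse = ", ")))
      }
    }
  }

  if (length(f) == 0) validation_report() else bind_findings(!!!f)
}

#' Assign visualization levels to provenance entities
#'
#' Maps each entity to its column in the eleven-level specimen display:
#' donor = 1 through library pool = 11; SC and DC share level 5, and the
#' substrate attaches at level 5.
#'
#' @param entities Entity data frame (see [validate_chain()]).
#' @return Tibble `id`, `type`, `level`.
#' @export
assign_levels <- function(entities) {
  entities <- normalize_entities(entities)
  et <- entity_types()
  unknown <- setdiff(entities$type, et$code)
  if (length(unknown) > 0) {
    abort(sprintf("unknown entity type(s): %s", paste(unknown, collapse = ", ")))
  }
  tibble(
    id = entities$id,
    type = entities$type,
    level = setNames(et$level, et$code)[entities$type]
  )
}

#' Export a provenance chain as JSON-LD
#'
#' Serializes entities and their deriving processes as a JSON-LD graph using
#' PROV vocabulary: each biospecimen is a node with `@id`, `@type` and
#' `prov:wasDerivedFrom` links; each derivation is a `prov:Activity` with
#' `prov:used` (parents) and `prov:generated` (child) links.
#'
#' @param entities Entity data frame.
#' @param assay_class Optional; when given the chain is validated first and
#'   an invalid chain is refused.
#' @return A list representing the JSON-LD document (`@context` + `@graph`);
#'   serialize with [write_jsonld()].
#' @export
export_jsonld <- function(entities, assay_class = NULL) {
  entities <- normalize_entities(entities)
  if (!is.null(assay_class)) {
    rep <- validate_chain(entities, assay_class)
    if (!is_conformant(rep)) {
      abort(c("refusing to export an invalid chain; findings:",
              setNames(head(rep$message, 10), rep("x", min(10, nrow(rep))))))
    }
  }
  et <- entity_types()
  label_of <- setNames(gsub(" ", "_", et$label), et$code)
  graph <- list()
  for (i in seq_len(nrow(entities))) {
    node <- list(
      "@id" = paste0("bspec:", entities$id[i]),
      "@type" = paste0("bspec:", label_of[[entities$type[i]]]),
      "rdfs:label" = entities$id[i]
    )
    parents <- entities$parents[[i]]
    if (length(parents) > 0) {
      node[["prov:wasDerivedFrom"]] <- lapply(parents, function(p) list("@id" = paste0("bspec:", p)))
    }
    graph[[length(graph) + 1]] <- node
    if (length(parents) > 0) {
      graph[[length(graph) + 1]] <- list(
        "@id" = paste0("bspec:process/", entities$id[i]),
        "@type" = "prov:Activity",
        "rdfs:label" = if (is.na(entities$process[i])) "derivation" else entities$process[i],
        "prov:used" = lapply(parents, function(p) list("@id" = paste0("bspec:", p))),
        "prov:generated" = list("@id" = paste0("bspec:", entities$id[i]))
      )
    }
  }
  list(
    "@context" = list(
      prov = "http://www.w3.org/ns/prov#",
      rdfs = "http://www.w3.org/2000/01/rdf-schema#",
      bspec = "https://example.org/biospecimen/"
    ),
    "@graph" = graph
  )
}

#' @rdname export_jsonld
#' @param doc A JSON-LD document from [export_jsonld()].
#' @param path Output `.jsonld` path.
#' @export
write_jsonld <- function(doc, path) {
  writeLines(canonical_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Triples of a PROV JSON-LD document
#'
#' Expands a document produced by [export_jsonld()] into subject-predicate-
#' object triples (the RDF view of the graph).
#'
#' @param doc JSON-LD document (list) or path to a `.jsonld` file.
#' @return Tibble with `subject`, `predicate`, `object`.
#' @export
jsonld_triples <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::read_json(doc)
  rows <- list()
  for (node in doc[["@graph"]]) {
    s <- node[["@id"]]
    for (key in setdiff(names(node), "@id")) {
      val <- node[[key]]
      pred <- if (key == "@type") "rdf:type" else key
      objs <- if (is.list(val) && !is.null(val[["@id"]])) list(val) else if (is.list(val)) val else list(val)
      for (o in objs) {
        obj <- if (is.list(o)) o[["@id"]] else as.character(o)
        rows[[length(rows) + 1]] <- tibble(subject = s, predicate = pred, object = obj)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(subject = character(), predicate = character(), object = character()))
  }
  bind_rows(rows)
}

#' Re-import entities from a PROV JSON-LD document
#'
#' Inverse of [export_jsonld()]: reconstructs the entity table (ids, types,
#' parent links, process labels) from the document's graph, for round-trip
#' and isomorphism checks.
#'
#' @param doc JSON-LD document (list) or path.
#' @return Entity tibble.
#' @export
parse_jsonld <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::read_json(doc)
  et <- entity_types()
  code_of <- setNames(et$code, paste0("bspec:", gsub(" ", "_", et$label)))
  strip <- function(x) sub("^bspec:", "", x)
  ents <- list(); procs <- list()
  for (node in doc[["@graph"]]) {
    if (identical(node[["@type"]], "prov:Activity")) {
      child <- strip(node[["prov:generated"]][["@id"]])
      procs[[child]] <- node[["rdfs:label"]]
    } else {
      parents <- vapply(node[["prov:wasDerivedFrom"]] %||% list(),
                        function(p) strip(p[["@id"]]), character(1))
      ents[[length(ents) + 1]] <- tibble(
        id = strip(node[["@id"]]),
        type = unname(code_of[node[["@type"]]]),
        parents = list(unname(parents))
      )
    }
  }
  out <- if (length(ents)) bind_rows(ents) else
    tibble(id = character(), type = character(), parents = list())
  out$process <- vapply(out$id, function(id) procs[[id]] %||% NA_character_, character(1))
  out$attributes <- rep(list(list()), nrow(out))
  out
}

#' Compare two provenance graphs for isomorphism
#'
#' Two chains are isomorphic here when they have the same entities (id and
#' type) and the same derivation edges.
#'
#' @param a,b Entity data frames.
#' @return Logical.
#' @export
provenance_isomorphic <- function(a, b) {
  a <- normalize_entities(a); b <- normalize_entities(b)
  nodes <- function(e) lex_sort(paste(e$id, e$type))
  edges <- function(e) {
    lex_sort(unlist(purrr::map2(e$id, e$parents, function(id, ps) {
      if (length(ps)) paste(id, lex_sort(ps)) else character()
    }), use.names = FALSE))
  }
  identical(nodes(a), nodes(b)) && identical(edges(a), edges(b))
}

#' Read a provenance chain
#'
#' `read_chain_json()` reads `{"entities": [{"id", "type", "parents",
#' "process", "attributes"}, ...]}`. `read_chain_tsv()` reads an edge list
#' with columns `child_id`, `child_type`, `parent_id`, `process` (empty
#' `parent_id` for roots; one row per parent).
#'
#' @param path Input file path.
#' @return Entity tibble as accepted by [validate_chain()].
#' @export
read_chain_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$entities)) abort("chain JSON lacks an 'entities' array")
  bind_rows(lapply(doc$entities, function(e) {
    tibble(
      id = e$id, type = e$type,
      parents = list(unlist(e$parents) %||% character()),
      process = e$process %||% NA_character_,
      attributes = list(e$attributes %||% list())
    )
  }))
}

#' @rdname read_chain_json
#' @export
read_chain_tsv <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c("child_id", "child_type", "parent_id")
  miss <- setdiff(needed, names(edges))
  if (length(miss) > 0) abort(sprintf("edge list lacks column(s): %s", paste(miss, collapse = ", ")))
  if (!"process" %in% names(edges)) edges$process <- NA_character_
  edges |>
    group_by(.data$child_id, .data$child_type) |>
    summarise(
      parents = list(.data$parent_id[!is.na(.data$parent_id) & nzchar(.data$parent_id)]),
      process = .data$process[1], .groups = "drop"
    ) |>
    rename(id = "child_id", type = "child_type") |>
    mutate(attributes = rep(list(list()), dplyr::n()))
}

#' Write a provenance chain as JSON
#' @param entities Entity tibble.
#' @param path Output path.
#' @export
write_chain_json <- function(entities, path) {
  entities <- normalize_entities(entities)
  doc <- list(entities = lapply(seq_len(nrow(entities)), function(i) {
    list(
      id = entities$id[i], type = entities$type[i],
      parents = as.list(entities$parents[[i]]),
      process = entities$process[i],
      attributes = entities$attributes[[i]]
    )
  }))
  writeLines(canonical_json(doc), path, useBytes = TRUE)
  invisible(path)
}
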