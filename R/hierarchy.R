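#' Hierarchical cell set assignments
#'
#' A cell set hierarchy organizes cells into nested groupings across ordered
#' annotation levels, coarsest first (e.g. `class`, `subclass`, `cluster`).
#' At every level each cell carries exactly one non-empty label (a partition),
#' and labels nest: all cells sharing a label at a fine level share the same
#' label at every coarser level, so the induced parent map is a tree.
#'
#' Each distinct (level, label) pair is a *cell set*. Cell sets receive
#' deterministic accessions of the form `<prefix>:<zero-padded integer>`,
#' assigned level-major and then in lexicographic label order, so the same
#' assignment table always yields the same accessions.
#'
#' @param assignments A data frame with a `cell_id` column plus one character
#'   column per hierarchy level. Ingested from TSV via [read_assignments()].
#' @param levels Ordered level names, coarsest first. Defaults to the
#'   assignment columns other than `cell_id`, in table order.
#' @param id_prefix Accession prefix, typically the taxonomy id.
#' @return An object of class `ait_hierarchy`: a list with `levels`,
#'   `assignments` (tibble) and `cell_sets` (tibble with `accession`, `label`,
#'   `level`, `parent_accession`, `n_cells`).
#' @examples
#' asn <- tibble::tibble(
#'   cell_id = c("c1", "c2", "c3", "c4"),
#'   class = c("A", "A", "A", "B"),
#'   cluster = c("A1", "A1", "A2", "B1")
#' )
#' h <- ait_hierarchy(asn)
#' cellsets(h)
#' @export
ait_hierarchy <- function(assignments, levels = NULL, id_prefix = "CS") {
  assignments <- check_assignments_table(assignments, levels)
  levels <- attr(assignments, "levels")
  attr(assignments, "levels") <- NULL
  h <- structure(
    list(levels = levels, assignments = assignments, cell_sets = NULL,
         id_prefix = id_prefix),
    class = "ait_hierarchy"
  )
  rep <- validate_hierarchy(h)
  if (is_conformant(rep)) h$cell_sets <- derive_cell_sets(assignments, levels, id_prefix)
  h
}

# Structural checks shared by the constructor and the validator. These are
# errors (malformed input), distinct from invariant findings.
check_assignments_table <- function(assignments, levels = NULL) {
  if (!is.data.frame(assignments)) abort("`assignments` must be a data frame")
  if (!"cell_id" %in% names(assignments)) abort("`assignments` must have a `cell_id` column")
  if (nrow(assignments) == 0) abort("`assignments` table is empty")
  if (is.null(levels)) levels <- setdiff(names(assignments), "cell_id")
  if (length(levels) == 0) abort("`assignments` has no level columns")
  miss <- setdiff(levels, names(assignments))
  if (length(miss) > 0) {
    abort(sprintf("level column(s) missing from assignments: %s", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(assignments)[, c("cell_id", levels)]
  out <- mutate(out, across(dplyr::everything(), as.character))
  attr(out, "levels") <- levels
  out
}

#' Validate a cell set hierarchy
#'
#' Checks the three structural invariants of a hierarchy and reports each
#' violation as a `MUST` finding:
#' * *partition*: every cell has a non-empty label at every level (empty
#'   strings, `NA`, and the literal `"NA"` count as missing), and cell ids
#'   are unique;
#' * *nesting*: cells sharing a label at a fine level agree at every coarser
#'   level (equivalently, each cell set has a single parent);
#' * *tree*: the induced parent map is a tree (single parent, no cycles) --
#'   with ordered levels this follows from the nesting check, which is the
#'   one reported.
#'
#' @param hierarchy An [ait_hierarchy()] object, or a raw assignments data
#'   frame (with `cell_id` plus level columns).
#' @param levels Level order when `hierarchy` is a raw data frame.
#' @return An [validation_report()] tibble; zero findings iff all invariants
#'   hold. Malformed tables (missing level column, empty table) raise an
#'   error instead of producing findings.
#' @export
validate_hierarchy <- function(hierarchy, levels = NULL) {
  if (inherits(hierarchy, "ait_hierarchy")) {
    asn <- hierarchy$assignments
    levels <- hierarchy$levels
  } else {
    asn <- check_assignments_table(hierarchy, levels)
    levels <- attr(asn, "levels")
  }
  findings <- list()

  dup <- unique(asn$cell_id[duplicated(asn$cell_id)])
  if (length(dup) > 0) {
    findings <- c(findings, list(finding(
      "MUST", "duplicate_cell_id", dup,
      sprintf("cell id '%s' appears more than once", dup)
    )))
  }

  for (lv in levels) {
    bad <- asn$cell_id[is_missing_label(asn[[lv]])]
    if (length(bad) > 0) {
      findings <- c(findings, list(finding(
        "MUST", "partition_missing_label", paste0(lv, "/", bad),
        sprintf("cell '%s' has a missing label at level '%s'", bad, lv)
      )))
    }
  }

  # nesting: a set at level k must map to exactly one label at level k-1
  if (length(levels) > 1) {
    for (k in 2:length(levels)) {
      fine <- levels[k]; coarse <- levels[k - 1]
      ok <- !is_missing_label(asn[[fine]]) & !is_missing_label(asn[[coarse]])
      tab <- unique(tibble(fine = asn[[fine]][ok], coarse = asn[[coarse]][ok]))
      multi <- tab$fine[duplicated(tab$fine)]
      for (s in lex_sort(unique(multi))) {
        parents <- lex_sort(tab$coarse[tab$fine == s])
        findings <- c(findings, list(finding(
          "MUST", "nesting_multiple_parents", paste0(fine, "/", s),
          sprintf("cell set '%s' at level '%s' has %d parents at level '%s': %s",
                  s, fine, length(parents), coarse, paste(parents, collapse = ", "))
        )))
      }
    }
  }

  if (length(findings) == 0) validation_report() else bind_findings(!!!findings)
}

# Deterministic cell set table: level-major, lexicographic label order,
# zero-padded accession integers.
derive_cell_sets <- function(asn, levels, id_prefix) {
  counter <- 0L
  sets <- list()
  label_to_acc <- list()
  for (k in seq_along(levels)) {
    lv <- levels[k]
    labels <- lex_sort(unique(asn[[lv]]))
    acc <- sprintf("%s:%04d", id_prefix, counter + seq_along(labels))
    counter <- counter + length(labels)
    label_to_acc[[lv]] <- setNames(acc, labels)
    parent <- rep(NA_character_, length(labels))
    if (k > 1) {
      coarse <- levels[k - 1]
      pair <- unique(tibble(fine = asn[[lv]], coarse = asn[[coarse]]))
      parent_label <- setNames(pair$coarse, pair$fine)[labels]
      parent <- unname(label_to_acc[[coarse]][parent_label])
    }
    n_cells <- as.integer(table(asn[[lv]])[labels])
    sets[[k]] <- tibble(
      accession = acc, label = labels, level = lv,
      parent_accession = parent, n_cells = n_cells
    )
  }
  bind_rows(sets)
}

#' @export
print.ait_hierarchy <- function(x, ...) {
  cat(sprintf("<cell set hierarchy> %d cells, %d level(s): %s\n",
              nrow(x$assignments), length(x$levels), paste(x$levels, collapse = " > ")))
  if (!is.null(x$cell_sets)) {
    per <- dplyr::count(x$cell_sets, .data$level)
    per <- per[match(x$levels, per$level), ]
    cat("  cell sets per level:", paste(sprintf("%s=%d", per$level, per$n), collapse = ", "), "\n")
  } else {
    cat("  (invalid hierarchy: see validate_hierarchy())\n")
  }
  invisible(x)
}

#' Cell set table of a hierarchy
#'
#' @param hierarchy An [ait_hierarchy()] object.
#' @return Tibble of cell sets (`accession`, `label`, `level`,
#'   `parent_accession`, `n_cells`).
#' @export
cellsets <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "ait_hierarchy"))
  if (is.null(hierarchy$cell_sets)) {
    abort("hierarchy is not valid; run validate_hierarchy() for the findings")
  }
  hierarchy$cell_sets
}

#' Members of a cell set
#'
#' Returns the ids of the cells labeled with the given cell set. For an
#' internal set this equals the union of its children's member sets.
#'
#' @param hierarchy An [ait_hierarchy()] object.
#' @param accession Cell set accession (see [cellsets()]).
#' @return Character vector of cell ids.
#' @export
cellset_membership <- function(hierarchy, accession) {
  cs <- cellsets(hierarchy)
  row <- cs[cs$accession == accession, ]
  if (nrow(row) == 0) abort(sprintf("unknown cell set accession '%s'", accession))
  asn <- hierarchy$assignments
  asn$cell_id[asn[[row$level]] == row$label]
}

#' Prune a hierarchy to a subset of cells
#'
#' Keeps exactly the requested cells; cell sets left with no members are
#' dropped at every level. The result is itself a valid hierarchy (accessions
#' are re-derived deterministically from the surviving sets).
#'
#' @param hierarchy An [ait_hierarchy()] object.
#' @param keep_cells Character vector of cell ids to keep (non-empty, all
#'   present in the hierarchy).
#' @return A pruned [ait_hierarchy()].
#' @export
prune_hierarchy <- function(hierarchy, keep_cells) {
  stopifnot(inherits(hierarchy, "ait_hierarchy"))
  if (length(keep_cells) == 0) abort("`keep_cells` is empty")
  unknown <- setdiff(keep_cells, hierarchy$assignments$cell_id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown cell id(s) in `keep_cells`: %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }
  asn <- hierarchy$assignments[hierarchy$assignments$cell_id %in% keep_cells, ]
  ait_hierarchy(asn, hierarchy$levels, hierarchy$id_prefix)
}

#' Read hierarchy assignments from TSV
#'
#' Expects a UTF-8 TSV with header `cell_id` plus one column per level,
#' coarsest first; no index column.
#'
#' @param path TSV file path.
#' @return Tibble of assignments (all columns character).
#' @export
read_assignments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
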