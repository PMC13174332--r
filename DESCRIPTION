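Package: aitkit
Title: Cell Type Taxonomy Files, Reference Mapping, and Biospecimen Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A toolkit for building, sharing, and using hierarchical cell type
    taxonomies from single-cell and spatial transcriptomics, following the
    layered standards developed for large brain cell atlas consortia. Builds
    annotated taxonomy objects from counts, cluster assignments and metadata;
    computes per-cell-set statistics, one-vs-sibling marker genes and a
    centroid dendrogram; serializes taxonomies to a single annotated-matrix
    (h5ad) container with normative-keyword validation and optional
    ("lightweight") expression matrices; embeds and extracts nested Cell
    Annotation Schema documents; supports taxonomy modes (named cell and gene
    subsets that behave as consistent derived taxonomies); maps query cells
    onto a taxonomy by flat or hierarchical correlation with bootstrap
    confidence; and models assay-agnostic biospecimen provenance chains with
    typed entities, per-assay-class grammar validation, deterministic
    identifier generation, an eleven-level visualization table, and JSON-LD
    export. A seeded synthetic-data module generates hierarchically clustered
    negative-binomial counts and canonical provenance chains so the full
    pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    Matrix,
    rhdf5,
    digest,
    readr,
    ggplot2,
    generics,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
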