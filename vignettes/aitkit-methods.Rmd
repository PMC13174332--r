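---
title: "Methods: taxonomy files, correlation mapping, and provenance chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomy files, correlation mapping, and provenance chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aitkit)
```

`aitkit` implements two connected pieces of data-standards machinery for
single-cell and spatial transcriptomics: a single-file format for
hierarchical cell type taxonomies (with building, validation, subsetting,
annotation exchange, and reference mapping on top of it), and an
assay-agnostic model of biospecimen provenance with grammar validation and
linked-data export. This vignette explains the models, the defaults, and the
design decisions, in the package's own terms.

## The cell set hierarchy

A taxonomy organizes cells into nested groupings across ordered levels,
coarsest first — typically `class`, `subclass`, `cluster`. The package
enforces three invariants:

* **partition** — at every level every cell carries exactly one non-empty
  label. Empty strings, `NA` values, and the literal string `"NA"` all count
  as missing; the last is a common hazard when tables pass through
  spreadsheet software. A cell that is labeled at a coarse level but not at
  a fine one is treated as a violation — partial annotation is a plausible
  future relaxation, but allowing it silently would make the per-level
  statistics below ill-defined.
* **nesting** — cells sharing a fine label agree at every coarser level, so
  each cell set has a unique parent.
* **tree** — the induced parent map is a tree. With ordered levels this
  follows from nesting, which is what the validator reports.

Cell sets receive accessions `<taxonomy_id>:<zero-padded integer>` assigned
level-major and then in lexicographic label order (radix order, so the
result is locale-independent). The same assignment table therefore always
yields the same accessions; note the corollary that pruning a hierarchy
re-derives accessions for the surviving sets.

## Building: normalization, statistics, markers, dendrogram

Counts are normalized to `log2(CPM + 1)`: counts per million within each
cell, log base 2, pseudocount 1. The transform maps zeros to zeros (sparsity
is preserved) and is invertible given the library size, which makes it
directly testable. It is the working scale for every downstream statistic.

For every cell set at every level the builder precomputes the mean
normalized expression per gene, the fraction of member cells with a nonzero
count per gene, and the member count. These statistics are sufficient for
mapping, which is what makes "lightweight" taxonomy files (no expression
matrices) useful.

**Marker selection** is a deterministic one-vs-sibling contrast. At every
node with at least two children (including the implicit root above the
coarsest level), each child `c` is scored against its siblings per gene `g`:

```
score(g) = mean_c(g) − max over siblings s of mean_s(g)
```

subject to the detection gate

```
fraction_c(g) − max over siblings s of fraction_s(g) ≥ min_fraction_diff
```

with `min_fraction_diff = 0.2` by default. Only genes with positive scores
are kept (a gene that fails the mean contrast is not a marker however it
passes the gate), ranked by score with ties broken by lexicographic gene id,
up to `markers_per_node = 20` per child. A node's marker set is the union
over its children. This is a mean-difference heuristic, not a rank test: it
is fast, fully deterministic, and sufficient to drive correlation mapping;
the scoring function is isolated so a different contrast could be swapped in.

**The dendrogram** is built over finest-level cell set centroids (not single
cells — at taxonomy scale the centroid tree is what atlases display),
restricted to the union of all selected markers (all genes if no markers
survived), with average linkage on the distance `1 − Pearson correlation`.
Leaves are processed in accession order, so the tree and its left-to-right
leaf order are reproducible. Non-finite correlations (constant centroid
profiles) are replaced with 0 before clustering.

The default pipeline contains no stochastic step; the build config still
carries a seed so that any future stochastic extension stays routed through
a single recorded value.

## The single-file container

Taxonomies serialize to an AnnData-compatible HDF5 (h5ad) file: normalized
values in `X`, raw counts in `layers/counts`, cell metadata plus one column
per hierarchy level in `obs`, gene metadata in `var`, and everything else
under `uns/AIT` — schema version, taxonomy id, the authoritative ordered
level list (obs columns are unordered by nature), the cell set table,
per-level statistics matrices (stored as float64 datasets so round trips
are bit-exact), marker lists and the dendrogram as JSON strings (there is
no standard HDF5 tree encoding), and mode masks. An embedded Cell
Annotation Schema document lives at `uns/cell_annotation_schema` as a single
JSON string rather than decomposed groups: a string round-trips byte-exactly
across h5ad implementations, nested groups do not reliably.

Files written by this implementation record dialect version `1.0.0`; the
reader refuses files whose major version is newer than it supports.

Validation follows normative-keyword practice: `MUST` findings (schema
version present and semantic, taxonomy id present, level columns present,
unique cell ids, hierarchy invariants) decide conformance; `RECOMMENDED`
findings (dendrogram, statistics, embedded CAS, populated ontology terms)
flag missing enrichment without failing the file. Reports are deterministic,
so fixtures can assert exact findings.

Matrices are read and written dense. At desk scale this is simple and exact;
h5ad files with matrices beyond a few hundred thousand cells are a known
pain point across ecosystems, and the lightweight path (`strip_matrix()`,
`include_matrix = FALSE`) is the supported answer rather than a sparse
on-disk encoding.

## CAS exchange

`annotations_to_cas()` emits one labelset per level with rank 0 for the
coarsest level (matching the package's level ordering) and one annotation
per cell set with parent links mirroring the tree; marker evidence is filled
from the precomputed statistics when present. The inverse,
`cas_to_annotations()`, needs only per-cell assignments at the finest
labelset and follows parent links upward, erroring on dangling accessions
and cycles. Byte-identity for embed/extract is defined over *canonical
JSON*: recursively sorted object keys, UTF-8, no insignificant whitespace,
full numeric precision. Canonicalization is what makes "the same document"
testable across platforms. Ontology term checking is syntactic only (CURIE
shape `PREFIX:0000000`, default allowed prefix `CL`); resolving terms
against a live ontology service is an extension point, not a dependency.

## Taxonomy modes

A mode is a named pair of boolean masks (cells, genes) stored in the file —
never a copy of the data. Materializing a mode follows one rule: **means
over fewer cells change, means over fewer genes do not**. A gene-only mode
therefore slices the statistics exactly; a cell mode recomputes statistics
and markers on the subset (and so requires the expression matrix). The
dendrogram of a derived view is always rebuilt from the surviving leaves
and genes — a pruned tree with stale heights would be misleading. Cell
modes drop an embedded CAS document, since pruning re-derives accessions;
gene modes keep it. Applying a mode never mutates the base taxonomy, and
applying mode `M` then `N` equals a single mode with intersected masks
(marker lists may differ, because selection over a restricted gene pool can
promote genes that were not globally top-ranked; the statistics agree
exactly).

Modes only subset. Re-clustering inside a mode (changing leaf boundaries)
is out of scope by design: a mode is a view of one taxonomy, not a new one.

## Mapping query cells

Queries are normalized exactly as the reference was. **Flat mapping**
correlates each query cell (Pearson, on the normalized scale) with every
finest-level centroid over the genes shared between the query and the
taxonomy's marker union (all reference genes if no markers are stored), and
assigns the argmax, ties to the lowest accession. **Hierarchical mapping**
descends greedily from the root, correlating at each node over that node's
own marker union and recursing into the best child; the accession path and
per-step scores are recorded. Greedy descent is the simplest faithful
reading of hierarchical annotation transfer; a beam width is a natural
extension but is not implemented. If a node's markers share no genes with
the query, that node falls back to all shared genes and the cell is flagged
`marker_fallback`. A constant query vector has no defined correlation; it is
assigned the first leaf with score 0 and flag `constant_query` rather than
erroring mid-batch. Zero gene overlap errors up front, reporting both sizes.

**Bootstrap confidence** re-runs the chosen mapper on `n_boot = 100` random
subsamples of `ceiling(0.7 × |markers|)` marker genes (without replacement)
and reports the fraction agreeing with the full-marker leaf. All bootstrap
randomness flows through one explicit seed. Note one consequence of
deterministic tie-breaking: two *exactly* identical centroids never split
the vote (the lower accession always wins), so the intuitive "coin-flip
between twins" behavior appears for near-identical, not identical, leaves.

## Biospecimen provenance

Every physical sample in a sequencing or spatial experiment is a typed
entity: donor (DO), slab (SL), region of interest (RI), tissue sample (TI),
section (SC) or dissociated cell sample (DC), enriched cell sample (EC),
barcoded cell sample (BC), amplified cDNA (AC), library (LI), library
aliquot (LA), library pool (LP), plus the slide substrate (SU) a section is
mounted on. Entities display in eleven ordered levels, donor = 1 through
library pool = 11. Reconciling thirteen codes with eleven columns is a
modeling decision: SC and DC are assay-specific alternatives occupying
level 5 (the section path is the spatial analog of the dissociated-sample
path), and SU attaches at level 5 without a column of its own.

Four assay-class grammars govern chain shape:

* `dissociated`: DO → [SL] → RI → TI → DC → [EC] → BC → [AC] → LI → LA → LP
* `multiome_like`: the same chain, but several library lineages (e.g. RNA
  and chromatin) may branch from the one barcoded sample
* `seq_spatial`: DO → [SL] → RI → TI → SC(+SU) → BC → [AC] → LI → LA → LP,
  with EC and DC forbidden
* `img_spatial`: ends at a barcoded-sample *analog* (attribute
  `analog = TRUE`) — no amplified cDNA or libraries exist for imaging

Brackets mark optional stages. Validation reports missing required types,
forbidden types, order violations (a parent must precede its child with no
required stage skipped), unexpected multi-parenthood (only LP pools many
aliquots; only SC attaches a substrate), duplicate stages, and orphans;
dangling identifier references are structural errors. Patch-seq style
experiments are the dissociated grammar with modality attributes — their
electrophysiology and morphology data files are out of scope.

Identifiers are `<CODE>-<10-char base32 of SHA-256(parent|name|salt)>`.
This is an internal, deterministic scheme in the spirit of consortium
biospecimen identifiers whose production format is not public; it claims
nothing about any registry's actual format.

JSON-LD export emits each entity as a node with `@id`, `@type` and
`prov:wasDerivedFrom` links, and each derivation as a `prov:Activity` with
`prov:used`/`prov:generated` — the PROV view of the chain. The package
includes its own triple expansion and graph-isomorphism check for the
document shape it emits (no R JSON-LD processor is assumed); the export was
additionally verified against an independent RDF parser during development,
which produced identical triple counts.

## The synthetic generator

`simulate_taxonomy_dataset()` emulates the input a taxonomy builder
consumes: a balanced 3 × 3 × 3 class/subclass/cluster tree (27 leaves, 50
cells each, 1350 cells, 300 genes), with 10 planted marker genes per tree
node elevated 3 log2 units across that node's subtree, negative-binomial
counts with dispersion 0.5, and lognormal per-cell sequencing depth
(meanlog 9.2, sdlog 0.3). Two modeling choices deserve explanation:

* **Depth is relative.** The lognormal draw is median-normalized into a
  per-cell scale factor, with `baseline_mean = 1` the negative-binomial
  mean of an unelevated gene in a median-depth cell. Over a 300-gene panel
  this yields realistic sparsity (roughly 40% zeros) and an on/off contrast
  between planted markers and background — the regime in which
  detection-fraction gates and correlation mapping are meaningful. Spreading
  a literal ~10k-count library over 300 genes would instead saturate every
  gene in every cell and make fraction-based marker selection vacuous.
* **Sibling-disjoint markers with cross-subtree reuse.** 39 tree nodes × 10
  markers exceed 300 genes, so genes may serve as markers of nodes in
  unrelated subtrees, but siblings never share a marker and a node never
  reuses its ancestors' markers; unused genes are preferred before any gene
  is reused. Sibling contrasts — the only contrasts the builder and the
  hierarchical mapper ever compute — therefore stay clean.

The generator returns its ground truth (tree, planted marker table,
per-cluster expression profiles) alongside the data, and all output is a
pure function of the config including the seed. `simulate_query_cells()`
draws held-out cells from the same per-cluster models, with `noise_scale`
added to the dispersion. `simulate_provenance_chain()` emits the canonical
chain of each assay class.

What the generator does *not* emulate: batch effects, doublets, ambient
RNA, cell-state gradients within clusters, gene–gene correlation beyond the
planted block structure, or spatial coordinates. Tests passing on this data
show the machinery is correct under its stated model — deterministic
normalization and statistics, marker recovery under clean planted contrast,
near-ceiling mapping recovery at a strong (8-fold) effect size, chance-level
recovery when the effect is removed. They do not show robustness to the
artifacts real data adds.

## Numerical choices and problem sizes

Group statistics are computed by sparse indicator-matrix products and are
required to match a naive per-set loop within `1e-10`; mapping must match a
brute-force nearest-centroid loop in its assignments. All ordering
tie-breaks use radix sort for locale independence. Degenerate inputs have
defined behavior rather than errors where a batch context demands it
(constant query cells) and errors where silence would corrupt results
(empty selections, unknown ids, invalid hierarchies, dangling references).

The shipped tests and the acceptance script run the full pipeline at the
generator's default scale — 1350 reference cells × 300 genes, 27 clusters,
500 held-out query cells, 100 bootstrap replicates — sizes chosen so a
complete run takes seconds while every code path (multi-level hierarchy,
marker reuse, mode slicing, lightweight files) is exercised.

## Known limitations

* Dense in-memory matrices bound the practical taxonomy size; the
  lightweight file path covers sharing and mapping but not re-building.
* Pruning (and therefore cell modes) re-derives accessions; stable
  accessions across subsetting would require a persistent registry, which a
  single-file format cannot provide alone.
* Ontology validation is syntactic; terms are not resolved against the Cell
  Ontology.
* The mapper is a deterministic correlation method; probabilistic mappers
  and cross-taxonomy label transfer are out of scope.
* The provenance grammars model the canonical chains; laboratory reality
  (re-pooling, re-aliquoting, QC failures) will need grammar extensions.
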