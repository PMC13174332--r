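test_that("identifier generation is deterministic, typed, and collision-free", {
  a <- make_nhash_id("DO", "", "donor7", "s")
  expect_match(a, "^DO-[A-Z2-7]{10}$")
  expect_identical(a, make_nhash_id("DO", "", "donor7", "s"))
  expect_false(a == make_nhash_id("DO", "", "donor8", "s"))
  expect_error(make_nhash_id("XX", "", "x", "s"), "unknown entity type")

  ids <- vapply(seq_len(1e5), function(i) make_nhash_id("TI", "p", as.character(i), ""),
                character(1))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("the level table spans exactly eleven levels, donor through library pool", {
  lv <- provenance_levels()
  expect_equal(nrow(lv), 11)
  expect_equal(lv$level, 1:11)
  expect_equal(lv$codes[1], "DO")
  expect_equal(lv$codes[11], "LP")
  expect_equal(lv$codes[5], "SC|DC")  # assay-specific alternatives share a column

  et <- entity_types()
  expect_equal(et$level[et$code == "SC"], et$level[et$code == "DC"])
  expect_false(et$own_column[et$code == "SU"])
  expect_equal(et$level[et$code == "SU"], 5L)

  # a dissociated chain with EC but without SL/AC spans the expected columns
  types <- c("DO", "RI", "TI", "DC", "EC", "BC", "LI", "LA", "LP")
  ids <- paste0(types, "-X")
  ch <- tibble::tibble(
    id = ids, type = types,
    parents = c(list(character()), as.list(ids[-length(ids)])),
    process = NA_character_, attributes = rep(list(list()), length(ids))
  )
  expect_equal(nrow(validate_chain(ch, "dissociated")), 0)
  expect_setequal(assign_levels(ch)$level, c(1, 3, 4, 5, 6, 7, 9, 10, 11))

  # the fully minimal chain drops the optional EC as well
  minimal <- simulate_provenance_chain("dissociated", with_optionals = FALSE)
  expect_setequal(assign_levels(minimal)$level, c(1, 3, 4, 5, 7, 9, 10, 11))

  # union over all four grammars covers all eleven
  all_lv <- unlist(lapply(assay_classes(), function(cl) {
    assign_levels(simulate_provenance_chain(cl, with_optionals = TRUE))$level
  }))
  expect_equal(sort(unique(all_lv)), 1:11)
})

test_that("canonical chains validate and forbidden entities are caught", {
  for (cls in assay_classes()) {
    ch <- simulate_provenance_chain(cls, with_optionals = TRUE)
    expect_equal(nrow(validate_chain(ch, cls)), 0, label = cls)
  }

  # an enriched cell sample inside a sequencing-based spatial chain
  ch <- simulate_provenance_chain("seq_spatial", with_optionals = TRUE)
  ec <- tibble::tibble(id = "EC-INTRUDER99", type = "EC",
                       parents = list(ch$id[ch$type == "SC"]),
                       process = "cell enrichment", attributes = list(list()))
  bad <- rbind(ch, ec)
  rep <- validate_chain(bad, "seq_spatial")
  expect_true("forbidden_type" %in% rep$code)
  expect_true("EC-INTRUDER99" %in% rep$path)

  expect_error(validate_chain(ch, "smFISH"), "unknown assay class")
})

test_that("grammar acceptance is closed under optional insertion and broken by required removal", {
  for (cls in assay_classes()) {
    with_opt <- simulate_provenance_chain(cls, with_optionals = TRUE)
    without <- simulate_provenance_chain(cls, with_optionals = FALSE)
    expect_equal(nrow(validate_chain(with_opt, cls)), 0)
    expect_equal(nrow(validate_chain(without, cls)), 0)

    grammar_required <- setdiff(with_opt$type, c("SL", "EC", "AC", "SU"))
    for (tp in grammar_required) {
      mut <- without
      victim <- mut$id[mut$type == tp][1]
      vparents <- mut$parents[[match(victim, mut$id)]]
      mut <- mut[mut$id != victim, ]
      mut$parents <- lapply(mut$parents, function(p) {
        if (victim %in% p) union(setdiff(p, victim), vparents) else p
      })
      expect_gt(nrow(validate_chain(mut, cls)), 0,
                label = sprintf("%s without %s", cls, tp))
    }
  }
})

test_that("single-edit mutations are all detected (50 per class by harness)", {
  for (cls in assay_classes()) {
    ch <- simulate_provenance_chain(cls, with_optionals = TRUE)
    muts <- chain_mutations(ch, cls, n = 50, seed = 42)
    expect_length(muts, 50)
    detected <- vapply(muts, function(m) {
      nrow(validate_chain(m$entities, cls)) > 0
    }, logical(1))
    expect_true(all(detected),
                label = sprintf("%s: %d/50 detected", cls, sum(detected)))
  }
})

test_that("dangling parent ids are structural errors", {
  ch <- simulate_provenance_chain("dissociated")
  ch$parents[[3]] <- "TI-DOESNOTEXIST"
  expect_error(validate_chain(ch, "dissociated"), "dangling")
})

test_that("JSON-LD export encodes entities, processes and derivations", {
  ch <- simulate_provenance_chain("dissociated", with_optionals = FALSE)
  three <- ch[1:3, ]
  doc <- export_jsonld(three)
  graph <- doc[["@graph"]]
  types <- vapply(graph, function(n) n[["@type"]], character(1))
  expect_equal(sum(types != "prov:Activity"), 3)  # entity nodes
  expect_equal(sum(types == "prov:Activity"), 2)  # one process per derived entity

  # triple count identity: 2 per entity (+1/parent), 3 per process (+1/parent)
  tr <- jsonld_triples(doc)
  expect_equal(nrow(tr), 3 * 2 + 2 * 1 + 2 * 3 + 2 * 1)

  # empty graph document
  empty <- export_jsonld(three[0, ])
  expect_length(empty[["@graph"]], 0)
  expect_equal(nrow(jsonld_triples(empty)), 0)

  # invalid chains are refused when a grammar is named
  bad <- three
  bad$type[2] <- "SC"
  expect_error(export_jsonld(bad, "dissociated"), "invalid chain")
})

test_that("JSON-LD round trip is graph-isomorphic for every assay class", {
  for (cls in assay_classes()) {
    ch <- simulate_provenance_chain(cls, with_optionals = TRUE)
    path <- withr::local_tempfile(fileext = ".jsonld")
    write_jsonld(export_jsonld(ch, cls), path)
    back <- parse_jsonld(path)
    expect_true(provenance_isomorphic(ch, back), label = cls)
  }
})

test_that("chain JSON and TSV ingestion round-trip the entity table", {
  ch <- simulate_provenance_chain("multiome_like", with_optionals = TRUE)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_chain_json(ch, jpath)
  back <- read_chain_json(jpath)
  expect_true(provenance_isomorphic(ch, back))
  expect_equal(nrow(validate_chain(back, "multiome_like")), 0)

  # TSV edge list
  tpath <- withr::local_tempfile(fileext = ".tsv")
  edges <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    ps <- ch$parents[[i]]
    if (length(ps) == 0) ps <- NA_character_
    data.frame(child_id = ch$id[i], child_type = ch$type[i],
               parent_id = ps, process = ch$process[i])
  }))
  readr::write_tsv(edges, tpath, progress = FALSE)
  back2 <- read_chain_tsv(tpath)
  expect_true(provenance_isomorphic(ch, back2))
})
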