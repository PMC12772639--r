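# Property-graph store: merge semantics, identity, indices, serialization.

test_that("merge_node creates, matches and enriches by identity key", {
  store <- kg_store()
  payload <- entity_node("disease", "Type 2 Diabetes Mellitus",
                         "SNOMEDCT:44054006", source = src())
  m1 <- merge_node(store, payload)
  expect_equal(m1$outcome, "created")
  expect_equal(kg_size(m1$store)[["nodes"]], 1L)

  m2 <- merge_node(m1$store, payload)
  expect_equal(m2$outcome, "matched")
  expect_equal(kg_size(m2$store)[["nodes"]], 1L)

  # same concept code under a different surface name still matches
  m3 <- merge_node(m2$store, entity_node("disease", "T2DM variant name",
                                         "SNOMEDCT:44054006",
                                         source = src()))
  expect_equal(m3$outcome, "matched")
  expect_equal(m3$node_id, m1$node_id)

  # enrichment via a new property: verify against a naive store dump
  before <- m3$store$nodes[[m1$node_id]]$properties
  m4 <- merge_node(m3$store, entity_node(
    "disease", "Type 2 Diabetes Mellitus", "SNOMEDCT:44054006",
    properties = list(abbreviation = "T2DM"), source = src()))
  expect_equal(m4$outcome, "enriched")
  expect_equal(m4$attrs_modified, 1L)
  after <- m4$store$nodes[[m1$node_id]]$properties
  expect_equal(setdiff(names(after), names(before)), "abbreviation")
  expect_equal(after$abbreviation$value, "T2DM")
})

test_that("conflicting concept codes in one namespace are rejected atomically", {
  m <- merge_node(kg_store(), entity_node("disease", "Gout",
                                          "SNOMEDCT:90560007",
                                          source = src()))
  dir_a <- withr::local_tempdir()
  kg_serialize(m$store, dir_a)
  expect_error(
    merge_node(m$store, entity_node("disease", "Gout",
                                    "SNOMEDCT:190828005", source = src())),
    class = "kg_code_conflict")
  # two same-namespace codes inside one payload are rejected too
  expect_error(
    merge_node(m$store, entity_node(
      "disease", "Gout", c("SNOMEDCT:1", "SNOMEDCT:2"), source = src())),
    class = "kg_code_conflict")
  # the store is byte-identical to before the failed merges
  dir_b <- withr::local_tempdir()
  kg_serialize(m$store, dir_b)
  expect_identical(readLines(file.path(dir_a, "nodes.jsonl")),
                   readLines(file.path(dir_b, "nodes.jsonl")))
})

test_that("higher-authority property values are never overwritten", {
  m <- merge_node(kg_store(), entity_node(
    "trial", "Trial ABC", properties = list(phase = "3"),
    source = src("regulatory_guideline", "2020-01-01")))
  # lower tier loses even when newer
  m2 <- merge_node(m$store, entity_node(
    "trial", "Trial ABC", properties = list(phase = "2"),
    source = src("unstructured_note", "2024-01-01")))
  expect_equal(m2$outcome, "matched")
  expect_equal(kg_get_property(m2$store, m2$node_id, "phase"), "3")
  # equal tier, newer date wins
  m3 <- merge_node(m2$store, entity_node(
    "trial", "Trial ABC", properties = list(phase = "4"),
    source = src("regulatory_guideline", "2023-01-01")))
  expect_equal(kg_get_property(m3$store, m3$node_id, "phase"), "4")
  # equal tier and date: incumbent kept
  m4 <- merge_node(m3$store, entity_node(
    "trial", "Trial ABC", properties = list(phase = "1"),
    source = src("regulatory_guideline", "2023-01-01")))
  expect_equal(kg_get_property(m4$store, m4$node_id, "phase"), "4")
})

test_that("merge_edge verifies entities, is idempotent, reports conflicts", {
  s <- store_with(list(name = "DrugX", type = "drug"),
                  list(name = "DisY", type = "disease"))
  cand <- edge_candidate(s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]],
                         0.9, src("textbook", "2010-05-01"))
  # dangling endpoint
  expect_error(
    merge_edge(s$store, edge_candidate("missing", "TREATS",
                                       s$ids[["DisY"]], 0.9, src())),
    class = "kg_entity_error")
  # malformed confidence
  expect_error(
    merge_edge(s$store, edge_candidate(s$ids[["DrugX"]], "TREATS",
                                       s$ids[["DisY"]], 1.7, src())),
    class = "kg_syntax_error")

  m1 <- merge_edge(s$store, cand)
  expect_equal(m1$outcome, "created")
  m2 <- merge_edge(m1$store, cand)
  expect_equal(m2$outcome, "matched")
  expect_equal(kg_size(m2$store)[["edges"]], 1L)

  # provenance union + max confidence on a duplicate from another source
  m3 <- merge_edge(m2$store, edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]], 0.95,
    src("regulatory_guideline", "2023-01-01")))
  expect_equal(m3$outcome, "enriched")
  e <- m3$store$edges[[m3$edge_id]]
  expect_length(e$provenance, 2L)
  expect_equal(e$confidence, 0.95)

  # a contraindication against an active treats edge is not written
  contra <- edge_candidate(s$ids[["DrugX"]], "CONTRAINDICATED_IN",
                           s$ids[["DisY"]], 0.9,
                           src("regulatory_guideline", "2023-06-01"))
  mc <- merge_edge(m3$store, contra)
  expect_equal(mc$outcome, "conflicted")
  expect_length(mc$conflicts, 1L)
  expect_equal(kg_size(mc$store)[["edges"]], 1L)
})

test_that("index lookups equal a linear-scan oracle on random stores", {
  set.seed(42)
  store <- kg_store()
  types <- kg_semantic_types()
  for (i in seq_len(200)) {
    has_code <- runif(1) < 0.5
    payload <- entity_node(
      sample(types, 1), paste("Entity", sample.int(120, 1)),
      if (has_code) paste0("LOCAL:", sample.int(150, 1)) else character(),
      source = src())
    store <- tryCatch(merge_node(store, payload)$store,
                      error = function(e) store)  # rare code clash: skip
  }
  for (nm in unique(vapply(store$nodes, `[[`, "", "preferred_name"))) {
    expect_identical(kg_find(store, name = nm), scan_find(store, name = nm))
  }
  codes <- unique(unlist(lapply(store$nodes, `[[`, "concept_ids")))
  for (cd in c(codes, "LOCAL:absent")) {
    expect_identical(kg_find(store, code = cd), scan_find(store, code = cd))
  }
  for (ty in types) {
    expect_identical(kg_find(store, semantic_type = ty),
                     scan_find(store, semantic_type = ty))
  }
  expect_true(kg_verify_indices(store))
})

test_that("serialization round-trips bit-stably, including empty stores", {
  d0 <- withr::local_tempdir()
  kg_serialize(kg_store(), d0)
  empty <- kg_deserialize(d0)
  expect_equal(kg_size(empty)[["nodes"]], 0L)

  set.seed(7)
  s <- kg_store()
  ids <- character()
  for (i in seq_len(40)) {
    m <- merge_node(s, entity_node(
      sample(c("drug", "disease"), 1), sprintf("Concept %02d", i),
      paste0("LOCAL:", i),
      properties = if (i %% 3 == 0) list(note = "x") else list(),
      source = src()))
    s <- m$store; ids <- c(ids, m$node_id)
  }
  for (i in seq_len(60)) {
    pair <- sample(ids, 2)
    cand <- edge_candidate(pair[1], sample(kg_predicates(), 1), pair[2],
                           round(runif(1), 3), src(),
                           valid_to = if (i %% 5 == 0) "2030-01-01")
    s <- tryCatch(merge_edge(s, cand, policy = NULL)$store,
                  error = function(e) s)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  kg_serialize(s, d1)
  s2 <- kg_deserialize(d1)
  kg_serialize(s2, d2)
  for (f in c("nodes.jsonl", "edges.jsonl")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(kg_verify_indices(s2))
  expect_identical(kg_size(s2), kg_size(s))

  # malformed line: parse error naming the line
  writeLines(c("{\"node_id\": \"a\"}", "{broken"),
             file.path(d1, "nodes.jsonl"))
  expect_error(kg_deserialize(d1), "line 2")
})

test_that("active-edge uniqueness holds under arbitrary merge sequences", {
  set.seed(11)
  s <- store_with(list(name = "A", type = "drug"),
                  list(name = "B", type = "disease"))
  store <- s$store
  for (i in seq_len(30)) {
    cand <- edge_candidate(s$ids[["A"]], "TREATS", s$ids[["B"]],
                           runif(1), src(date = "2020-01-01"),
                           valid_to = if (i %% 4 == 0) "2021-01-01")
    store <- merge_edge(store, cand, policy = NULL)$store
  }
  active <- Filter(function(e) is.null(e$valid_to), store$edges)
  keys <- vapply(active, function(e)
    paste(e$subject, e$predicate, e$object), "")
  expect_false(any(duplicated(keys)))
})

test_that("cypher export writes one statement per element", {
  s <- store_with(list(name = "DrugX", type = "drug"),
                  list(name = "DisY", type = "disease"))
  st <- merge_edge(s$store, edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]], 0.9, src()))$store
  path <- withr::local_tempfile(fileext = ".cypher")
  kg_export_cypher(st, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_true(any(grepl("^MERGE \\(n:drug", lines)))
  expect_true(any(grepl("CREATE \\(a\\)-\\[:TREATS", lines)))
})
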