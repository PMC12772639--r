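# Query layer: entity retrieval, path and subgraph queries with temporal
# validity, deterministic rendering with provenance.

diabetes_fixture <- function() {
  s <- store_with(list(name = "DrugA", type = "drug"),
                  list(name = "DrugB", type = "drug"),
                  list(name = "DrugC", type = "drug"),
                  list(name = "Diabetes", type = "disease"))
  store <- s$store
  for (d in c("DrugA", "DrugB", "DrugC")) {
    store <- merge_edge(store, edge_candidate(
      s$ids[[d]], "TREATS", s$ids[["Diabetes"]], 0.81,
      src("textbook", "2015-01-01", paste0("tb-", d))))$store
  }
  # supersede DrugC's indication with a 2023 contraindication
  contra <- edge_candidate(s$ids[["DrugC"]], "CONTRAINDICATED_IN",
                           s$ids[["Diabetes"]], 0.86,
                           src("regulatory_guideline", "2023-01-01",
                               "guide-C"))
  rep <- detect_conflicts(store, contra)[[1]]
  store <- resolve_conflict(store, rep)$store
  list(store = store, ids = s$ids)
}

test_that("entity queries respect validity and equal a brute-force filter", {
  f <- diabetes_fixture()
  res <- entity_query(f$store, list(semantic_type = "drug",
                                    predicate = "TREATS",
                                    object = f$ids[["Diabetes"]]))
  expect_setequal(res$node_ids, unname(f$ids[c("DrugA", "DrugB")]))
  # brute-force oracle over all nodes and edges
  oracle <- sort(unique(unlist(lapply(f$store$edges, function(e) {
    if (e$predicate == "TREATS" && is.null(e$valid_to) &&
        e$object == f$ids[["Diabetes"]]) e$subject else NULL
  }))))
  expect_identical(res$node_ids, oracle)
  expect_true(length(res$provenance) >= 1)

  # before the contraindication date the third drug still counts
  res2 <- entity_query(f$store, list(predicate = "TREATS",
                                     object = f$ids[["Diabetes"]]),
                       as_of = "2020-06-01")
  expect_setequal(res2$node_ids, unname(f$ids[c("DrugA", "DrugB",
                                                "DrugC")]))
  # before any valid_from: empty
  res3 <- entity_query(f$store, list(predicate = "TREATS",
                                     object = f$ids[["Diabetes"]]),
                       as_of = "2001-01-01")
  expect_length(res3$node_ids, 0L)
  # empty graph
  expect_length(entity_query(kg_store(),
                             list(semantic_type = "drug"))$node_ids, 0L)
  expect_error(entity_query(f$store, list(bogus_key = 1)), "unknown filter")
})

test_that("temporal monotonicity: widening as_of never removes results", {
  s <- store_with(list(name = "D1", type = "drug"),
                  list(name = "D2", type = "drug"),
                  list(name = "Dis", type = "disease"))
  store <- s$store
  store <- merge_edge(store, edge_candidate(
    s$ids[["D1"]], "TREATS", s$ids[["Dis"]], 0.8,
    src(date = "2015-01-01")))$store
  store <- merge_edge(store, edge_candidate(
    s$ids[["D2"]], "TREATS", s$ids[["Dis"]], 0.8,
    src(date = "2019-01-01")))$store
  dates <- c("2014-01-01", "2016-01-01", "2020-01-01")
  sets <- lapply(dates, function(d)
    entity_query(store, list(predicate = "TREATS",
                             object = s$ids[["Dis"]]), as_of = d)$node_ids)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
  expect_length(sets[[1]], 0L)
  expect_length(sets[[3]], 2L)
})

test_that("path queries find the drug-trial-side-effect chain", {
  s <- store_with(list(name = "Drug A", type = "drug"),
                  list(name = "Trial X", type = "trial"),
                  list(name = "Side Effect B", type = "side_effect"),
                  list(name = "Lonely", type = "outcome"))
  store <- s$store
  store <- merge_edge(store, edge_candidate(
    s$ids[["Drug A"]], "USED_IN_TRIAL", s$ids[["Trial X"]], 0.9, src()))$store
  store <- merge_edge(store, edge_candidate(
    s$ids[["Trial X"]], "REPORTED", s$ids[["Side Effect B"]], 0.9,
    src()))$store
  res <- path_query(store, s$ids[["Drug A"]], s$ids[["Side Effect B"]],
                    max_hops = 2)
  expect_length(res$paths, 1L)
  expect_equal(res$paths[[1]]$nodes,
               unname(s$ids[c("Drug A", "Trial X", "Side Effect B")]))
  # one hop is not enough
  expect_length(path_query(store, s$ids[["Drug A"]],
                           s$ids[["Side Effect B"]], 1)$paths, 0L)
  # disconnected endpoints
  expect_length(path_query(store, s$ids[["Drug A"]], s$ids[["Lonely"]],
                           4)$paths, 0L)
  expect_error(path_query(store, "nope", s$ids[["Lonely"]], 2),
               class = "kg_entity_error")
})

test_that("path results equal the exhaustive DFS oracle on random graphs", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(8:20, 1)
    args <- lapply(seq_len(n), function(i)
      list(name = sprintf("N%02d", i), type = "drug"))
    s <- do.call(store_with, args)
    store <- s$store
    for (k in seq_len(3 * n)) {
      pair <- sample(unname(s$ids), 2)
      store <- merge_edge(store, edge_candidate(
        pair[1], "ASSOCIATED_WITH", pair[2], 0.8, src(),
        valid_to = if (runif(1) < 0.15) "2030-01-01"),
        policy = NULL)$store
    }
    for (k in 1:5) {
      ends <- sample(unname(s$ids), 2)
      hops <- sample(1:4, 1)
      got <- lapply(path_query(store, ends[1], ends[2], hops)$paths,
                    `[[`, "nodes")
      want <- oracle_paths(store, ends[1], ends[2], hops)
      key <- function(p) paste(p, collapse = ">")
      expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
      # deterministic ordering: by length then lexicographic node ids
      if (length(got) > 1) {
        ord <- vapply(got, function(p)
          sprintf("%03d|%s", length(p) - 1L, key(p)), "")
        expect_identical(ord, sort(ord))
      }
    }
  }
})

test_that("subgraph extraction is induced, provenance-complete, idempotent", {
  s <- store_with(list(name = "Trial X", type = "trial"),
                  list(name = "Drug A", type = "drug"),
                  list(name = "Outcome O", type = "outcome"),
                  list(name = "SE B", type = "side_effect"),
                  list(name = "Far Away", type = "disease"))
  store <- s$store
  link <- function(store, a, p, b) merge_edge(store, edge_candidate(
    s$ids[[a]], p, s$ids[[b]], 0.9, src()))$store
  store <- link(store, "Drug A", "USED_IN_TRIAL", "Trial X")
  store <- link(store, "Trial X", "RESULTS_IN", "Outcome O")
  store <- link(store, "Trial X", "REPORTED", "SE B")
  store <- link(store, "Drug A", "TREATS", "Far Away")

  r0 <- subgraph_query(store, s$ids[["Trial X"]], radius = 0)
  expect_equal(r0$node_ids, unname(s$ids[["Trial X"]]))
  expect_length(r0$subgraph$edges, 0L)

  r1 <- subgraph_query(store, s$ids[["Trial X"]], radius = 1)
  expect_setequal(r1$node_ids,
                  unname(s$ids[c("Trial X", "Drug A", "Outcome O",
                                 "SE B")]))
  # induced: all active edges among the returned nodes, none beyond
  expect_length(r1$subgraph$edges, 3L)
  expect_true(length(r1$provenance) >= 1)

  # fixed point: extracting again from the subgraph changes nothing
  r2 <- subgraph_query(r1$subgraph, s$ids[["Trial X"]], radius = 1)
  expect_setequal(r2$node_ids, r1$node_ids)
  expect_setequal(names(r2$subgraph$edges), names(r1$subgraph$edges))

  expect_error(subgraph_query(store, "ghost", 1),
               class = "kg_entity_error")
})

test_that("answers render deterministically with provenance", {
  f <- diabetes_fixture()
  res <- entity_query(f$store, list(predicate = "TREATS",
                                    object = f$ids[["Diabetes"]]))
  ans <- render_answer(res, f$store)
  expect_match(ans$text, "^DrugA; DrugB\\. \\[sources: ")
  expect_true(all(c("tb-DrugA", "tb-DrugB") %in% ans$provenance))

  none <- entity_query(f$store, list(predicate = "TREATS",
                                     object = f$ids[["Diabetes"]]),
                       as_of = "1990-01-01")
  expect_equal(render_answer(none, f$store)$text,
               "no supporting evidence in graph")

  scripted <- function(store, result, question) "scripted generation"
  ans2 <- render_answer(res, f$store, renderer = scripted)
  expect_equal(ans2$text, "scripted generation")
  expect_identical(ans2$provenance, res$provenance)
})
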