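# Phase-2 updater: validation, conflict detection/resolution, confidence
# scoring, batch application and change accounting.

test_that("validation separates syntactic and semantic failures", {
  s <- store_with(list(name = "DrugX", type = "drug"),
                  list(name = "DisY", type = "disease"),
                  list(name = "Coughing", type = "symptom"))
  ok <- validate_candidate(edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]], 0.9, src()), s$store)
  expect_true(ok$syntactic_ok && ok$semantic_ok && ok$ok)

  # disease as TREATS subject violates the domain rule
  bad_dom <- validate_candidate(edge_candidate(
    s$ids[["DisY"]], "TREATS", s$ids[["DrugX"]], 0.9, src()), s$store)
  expect_true(bad_dom$syntactic_ok)
  expect_false(bad_dom$semantic_ok)
  expect_match(bad_dom$semantic_diagnostics[1], "domain rule TREATS")

  # symptom object is allowed for TREATS
  sym_ok <- validate_candidate(edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["Coughing"]], 0.9, src()), s$store)
  expect_true(sym_ok$semantic_ok)

  # malformed date property is a syntactic failure naming the property
  bad_date <- validate_candidate(edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]], 0.9, src(),
    properties = list(review_date = "2023-13-40")), s$store)
  expect_false(bad_date$syntactic_ok)
  expect_match(bad_date$syntactic_diagnostics[1], "review_date")

  bad_conf <- validate_candidate(edge_candidate(
    s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]], -0.2, src()), s$store)
  expect_false(bad_conf$syntactic_ok)
})

test_that("indexed conflict detection equals the brute-force oracle", {
  policy <- kg_default_policy()
  for (seed in 1:4) {
    set.seed(seed)
    drugs <- sprintf("Drug%02d", 1:8)
    diseases <- sprintf("Dis%02d", 1:6)
    args <- c(lapply(drugs, function(d) list(name = d, type = "drug")),
              lapply(diseases, function(d) list(name = d,
                                                type = "disease")))
    s <- do.call(store_with, args)
    store <- s$store
    n_edges <- sample(50:200, 1)
    for (i in seq_len(n_edges)) {
      cand <- edge_candidate(
        s$ids[[sample(drugs, 1)]],
        sample(c("TREATS", "CONTRAINDICATED_IN", "CAUSES"), 1),
        s$ids[[sample(diseases, 1)]], runif(1),
        src(date = "2020-01-01"),
        valid_to = if (runif(1) < 0.2) "2021-06-01")
      store <- merge_edge(store, cand, policy = NULL)$store
    }
    for (k in 1:25) {
      cand <- edge_candidate(
        s$ids[[sample(drugs, 1)]],
        sample(c("TREATS", "CONTRAINDICATED_IN"), 1),
        s$ids[[sample(diseases, 1)]], runif(1), src())
      got <- sort(vapply(detect_conflicts(store, cand, policy),
                         function(r) r$incumbent$edge_id, ""))
      expect_identical(got, scan_conflicts(store, cand,
                                           policy$exclusions))
    }
  }
  # duplicate same-predicate assertions are the merge path, not a conflict
  s <- store_with(list(name = "A", type = "drug"),
                  list(name = "B", type = "disease"))
  st <- merge_edge(s$store, edge_candidate(
    s$ids[["A"]], "TREATS", s$ids[["B"]], 0.9, src()))$store
  expect_length(detect_conflicts(st, edge_candidate(
    s$ids[["A"]], "TREATS", s$ids[["B"]], 0.8, src()), policy), 0L)
})

challenger_for <- function(f) {
  edge_candidate(f$ids[["DrugX"]], "CONTRAINDICATED_IN", f$ids[["DisY"]],
                 0.86, src("regulatory_guideline", "2023-06-15"))
}

test_that("authority then recency resolves conflicts with temporal supersedence", {
  mk <- function() {
    s <- store_with(list(name = "DrugX", type = "drug"),
                    list(name = "DisY", type = "disease"))
    st <- merge_edge(s$store, edge_candidate(
      s$ids[["DrugX"]], "TREATS", s$ids[["DisY"]],
      0.81, src("textbook", "2010-03-01", "textbook-2010")))$store
    list(store = st, ids = s$ids)
  }
  policy <- kg_default_policy()

  # a 2023 guideline supersedes the 2010 textbook statement
  f <- mk()
  challenger <- edge_candidate(
    f$ids[["DrugX"]], "CONTRAINDICATED_IN", f$ids[["DisY"]], 0.86,
    src("regulatory_guideline", "2023-06-15", "guideline-2023"))
  rep <- detect_conflicts(f$store, challenger, policy)[[1]]
  r <- resolve_conflict(f$store, rep, policy)
  expect_equal(r$resolution, "supersede")
  old <- Filter(function(e) e$predicate == "TREATS", r$store$edges)[[1]]
  expect_equal(old$valid_to, "2023-06-15")   # half-open closure
  new <- Filter(function(e) e$predicate == "CONTRAINDICATED_IN",
                r$store$edges)[[1]]
  expect_null(new$valid_to)
  # the superseded edge is inactive from the winner's date, active before
  expect_false(edge_active_at(old, "2023-06-15"))
  expect_true(edge_active_at(old, "2023-06-14"))

  # lower authority challenger loses
  f <- mk()
  weak <- edge_candidate(
    f$ids[["DrugX"]], "CONTRAINDICATED_IN", f$ids[["DisY"]], 0.5,
    src("unstructured_note", "2024-01-01"))
  r2 <- resolve_conflict(f$store,
                         detect_conflicts(f$store, weak, policy)[[1]],
                         policy)
  expect_equal(r2$resolution, "keep_incumbent")
  expect_equal(kg_size(r2$store)[["edges"]], 1L)

  # structured EMR evidence outranks an unstructured-note assertion
  s2 <- store_with(list(name = "DrugZ", type = "drug"),
                   list(name = "DisW", type = "disease"))
  st2 <- merge_edge(s2$store, edge_candidate(
    s2$ids[["DrugZ"]], "CONTRAINDICATED_IN", s2$ids[["DisW"]], 0.54,
    src("unstructured_note", "2022-01-01")))$store
  emr_cand <- edge_candidate(
    s2$ids[["DrugZ"]], "TREATS", s2$ids[["DisW"]], 0.9,
    src("structured_emr", "2021-05-01"))
  r3 <- resolve_conflict(st2,
                         detect_conflicts(st2, emr_cand, policy)[[1]],
                         policy)
  expect_equal(r3$resolution, "supersede")

  # full tie: flagged, graph assertions unchanged
  f <- mk()
  tie <- edge_candidate(
    f$ids[["DrugX"]], "CONTRAINDICATED_IN", f$ids[["DisY"]], 0.81,
    src("textbook", "2010-03-01", "other-textbook"))
  r4 <- resolve_conflict(f$store,
                         detect_conflicts(f$store, tie, policy)[[1]],
                         policy)
  expect_equal(r4$resolution, "flagged")
  expect_equal(r4$flagged, 1L)
  expect_equal(kg_size(r4$store)[["active_edges"]], 1L)

  # adjudicated qualified reconciliation keeps both edges
  f <- mk()
  adj <- function(req) list(choice = "coexist_qualified",
                            rationale = "contraindicated in this patient due to Comorbidity Z")
  r5 <- resolve_conflict(f$store,
                         detect_conflicts(f$store, challenger_for(f),
                                          policy)[[1]],
                         policy, adjudicator = adj)
  expect_equal(r5$resolution, "coexist_qualified")
  expect_equal(kg_size(r5$store)[["active_edges"]], 2L)
  qual <- Filter(function(e) e$predicate == "CONTRAINDICATED_IN",
                 r5$store$edges)[[1]]
  expect_match(qual$properties$qualifier$value, "Comorbidity Z")

  # malformed adjudicator response: flagged, unchanged
  f <- mk()
  bad <- function(req) list(choice = "do something else")
  r6 <- resolve_conflict(f$store,
                         detect_conflicts(f$store, challenger_for(f),
                                          policy)[[1]],
                         policy, adjudicator = bad)
  expect_equal(r6$resolution, "flagged")
})



test_that("confidence scoring follows the tier-by-method table", {
  expect_equal(score_confidence("regulatory_guideline", "crosswalk"), 0.95)
  expect_equal(score_confidence("unstructured_note", "similarity"), 0.48)
  expect_equal(score_confidence("structured_emr", "direct_kg"), 0.90)
  expect_equal(score_confidence("textbook", "rule"), 0.81)
  expect_error(score_confidence("oracle_bones", "rule"), "tier")
  expect_error(score_confidence("textbook", "telepathy"), "method")
  for (tier in names(authority_tiers())) {
    for (m in c("ontology", "crosswalk", "direct_kg", "rule",
                "adjudicator", "similarity")) {
      v <- score_confidence(tier, m)
      expect_true(v >= 0 && v <= 1)
    }
  }
})

test_that("apply_update is conservative and replay yields the zero changeset", {
  run <- default_pipeline()
  before <- kg_size(run$init$store)
  after <- kg_size(run$update$store)
  cs <- run$update$changeset
  # ChangeSet conservation: counters match observed store growth
  expect_equal(after[["nodes"]] - before[["nodes"]], cs$nodes_added)
  expect_equal(after[["edges"]] - before[["edges"]], cs$edges_added)
  expect_equal(cs$items_failed, 0L)
  # per-item accounting sums to the totals
  items <- changeset_items(cs)
  expect_equal(sum(items$nodes), cs$nodes_added)
  expect_equal(sum(items$edges), cs$edges_added)
  expect_equal(sum(items$attrs), cs$attributes_modified)
  # replaying the already-applied stream changes nothing
  dir <- default_corpus_dir()
  rep <- apply_update(run$update$store, file.path(dir, "update"),
                      run$ont, adjudicator = run$adjudicator)
  expect_equal(rep$changeset$nodes_added, 0L)
  expect_equal(rep$changeset$edges_added, 0L)
  expect_equal(rep$changeset$attributes_modified, 0L)
  expect_equal(rep$changeset$conflicts_flagged, 0L)
})

test_that("supersedence never closes a strictly higher-authority newer edge", {
  run <- default_pipeline()
  store <- run$update$store
  rank <- function(tier) authority_tiers()[[tier]]
  for (e in store$edges) {
    if (is.null(e$valid_to)) next
    # find the active partner that superseded it
    partner <- if (e$predicate == "TREATS") "CONTRAINDICATED_IN" else
      if (e$predicate == "CONTRAINDICATED_IN") "TREATS" else next
    winner_key <- paste(e$subject, partner, e$object, sep = "|")
    winner_ids <- Filter(function(x) startsWith(x, winner_key),
                         names(store$edges))
    for (wid in winner_ids) {
      w <- store$edges[[wid]]
      if (!is.null(w$valid_to)) next
      loser_src <- e$provenance[[1]]
      winner_src <- w$provenance[[1]]
      stronger_loser <-
        rank(loser_src$authority_tier) > rank(winner_src$authority_tier) ||
        (rank(loser_src$authority_tier) ==
           rank(winner_src$authority_tier) &&
           as.Date(loser_src$date) > as.Date(winner_src$date))
      expect_false(stronger_loser)
    }
  }
})
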