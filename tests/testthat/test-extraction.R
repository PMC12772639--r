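# Phase-1 extraction: recognizer, relation patterns, schema alignment,
# temporal precedence, comorbidity attribution.

test_that("mention extraction is longest-match with half-open offsets", {
  ont <- tiny_ontology()
  lex <- build_lexicon(ont)
  text <- "Metformin treats Type 2 Diabetes Mellitus"
  m <- extract_mentions(text, lex)
  expect_equal(m$text, c("Metformin", "Type 2 Diabetes Mellitus"))
  expect_equal(m$start, c(0L, 17L))
  expect_equal(m$end, c(9L, 41L))
  expect_equal(substr(text, m$start[1] + 1, m$end[1]), "Metformin")

  expect_equal(nrow(extract_mentions("", lex)), 0L)

  # a lexicon containing both "Diabetes" and the longer phrase reports only
  # the longer span; verified against brute force over all lexicon spans
  lex2 <- rbind(lex, data.frame(term = "Diabetes", concept = "LOCAL:d",
                                semantic_type = "disease"))
  m2 <- extract_mentions(text, lex2)
  expect_false("Diabetes" %in% m2$term)
  expect_true("Type 2 Diabetes Mellitus" %in% m2$term)
  # brute force: every reported span must be a real occurrence, and no two
  # kept spans overlap
  for (i in seq_len(nrow(m2))) {
    expect_equal(tolower(substr(text, m2$start[i] + 1, m2$end[i])),
                 tolower(m2$term[i]))
  }
  if (nrow(m2) > 1L) {
    for (i in seq_len(nrow(m2) - 1L)) {
      expect_true(m2$end[i] <= m2$start[i + 1])
    }
  }
})

test_that("surface patterns extract triples including relative clauses", {
  doc <- clinical_document("d1", "textbook", "2020-01-01",
    paste("Metformin treats Type 2 Diabetes Mellitus.",
          "Drug A was used in Trial X, which reported Side Effect B.",
          "The weather was pleasant that day."))
  tr <- extract_triples(doc)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$predicate, c("TREATS", "USED_IN_TRIAL", "REPORTED"))
  expect_equal(tr$subject[2:3], c("Drug A", "Trial X"))
  expect_equal(tr$object[2:3], c("Trial X", "Side Effect B"))
  expect_match(tr$context[2], "which reported")

  # every predicate's surface form parses back to itself
  for (p in kg_predicates()) {
    d <- clinical_document("d2", "note", "2020-01-01",
                           clinkg:::sentence_of("Alpha Thing", p,
                                                "Beta Thing"))
    got <- extract_triples(d)
    expect_equal(got$predicate, p)
    expect_equal(got$subject, "Alpha Thing")
    expect_equal(got$object, "Beta Thing")
  }

  # attribute statements
  da <- clinical_document("d3", "trial_report", "2021-01-01",
                          "Trial X has phase 3. Trial X has start date 2020-02-01.")
  at <- extract_attributes(da)
  expect_equal(at$key, c("phase", "start_date"))
  expect_equal(at$value, c("3", "2020-02-01"))
})

test_that("schema alignment cascades exact, similarity, ontology", {
  ont <- tiny_ontology()
  kg_schema <- data.frame(
    name = c("diagnosis_code", "lab_creatinine", "medication_name"),
    code = c("", "SNOMEDCT:166717003", ""),
    stringsAsFactors = FALSE)
  fields <- data.frame(
    field_name = c("diagnosis_code", "dx code", "serum_creat_result",
                   "completely_unrelated_field"),
    description = c("", "", "", ""),
    code = c("", "", "LOINC:2160-0", ""),
    stringsAsFactors = FALSE)
  out <- align_schema(fields, kg_schema, ont)

  expect_equal(out$method[1], "exact")
  expect_equal(out$score[1], 1)
  expect_true(out$accepted[1])
  expect_false(out$flagged_for_review[1])

  # hand-computed token-set cosine: {dx, code} vs {diagnosis, code}
  # -> 1 / sqrt(2 * 2) = 0.5
  expect_equal(out$method[2], "similarity")
  expect_equal(out$score[2], 0.5)
  expect_equal(out$target[2], "diagnosis_code")
  expect_false(out$accepted[2])
  expect_true(out$flagged_for_review[2])
  expect_equal(token_set_cosine("dx code", "diagnosis_code"), 0.5)

  # LOINC-coded field maps through the crosswalk to the SNOMED-coded column
  expect_equal(out$method[3], "ontology")
  expect_equal(out$target[3], "lab_creatinine")
  expect_true(out$accepted[3])

  expect_false(out$accepted[4])
  expect_true(out$flagged_for_review[4])

  # cascade order: an exact match never consults the embedder
  bomb <- function(a, b) stop("embedder must not run")
  exact_only <- align_schema(
    data.frame(field_name = "diagnosis_code"), kg_schema, ont,
    embedder = bomb)
  expect_equal(exact_only$method, "exact")
})

test_that("temporal precedence orders events strictly and flags ties", {
  ev <- data.frame(
    field_name = c("medication", "medication"),
    value = c("Lisinopril", "Metformin"),
    timestamp = c("2023-01-01T08:00:00", "2023-03-01T09:00:00"))
  p <- temporal_precedence(ev)
  expect_equal(nrow(p$precedes), 1L)
  expect_equal(p$precedes$before, 1L)  # antihypertensive first
  expect_equal(p$sequence$rank, c(1L, 2L))
  expect_false(any(p$sequence$tie))

  tie <- temporal_precedence(data.frame(
    field_name = c("a", "b"), value = c("1", "2"),
    timestamp = rep("2023-01-01T08:00:00", 2)))
  expect_equal(nrow(tie$precedes), 0L)
  expect_equal(nrow(tie$ties), 1L)
  expect_true(all(tie$sequence$tie))
  expect_equal(tie$sequence$rank, c(1L, 1L))

  single <- temporal_precedence(data.frame(
    field_name = "a", value = "1", timestamp = "2023-01-01"))
  expect_equal(nrow(single$precedes), 0L)

  expect_error(temporal_precedence(data.frame(
    field_name = "a", value = "1", timestamp = "not-a-time")),
    class = "kg_timestamp_error")
})

test_that("attribution follows direct-kg, rule, and adjudicator tiers", {
  s <- store_with(list(name = "Elevated Serum Creatinine", type = "lab"),
                  list(name = "Acute Kidney Injury", type = "disease"),
                  list(name = "Pneumonia", type = "disease"))
  store <- merge_edge(s$store, edge_candidate(
    s$ids[["Elevated Serum Creatinine"]], "INDICATES",
    s$ids[["Acute Kidney Injury"]], 0.86,
    src("regulatory_guideline", "2019-01-01")))$store
  comorbs <- s$ids[c("Acute Kidney Injury", "Pneumonia")]

  # unique strong association: direct knowledge retrieval
  att <- attribute_clinical_item(s$ids[["Elevated Serum Creatinine"]],
                                 comorbs, store)
  expect_equal(att$method, "direct_kg")
  expect_equal(att$attributed_to, s$ids[["Acute Kidney Injury"]])
  expect_equal(att$confidence, 0.86)

  # single active comorbidity: rule
  att2 <- attribute_clinical_item(s$ids[["Elevated Serum Creatinine"]],
                                  s$ids["Pneumonia"], store)
  expect_equal(att2$method, "rule")
  expect_equal(att2$attributed_to, unname(s$ids[["Pneumonia"]]))

  # below the direct-link threshold the edge does not count as strong
  weak <- merge_edge(s$store, edge_candidate(
    s$ids[["Elevated Serum Creatinine"]], "INDICATES",
    s$ids[["Acute Kidney Injury"]], 0.5, src()))$store
  att3 <- attribute_clinical_item(s$ids[["Elevated Serum Creatinine"]],
                                  comorbs, weak)
  expect_equal(att3$method, "unattributed")
  expect_null(att3$attributed_to)

  # scripted adjudicator echoes its scripted choice and confidence
  key <- adjudication_key(adjudication_request(
    "attribution", "Elevated Serum Creatinine",
    options = sort(c("Acute Kidney Injury", "Pneumonia"))))
  adj <- adjudicator_scripted(stats::setNames(
    list(list(choice = "Pneumonia", confidence = 0.7,
              rationale = "scripted")), key))
  att4 <- attribute_clinical_item(s$ids[["Elevated Serum Creatinine"]],
                                  comorbs, weak, adjudicator = adj)
  expect_equal(att4$method, "adjudicator")
  expect_equal(att4$attributed_to, unname(s$ids[["Pneumonia"]]))
  expect_equal(att4$confidence, 0.7)

  # the answer always lies inside the active comorbidity list
  rogue <- function(req) list(choice = "Somewhere Else", confidence = 1)
  att5 <- attribute_clinical_item(s$ids[["Elevated Serum Creatinine"]],
                                  comorbs, weak, adjudicator = rogue)
  expect_equal(att5$method, "unattributed")
})
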