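# Synthetic-data generator: ontology fixtures, an initialization corpus and
# an update stream (documents + EMR records) with a complete ground-truth
# manifest. Every document sentence is produced by the same pattern grammar
# the reference relation backend parses, so reference extraction recovers
# exactly the intended triples. The generator mirrors the updater's change
# accounting while it emits items, so the manifest predicts the pipeline's
# ChangeSet exactly.

#' Configuration of the synthetic-data generator
#'
#' Defaults define the study conditions of the desk-scale corpus: 50
#' initialization documents, 500 update documents and 200 EMR encounters,
#' with 85% of final-graph nodes established at initialization and at
#' least 80% of update operations enriching existing elements.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_init_docs,n_update_docs,n_emr_records Corpus sizes.
#' @param target_init_node_fraction Fraction of final nodes created at
#'   initialization (sizing the novel-concept injection), in `(0, 1]`.
#' @param target_enrichment_update_fraction Minimum fraction of update
#'   operations that must be edge insertions or attribute modifications.
#' @param conflict_injection_rate Fraction of update documents that carry
#'   an injected contradiction.
#' @param ambiguity_injection_rate Fraction of EMR encounters with an
#'   ambiguous lab attribution answered by the scripted adjudicator.
#' @param n_drugs,n_diseases,n_symptoms,n_side_effects,n_labs,n_outcomes,n_trials
#'   Generated concept counts (the mandatory terminology rows are always
#'   present on top of these).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_init_docs = 50L, n_update_docs = 500L,
                         n_emr_records = 200L,
                         target_init_node_fraction = 0.85,
                         target_enrichment_update_fraction = 0.80,
                         conflict_injection_rate = 0.02,
                         ambiguity_injection_rate = 0.02,
                         n_drugs = 28L, n_diseases = 16L, n_symptoms = 8L,
                         n_side_effects = 10L, n_labs = 6L,
                         n_outcomes = 6L, n_trials = 15L) {
  fr <- c(target_init_node_fraction, target_enrichment_update_fraction,
          conflict_injection_rate, ambiguity_injection_rate)
  if (any(fr < 0) || any(fr > 1)) {
    stop("fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (target_init_node_fraction <= 0) {
    stop("target_init_node_fraction must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

# --- name pools (fixed fake-but-plausible lexicon + literal examples) ------

drug_stems <- c("Abexo", "Veltra", "Cormi", "Dulza", "Ephra", "Fenvo",
                "Galto", "Hyrra", "Ivoca", "Julma", "Kevra", "Lomza",
                "Mirto", "Nexva", "Orlid", "Pavno", "Quilta", "Rexna",
                "Solva", "Trivo", "Ulzom", "Vepra", "Wolxa", "Xenda",
                "Yorvi", "Zelta", "Brivo", "Cestra", "Dremo", "Elvan",
                "Frato", "Gelvi")
drug_suffixes <- c("nib", "mab", "pril", "statin")

disease_stems <- c("Aldermann", "Bextrel", "Corvan", "Delmar", "Ellory",
                   "Fenwick", "Garmon", "Hastel", "Imbren", "Jorvik",
                   "Kestner", "Lomond", "Merrow", "Norvell", "Ostrand",
                   "Pellard", "Quimby", "Raston", "Selwyn", "Tarrow")
disease_suffixes <- c("Syndrome", "Disease")

symptom_pool <- c("Chronic Fatigue", "Night Sweats", "Persistent Cough",
                  "Joint Stiffness", "Dizziness", "Blurred Vision",
                  "Chest Tightness", "Morning Headache", "Leg Swelling",
                  "Dry Eyes")
side_effect_pool <- c("Nausea", "Skin Rash", "Dry Mouth", "Insomnia",
                      "Peripheral Edema", "Hair Loss", "Muscle Cramps",
                      "Mild Fever", "Loss of Appetite", "Tremor",
                      "Metallic Taste", "Night Cramps")
lab_pool <- c("Fasting Glucose", "Hemoglobin A1c", "Serum Potassium",
              "Alanine Aminotransferase", "Total Bilirubin",
              "Platelet Count", "Serum Albumin", "Uric Acid")
lab_loinc <- c("1558-6", "4548-4", "2823-3", "1742-6", "1975-2", "777-3",
               "1751-7", "3084-1")
outcome_pool <- c("Complete Remission", "Partial Response",
                  "Disease Progression", "Improved Survival",
                  "Symptom Relief", "Stable Disease", "Reduced Mortality",
                  "Shorter Hospital Stay")

#' Generate the terminology fixture files
#'
#' Writes `concepts.tsv`, `synonyms.tsv` and `crosswalk.tsv` to `dir`.
#' The fixture always contains the worked terminology rows: the ICD-10-CM
#' E11.9 to SNOMED CT 44054006 crosswalk row (ICD10CM_SNOMEDCT_REL) and
#' the RxNorm 860975 extended-release metformin concept with its
#' `"Metformin 500 mg extended-release"` synonym, plus LOINC-to-SNOMED lab
#' rows. Generated concepts are deterministic functions of the counts in
#' `config`; with all counts zero only the mandatory rows are present.
#' Same config, same bytes.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return The `kg_ontology`, invisibly.
#' @export
generate_ontology <- function(config = synth_config(), dir) {
  con <- function(ns, code, term, type) {
    data.frame(namespace = ns, code = code, preferred_term = term,
               semantic_type = type, stringsAsFactors = FALSE)
  }
  concepts <- rbind(
    con("SNOMEDCT", "44054006", "Type 2 Diabetes Mellitus", "disease"),
    con("RXNORM", "860975",
        "metformin hydrochloride 500 mg 24HR extended-release oral tablet",
        "drug"),
    con("RXNORM", "6809", "Metformin", "drug"),
    con("RXNORM", "1547545", "Pembrolizumab", "drug"),
    con("SNOMEDCT", "363358000", "Lung Cancer", "disease"),
    con("SNOMEDCT", "14669001", "Acute Kidney Injury", "disease"),
    con("SNOMEDCT", "233604007", "Pneumonia", "disease"),
    con("SNOMEDCT", "38341003", "Hypertension", "disease"),
    con("SNOMEDCT", "166717003", "Elevated Serum Creatinine", "lab"),
    con("SNOMEDCT", "414478003", "Elevated White Blood Cell Count", "lab")
  )
  synonyms <- data.frame(
    namespace = c("RXNORM", "SNOMEDCT"),
    code = c("860975", "44054006"),
    synonym = c("Metformin 500 mg extended-release", "Type II Diabetes"),
    stringsAsFactors = FALSE
  )
  cw <- function(sns, scode, tns, tcode, tbl) {
    data.frame(source_ns = sns, source_code = scode, target_ns = tns,
               target_code = tcode, table_name = tbl,
               stringsAsFactors = FALSE)
  }
  crosswalk <- rbind(
    cw("ICD10CM", "E11.9", "SNOMEDCT", "44054006", "ICD10CM_SNOMEDCT_REL"),
    cw("ICD10CM", "C34.90", "SNOMEDCT", "363358000",
       "ICD10CM_SNOMEDCT_REL"),
    cw("ICD10CM", "N17.9", "SNOMEDCT", "14669001", "ICD10CM_SNOMEDCT_REL"),
    cw("ICD10CM", "J18.9", "SNOMEDCT", "233604007",
       "ICD10CM_SNOMEDCT_REL"),
    cw("ICD10CM", "I10", "SNOMEDCT", "38341003", "ICD10CM_SNOMEDCT_REL"),
    cw("LOINC", "2160-0", "SNOMEDCT", "166717003", "LNC_SNOMEDCT_MAP"),
    cw("LOINC", "6690-2", "SNOMEDCT", "414478003", "LNC_SNOMEDCT_MAP")
  )

  if (config$n_drugs > 0) {
    i <- seq_len(config$n_drugs)
    nm <- paste0(drug_stems[(i - 1L) %% length(drug_stems) + 1L],
                 drug_suffixes[(i - 1L) %% length(drug_suffixes) + 1L])
    concepts <- rbind(concepts,
                      con("RXNORM", sprintf("9%05d", 10000L + i), nm,
                          "drug"))
  }
  if (config$n_diseases > 0) {
    i <- seq_len(config$n_diseases)
    nm <- paste(disease_stems[(i - 1L) %% length(disease_stems) + 1L],
                disease_suffixes[(i - 1L) %% length(disease_suffixes) + 1L])
    code <- sprintf("7%06d", 100000L + i)
    concepts <- rbind(concepts, con("SNOMEDCT", code, nm, "disease"))
    crosswalk <- rbind(crosswalk,
                       cw("ICD10CM", sprintf("Q%02d.%d", 10L + i, i %% 10L),
                          "SNOMEDCT", code, "ICD10CM_SNOMEDCT_REL"))
    synonyms <- rbind(synonyms, data.frame(
      namespace = "SNOMEDCT", code = code,
      synonym = paste0(nm, " of Type ", (i %% 3L) + 1L),
      stringsAsFactors = FALSE))
  }
  add_pool <- function(concepts, n, pool, type, prefix) {
    if (n <= 0) return(concepts)
    i <- seq_len(min(n, length(pool)))
    rbind(concepts,
          con("SNOMEDCT", sprintf("%s%06d", prefix, 100000L + i),
              pool[i], type))
  }
  concepts <- add_pool(concepts, config$n_symptoms, symptom_pool,
                       "symptom", "1")
  concepts <- add_pool(concepts, config$n_side_effects, side_effect_pool,
                       "side_effect", "2")
  concepts <- add_pool(concepts, config$n_outcomes, outcome_pool,
                       "outcome", "3")
  if (config$n_labs > 0) {
    i <- seq_len(min(config$n_labs, length(lab_pool)))
    code <- sprintf("8%06d", 100000L + i)
    concepts <- rbind(concepts, con("SNOMEDCT", code, lab_pool[i], "lab"))
    crosswalk <- rbind(crosswalk,
                       cw("LOINC", lab_loinc[i], "SNOMEDCT", code,
                          "LNC_SNOMEDCT_MAP"))
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(concepts, "concepts.tsv")
  wr(synonyms, "synonyms.tsv")
  wr(crosswalk, "crosswalk.tsv")
  invisible(ontology(concepts, synonyms, crosswalk))
}

# --- the ground-truth mirror ------------------------------------------------
# Replicates the updater's counting rules while the corpus is generated, so
# the manifest predicts the pipeline's ChangeSet and final graph exactly.

new_mirror <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()    # key -> phase
  env$edges <- list()    # spo key -> list(active, conf, src_tier, src_date)
  env$eprops <- list()   # "spo|prop" -> cell
  env$nprops <- list()   # "node|prop" -> cell
  env
}

mirror_node <- function(mir, key, phase) {
  if (is.null(mir$nodes[[key]])) {
    mir$nodes[[key]] <- phase
    return(1L)
  }
  0L
}

mirror_cell <- function(cells_name, mir, key, value, tier, date) {
  cur <- mir[[cells_name]][[key]]
  res <- update_property_cell(cur, value, tier, date)
  if (res$changed) mir[[cells_name]][[key]] <- res$cell
  as.integer(res$changed)
}

mirror_edge <- function(mir, s, p, o, tier, date, conf, props = list()) {
  counts <- c(edges = 0L, attrs = 0L, flagged = 0L)
  resolution <- NA_character_
  partner <- if (p == "TREATS") "CONTRAINDICATED_IN" else
    if (p == "CONTRAINDICATED_IN") "TREATS" else NULL
  pk <- if (is.null(partner)) NULL else spo_key(s, partner, o)
  if (!is.null(pk) && !is.null(mir$edges[[pk]]) && mir$edges[[pk]]$active) {
    inc <- mir$edges[[pk]]
    ch_rank <- tier_rank(tier); in_rank <- tier_rank(inc$src_tier)
    winner <- if (ch_rank != in_rank) {
      if (ch_rank > in_rank) "challenger" else "incumbent"
    } else if (as.Date(date) > as.Date(inc$src_date)) "challenger"
    else if (as.Date(date) < as.Date(inc$src_date)) "incumbent" else "tie"
    if (winner == "tie") {
      counts[["flagged"]] <- 1L
      resolution <- "flagged"
    } else if (winner == "incumbent") {
      resolution <- "keep_incumbent"
    } else {
      inc$active <- FALSE
      mir$edges[[pk]] <- inc
      key <- spo_key(s, p, o)
      mir$edges[[key]] <- list(active = TRUE, conf = conf,
                               src_tier = tier, src_date = date)
      counts[["edges"]] <- 1L
      counts[["attrs"]] <- 1L  # the loser's valid_to closure
      resolution <- "supersede"
    }
    return(list(counts = counts, resolution = resolution))
  }
  key <- spo_key(s, p, o)
  cur <- mir$edges[[key]]
  if (!is.null(cur) && cur$active) {
    if (conf > cur$conf) {
      cur$conf <- conf
      mir$edges[[key]] <- cur
    }
    for (nm in names(props)) {
      counts[["attrs"]] <- counts[["attrs"]] +
        mirror_cell("eprops", mir, paste0(key, "|", nm), props[[nm]],
                    tier, date)
    }
    return(list(counts = counts, resolution = "matched"))
  }
  mir$edges[[key]] <- list(active = TRUE, conf = conf, src_tier = tier,
                           src_date = date)
  for (nm in names(props)) {
    mir$eprops[[paste0(key, "|", nm)]] <-
      property_cell(props[[nm]], tier, date)
  }
  counts[["edges"]] <- 1L
  list(counts = counts, resolution = "created")
}

mirror_strong_links <- function(mir, item_key, comorb_keys, threshold) {
  Filter(function(cm) {
    for (pred in c("INDICATES", "TREATS")) {
      e <- mir$edges[[spo_key(item_key, pred, cm)]]
      if (!is.null(e) && e$active && e$conf >= threshold) return(TRUE)
    }
    FALSE
  }, comorb_keys)
}

# --- corpus generation ------------------------------------------------------

doc_header <- function(doc_id, kind, date) {
  c("---", paste0("doc_id: ", doc_id), paste0("kind: ", kind),
    paste0("date: ", date), "---")
}

sentence_of <- function(s, p, o) {
  switch(p,
    TREATS = sprintf("%s treats %s.", s, o),
    CAUSES = sprintf("%s causes %s.", s, o),
    RESULTS_IN = sprintf("%s results in %s.", s, o),
    ASSOCIATED_WITH = sprintf("%s is associated with %s.", s, o),
    CONTRAINDICATED_IN = sprintf("%s is contraindicated in %s.", s, o),
    USED_IN_TRIAL = sprintf("%s was used in %s.", s, o),
    REPORTED = sprintf("%s reported %s.", s, o),
    INDICATES = sprintf("%s is an indicator of %s.", s, o)
  )
}

#' Generate the full synthetic corpus with its ground-truth manifest
#'
#' Produces, under `dir`: `ontology/` (TSV fixtures), `init/` (the
#' initialization documents), `update/` (the update documents plus
#' `emr.csv` and `adjudicator.json`, the scripted answers to the injected
#' ambiguities), and `manifest.json`. All randomness is fixed by
#' `config$seed`; the same config yields byte-identical output. Injected
#' contradictions pair a high-authority recent source against a
#' low-authority old one (plus deliberate keep-incumbent and flagged-tie
#' cases), each annotated with the policy-predicted resolution.
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return The manifest (class `kg_manifest`), invisibly.
#' @export
generate_corpus <- function(config = synth_config(), dir) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  ont <- generate_ontology(config, file.path(dir, "ontology"))
  co <- ont$concepts
  terms_of <- function(type) co$preferred_term[co$semantic_type == type]
  key_of_term <- stats::setNames(
    paste0("c/", co$namespace, ":", co$code), co$preferred_term)
  # the extended-release metformin concept is terminology-only
  er_met <- "metformin hydrochloride 500 mg 24HR extended-release oral tablet"
  drugs <- setdiff(terms_of("drug"), er_met)
  diseases <- terms_of("disease")
  symptoms <- terms_of("symptom")
  side_effects <- terms_of("side_effect")
  labs <- terms_of("lab")
  outcomes <- terms_of("outcome")
  if (length(drugs) < 6L || length(diseases) < 4L || !length(symptoms) ||
      !length(side_effects) || !length(outcomes) || length(labs) < 2L) {
    stop("corpus generation needs the default concept pools; ",
         "increase the n_* counts", call. = FALSE)
  }

  trials <- sprintf("Trial NVK-%04d", 1000L + seq_len(config$n_trials))
  trial_key <- function(t) paste0("n/", canonicalize(t), "|trial")
  novel_key <- function(t, type) paste0("n/", canonicalize(t), "|", type)

  n_init_entities <- length(drugs) + length(diseases) + length(symptoms) +
    length(side_effects) + length(labs) + length(outcomes) +
    length(trials)
  f <- config$target_init_node_fraction
  n_novel <- if (f >= 1) 0L else
    as.integer(round(n_init_entities * (1 - f) / f))
  if (config$target_enrichment_update_fraction >= 1 && n_novel > 0L) {
    stop("infeasible fractions: enrichment fraction 1 is impossible when ",
         "novel nodes must be injected", call. = FALSE)
  }
  n_novel_drugs <- ceiling(n_novel * 0.6)
  n_novel_trials <- n_novel - n_novel_drugs
  novel_drugs <- if (n_novel_drugs) {
    sprintf("Compound ZQ-%03d", 100L + seq_len(n_novel_drugs))
  } else character()
  novel_trials <- if (n_novel_trials) {
    sprintf("Trial NVX-%04d", 9000L + seq_len(n_novel_trials))
  } else character()

  # ---- intended initialization edges --------------------------------------
  n_conf <- as.integer(round(config$conflict_injection_rate *
                               config$n_update_docs))
  edge <- function(s, p, o) list(s = s, p = p, o = o)
  init_edges <- list()
  treats_of <- list()  # drug -> diseases (intended at init)
  add_treats <- function(d, dis) {
    init_edges[[length(init_edges) + 1L]] <<- edge(d, "TREATS", dis)
    treats_of[[d]] <<- c(treats_of[[d]], dis)
  }
  add_treats("Metformin", "Type 2 Diabetes Mellitus")
  add_treats("Pembrolizumab", "Lung Cancer")
  plain_drugs <- setdiff(drugs, c("Metformin", "Pembrolizumab"))
  for (i in seq_along(plain_drugs)) {
    add_treats(plain_drugs[i], diseases[(i - 1L) %% length(diseases) + 1L])
  }
  # second indications for some drugs
  second <- plain_drugs[seq_len(min(10L, length(plain_drugs)))]
  for (i in seq_along(second)) {
    dis <- diseases[(i + 6L) %% length(diseases) + 1L]
    if (!dis %in% treats_of[[second[i]]]) add_treats(second[i], dis)
  }
  # reserved conflict pairs: last drugs' first indications, kept out of the
  # EMR medication pool and update repeats
  if (n_conf > length(plain_drugs) - 6L) {
    stop("conflict_injection_rate too high for the drug pool", call. = FALSE)
  }
  reserved_drugs <- rev(plain_drugs)[seq_len(n_conf)]
  reserved_pairs <- lapply(reserved_drugs, function(d)
    c(d, treats_of[[d]][1L]))
  for (i in seq_along(drugs)) {
    init_edges[[length(init_edges) + 1L]] <- edge(
      drugs[i], "CAUSES",
      side_effects[(i - 1L) %% length(side_effects) + 1L])
  }
  for (i in seq_along(diseases)) {
    init_edges[[length(init_edges) + 1L]] <- edge(
      diseases[i], "ASSOCIATED_WITH",
      symptoms[(i - 1L) %% length(symptoms) + 1L])
  }
  indicated_by <- list()  # lab -> disease
  fix_ind <- c("Elevated Serum Creatinine" = "Acute Kidney Injury",
               "Elevated White Blood Cell Count" = "Pneumonia")
  for (i in seq_along(labs)) {
    dis <- if (labs[i] %in% names(fix_ind)) fix_ind[[labs[i]]] else
      diseases[(i + 2L) %% length(diseases) + 1L]
    indicated_by[[labs[i]]] <- dis
    init_edges[[length(init_edges) + 1L]] <- edge(labs[i], "INDICATES", dis)
  }
  usable_drugs <- setdiff(drugs, reserved_drugs)
  for (i in seq_along(trials)) {
    init_edges[[length(init_edges) + 1L]] <- edge(
      usable_drugs[(i - 1L) %% length(usable_drugs) + 1L],
      "USED_IN_TRIAL", trials[i])
    init_edges[[length(init_edges) + 1L]] <- edge(
      trials[i], "REPORTED",
      side_effects[(i + 3L) %% length(side_effects) + 1L])
    init_edges[[length(init_edges) + 1L]] <- edge(
      trials[i], "RESULTS_IN", outcomes[(i - 1L) %% length(outcomes) + 1L])
  }

  # ---- mirror + item emission ---------------------------------------------
  mir <- new_mirror()
  key_of <- function(term, type) {
    k <- key_of_term[term]
    if (!is.na(k)) unname(k) else
      if (type == "trial") trial_key(term) else novel_key(term, type)
  }
  role_of <- local({
    rules <- kg_semantic_rules()
    function(p, side) {
      row <- rules[rules$predicate == p, ]
      strsplit(row[[paste0(side, "_types")]], ",")[[1L]][1L]
    }
  })

  per_item <- list()
  triples_rows <- list()
  attr_rows <- list()
  conflict_rows <- list()
  ambiguity_rows <- list()
  entity_rows <- list()
  script <- list()
  seen_entity <- character()

  note_entity <- function(term, type, phase) {
    key <- key_of(term, type)
    if (!key %in% seen_entity) {
      seen_entity <<- c(seen_entity, key)
      entity_rows[[length(entity_rows) + 1L]] <<- data.frame(
        term = term, key = key, semantic_type = type, phase = phase,
        stringsAsFactors = FALSE)
    }
    key
  }

  # process one document's sentences through the mirror
  mirror_document <- function(doc_id, kind, date, edges, attrs = list(),
                              phase) {
    tier <- kind_to_tier(kind)
    conf <- score_confidence(tier, "rule")
    nodes <- 0L; eadd <- 0L; aadd <- 0L; fl <- 0L
    for (e in edges) {
      st <- role_of(e$p, "subject"); ot <- role_of(e$p, "object")
      sk <- note_entity(e$s, st, phase)
      ok <- note_entity(e$o, ot, phase)
      nodes <- nodes + mirror_node(mir, sk, phase) +
        mirror_node(mir, ok, phase)
      r <- mirror_edge(mir, sk, e$p, ok, tier, date, conf)
      eadd <- eadd + r$counts[["edges"]]
      aadd <- aadd + r$counts[["attrs"]]
      fl <- fl + r$counts[["flagged"]]
      triples_rows[[length(triples_rows) + 1L]] <<- data.frame(
        doc_id = doc_id, subject = e$s, predicate = e$p, object = e$o,
        stringsAsFactors = FALSE)
      if (e$p == "CONTRAINDICATED_IN") {
        conflict_rows[[length(conflict_rows) + 1L]] <<- data.frame(
          doc_id = doc_id, subject = e$s, object = e$o,
          challenger_predicate = e$p,
          expected_resolution = r$resolution, stringsAsFactors = FALSE)
      }
    }
    for (a in attrs) {
      tk <- key_of(a$entity, "trial")
      aadd <- aadd + mirror_cell("nprops", mir, paste0(tk, "|", a$key),
                                 a$value, tier, date)
      attr_rows[[length(attr_rows) + 1L]] <<- data.frame(
        doc_id = doc_id, entity = a$entity, key = a$key, value = a$value,
        stringsAsFactors = FALSE)
    }
    per_item[[length(per_item) + 1L]] <<- data.frame(
      item_id = doc_id, phase = phase, kind = "document", nodes = nodes,
      edges = eadd, attrs = aadd, flagged = fl, stringsAsFactors = FALSE)
  }

  write_doc <- function(path, doc_id, kind, date, sentences) {
    writeLines(c(doc_header(doc_id, kind, date), paste(sentences,
                                                       collapse = " ")),
               path, useBytes = TRUE)
  }

  # ---- initialization documents -------------------------------------------
  init_dir <- file.path(dir, "init")
  dir.create(init_dir, recursive = TRUE, showWarnings = FALSE)
  reserved_idx <- vapply(reserved_pairs, function(rp) {
    which(vapply(init_edges, function(e)
      e$p == "TREATS" && e$s == rp[1L] && e$o == rp[2L], logical(1L)))[1L]
  }, integer(1L))
  # scenario metadata for the reserved incumbents:
  #  1..ceil(0.6 n): textbook 2010-2012 (will be superseded by a 2023
  #  guideline); next 2: guideline 2016 (challenger note loses); rest:
  #  textbook on a fixed date (tie -> flagged)
  n_sup <- if (n_conf > 4L) n_conf - 4L else max(0L, n_conf - 2L)
  n_keep <- min(2L, max(0L, n_conf - n_sup))
  scenario <- rep("supersede", n_conf)
  if (n_conf >= n_sup + 1L) {
    scenario[seq_len(n_keep) + n_sup] <- "keep_incumbent"
  }
  if (n_conf > n_sup + n_keep) {
    scenario[(n_sup + n_keep + 1L):n_conf] <- "flagged"
  }
  doc_no <- 0L
  next_doc_id <- function(prefix) {
    doc_no <<- doc_no + 1L
    sprintf("%s-%04d", prefix, doc_no)
  }
  incumbent_meta <- list()
  for (i in seq_along(reserved_idx)) {
    meta <- switch(scenario[i],
      supersede = list(kind = "textbook",
                       date = sprintf("201%d-03-01", i %% 3L)),
      keep_incumbent = list(kind = "guideline", date = "2016-05-01"),
      flagged = list(kind = "textbook", date = "2012-09-15"))
    incumbent_meta[[i]] <- meta
    id <- next_doc_id("init")
    e <- init_edges[[reserved_idx[i]]]
    write_doc(file.path(init_dir, paste0(id, ".txt")), id, meta$kind,
              meta$date, sentence_of(e$s, e$p, e$o))
    mirror_document(id, meta$kind, meta$date, list(e), phase = "init")
  }
  rest <- init_edges[setdiff(seq_along(init_edges), reserved_idx)]
  n_rest_docs <- max(1L, config$n_init_docs - length(reserved_idx))
  chunks <- split(rest, rep(seq_len(n_rest_docs),
                            length.out = length(rest)))
  init_kinds <- c("guideline", "textbook")
  for (ci in seq_along(chunks)) {
    id <- next_doc_id("init")
    kind <- init_kinds[(ci - 1L) %% 2L + 1L]
    date <- sprintf("201%d-0%d-10", 4L + (ci %% 5L), (ci %% 9L) + 1L)
    sents <- vapply(chunks[[ci]], function(e) sentence_of(e$s, e$p, e$o),
                    "")
    write_doc(file.path(init_dir, paste0(id, ".txt")), id, kind, date,
              sents)
    mirror_document(id, kind, date, chunks[[ci]], phase = "init")
  }

  # ---- update documents ---------------------------------------------------
  upd_dir <- file.path(dir, "update")
  dir.create(upd_dir, recursive = TRUE, showWarnings = FALSE)
  doc_no <- 0L
  upd_docs <- list()  # list of list(kind, date, edges, attrs)
  add_upd <- function(kind, date, edges = list(), attrs = list()) {
    upd_docs[[length(upd_docs) + 1L]] <<-
      list(kind = kind, date = date, edges = edges, attrs = attrs)
  }
  # (a) novel concepts
  for (i in seq_along(novel_drugs)) {
    dis <- diseases[(i + 4L) %% length(diseases) + 1L]
    add_upd("trial_report", sprintf("2021-%02d-05", (i %% 12L) + 1L),
            edges = list(edge(novel_drugs[i], "TREATS", dis)))
  }
  for (i in seq_along(novel_trials)) {
    d <- usable_drugs[(i + 2L) %% length(usable_drugs) + 1L]
    se <- side_effects[(i + 1L) %% length(side_effects) + 1L]
    add_upd("trial_report", sprintf("2021-%02d-18", (i %% 12L) + 1L),
            edges = list(edge(d, "USED_IN_TRIAL", novel_trials[i]),
                         edge(novel_trials[i], "REPORTED", se)))
  }
  # (b) enrichment: new edges among existing entities
  asserted <- function(s, p, o, st, ot) {
    k <- spo_key(key_of(s, st), p, key_of(o, ot))
    !is.null(mir$edges[[k]])
  }
  enrich <- list()
  grid_add <- function(n, maker) {
    tries <- 0L
    while (n > 0L && tries < 2000L) {
      tries <- tries + 1L
      e <- maker()
      if (is.null(e)) next
      dup <- any(vapply(enrich, function(x)
        identical(x, e), logical(1L)))
      if (dup ||
          asserted(e$s, e$p, e$o, role_of(e$p, "subject"),
                   role_of(e$p, "object"))) next
      enrich[[length(enrich) + 1L]] <<- e
      n <- n - 1L
    }
  }
  grid_add(30L, function() {
    d <- sample(usable_drugs, 1L)
    edge(d, "TREATS", sample(diseases, 1L))
  })
  grid_add(20L, function()
    edge(sample(diseases, 1L), "ASSOCIATED_WITH", sample(symptoms, 1L)))
  grid_add(15L, function()
    edge(sample(trials, 1L), "REPORTED", sample(side_effects, 1L)))
  grid_add(15L, function()
    edge(sample(usable_drugs, 1L), "USED_IN_TRIAL", sample(trials, 1L)))
  grid_add(20L, function()
    edge(sample(usable_drugs, 1L), "CAUSES", sample(side_effects, 1L)))
  upd_kinds <- c("trial_report", "note")
  for (i in seq_along(enrich)) {
    add_upd(upd_kinds[(i - 1L) %% 2L + 1L],
            sprintf("2021-%02d-%02d", (i %% 12L) + 1L, (i %% 27L) + 1L),
            edges = enrich[i])
  }
  # (c) trial attributes, then authority-backed revisions
  for (i in seq_along(trials)) {
    add_upd("trial_report", sprintf("2022-%02d-09", (i %% 12L) + 1L),
            attrs = list(
              list(entity = trials[i], key = "phase",
                   value = as.character(2L + (i %% 2L))),
              list(entity = trials[i], key = "status", value = "active"),
              list(entity = trials[i], key = "start_date",
                   value = sprintf("2020-%02d-01", (i %% 12L) + 1L))))
  }
  n_rev <- min(5L, length(trials))
  for (i in seq_len(n_rev)) {
    add_upd("guideline", sprintf("2023-%02d-20", i),
            attrs = list(list(entity = trials[i], key = "phase",
                              value = "4")))
  }
  # (d) repeats: pure provenance enrichment, no counted operations
  repeatable <- Filter(function(e) {
    !(e$p == "TREATS" && any(vapply(reserved_pairs, function(rp)
      identical(c(e$s, e$o), rp), logical(1L))))
  }, init_edges)
  n_fixed <- length(upd_docs) + n_conf
  n_repeats <- max(0L, config$n_update_docs - n_fixed)
  for (i in seq_len(n_repeats)) {
    e <- repeatable[[sample.int(length(repeatable), 1L)]]
    add_upd("note", sprintf("2022-%02d-%02d", (i %% 12L) + 1L,
                            (i %% 27L) + 1L), edges = list(e))
  }
  # (e) injected conflicts, challenger kind/date chosen per scenario
  for (i in seq_along(reserved_pairs)) {
    rp <- reserved_pairs[[i]]
    meta <- switch(scenario[i],
      supersede = list(kind = "guideline", date = "2023-06-15"),
      keep_incumbent = list(kind = "note", date = "2022-11-02"),
      flagged = list(kind = "textbook", date = incumbent_meta[[i]]$date))
    add_upd(meta$kind, meta$date,
            edges = list(edge(rp[1L], "CONTRAINDICATED_IN", rp[2L])))
  }
  # emit the update documents in order
  for (d in upd_docs) {
    id <- next_doc_id("upd")
    sents <- c(
      vapply(d$edges, function(e) sentence_of(e$s, e$p, e$o), ""),
      vapply(d$attrs, function(a) sprintf("%s has %s %s.", a$entity,
                                          gsub("_", " ", a$key), a$value),
             "")
    )
    write_doc(file.path(upd_dir, paste0(id, ".txt")), id, d$kind, d$date,
              sents)
    mirror_document(id, d$kind, d$date, d$edges, d$attrs,
                    phase = "update")
  }

  # ---- EMR encounters -----------------------------------------------------
  threshold <- 0.80
  dis_key <- function(d) key_of(d, "disease")
  drug_key <- function(d) key_of(d, "drug")
  lab_key <- function(l) key_of(l, "lab")
  icd_of <- local({
    cwk <- ont$crosswalk
    function(dis) {
      code <- sub("^c/SNOMEDCT:", "", dis_key(dis))
      row <- which(cwk$target_code == code & cwk$source_ns == "ICD10CM")
      if (length(row)) cwk$source_code[row[1L]] else NA_character_
    }
  })
  active_treats_among <- function(drug, active_dis) {
    Filter(function(dis) {
      e <- mir$edges[[spo_key(drug_key(drug), "TREATS", dis_key(dis))]]
      !is.null(e) && e$active && e$conf >= threshold
    }, active_dis)
  }
  pick_med <- function(active_dis) {
    cands <- Filter(function(d)
      length(active_treats_among(d, active_dis)) == 1L, usable_drugs)
    if (!length(cands)) NULL else
      cands[[sample.int(length(cands), 1L)]]
  }
  pick_direct_lab <- function(active_dis) {
    cands <- Filter(function(l) {
      hits <- mirror_strong_links(mir, lab_key(l),
                                  vapply(active_dis, dis_key, ""),
                                  threshold)
      length(hits) == 1L
    }, labs)
    if (!length(cands)) NULL else cands[[sample.int(length(cands), 1L)]]
  }
  pick_ambiguous_lab <- function(active_dis, used) {
    cands <- Filter(function(l) {
      hits <- mirror_strong_links(mir, lab_key(l),
                                  vapply(active_dis, dis_key, ""),
                                  threshold)
      length(hits) == 0L && !l %in% used
    }, labs)
    if (!length(cands)) NULL else cands[[sample.int(length(cands), 1L)]]
  }

  eligible_dis <- Filter(function(dis)
    length(Filter(function(d) dis %in% (treats_of[[d]] %||% character()),
                  usable_drugs)) > 0L, diseases)
  emr_rows <- list()
  used_amb_labs <- character()
  n_amb <- as.integer(round(config$ambiguity_injection_rate *
                              config$n_emr_records))
  amb_slots <- if (n_amb > 0L && config$n_emr_records > 1L) {
    1L + seq_len(min(n_amb, config$n_emr_records - 1L))
  } else integer()

  emit_encounter <- function(i) {
    enc <- sprintf("enc-%04d", i)
    date <- format(as.Date("2024-01-01") + (i - 1L), "%Y-%m-%d")
    if (i == 1L) {
      actives <- c("Acute Kidney Injury", "Pneumonia")
    } else {
      n_com <- 1L + (i %% 3L)
      actives <- unique(c(sample(eligible_dis,
                                 min(n_com, length(eligible_dis)))))
    }
    primary <- actives[[1L]]
    ts <- function(h) sprintf("%sT%02d:00:00", date, h)
    rows <- list()
    row <- function(field, value, h) {
      rows[[length(rows) + 1L]] <<- data.frame(
        encounter_id = enc, patient_id = sprintf("pt-%04d", 1000L + i),
        field_name = field, value = value, timestamp = ts(h),
        stringsAsFactors = FALSE)
    }
    for (a in actives) row("comorbidity", a, 8L)
    icd <- icd_of(primary)
    if (!is.na(icd)) row("diagnosis_code", icd, 8L)
    meds <- character()
    n_med <- if (length(actives) >= 2L) 2L else 1L
    for (m in seq_len(n_med)) {
      d <- pick_med(actives)
      if (is.null(d) || d %in% meds) next
      meds <- c(meds, d)
      row("medication", d, 8L + length(meds))
    }
    lab <- NULL
    ambiguous <- i %in% amb_slots
    if (i == 1L) {
      lab <- "Elevated Serum Creatinine"
    } else if (ambiguous) {
      lab <- pick_ambiguous_lab(actives, used_amb_labs)
      if (!is.null(lab)) used_amb_labs <<- c(used_amb_labs, lab)
      else ambiguous <- FALSE
    } else if (i %% 3L != 0L) {
      lab <- pick_direct_lab(actives)
    }
    if (!is.null(lab)) row("lab_result", lab, 11L)

    # mirror the pipeline's processing of this encounter
    nodes <- 0L; eadd <- 0L; aadd <- 0L; fl <- 0L
    tier <- "structured_emr"
    if (!is.na(icd)) {
      aadd <- aadd + mirror_cell("nprops", mir,
                                 paste0(dis_key(primary), "|icd10cm"),
                                 icd, tier, date)
    }
    attribute <- function(item_key, item_name) {
      if (length(actives) == 1L) {
        return(list(to = dis_key(actives[[1L]]), method = "rule"))
      }
      hits <- mirror_strong_links(mir, item_key,
                                  vapply(actives, dis_key, ""), threshold)
      if (length(hits) == 1L) {
        return(list(to = hits[[1L]], method = "direct_kg"))
      }
      # ambiguous: scripted adjudicator answer = first active by name
      answer <- sort(actives)[[1L]]
      req <- adjudication_request("attribution", item_name,
                                  options = sort(actives))
      script[[adjudication_key(req)]] <<- list(
        choice = answer, confidence = 0.7,
        rationale = "scripted contextual disambiguation")
      ambiguity_rows[[length(ambiguity_rows) + 1L]] <<- data.frame(
        encounter_id = enc, item = item_name,
        options = paste(sort(actives), collapse = ";"), answer = answer,
        stringsAsFactors = FALSE)
      list(to = dis_key(answer), method = "adjudicator")
    }
    for (m in seq_along(meds)) {
      att <- attribute(drug_key(meds[m]), meds[m])
      props <- if (length(meds) >= 2L) list(rx_order = m) else list()
      r <- mirror_edge(mir, drug_key(meds[m]), "TREATS", att$to, tier,
                       date, score_confidence(tier, att$method), props)
      eadd <- eadd + r$counts[["edges"]]
      aadd <- aadd + r$counts[["attrs"]]
      fl <- fl + r$counts[["flagged"]]
    }
    if (!is.null(lab)) {
      att <- attribute(lab_key(lab), lab)
      r <- mirror_edge(mir, lab_key(lab), "INDICATES", att$to, tier, date,
                       score_confidence(tier, att$method), list())
      eadd <- eadd + r$counts[["edges"]]
      aadd <- aadd + r$counts[["attrs"]]
    }
    per_item[[length(per_item) + 1L]] <<- data.frame(
      item_id = enc, phase = "update", kind = "emr", nodes = nodes,
      edges = eadd, attrs = aadd, flagged = fl, stringsAsFactors = FALSE)
    rows
  }

  for (i in seq_len(config$n_emr_records)) {
    emr_rows <- c(emr_rows, emit_encounter(i))
  }
  emr_df <- do.call(rbind, emr_rows)
  utils::write.csv(emr_df, file.path(upd_dir, "emr.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(script, file.path(upd_dir, "adjudicator.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # ---- manifest -----------------------------------------------------------
  per_item_df <- do.call(rbind, per_item)
  totals <- function(ph) {
    d <- per_item_df[per_item_df$phase == ph, , drop = FALSE]
    list(nodes_added = sum(d$nodes), edges_added = sum(d$edges),
         attributes_modified = sum(d$attrs),
         conflicts_flagged = sum(d$flagged))
  }
  active_keys <- sort(names(Filter(function(e) e$active, mir$edges)))
  superseded <- sort(names(Filter(function(e) !e$active, mir$edges)))
  node_phase <- vapply(names(mir$nodes), function(k) mir$nodes[[k]], "")
  manifest <- list(
    config = unclass(config),
    entities = do.call(rbind, entity_rows),
    triples = do.call(rbind, triples_rows),
    attributes = do.call(rbind, attr_rows),
    conflicts = if (length(conflict_rows)) do.call(rbind, conflict_rows)
      else NULL,
    ambiguities = if (length(ambiguity_rows))
      do.call(rbind, ambiguity_rows) else NULL,
    per_item = per_item_df,
    expected = list(init = totals("init"), update = totals("update")),
    final_graph = list(
      nodes = data.frame(key = sort(names(node_phase)),
                         phase = node_phase[sort(names(node_phase))],
                         row.names = NULL, stringsAsFactors = FALSE),
      active_edges = active_keys,
      superseded_edges = superseded
    )
  )
  class(manifest) <- "kg_manifest"
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}

#' Read a ground-truth manifest written by [generate_corpus()]
#'
#' @param path Path to `manifest.json`.
#' @return A `kg_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (nm in c("entities", "triples", "attributes", "conflicts",
               "ambiguities", "per_item")) {
    if (!is.null(m[[nm]])) m[[nm]] <- as.data.frame(m[[nm]])
  }
  class(m) <- "kg_manifest"
  m
}

#' Inject contradictions into a document stream
#'
#' Picks a fraction of the stream's `TREATS` assertions and appends, for
#' each, a 2023 guideline document asserting the contradictory
#' `CONTRAINDICATED_IN` relation. Each injection is annotated with the
#' resolution the authority-then-recency policy predicts for it. Rate 0
#' returns the stream unchanged.
#'
#' @param stream List of `kg_document` objects.
#' @param rate Fraction of documents to pair with an injected conflict, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `stream` (original plus injected documents) and
#'   `expected` (data frame of injections with `expected_resolution`).
#' @export
inject_conflicts <- function(stream, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop("rate must lie in [0, 1]", call. = FALSE)
  }
  empty <- data.frame(doc_id = character(), subject = character(),
                      object = character(),
                      expected_resolution = character(),
                      stringsAsFactors = FALSE)
  n <- round(rate * length(stream))
  if (n == 0L) return(list(stream = stream, expected = empty))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  treats <- list()
  for (doc in stream) {
    tr <- extract_triples(doc)
    tr <- tr[tr$predicate == "TREATS", , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      treats[[length(treats) + 1L]] <-
        list(doc = doc, subject = tr$subject[i], object = tr$object[i])
    }
  }
  if (!length(treats)) return(list(stream = stream, expected = empty))
  picks <- sample.int(length(treats), min(n, length(treats)))
  inj_docs <- list()
  exp_rows <- list()
  for (k in seq_along(picks)) {
    t <- treats[[picks[k]]]
    date <- "2023-06-15"
    doc_id <- sprintf("conflict-%04d", k)
    inj_docs[[k]] <- clinical_document(
      doc_id, "guideline", date,
      sentence_of(t$subject, "CONTRAINDICATED_IN", t$object))
    ch <- tier_rank("regulatory_guideline")
    inc <- tier_rank(kind_to_tier(t$doc$kind))
    resolution <- if (ch > inc || (ch == inc &&
                                   as.Date(date) > as.Date(t$doc$date))) {
      "supersede"
    } else if (ch == inc && as.Date(date) == as.Date(t$doc$date)) {
      "flagged"
    } else "keep_incumbent"
    exp_rows[[k]] <- data.frame(
      doc_id = doc_id, subject = t$subject, object = t$object,
      expected_resolution = resolution, stringsAsFactors = FALSE)
  }
  list(stream = c(stream, inj_docs), expected = do.call(rbind, exp_rows))
}
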