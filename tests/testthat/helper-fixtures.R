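# In-code fixtures and independent oracles shared across the suite.

tiny_ontology <- function() {
  concepts <- data.frame(
    namespace = c("SNOMEDCT", "RXNORM", "SNOMEDCT", "SNOMEDCT", "SNOMEDCT",
                  "SNOMEDCT", "SNOMEDCT", "SNOMEDCT", "RXNORM"),
    code = c("44054006", "6809", "14669001", "233604007", "166717003",
             "64531003", "58000006", "38341003", "860975"),
    preferred_term = c("Type 2 Diabetes Mellitus", "Metformin",
                       "Acute Kidney Injury", "Pneumonia",
                       "Elevated Serum Creatinine", "Nasal Discharge",
                       "Patient Discharge", "Hypertension",
                       "metformin hydrochloride 500 mg 24HR extended-release oral tablet"),
    semantic_type = c("disease", "drug", "disease", "disease", "lab",
                      "symptom", "procedure", "disease", "drug"),
    stringsAsFactors = FALSE
  )
  synonyms <- data.frame(
    namespace = c("SNOMEDCT", "RXNORM"),
    code = c("44054006", "860975"),
    synonym = c("Type II Diabetes", "Metformin 500 mg extended-release"),
    stringsAsFactors = FALSE
  )
  crosswalk <- data.frame(
    source_ns = c("ICD10CM", "LOINC"),
    source_code = c("E11.9", "2160-0"),
    target_ns = c("SNOMEDCT", "SNOMEDCT"),
    target_code = c("44054006", "166717003"),
    table_name = c("ICD10CM_SNOMEDCT_REL", "LNC_SNOMEDCT_MAP"),
    stringsAsFactors = FALSE
  )
  ontology(concepts, synonyms, crosswalk)
}

src <- function(tier = "textbook", date = "2020-01-01",
                id = paste0("doc-", tier, "-", date),
                modality = if (tier == "structured_emr") "structured"
                else "unstructured") {
  source_ref(id, modality, tier, date)
}

# a store with a few typed nodes; returns list(store, ids)
store_with <- function(...) {
  specs <- list(...)
  store <- kg_store()
  ids <- character()
  for (sp in specs) {
    m <- merge_node(store, entity_node(sp$type, sp$name,
                                       sp$codes %||% character(),
                                       source = src()))
    store <- m$store
    ids[sp$name] <- m$node_id
  }
  list(store = store, ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles ---------------------------------------------------------------

# brute-force node lookup ignoring all indices
scan_find <- function(store, name = NULL, code = NULL,
                      semantic_type = NULL) {
  hit <- vapply(store$nodes, function(n) {
    if (!is.null(name)) {
      !is.null(n$preferred_name) &&
        canonicalize(n$preferred_name) == canonicalize(name)
    } else if (!is.null(code)) {
      code %in% n$concept_ids
    } else {
      n$semantic_type == semantic_type
    }
  }, logical(1L))
  sort(names(store$nodes)[hit])
}

# O(n^2) brute-force conflict scan
scan_conflicts <- function(store, cand, exclusions) {
  partners <- character()
  for (pair in exclusions) {
    if (cand$predicate == pair[1]) partners <- c(partners, pair[2])
    if (cand$predicate == pair[2]) partners <- c(partners, pair[1])
  }
  hits <- Filter(function(e) {
    is.null(e$valid_to) && e$subject == cand$subject &&
      e$object == cand$object && e$predicate %in% partners
  }, store$edges)
  sort(unname(vapply(hits, `[[`, "", "edge_id")))
}

# exhaustive DFS path enumeration, written against the raw edge list
oracle_paths <- function(store, source, target, max_hops,
                         predicates = NULL, as_of = NULL) {
  eds <- Filter(function(e) {
    (is.null(predicates) || e$predicate %in% predicates) &&
      edge_active_at(e, as_of)
  }, store$edges)
  out <- list()
  recurse <- function(node, visited, hops) {
    if (node == target && hops > 0L) {
      out[[length(out) + 1L]] <<- visited
      return()
    }
    if (hops >= max_hops) return()
    for (e in eds) {
      if (e$subject == node && !e$object %in% visited) {
        recurse(e$object, c(visited, e$object), hops + 1L)
      }
    }
  }
  recurse(source, source, 0L)
  out
}

# independent clipped n-gram precision computation for the BLEU oracle
oracle_bleu <- function(candidate, references) {
  toks <- function(x) strsplit(tolower(trimws(x)), "\\s+")[[1L]]
  grams <- function(tk, n) {
    if (length(tk) < n) return(character())
    sapply(seq_len(length(tk) - n + 1L),
           function(i) paste(tk[i:(i + n - 1L)], collapse = ""))
  }
  cand <- toks(candidate)
  refs <- lapply(references, toks)
  logp <- c()
  for (n in seq_len(min(4L, length(cand)))) {
    cg <- grams(cand, n)
    clip <- 0
    for (g in unique(cg)) {
      clip <- clip + min(sum(cg == g),
                         max(sapply(refs, function(r)
                           sum(grams(r, n) == g))))
    }
    p <- if (n == 1L) clip / length(cg) else
      (clip + 1) / (length(cg) + 1)
    if (n == 1L && p == 0) return(0)
    logp <- c(logp, log(p))
  }
  rl <- sapply(refs, length)
  r <- rl[order(abs(rl - length(cand)), rl)][1L]
  bp <- if (length(cand) > r) 1 else exp(1 - r / length(cand))
  bp * exp(mean(logp))
}

# exponential-time LCS by subsequence enumeration (lengths <= 10)
oracle_lcs <- function(a, b) {
  if (!length(a)) return(0L)
  subseqs <- function(x) {
    idx <- unlist(lapply(seq_along(x), function(k)
      utils::combn(seq_along(x), k, simplify = FALSE)), recursive = FALSE)
    lapply(idx, function(i) x[i])
  }
  best <- 0L
  for (s in subseqs(a)) {
    if (length(s) <= best) next
    # is s a subsequence of b?
    j <- 1L
    for (t in b) {
      if (j <= length(s) && t == s[j]) j <- j + 1L
    }
    if (j == length(s) + 1L) best <- length(s)
  }
  best
}

# --- cached default corpus + pipeline run ----------------------------------

.pipeline_cache <- new.env(parent = emptyenv())

default_corpus_dir <- function() {
  if (is.null(.pipeline_cache$dir)) {
    dir <- file.path(tempdir(), "clinkg-default-corpus")
    unlink(dir, recursive = TRUE)
    .pipeline_cache$manifest <- generate_corpus(synth_config(seed = 1), dir)
    .pipeline_cache$dir <- dir
  }
  .pipeline_cache$dir
}

default_manifest <- function() {
  default_corpus_dir()
  .pipeline_cache$manifest
}

default_pipeline <- function() {
  if (is.null(.pipeline_cache$run)) {
    dir <- default_corpus_dir()
    ont <- load_ontology(file.path(dir, "ontology"))
    adj <- load_adjudicator_script(file.path(dir, "update",
                                             "adjudicator.json"))
    ini <- kg_init(file.path(dir, "init"), ont)
    upd <- apply_update(ini$store, file.path(dir, "update"), ont,
                        adjudicator = adj)
    .pipeline_cache$run <- list(ont = ont, adjudicator = adj, init = ini,
                                update = upd)
  }
  .pipeline_cache$run
}
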