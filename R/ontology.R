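# Terminology service: concept tables, synonym expansion, code crosswalks,
# and the three-stage term-normalization cascade.

#' Construct a terminology service from data frames
#'
#' @param concepts Data frame with columns `namespace`, `code`,
#'   `preferred_term`, `semantic_type`. The pair (`namespace`, `code`) must
#'   be unique.
#' @param synonyms Data frame with columns `namespace`, `code`, `synonym`;
#'   each row attaches one synonym string to an existing concept.
#' @param crosswalk Data frame with columns `source_ns`, `source_code`,
#'   `target_ns`, `target_code`, `table_name`. Source and target namespaces
#'   must differ within a row.
#' @return An object of class `kg_ontology`.
#' @export
ontology <- function(concepts,
                     synonyms = empty_synonyms(),
                     crosswalk = empty_crosswalk()) {
  req <- c("namespace", "code", "preferred_term", "semantic_type")
  if (!all(req %in% names(concepts))) {
    stop("concepts table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  key <- paste(concepts$namespace, concepts$code, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (namespace, code) in concepts table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  bad_ns <- setdiff(unique(concepts$namespace), kg_namespaces())
  if (length(bad_ns)) {
    stop("unknown namespace in concepts table: ",
         paste(bad_ns, collapse = ", "), call. = FALSE)
  }
  bad_ty <- setdiff(unique(concepts$semantic_type), kg_semantic_types())
  if (length(bad_ty)) {
    stop("unknown semantic type in concepts table: ",
         paste(bad_ty, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(concepts$preferred_term))) {
    stop("preferred_term must be non-empty", call. = FALSE)
  }
  synonyms <- as.data.frame(synonyms, stringsAsFactors = FALSE)
  crosswalk <- as.data.frame(crosswalk, stringsAsFactors = FALSE)
  if (nrow(crosswalk) &&
      any(crosswalk$source_ns == crosswalk$target_ns)) {
    stop("crosswalk rows must map between different namespaces",
         call. = FALSE)
  }

  ont <- structure(
    list(concepts = concepts, synonyms = synonyms, crosswalk = crosswalk),
    class = "kg_ontology"
  )
  ont$lut <- build_ontology_lut(ont)
  ont
}

empty_synonyms <- function() {
  data.frame(namespace = character(), code = character(),
             synonym = character(), stringsAsFactors = FALSE)
}

empty_crosswalk <- function() {
  data.frame(source_ns = character(), source_code = character(),
             target_ns = character(), target_code = character(),
             table_name = character(), stringsAsFactors = FALSE)
}

# Precomputed lookup tables: canonical preferred term -> concept ids,
# canonical synonym -> concept ids, concept id -> row index.
build_ontology_lut <- function(ont) {
  ids <- paste(ont$concepts$namespace, ont$concepts$code, sep = ":")
  pref_canon <- vapply(ont$concepts$preferred_term, canonicalize, "")
  by_pref <- split(ids, pref_canon)
  by_syn <- list()
  if (nrow(ont$synonyms)) {
    syn_ids <- paste(ont$synonyms$namespace, ont$synonyms$code, sep = ":")
    syn_canon <- vapply(ont$synonyms$synonym, canonicalize, "")
    by_syn <- lapply(split(syn_ids, syn_canon), unique)
  }
  row_of <- stats::setNames(seq_along(ids), ids)
  list(by_pref = by_pref, by_syn = by_syn, row_of = row_of, ids = ids)
}

#' Look up the concept record behind a concept id
#'
#' @param ont A `kg_ontology`.
#' @param id Concept-id string.
#' @return One-row data frame, or `NULL` when the concept is unknown.
#' @export
concept_record <- function(ont, id) {
  i <- ont$lut$row_of[id]
  if (is.na(i)) return(NULL)
  ont$concepts[i, , drop = FALSE]
}

#' Load a terminology fixture from delimited text files
#'
#' Reads `concepts.tsv`, `synonyms.tsv` and `crosswalk.tsv` (tab-separated,
#' with headers) from a directory. Headers are validated and duplicate
#' (namespace, code) concept rows are rejected.
#'
#' @param dir Directory holding the three TSV files.
#' @return A `kg_ontology`.
#' @export
load_ontology <- function(dir) {
  read_tsv_checked <- function(file, cols, required = TRUE) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      if (required) stop("missing ontology file: ", path, call. = FALSE)
      return(NULL)
    }
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE, quote = "",
                            fileEncoding = "UTF-8")
    if (!identical(names(df), cols)) {
      stop(file, " must have header: ", paste(cols, collapse = "\t"),
           call. = FALSE)
    }
    df
  }
  concepts <- read_tsv_checked(
    "concepts.tsv", c("namespace", "code", "preferred_term", "semantic_type"))
  synonyms <- read_tsv_checked(
    "synonyms.tsv", c("namespace", "code", "synonym"), required = FALSE)
  crosswalk <- read_tsv_checked(
    "crosswalk.tsv", c("source_ns", "source_code", "target_ns",
                       "target_code", "table_name"), required = FALSE)
  ontology(concepts,
           synonyms %||% empty_synonyms(),
           crosswalk %||% empty_crosswalk())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a concept code to another vocabulary through the crosswalk tables
#'
#' Deterministic lookup in the loaded crosswalk rows (e.g. the
#' ICD-10-CM to SNOMED CT relation table). Rows with several targets return
#' all of them, carrying the crosswalk table name as an attribute.
#'
#' @param ont A `kg_ontology`.
#' @param code Source concept-id string, e.g. `"ICD10CM:E11.9"`.
#' @param target_namespace Namespace to map into.
#' @return Character vector of target concept ids with attribute
#'   `table_name`, or `NULL` when no mapping exists (the typed no-mapping
#'   signal; absence of a row is not an error).
#' @export
map_code <- function(ont, code, target_namespace) {
  parts <- split_concept_id(code)
  if (!target_namespace %in% kg_namespaces()) {
    stop("unknown target namespace: ", target_namespace, call. = FALSE)
  }
  cw <- ont$crosswalk
  if (!nrow(cw)) return(NULL)
  hit <- cw$source_ns == parts$namespace & cw$source_code == parts$code &
    cw$target_ns == target_namespace
  if (!any(hit)) return(NULL)
  rows <- cw[hit, , drop = FALSE]
  out <- paste(rows$target_ns, rows$target_code, sep = ":")
  attr(out, "table_name") <- rows$table_name
  out
}

#' Normalize a clinical term to a standard vocabulary concept
#'
#' Implements the three-stage normalization cascade with a separate
#' crosswalk branch for terms that arrive carrying a terminology code:
#'
#' * crosswalk branch: when `code` is supplied, it is first mapped through
#'   the crosswalk tables into `target_namespace` (or accepted directly when
#'   it already names a known concept);
#' * stage 1: exact lexical match of the canonicalized term against
#'   canonicalized preferred terms (score 1);
#' * stage 2: exact match against canonicalized synonym expansions;
#' * stage 3: adjudicated ranking of the surviving candidates, constrained
#'   by the semantic-type filter; an adjudicator answer outside the filter
#'   or outside the candidate set is rejected to `unresolved`.
#'
#' Stages are tried strictly in order; the audit trail of stages consulted
#' is recorded on the result.
#'
#' @param term Term to normalize.
#' @param ont A `kg_ontology`.
#' @param code Optional concept-id string attached to the term (e.g. an
#'   ICD-10-CM diagnosis code from an EMR field).
#' @param context Optional context snippet handed to the adjudicator.
#' @param semantic_filter Optional character vector of admissible semantic
#'   types.
#' @param adjudicator Optional adjudicator function (see
#'   [adjudicator_scripted()]); when absent, ambiguous terms degrade to
#'   `unresolved`.
#' @param target_namespace Namespace the crosswalk branch maps into.
#' @return An object of class `kg_normalization` with fields `input_term`,
#'   `resolved` (concept id or `NULL`), `stage`
#'   (`"1"`, `"2"`, `"3"`, `"crosswalk"` or `"unresolved"`), `score`,
#'   `candidates` and `stages_tried`.
#' @export
normalize_term <- function(term, ont, code = NULL, context = NULL,
                           semantic_filter = NULL, adjudicator = NULL,
                           target_namespace = "SNOMEDCT") {
  canon <- canonicalize(term)
  tried <- character()
  result <- function(resolved, stage, score, candidates = character(),
                     note = NULL) {
    structure(
      list(input_term = term, resolved = resolved, stage = stage,
           score = score, candidates = candidates, stages_tried = tried,
           note = note),
      class = "kg_normalization"
    )
  }
  admissible <- function(id) {
    rec <- concept_record(ont, id)
    !is.null(rec) &&
      (is.null(semantic_filter) || rec$semantic_type %in% semantic_filter)
  }

  if (!is.null(code)) {
    tried <- c(tried, "crosswalk")
    mapped <- map_code(ont, code, target_namespace)
    if (!is.null(mapped)) {
      keep <- Filter(admissible, as.character(mapped))
      if (length(keep) == 1L) {
        return(result(keep[[1L]], "crosswalk", 1))
      }
    } else if (!is.null(concept_record(ont, code)) && admissible(code)) {
      # the attached code itself names a known concept
      return(result(code, "crosswalk", 1))
    }
  }

  tried <- c(tried, "1")
  hits <- Filter(admissible, ont$lut$by_pref[[canon]] %||% character())
  if (length(hits) == 1L) {
    return(result(hits[[1L]], "1", 1))
  }
  carried <- hits

  tried <- c(tried, "2")
  syn_hits <- Filter(admissible, ont$lut$by_syn[[canon]] %||% character())
  if (length(syn_hits) == 1L && length(carried) == 0L) {
    return(result(syn_hits[[1L]], "2", 1))
  }
  carried <- unique(c(carried, syn_hits))

  tried <- c(tried, "3")
  candidates <- carried
  if (length(candidates) == 0L) {
    # token-overlap candidate generation for the adjudicator
    toks <- strsplit(canon, " ", fixed = TRUE)[[1L]]
    pref_canon <- names(ont$lut$by_pref)
    overlap <- vapply(strsplit(pref_canon, " ", fixed = TRUE),
                      function(p) any(toks %in% p), logical(1L))
    candidates <- Filter(admissible,
                         unique(unlist(ont$lut$by_pref[overlap],
                                       use.names = FALSE)))
  }
  candidates <- sort(as.character(candidates))
  if (length(candidates) == 0L) {
    return(result(NULL, "unresolved", 0,
                  note = "no candidate concepts"))
  }
  if (is.null(adjudicator)) {
    return(result(NULL, "unresolved", 0, candidates,
                  note = "ambiguous term and no adjudicator available"))
  }
  req <- adjudication_request(
    kind = "normalization", item = term, options = candidates,
    context = context
  )
  resp <- tryCatch(adjudicator(req), error = function(e) e)
  if (inherits(resp, "error")) {
    return(result(NULL, "unresolved", 0, candidates,
                  note = paste("adjudicator failure:",
                               conditionMessage(resp))))
  }
  if (is.null(resp)) {
    return(result(NULL, "unresolved", 0, candidates,
                  note = "adjudicator declined"))
  }
  choice <- resp$choice %||% ""
  if (!is.character(choice) || length(choice) != 1L ||
      !choice %in% candidates || !admissible(choice)) {
    return(result(NULL, "unresolved", 0, candidates,
                  note = "adjudicator answer rejected by semantic filter"))
  }
  score <- suppressWarnings(as.numeric(resp$confidence %||% NA_real_))
  if (is.na(score)) score <- 0.5
  result(choice, "3", min(1, max(0, score)), candidates)
}

#' @export
print.kg_normalization <- function(x, ...) {
  res <- if (is.null(x$resolved)) "<unresolved>" else x$resolved
  cat(sprintf("normalization: %s -> %s (stage %s, score %.2f)\n",
              x$input_term, res, x$stage, x$score))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Build a recognition lexicon from a terminology service
#'
#' The reference entity recognizer is a longest-match dictionary scan over
#' surface forms; this assembles the dictionary from preferred terms and
#' synonyms, optionally extended with extra surface forms (e.g. trial names
#' that are not part of any vocabulary).
#'
#' @param ont A `kg_ontology`.
#' @param extra Optional data frame with columns `term`, `concept`,
#'   `semantic_type` for out-of-vocabulary surface forms.
#' @return Data frame with columns `term`, `concept`, `semantic_type`.
#' @export
build_lexicon <- function(ont, extra = NULL) {
  ids <- ont$lut$ids
  lex <- data.frame(
    term = ont$concepts$preferred_term,
    concept = ids,
    semantic_type = ont$concepts$semantic_type,
    stringsAsFactors = FALSE
  )
  if (nrow(ont$synonyms)) {
    syn_ids <- paste(ont$synonyms$namespace, ont$synonyms$code, sep = ":")
    sem <- ont$concepts$semantic_type[ont$lut$row_of[syn_ids]]
    lex <- rbind(lex, data.frame(
      term = ont$synonyms$synonym, concept = syn_ids, semantic_type = sem,
      stringsAsFactors = FALSE
    ))
  }
  if (!is.null(extra)) {
    lex <- rbind(lex, extra[, c("term", "concept", "semantic_type")])
  }
  lex[!duplicated(lex$term), , drop = FALSE]
}
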