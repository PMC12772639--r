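# Phase-1 information extraction from unstructured documents: reference
# recognizer (longest-match dictionary scan), reference relation backend
# (surface patterns), and readers for the external document/EMR formats.

#' Read a clinical document with YAML front matter
#'
#' Documents are plain-text files beginning with a `---` delimited YAML
#' header carrying `doc_id`, `kind` (guideline | textbook | trial_report |
#' note) and `date`; the body is the document text. The document kind
#' determines the source authority tier.
#'
#' @param path Path to the document file.
#' @return A list of class `kg_document` with fields `doc_id`, `kind`,
#'   `date`, `text`, `source`.
#' @export
read_document <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L || lines[[1L]] != "---") {
    stop("document missing YAML front matter: ", path, call. = FALSE)
  }
  end <- which(lines == "---")[2L]
  if (is.na(end)) {
    stop("unterminated YAML front matter: ", path, call. = FALSE)
  }
  meta <- yaml::yaml.load(paste(lines[2:(end - 1L)], collapse = "\n"))
  text <- paste(lines[(end + 1L):length(lines)], collapse = " ")
  clinical_document(meta$doc_id, meta$kind, as.character(meta$date),
                    trimws(text))
}

#' Construct a clinical document in code
#'
#' @param doc_id Identifier.
#' @param kind One of guideline, textbook, trial_report, note.
#' @param date ISO date.
#' @param text Document body.
#' @return A `kg_document`.
#' @export
clinical_document <- function(doc_id, kind, date, text) {
  tier <- kind_to_tier(kind)
  structure(
    list(doc_id = doc_id, kind = kind, date = date, text = text,
         source = source_ref(doc_id, "unstructured", tier, date)),
    class = "kg_document"
  )
}

#' Read EMR records from the packaged CSV layout
#'
#' The CSV has columns `encounter_id`, `patient_id`, `field_name`, `value`,
#' `timestamp` (ISO-8601). Rows are grouped into encounters; rows with
#' `field_name == "comorbidity"` list the encounter's active comorbidities.
#' Each encounter becomes a structured-modality source dated at its first
#' event.
#'
#' @param path Path to the CSV file.
#' @return List of `kg_emr_record` objects, ordered by encounter id.
#' @export
read_emr_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  req <- c("encounter_id", "patient_id", "field_name", "value", "timestamp")
  if (!all(req %in% names(df))) {
    stop("EMR CSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$encounter_id)
  out <- lapply(sort(ids), function(id) {
    rows <- df[df$encounter_id == id, , drop = FALSE]
    date <- substr(min(rows$timestamp), 1L, 10L)
    structure(
      list(
        encounter_id = id,
        patient_id = rows$patient_id[[1L]],
        date = date,
        active_comorbidities =
          rows$value[rows$field_name == "comorbidity"],
        events = rows[rows$field_name != "comorbidity",
                      c("field_name", "value", "timestamp"), drop = FALSE],
        source = source_ref(id, "structured", "structured_emr", date)
      ),
      class = "kg_emr_record"
    )
  })
  out
}

#' Read a corpus directory
#'
#' Collects `*.txt` documents (sorted by file name) and an optional
#' `emr.csv` from a directory.
#'
#' @param dir Corpus directory.
#' @return A list of class `kg_corpus` with `documents` and `emr`.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(files, read_document)
  emr_path <- file.path(dir, "emr.csv")
  emr <- if (file.exists(emr_path)) read_emr_records(emr_path) else list()
  structure(list(documents = docs, emr = emr), class = "kg_corpus")
}

# --- entity recognition -----------------------------------------------------

#' Extract entity mentions from text
#'
#' The reference recognizer backend: a case-insensitive, word-boundary,
#' longest-match dictionary scan over the lexicon's surface forms. Returned
#' spans are non-overlapping (longer matches shadow shorter ones) with
#' 0-based, half-open character offsets over the raw text. Any function
#' conforming to the `text -> mentions` contract can stand in for it.
#'
#' @param text Character scalar (may be empty).
#' @param lexicon Data frame from [build_lexicon()] with columns `term`,
#'   `concept`, `semantic_type`.
#' @return Data frame with columns `start`, `end`, `text`, `term`,
#'   `concept`, `semantic_type`, sorted by `start`.
#' @export
extract_mentions <- function(text, lexicon) {
  empty <- data.frame(start = integer(), end = integer(),
                      text = character(), term = character(),
                      concept = character(), semantic_type = character(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text) || !nrow(lexicon)) return(empty)
  cand <- list()
  for (i in seq_len(nrow(lexicon))) {
    term <- lexicon$term[[i]]
    pat <- paste0("(?i)(?<![A-Za-z0-9])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                  "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      cand[[length(cand) + 1L]] <- list(
        start = as.integer(m[j]) - 1L,
        end = as.integer(m[j]) - 1L + len[j],
        term = term, concept = lexicon$concept[[i]],
        semantic_type = lexicon$semantic_type[[i]]
      )
    }
  }
  if (!length(cand)) return(empty)
  # longest-match selection: longest first, leftmost breaks ties
  lens <- vapply(cand, function(x) x$end - x$start, integer(1L))
  starts <- vapply(cand, `[[`, integer(1L), "start")
  ord <- order(-lens, starts)
  taken <- logical(nchar(text))
  keep <- list()
  for (k in ord) {
    span <- (cand[[k]]$start + 1L):cand[[k]]$end
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep[[length(keep) + 1L]] <- cand[[k]]
    }
  }
  out <- do.call(rbind, lapply(keep, function(x) {
    data.frame(start = x$start, end = x$end,
               text = substr(text, x$start + 1L, x$end),
               term = x$term, concept = x$concept,
               semantic_type = x$semantic_type, stringsAsFactors = FALSE)
  }))
  out[order(out$start), , drop = FALSE]
}

# --- relation extraction ----------------------------------------------------

split_sentences <- function(text) {
  s <- strsplit(text, "(?<=\\.)\\s+", perl = TRUE)[[1L]]
  s <- sub("\\.$", "", s)
  trimws(s[nzchar(trimws(s))])
}

relation_patterns <- function() {
  list(
    INDICATES = "^(.+?) is an indicator of (.+)$",
    ASSOCIATED_WITH = "^(.+?) is associated with (.+)$",
    CONTRAINDICATED_IN = "^(.+?) is contraindicated in (.+)$",
    USED_IN_TRIAL = "^(.+?) was used in (.+)$",
    RESULTS_IN = "^(.+?) results in (.+)$",
    TREATS = "^(.+?) treats (.+)$",
    CAUSES = "^(.+?) causes (.+)$",
    REPORTED = "^(.+?) reported (.+)$"
  )
}

match_clause <- function(clause) {
  for (pred in names(relation_patterns())) {
    m <- regmatches(clause, regexec(relation_patterns()[[pred]], clause))[[1L]]
    if (length(m) == 3L) {
      return(list(subject = trimws(m[[2L]]), predicate = pred,
                  object = trimws(m[[3L]])))
    }
  }
  NULL
}

#' Extract candidate triples from a document
#'
#' The reference relation backend: sentences are split on period plus
#' whitespace and matched against the surface-pattern grammar
#' (`X treats Y`, `X causes Z`, `X was used in T`, `T reported S`,
#' `X results in O`, `X is an indicator of Y`, `X is associated with Y`,
#' `X is contraindicated in Y`). A relative clause of the form
#' `..., which <pattern>` is expanded with the main clause's object as its
#' subject. Sentences matching no pattern yield nothing. Each triple cites
#' the sentence it came from as its context snippet.
#'
#' @param doc A `kg_document` (or any list with `text` and `source`).
#' @param mentions Optional mention table from [extract_mentions()]; when
#'   supplied, extracted argument strings must correspond to recognized
#'   mention texts (others are dropped).
#' @param relation_backend Optional replacement backend,
#'   `function(sentence) -> list of triples`.
#' @return Data frame of class `kg_triples` with columns `subject`,
#'   `predicate`, `object`, `context`, `confidence`.
#' @export
extract_triples <- function(doc, mentions = NULL, relation_backend = NULL) {
  sentences <- split_sentences(doc$text)
  rows <- list()
  add <- function(tr, context) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = tr$subject, predicate = tr$predicate, object = tr$object,
      context = context, confidence = 1, stringsAsFactors = FALSE)
  }
  for (s in sentences) {
    if (!is.null(relation_backend)) {
      for (tr in relation_backend(s)) add(tr, s)
      next
    }
    rel <- NULL
    main <- s
    if (grepl(", which ", s, fixed = TRUE)) {
      parts <- strsplit(s, ", which ", fixed = TRUE)[[1L]]
      main <- parts[[1L]]
      rel <- paste(parts[-1L], collapse = ", which ")
    }
    tr <- match_clause(main)
    if (is.null(tr)) next
    add(tr, s)
    if (!is.null(rel)) {
      tr2 <- match_clause(paste(tr$object, rel))
      if (!is.null(tr2)) add(tr2, s)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), predicate = character(),
               object = character(), context = character(),
               confidence = numeric(), stringsAsFactors = FALSE)
  if (!is.null(mentions) && nrow(out)) {
    ok <- out$subject %in% mentions$text & out$object %in% mentions$text
    out <- out[ok, , drop = FALSE]
  }
  class(out) <- c("kg_triples", class(out))
  out
}

#' Extract attribute statements from a document
#'
#' Attribute statements carry node enrichments through the pattern
#' `"<entity> has <key> <value>."` with keys from a small closed set
#' (phase, status, enrollment, start date, end date).
#'
#' @param doc A `kg_document`.
#' @return Data frame with columns `entity`, `key`, `value`, `context`.
#' @export
extract_attributes <- function(doc) {
  pat <- "^(.+?) has (phase|status|enrollment|start date|end date) (.+)$"
  rows <- list()
  for (s in split_sentences(doc$text)) {
    m <- regmatches(s, regexec(pat, s))[[1L]]
    if (length(m) == 4L) {
      rows[[length(rows) + 1L]] <- data.frame(
        entity = trimws(m[[2L]]), key = gsub(" ", "_", m[[3L]]),
        value = trimws(m[[4L]]), context = s, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(entity = character(), key = character(), value = character(),
               context = character(), stringsAsFactors = FALSE)
}
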