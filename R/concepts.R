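# Controlled vocabularies, concept identifiers, canonicalization, source
# references and authority tiers. These primitives are shared by every other
# module.

#' Controlled vocabulary namespaces
#'
#' The closed set of terminology namespaces a concept code may belong to.
#' @return Character vector of namespace names.
#' @export
kg_namespaces <- function() {
  c("SNOMEDCT", "ICD10CM", "RXNORM", "LOINC", "LOCAL")
}

#' Semantic types of knowledge-graph entities
#' @return Character vector of the closed semantic-type set.
#' @export
kg_semantic_types <- function() {
  c("drug", "disease", "symptom", "side_effect", "outcome", "trial",
    "lab", "procedure")
}

#' Relationship predicates
#' @return Character vector of the closed predicate set.
#' @export
kg_predicates <- function() {
  c("TREATS", "CAUSES", "RESULTS_IN", "ASSOCIATED_WITH",
    "CONTRAINDICATED_IN", "USED_IN_TRIAL", "REPORTED", "INDICATES")
}

#' Build a concept identifier
#'
#' A concept identifier is the string `"<NAMESPACE>:<code>"`, e.g.
#' `"SNOMEDCT:44054006"`. The namespace must come from [kg_namespaces()] and
#' the code must be non-empty.
#'
#' @param namespace Vocabulary name.
#' @param code Opaque code string.
#' @return A concept-id string.
#' @export
concept_id <- function(namespace, code) {
  if (!is.character(namespace) || length(namespace) != 1L ||
      !namespace %in% kg_namespaces()) {
    stop("unknown concept namespace: ", paste(namespace, collapse = ", "),
         call. = FALSE)
  }
  code <- as.character(code)
  if (length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop("concept code must be a non-empty string", call. = FALSE)
  }
  paste0(namespace, ":", code)
}

#' Split a concept identifier into namespace and code
#'
#' @param x Concept-id string such as `"ICD10CM:E11.9"`.
#' @return List with elements `namespace` and `code`.
#' @export
split_concept_id <- function(x) {
  if (!is.character(x) || length(x) != 1L || !grepl(":", x, fixed = TRUE)) {
    stop("malformed concept id: ", x, call. = FALSE)
  }
  ns <- sub(":.*$", "", x)
  code <- sub("^[^:]*:", "", x)
  if (!ns %in% kg_namespaces()) {
    stop("unknown concept namespace: ", ns, call. = FALSE)
  }
  if (!nzchar(code)) stop("concept code must be non-empty", call. = FALSE)
  list(namespace = ns, code = code)
}

#' Canonicalize a clinical term
#'
#' Deterministic lexical canonicalization used for exact matching: the term
#' is lower-cased, punctuation is replaced by spaces, whitespace is
#' collapsed, and the remaining tokens are sorted lexicographically. The
#' function is pure and idempotent.
#'
#' @param term Non-empty character scalar.
#' @return Canonical form of `term`.
#' @examples
#' canonicalize("Type 2 Diabetes Mellitus")  # "2 diabetes mellitus type"
#' @export
canonicalize <- function(term) {
  if (!is.character(term) || length(term) != 1L || is.na(term)) {
    stop("term must be a character scalar", call. = FALSE)
  }
  x <- tolower(term)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  if (!nzchar(x)) stop("term is empty after canonicalization", call. = FALSE)
  tokens <- strsplit(x, " ", fixed = TRUE)[[1L]]
  paste(sort(tokens), collapse = " ")
}

canonical_tokens <- function(term) {
  strsplit(canonicalize(term), " ", fixed = TRUE)[[1L]]
}

#' Authority tiers of clinical sources
#'
#' Ordered trust levels used for confidence scoring and conflict
#' resolution: regulatory guidelines outrank structured EMR data and
#' textbooks (which are peers), which outrank trial reports, which outrank
#' unstructured notes.
#'
#' @return Named integer vector mapping tier name to rank (higher = more
#'   authoritative).
#' @export
authority_tiers <- function() {
  c(regulatory_guideline = 4L, structured_emr = 3L, textbook = 3L,
    trial_report = 2L, unstructured_note = 1L)
}

tier_rank <- function(tier) {
  tiers <- authority_tiers()
  if (!tier %in% names(tiers)) {
    stop("unknown authority tier: ", tier, call. = FALSE)
  }
  unname(tiers[[tier]])
}

#' Parse an ISO-8601 date or datetime
#'
#' @param x Character scalar, `"YYYY-MM-DD"` or `"YYYY-MM-DDTHH:MM:SS"`.
#' @return A `Date` (date input) or `POSIXct` (datetime input); `NA` if the
#'   value is not parseable.
#' @export
parse_iso_datetime <- function(x) {
  if (is.null(x) || length(x) != 1L || is.na(x)) return(NA)
  x <- as.character(x)
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
    # as.Date tolerates out-of-range components on some platforms; re-check
    if (!is.na(d) && format(d, "%Y-%m-%d") == x) return(d)
    return(NA)
  }
  if (grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", x)) {
    t <- tryCatch(
      as.POSIXct(sub("T", " ", x), tz = "UTC"),
      error = function(e) NA
    )
    if (!is.na(t)) return(t)
  }
  NA
}

is_iso_date <- function(x) {
  !is.na(suppressWarnings(parse_iso_datetime(x)))
}

#' Build a source reference
#'
#' A `SourceRef` ties an assertion to the document or record it came from,
#' and carries the authority tier and date that drive confidence scoring and
#' supersedence.
#'
#' @param doc_id Document or record identifier.
#' @param modality `"structured"` or `"unstructured"`.
#' @param authority_tier One of `names(authority_tiers())`.
#' @param date ISO-8601 date string.
#' @return A list of class `kg_source`.
#' @export
source_ref <- function(doc_id, modality, authority_tier, date) {
  if (!is.character(doc_id) || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string", call. = FALSE)
  }
  if (!modality %in% c("structured", "unstructured")) {
    stop("modality must be 'structured' or 'unstructured'", call. = FALSE)
  }
  tier_rank(authority_tier)  # validates
  if (!is_iso_date(date)) {
    stop("source date is not a parseable ISO-8601 date: ", date,
         call. = FALSE)
  }
  structure(
    list(doc_id = doc_id, modality = modality,
         authority_tier = authority_tier, date = as.character(date)),
    class = "kg_source"
  )
}

# Map a document kind to its authority tier.
kind_to_tier <- function(kind) {
  switch(kind,
    guideline = "regulatory_guideline",
    textbook = "textbook",
    trial_report = "trial_report",
    note = "unstructured_note",
    stop("unknown document kind: ", kind, call. = FALSE)
  )
}
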