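# The adjudicator contract: a pluggable disambiguation oracle standing in
# for contextual reasoning. A request is a structured record; a response is
# a list with `choice`, `confidence` and `rationale` (or NULL to decline).
# Scripted adjudicators keyed by a deterministic request key make every
# ambiguous decision replayable in tests and generated corpora.

#' Build an adjudication request
#'
#' @param kind Question kind: `"normalization"`, `"attribution"` or
#'   `"conflict"`.
#' @param item The item under question (term, lab/medication name, or
#'   conflicting pair description).
#' @param options Admissible answers.
#' @param context Optional context snippet.
#' @param history Optional relevant history (free-form).
#' @return A list of class `kg_adjudication_request`.
#' @export
adjudication_request <- function(kind, item, options, context = NULL,
                                 history = NULL) {
  structure(
    list(kind = kind, item = item, options = as.character(options),
         context = context, history = history),
    class = "kg_adjudication_request"
  )
}

#' Deterministic key of an adjudication request
#'
#' Used to index scripted responses: `"<kind>|<item>|<sorted options>"`.
#'
#' @param req A `kg_adjudication_request`.
#' @return Character scalar key.
#' @export
adjudication_key <- function(req) {
  paste(req$kind, req$item,
        paste(sort(req$options), collapse = ";"), sep = "|")
}

#' The no-op adjudicator stub
#'
#' Declines every request (returns `NULL`), so ambiguous cases degrade to
#' unresolved/unattributed rather than being guessed.
#'
#' @return An adjudicator function.
#' @export
adjudicator_stub <- function() {
  function(req) NULL
}

#' A scripted adjudicator
#'
#' Answers requests from a fixed map keyed by [adjudication_key()]. Unknown
#' keys are declined. This is the deterministic test/corpus backend for the
#' pluggable adjudicator contract.
#'
#' @param script Named list mapping request keys to responses (lists with
#'   `choice`, `confidence`, `rationale`).
#' @return An adjudicator function.
#' @export
adjudicator_scripted <- function(script) {
  stopifnot(is.list(script))
  function(req) {
    script[[adjudication_key(req)]]
  }
}

#' Load a scripted adjudicator from a JSON map file
#'
#' @param path Path to a JSON object mapping request keys to responses.
#' @return An adjudicator function.
#' @export
load_adjudicator_script <- function(path) {
  script <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  adjudicator_scripted(script)
}
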