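# EMR schema alignment, temporal precedence over encounter events, and
# attribution of clinical items to concurrently documented comorbidities.

#' Token-set cosine similarity (reference embedder)
#'
#' Similarity between two strings as the cosine of their canonical token
#' sets: `|A ∩ B| / sqrt(|A| |B|)`. This is the deterministic reference
#' implementation of the embedder contract (two strings -> similarity in
#' `[0, 1]`); any conforming function can replace it.
#'
#' @param a,b Strings.
#' @return Similarity in `[0, 1]`.
#' @export
token_set_cosine <- function(a, b) {
  ta <- unique(canonical_tokens(a))
  tb <- unique(canonical_tokens(b))
  if (!length(ta) || !length(tb)) return(0)
  length(intersect(ta, tb)) / sqrt(length(ta) * length(tb))
}

#' Align structured-record fields to the knowledge-graph schema
#'
#' Implements the schema-alignment cascade for structured EMR sources:
#' (1) exact matching of canonicalized field names against schema attribute
#' names; (2) semantic similarity between field names/descriptions and
#' schema names through the embedder contract, accepted only at or above
#' the acceptance threshold; (3) terminology-code crosswalks for fields
#' carrying codes (e.g. a LOINC-coded lab field mapping to the
#' SNOMED-coded attribute). A field whose best score falls below the review
#' threshold is flagged for review; an exact match never reaches the later
#' stages.
#'
#' @param fields Data frame with columns `field_name` and optionally
#'   `description` and `code` (concept-id string).
#' @param kg_schema Data frame with columns `name` and optionally `code`
#'   (concept-id string of the attribute's terminology anchor).
#' @param ont Optional `kg_ontology` supplying the crosswalk tables.
#' @param embedder Similarity function; defaults to [token_set_cosine()].
#' @param config A [kg_config()] supplying `schema_accept` and
#'   `schema_review` thresholds.
#' @return Data frame with columns `field_name`, `target`, `method`
#'   (`exact` | `similarity` | `ontology` | `NA`), `score`, `accepted`,
#'   `flagged_for_review`.
#' @export
align_schema <- function(fields, kg_schema, ont = NULL,
                         embedder = token_set_cosine,
                         config = kg_config()) {
  fields <- as.data.frame(fields, stringsAsFactors = FALSE)
  if (is.null(fields$description)) fields$description <- ""
  if (is.null(fields$code)) fields$code <- ""
  if (is.null(kg_schema$code)) kg_schema$code <- ""
  schema_canon <- vapply(kg_schema$name, canonicalize, "")

  one <- function(i) {
    fn <- fields$field_name[[i]]
    # stage 1: exact
    hit <- which(schema_canon == canonicalize(fn))
    if (length(hit)) {
      return(data.frame(field_name = fn, target = kg_schema$name[[hit[1L]]],
                        method = "exact", score = 1, accepted = TRUE,
                        flagged_for_review = FALSE,
                        stringsAsFactors = FALSE))
    }
    # stage 2: similarity over names and descriptions
    sims <- vapply(seq_len(nrow(kg_schema)), function(j) {
      s <- embedder(fn, kg_schema$name[[j]])
      if (nzchar(fields$description[[i]])) {
        s <- max(s, embedder(fields$description[[i]], kg_schema$name[[j]]))
      }
      s
    }, numeric(1L))
    best <- if (length(sims)) which.max(sims) else integer()
    best_score <- if (length(best)) sims[[best]] else 0
    if (length(best) && best_score >= config$schema_accept) {
      return(data.frame(field_name = fn, target = kg_schema$name[[best]],
                        method = "similarity", score = best_score,
                        accepted = TRUE,
                        flagged_for_review =
                          best_score < config$schema_review,
                        stringsAsFactors = FALSE))
    }
    # stage 3: terminology-code crosswalk
    if (nzchar(fields$code[[i]]) && !is.null(ont)) {
      for (ns in kg_namespaces()) {
        mapped <- tryCatch(map_code(ont, fields$code[[i]], ns),
                           error = function(e) NULL)
        if (is.null(mapped)) next
        j <- which(kg_schema$code %in% as.character(mapped))
        if (length(j)) {
          return(data.frame(field_name = fn,
                            target = kg_schema$name[[j[1L]]],
                            method = "ontology", score = 1, accepted = TRUE,
                            flagged_for_review = FALSE,
                            stringsAsFactors = FALSE))
        }
      }
    }
    data.frame(field_name = fn,
               target = if (length(best)) kg_schema$name[[best]] else
                 NA_character_,
               method = if (length(best)) "similarity" else NA_character_,
               score = best_score, accepted = FALSE,
               flagged_for_review = best_score < config$schema_review,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(fields)), one))
}

#' Temporal precedence over the events of one encounter
#'
#' Orders an encounter's events strictly by timestamp: an event precedes
#' another iff its timestamp is strictly earlier. Events with equal
#' timestamps are incomparable and flagged as ties. The derived sequence
#' ranks (1-based, ties sharing a rank) are what update pipelines attach to
#' emitted relationship properties (e.g. antihypertensives prescribed
#' before diabetes medications).
#'
#' @param events Data frame with columns `field_name`, `value`,
#'   `timestamp` (ISO-8601). An unparseable timestamp rejects the whole
#'   record with a classed error (`kg_timestamp_error`).
#' @return List of class `kg_precedence` with `precedes` (data frame of
#'   `before`/`after` event indices), `ties` (data frame of tied index
#'   pairs), and `sequence` (the events with `rank` and `tie` columns).
#' @export
temporal_precedence <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  n <- nrow(events)
  ts <- lapply(events$timestamp, parse_iso_datetime)
  bad <- vapply(ts, function(x) length(x) != 1L || is.na(x), logical(1L))
  if (any(bad)) {
    kg_error("kg_timestamp_error", paste(
      "unparseable timestamp(s):",
      paste(events$timestamp[bad], collapse = ", ")))
  }
  num <- vapply(ts, as.numeric, numeric(1L))
  prec <- list(); ties <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (num[i] < num[j]) {
        prec[[length(prec) + 1L]] <- c(i, j)
      } else if (num[j] < num[i]) {
        prec[[length(prec) + 1L]] <- c(j, i)
      } else {
        ties[[length(ties) + 1L]] <- c(i, j)
      }
    }
  }
  to_df <- function(x, nms) {
    if (length(x)) {
      m <- do.call(rbind, x)
      stats::setNames(data.frame(m[, 1L], m[, 2L]), nms)
    } else stats::setNames(data.frame(integer(), integer()), nms)
  }
  seq_df <- events
  seq_df$rank <- if (n) rank(num, ties.method = "min") else integer()
  tied_idx <- unique(unlist(ties))
  seq_df$tie <- seq_len(n) %in% tied_idx
  structure(
    list(precedes = to_df(prec, c("before", "after")),
         ties = to_df(ties, c("a", "b")),
         sequence = seq_df),
    class = "kg_precedence"
  )
}

#' Attribute a lab or medication to one of several active comorbidities
#'
#' Hierarchical attribution: (1) with a single active comorbidity, the item
#' is attributed to it by rule; (2) when exactly one active comorbidity has
#' a strong, specific association to the item in the graph (an active
#' `INDICATES` or `TREATS` edge at or above the direct-link confidence
#' threshold), that direct knowledge wins; (3) otherwise the adjudicator
#' receives the comorbidity list, the item, the context snippet and any
#' relevant history, and must pick one. Without an adjudicator an ambiguous
#' case is returned unattributed with a diagnostic — never silently
#' guessed. The chosen comorbidity is always one of the encounter's active
#' comorbidities.
#'
#' @param item Node id (or preferred name resolvable in the store) of the
#'   lab or medication.
#' @param active_comorbidities Character vector of comorbidity node ids.
#' @param store A `kg_store`.
#' @param adjudicator Optional adjudicator function.
#' @param config A [kg_config()] supplying `direct_link`.
#' @param context,history Passed through to the adjudicator.
#' @return Object of class `kg_attribution` with `item`, `attributed_to`
#'   (node id or `NULL`), `method` (`rule` | `direct_kg` | `adjudicator` |
#'   `unattributed`), `confidence`, `rationale`.
#' @export
attribute_clinical_item <- function(item, active_comorbidities, store,
                                    adjudicator = NULL,
                                    config = kg_config(),
                                    context = NULL, history = NULL) {
  if (is.null(store$nodes[[item]])) {
    ids <- kg_find(store, name = item)
    if (length(ids) != 1L) {
      kg_error("kg_entity_error", paste("cannot resolve item:", item))
    }
    item <- ids[[1L]]
  }
  comorbs <- as.character(active_comorbidities)
  missing <- comorbs[!comorbs %in% names(store$nodes)]
  if (length(missing)) {
    kg_error("kg_entity_error", paste(
      "active comorbidities not in store:", paste(missing, collapse = ", ")))
  }
  res <- function(to, method, confidence, rationale) {
    structure(list(item = item, attributed_to = to, method = method,
                   confidence = confidence, rationale = rationale),
              class = "kg_attribution")
  }
  if (length(comorbs) == 1L) {
    return(res(comorbs, "rule", 1,
               "single active comorbidity in the encounter"))
  }
  direct <- Filter(function(cm) {
    for (pred in c("INDICATES", "TREATS")) {
      eid <- store$idx$spo_active[[spo_key(item, pred, cm)]]
      if (!is.null(eid) &&
          store$edges[[eid]]$confidence >= config$direct_link) {
        return(TRUE)
      }
    }
    FALSE
  }, comorbs)
  if (length(direct) == 1L) {
    cm <- direct[[1L]]
    conf <- max(vapply(c("INDICATES", "TREATS"), function(pred) {
      eid <- store$idx$spo_active[[spo_key(item, pred, cm)]]
      if (is.null(eid)) 0 else store$edges[[eid]]$confidence
    }, numeric(1L)))
    return(res(cm, "direct_kg", conf,
               "unique strong association in the knowledge graph"))
  }
  # several or none: contextual disambiguation
  names_of <- vapply(comorbs, function(id)
    store$nodes[[id]]$preferred_name %||% id, "")
  item_name <- store$nodes[[item]]$preferred_name %||% item
  if (is.null(adjudicator)) {
    return(res(NULL, "unattributed", 0, paste(
      "ambiguous attribution (", length(direct),
      " strong links) and no adjudicator available", sep = "")))
  }
  req <- adjudication_request("attribution", item_name,
                              options = sort(unname(names_of)),
                              context = context, history = history)
  resp <- tryCatch(adjudicator(req), error = function(e) NULL)
  if (is.null(resp) || is.null(resp$choice) ||
      !resp$choice %in% names_of) {
    return(res(NULL, "unattributed", 0,
               "adjudicator declined or gave an answer outside the active comorbidities"))
  }
  cm <- comorbs[[match(resp$choice, names_of)]]
  conf <- suppressWarnings(as.numeric(resp$confidence %||% 0.5))
  if (is.na(conf)) conf <- 0.5
  res(cm, "adjudicator", min(1, max(0, conf)),
      resp$rationale %||% "adjudicated contextual disambiguation")
}
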