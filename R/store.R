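# Property-graph data model: in-memory store with attribute indices, atomic
# idempotent merge semantics and an append-only change log. The store has
# value semantics (functions return the updated store), which makes per-call
# atomicity trivial: a failed merge raises a classed condition and the
# caller's store is untouched.

#' Create an empty knowledge-graph store
#'
#' The store keeps nodes and edges in named lists, plus attribute indices:
#' concept code -> node, canonical name -> nodes, canonical name + semantic
#' type -> identity node, semantic type -> nodes, and
#' (subject, predicate, object) -> edges (all, and the single active one).
#'
#' @return An object of class `kg_store`.
#' @export
kg_store <- function() {
  structure(
    list(
      nodes = list(),
      edges = list(),
      idx = list(code = list(), name = list(), ident = list(),
                 type = list(), spo = list(), spo_active = list()),
      change_log = list()
    ),
    class = "kg_store"
  )
}

node_ident_key <- function(preferred_name, semantic_type) {
  paste0(canonicalize(preferred_name), "||", semantic_type)
}

spo_key <- function(subject, predicate, object) {
  paste(subject, predicate, object, sep = "|")
}

# Deterministic surrogate node id from the identity key, so replays of the
# same payload stream produce the same ids.
make_node_id <- function(concept_ids, preferred_name, semantic_type) {
  if (length(concept_ids)) {
    paste0("c/", sort(concept_ids)[[1L]])
  } else {
    paste0("n/", canonicalize(preferred_name), "|", semantic_type)
  }
}

kg_error <- function(class, msg) {
  stop(structure(
    class = c(class, "kg_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# --- property cells ---------------------------------------------------------
# Single-valued properties are stored as cells carrying the value plus the
# authority tier and date of the source that set them, so enrichment can
# apply the higher-authority-then-more-recent overwrite rule.

property_cell <- function(value, tier, date) {
  list(value = value, tier = tier, date = as.character(date))
}

# Returns list(cell, changed): overwrite only when the incoming (tier, date)
# is strictly greater lexicographically; equal values never change state.
update_property_cell <- function(cell, value, tier, date) {
  if (is.null(cell)) {
    return(list(cell = property_cell(value, tier, date), changed = TRUE))
  }
  if (identical(as.character(cell$value), as.character(value))) {
    return(list(cell = cell, changed = FALSE))
  }
  new_rank <- tier_rank(tier)
  old_rank <- tier_rank(cell$tier)
  wins <- new_rank > old_rank ||
    (new_rank == old_rank && as.Date(date) > as.Date(cell$date))
  if (wins) {
    list(cell = property_cell(value, tier, date), changed = TRUE)
  } else {
    list(cell = cell, changed = FALSE)
  }
}

apply_properties <- function(cells, values, source) {
  changed <- 0L
  for (key in names(values)) {
    res <- update_property_cell(cells[[key]], values[[key]],
                                source$authority_tier, source$date)
    if (res$changed) {
      cells[[key]] <- res$cell
      changed <- changed + 1L
    }
  }
  list(cells = cells, changed = changed)
}

#' Read a node or edge property value
#'
#' @param store A `kg_store`.
#' @param id Node or edge id.
#' @param key Property name.
#' @return The stored value, or `NULL`.
#' @export
kg_get_property <- function(store, id, key) {
  el <- store$nodes[[id]] %||% store$edges[[id]]
  if (is.null(el)) return(NULL)
  cell <- el$properties[[key]]
  if (is.null(cell)) NULL else cell$value
}

# --- node merge -------------------------------------------------------------

#' Build an entity-node payload
#'
#' @param semantic_type One of [kg_semantic_types()].
#' @param preferred_name Display name (optional when `concept_ids` given).
#' @param concept_ids Character vector of concept-id strings.
#' @param properties Named list of plain attribute values.
#' @param source A [source_ref()] describing where the entity came from.
#' @return A node payload list.
#' @export
entity_node <- function(semantic_type, preferred_name = NULL,
                        concept_ids = character(), properties = list(),
                        source = NULL) {
  list(semantic_type = semantic_type, preferred_name = preferred_name,
       concept_ids = as.character(concept_ids), properties = properties,
       source = source)
}

#' Merge an entity into the store
#'
#' Atomic, idempotent upsert. Identity matching is by shared concept code
#' first, else by canonicalized preferred name plus semantic type. A new
#' entity is created when neither matches; an existing entity is enriched by
#' unioning concept codes and applying properties under the
#' authority-then-recency rule (existing values from higher-authority
#' sources are never overwritten). Conflicting codes in the same namespace
#' are rejected with a classed error (`kg_code_conflict`) and the store is
#' left unchanged.
#'
#' @param store A `kg_store`.
#' @param payload An [entity_node()] payload. Must carry `semantic_type` and
#'   at least one of `preferred_name`, `concept_ids`.
#' @param phase `"init"` or `"update"`; recorded as `created_phase` on
#'   creation.
#' @return List with `store` (updated), `outcome` (`"created"`, `"matched"`
#'   or `"enriched"`), `node_id`, and `attrs_modified` (count of property
#'   assignments applied).
#' @export
merge_node <- function(store, payload, phase = "update") {
  stopifnot(inherits(store, "kg_store"))
  if (is.null(payload$semantic_type) ||
      !payload$semantic_type %in% kg_semantic_types()) {
    kg_error("kg_syntax_error",
             paste("invalid semantic type:",
                   payload$semantic_type %||% "<missing>"))
  }
  codes <- unique(as.character(payload$concept_ids %||% character()))
  if (!length(codes) && is.null(payload$preferred_name)) {
    kg_error("kg_syntax_error",
             "payload needs a preferred_name or at least one concept id")
  }
  for (cd in codes) split_concept_id(cd)  # validates
  ns <- vapply(codes, function(cd) split_concept_id(cd)$namespace, "")
  if (anyDuplicated(ns)) {
    kg_error("kg_code_conflict",
             "payload carries two codes in the same namespace")
  }

  # identity resolution: codes dominate name matching
  hit <- unique(unlist(store$idx$code[codes], use.names = FALSE))
  if (length(hit) > 1L) {
    kg_error("kg_code_conflict",
             "payload codes match more than one existing node")
  }
  if (!length(hit) && !is.null(payload$preferred_name)) {
    hit <- store$idx$ident[[
      node_ident_key(payload$preferred_name, payload$semantic_type)
    ]] %||% character()
  }

  src <- payload$source %||%
    source_ref("unknown", "unstructured", "unstructured_note", "1970-01-01")

  if (!length(hit)) {
    node_id <- make_node_id(codes, payload$preferred_name,
                            payload$semantic_type)
    props <- apply_properties(list(), payload$properties %||% list(), src)
    node <- list(
      node_id = node_id,
      semantic_type = payload$semantic_type,
      preferred_name = payload$preferred_name %||%
        concept_record_name(codes),
      concept_ids = sort(codes),
      properties = props$cells,
      created_by = unclass(src),
      created_phase = phase
    )
    store$nodes[[node_id]] <- node
    store <- index_node(store, node)
    store$change_log <- c(store$change_log,
                          list(list(op = "merge_node", id = node_id,
                                    outcome = "created")))
    return(list(store = store, outcome = "created", node_id = node_id,
                attrs_modified = 0L))
  }

  node_id <- hit[[1L]]
  node <- store$nodes[[node_id]]
  # reject codes conflicting with the incumbent's in the same namespace
  for (cd in codes) {
    p <- split_concept_id(cd)
    same_ns <- vapply(node$concept_ids,
                      function(x) split_concept_id(x)$namespace == p$namespace,
                      logical(1L))
    if (any(same_ns) && !cd %in% node$concept_ids) {
      kg_error("kg_code_conflict", sprintf(
        "node %s already holds a %s code different from %s",
        node_id, p$namespace, cd))
    }
  }
  changed <- FALSE
  new_codes <- setdiff(codes, node$concept_ids)
  if (length(new_codes)) {
    node$concept_ids <- sort(c(node$concept_ids, new_codes))
    for (cd in new_codes) store$idx$code[[cd]] <- node_id
    changed <- TRUE
  }
  props <- apply_properties(node$properties, payload$properties %||% list(),
                            src)
  if (props$changed > 0L) {
    node$properties <- props$cells
    changed <- TRUE
  }
  store$nodes[[node_id]] <- node
  outcome <- if (changed) "enriched" else "matched"
  store$change_log <- c(store$change_log,
                        list(list(op = "merge_node", id = node_id,
                                  outcome = outcome)))
  list(store = store, outcome = outcome, node_id = node_id,
       attrs_modified = props$changed)
}

concept_record_name <- function(codes) {
  if (!length(codes)) return(NULL)
  sort(codes)[[1L]]
}

index_node <- function(store, node) {
  for (cd in node$concept_ids) store$idx$code[[cd]] <- node$node_id
  if (!is.null(node$preferred_name)) {
    canon <- canonicalize(node$preferred_name)
    store$idx$name[[canon]] <-
      sort(unique(c(store$idx$name[[canon]], node$node_id)))
    store$idx$ident[[paste0(canon, "||", node$semantic_type)]] <-
      node$node_id
  }
  store$idx$type[[node$semantic_type]] <-
    sort(unique(c(store$idx$type[[node$semantic_type]], node$node_id)))
  store
}

# --- edge merge -------------------------------------------------------------

#' Build a relationship-edge candidate
#'
#' @param subject,object Node ids of the endpoints.
#' @param predicate One of [kg_predicates()].
#' @param confidence Real in `[0, 1]`.
#' @param source A [source_ref()].
#' @param valid_from ISO date the assertion holds from (defaults to the
#'   source date). Validity intervals are half-open `[valid_from, valid_to)`;
#'   an absent `valid_to` means currently active.
#' @param valid_to Optional ISO date the assertion stops holding.
#' @param properties Named list of plain attribute values.
#' @param inference_method How the assertion was inferred: `"direct_kg"`,
#'   `"rule"`, `"schema_map"` or `"adjudicator"`.
#' @return An edge candidate list.
#' @export
edge_candidate <- function(subject, predicate, object, confidence, source,
                           valid_from = NULL, valid_to = NULL,
                           properties = list(),
                           inference_method = "rule") {
  list(subject = subject, predicate = predicate, object = object,
       confidence = confidence, source = source,
       valid_from = valid_from %||% source$date, valid_to = valid_to,
       properties = properties, inference_method = inference_method)
}

check_edge_syntax <- function(cand) {
  if (!cand$predicate %in% kg_predicates()) {
    kg_error("kg_syntax_error",
             paste("unknown predicate:", cand$predicate))
  }
  conf <- suppressWarnings(as.numeric(cand$confidence))
  if (length(conf) != 1L || is.na(conf) || conf < 0 || conf > 1) {
    kg_error("kg_syntax_error", "confidence must be a real in [0, 1]")
  }
  if (!is_iso_date(cand$valid_from)) {
    kg_error("kg_syntax_error",
             paste("valid_from is not an ISO-8601 date:", cand$valid_from))
  }
  if (!is.null(cand$valid_to)) {
    if (!is_iso_date(cand$valid_to)) {
      kg_error("kg_syntax_error",
               paste("valid_to is not an ISO-8601 date:", cand$valid_to))
    }
    if (as.Date(cand$valid_from) > as.Date(cand$valid_to)) {
      kg_error("kg_syntax_error", "valid_from must be <= valid_to")
    }
  }
  invisible(TRUE)
}

same_source <- function(a, b) {
  identical(a$doc_id, b$doc_id) && identical(a$date, b$date)
}

#' Merge a relationship assertion into the store
#'
#' Verifies both endpoints exist, checks syntax, and — unless the candidate
#' has already been conflict-checked — detects contradictions against the
#' exclusion policy: contradiction candidates are *not* written; the outcome
#' `"conflicted"` is returned together with the conflict reports for the
#' updater to resolve. A duplicate of the active edge on the same
#' (subject, predicate, object) collapses into it, unioning provenance,
#' keeping the maximum confidence, and enriching properties under the
#' authority rule.
#'
#' @param store A `kg_store`.
#' @param cand An [edge_candidate()].
#' @param policy A [kg_default_policy()] used for conflict detection, or
#'   `NULL` to skip detection (the updater resolves conflicts explicitly
#'   before merging).
#' @return List with `store`, `outcome` (`"created"`, `"matched"`,
#'   `"enriched"` or `"conflicted"`), `edge_id` (`NULL` when conflicted),
#'   `attrs_modified`, and `conflicts` (list of conflict reports when
#'   conflicted).
#' @export
merge_edge <- function(store, cand, policy = kg_default_policy()) {
  stopifnot(inherits(store, "kg_store"))
  if (is.null(store$nodes[[cand$subject]]) ||
      is.null(store$nodes[[cand$object]])) {
    kg_error("kg_entity_error", sprintf(
      "entity verification failed: %s or %s not in store",
      cand$subject, cand$object))
  }
  check_edge_syntax(cand)

  if (!is.null(policy)) {
    reports <- detect_conflicts(store, cand, policy)
    if (length(reports)) {
      return(list(store = store, outcome = "conflicted", edge_id = NULL,
                  attrs_modified = 0L, conflicts = reports))
    }
  }

  key <- spo_key(cand$subject, cand$predicate, cand$object)
  active_id <- store$idx$spo_active[[key]]
  if (!is.null(active_id)) {
    edge <- store$edges[[active_id]]
    changed <- FALSE
    if (!any(vapply(edge$provenance, same_source, logical(1L),
                    b = cand$source))) {
      edge$provenance <- c(edge$provenance, list(unclass(cand$source)))
      changed <- TRUE  # provenance growth: audit-only, not an attr count
    }
    if (cand$confidence > edge$confidence) {
      edge$confidence <- cand$confidence
      changed <- TRUE
    }
    props <- apply_properties(edge$properties, cand$properties %||% list(),
                              cand$source)
    if (props$changed > 0L) {
      edge$properties <- props$cells
      changed <- TRUE
    }
    store$edges[[active_id]] <- edge
    outcome <- if (changed) "enriched" else "matched"
    store$change_log <- c(store$change_log,
                          list(list(op = "merge_edge", id = active_id,
                                    outcome = outcome)))
    return(list(store = store, outcome = outcome, edge_id = active_id,
                attrs_modified = props$changed, conflicts = NULL))
  }

  k <- length(store$idx$spo[[key]]) + 1L
  edge_id <- paste0(key, "#", k)
  props <- apply_properties(list(), cand$properties %||% list(), cand$source)
  edge <- list(
    edge_id = edge_id, subject = cand$subject, predicate = cand$predicate,
    object = cand$object, confidence = as.numeric(cand$confidence),
    provenance = list(unclass(cand$source)),
    valid_from = as.character(cand$valid_from),
    valid_to = if (is.null(cand$valid_to)) NULL else
      as.character(cand$valid_to),
    inference_method = cand$inference_method %||% "rule",
    properties = props$cells
  )
  store$edges[[edge_id]] <- edge
  store$idx$spo[[key]] <- c(store$idx$spo[[key]], edge_id)
  if (is.null(edge$valid_to)) store$idx$spo_active[[key]] <- edge_id
  store$change_log <- c(store$change_log,
                        list(list(op = "merge_edge", id = edge_id,
                                  outcome = "created")))
  list(store = store, outcome = "created", edge_id = edge_id,
       attrs_modified = 0L, conflicts = NULL)
}

# Close an edge's validity interval at `date` (half-open: the edge stops
# holding at `date`). Used by conflict supersedence.
close_edge <- function(store, edge_id, date) {
  edge <- store$edges[[edge_id]]
  stopifnot(!is.null(edge))
  edge$valid_to <- as.character(date)
  store$edges[[edge_id]] <- edge
  key <- spo_key(edge$subject, edge$predicate, edge$object)
  if (identical(store$idx$spo_active[[key]], edge_id)) {
    store$idx$spo_active[[key]] <- NULL
  }
  store$change_log <- c(store$change_log,
                        list(list(op = "close_edge", id = edge_id,
                                  outcome = "superseded")))
  store
}

#' Set a node property through the authority rule
#'
#' @param store A `kg_store`.
#' @param node_id Target node.
#' @param key,value Property assignment.
#' @param source A [source_ref()] supplying tier and date for the overwrite
#'   rule.
#' @return List with `store` and `changed` (0 or 1).
#' @export
kg_set_property <- function(store, node_id, key, value, source) {
  node <- store$nodes[[node_id]]
  if (is.null(node)) kg_error("kg_entity_error",
                              paste("no such node:", node_id))
  vals <- stats::setNames(list(value), key)
  props <- apply_properties(node$properties, vals, source)
  if (props$changed > 0L) {
    node$properties <- props$cells
    store$nodes[[node_id]] <- node
    store$change_log <- c(store$change_log,
                          list(list(op = "set_property", id = node_id,
                                    outcome = key)))
  }
  list(store = store, changed = props$changed)
}

# --- lookup -----------------------------------------------------------------

#' Find nodes by name, concept code, or semantic type
#'
#' Index-backed lookup; the result equals a brute-force scan of all nodes
#' for the same key. Names are compared after canonicalization.
#'
#' @param store A `kg_store`.
#' @param name,code,semantic_type Exactly one lookup key.
#' @return Sorted character vector of node ids (empty for misses).
#' @export
kg_find <- function(store, name = NULL, code = NULL, semantic_type = NULL) {
  n_keys <- sum(!is.null(name), !is.null(code), !is.null(semantic_type))
  if (n_keys != 1L) {
    stop("supply exactly one of name, code, semantic_type", call. = FALSE)
  }
  out <- if (!is.null(name)) {
    store$idx$name[[canonicalize(name)]]
  } else if (!is.null(code)) {
    store$idx$code[[code]]
  } else {
    store$idx$type[[semantic_type]]
  }
  sort(unique(as.character(out %||% character())))
}

#' Verify that the store indices equal a full rescan
#'
#' Rebuilds every index from the raw node/edge lists and compares with the
#' incrementally maintained ones.
#'
#' @param store A `kg_store`.
#' @return `TRUE` if all indices are consistent, otherwise `FALSE`.
#' @export
kg_verify_indices <- function(store) {
  fresh <- rebuild_indices(store)
  norm <- function(idx) {
    if (!length(idx)) return(list())
    idx <- idx[order(names(idx))]
    lapply(idx, function(v) sort(unname(unlist(v))))
  }
  all(vapply(names(fresh), function(nm) {
    identical(norm(fresh[[nm]]), norm(store$idx[[nm]]))
  }, logical(1L)))
}

rebuild_indices <- function(store) {
  idx <- list(code = list(), name = list(), ident = list(),
              type = list(), spo = list(), spo_active = list())
  tmp <- store
  tmp$idx <- idx
  for (node in store$nodes) tmp <- index_node(tmp, node)
  for (edge in store$edges) {
    key <- spo_key(edge$subject, edge$predicate, edge$object)
    tmp$idx$spo[[key]] <- c(tmp$idx$spo[[key]], edge$edge_id)
    if (is.null(edge$valid_to)) tmp$idx$spo_active[[key]] <- edge$edge_id
  }
  tmp$idx
}

#' Number of nodes and edges in a store
#' @param store A `kg_store`.
#' @return Named integer vector `c(nodes = , edges = , active_edges = )`.
#' @export
kg_size <- function(store) {
  active <- sum(vapply(store$edges, function(e) is.null(e$valid_to),
                       logical(1L)))
  c(nodes = length(store$nodes), edges = length(store$edges),
    active_edges = as.integer(active))
}

#' @export
print.kg_store <- function(x, ...) {
  s <- kg_size(x)
  cat(sprintf("<kg_store> %d nodes, %d edges (%d active), %d log entries\n",
              s[["nodes"]], s[["edges"]], s[["active_edges"]],
              length(x$change_log)))
  invisible(x)
}

#' @export
summary.kg_store <- function(object, ...) {
  types <- table(vapply(object$nodes, `[[`, "", "semantic_type"))
  preds <- table(vapply(object$edges, `[[`, "", "predicate"))
  by_phase <- table(vapply(object$nodes, `[[`, "", "created_phase"))
  structure(list(size = kg_size(object), node_types = types,
                 predicates = preds, created_phase = by_phase),
            class = "summary.kg_store")
}

#' @export
print.summary.kg_store <- function(x, ...) {
  cat("knowledge-graph store\n")
  print(x$size)
  cat("\nnodes by semantic type:\n"); print(x$node_types)
  cat("\nedges by predicate:\n"); print(x$predicates)
  cat("\nnodes by creation phase:\n"); print(x$created_phase)
  invisible(x)
}
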