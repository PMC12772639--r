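# Entity retrieval, path queries and subgraph extraction over the KG, with
# half-open temporal validity filtering and deterministic answer rendering
# carrying provenance.

#' Is an edge active at a reference date?
#'
#' Validity intervals are half-open `[valid_from, valid_to)`. With
#' `as_of = NULL` (the default, "latest") an edge is active iff `valid_to`
#' is absent; with a date, iff `valid_from <= as_of` and either `valid_to`
#' is absent or `as_of < valid_to`.
#'
#' @param edge An edge record.
#' @param as_of Optional ISO date.
#' @return Logical.
#' @export
edge_active_at <- function(edge, as_of = NULL) {
  if (is.null(as_of)) return(is.null(edge$valid_to))
  d <- as.Date(as_of)
  if (as.Date(edge$valid_from) > d) return(FALSE)
  is.null(edge$valid_to) || d < as.Date(edge$valid_to)
}

active_edges <- function(store, as_of = NULL, predicates = NULL) {
  Filter(function(e) {
    (is.null(predicates) || e$predicate %in% predicates) &&
      edge_active_at(e, as_of)
  }, store$edges)
}

edge_doc_ids <- function(edges) {
  sort(unique(unlist(lapply(edges, function(e) {
    vapply(e$provenance, `[[`, "", "doc_id")
  }), use.names = FALSE)))
}

query_result <- function(kind, node_ids = character(), paths = list(),
                         subgraph = NULL, provenance = character(),
                         as_of = NULL) {
  structure(
    list(kind = kind, node_ids = node_ids, paths = paths,
         subgraph = subgraph, provenance = provenance, as_of = as_of),
    class = "kg_query_result"
  )
}

#' @export
print.kg_query_result <- function(x, ...) {
  n <- switch(x$kind, entity = length(x$node_ids),
              path = length(x$paths),
              subgraph = length(x$subgraph$nodes))
  cat(sprintf("<kg_query_result> %s query: %d result(s), %d provenance doc(s)\n",
              x$kind, n, length(x$provenance)))
  invisible(x)
}

#' Entity retrieval
#'
#' Retrieves nodes by attribute filters, optionally constrained through an
#' edge pattern ("what drugs treat diabetes" = `semantic_type = "drug"`,
#' `predicate = "TREATS"`, `object` = the diabetes node). Only edges active
#' at `as_of` count; the result equals a brute-force filter over all nodes
#' and edges.
#'
#' Supported filter keys: `semantic_type`, `name`, `code`, `property`
#' (named list), `predicate` with `object` (returns subjects) or with
#' `subject` (returns objects). Unknown keys are an error.
#'
#' @param store A `kg_store`.
#' @param filters Named list of filters.
#' @param as_of Optional ISO date.
#' @return A `kg_query_result` with sorted `node_ids` and provenance.
#' @export
entity_query <- function(store, filters, as_of = NULL) {
  known <- c("semantic_type", "name", "code", "property", "predicate",
             "subject", "object")
  bad <- setdiff(names(filters), known)
  if (length(bad)) {
    stop("unknown filter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- names(store$nodes)
  used_edges <- list()
  if (!is.null(filters$semantic_type)) {
    ids <- intersect(ids, kg_find(store,
                                  semantic_type = filters$semantic_type))
  }
  if (!is.null(filters$name)) {
    ids <- intersect(ids, kg_find(store, name = filters$name))
  }
  if (!is.null(filters$code)) {
    ids <- intersect(ids, kg_find(store, code = filters$code))
  }
  if (!is.null(filters$property)) {
    for (key in names(filters$property)) {
      want <- filters$property[[key]]
      ids <- Filter(function(id) {
        identical(as.character(kg_get_property(store, id, key) %||% ""),
                  as.character(want))
      }, ids)
    }
  }
  if (!is.null(filters$predicate)) {
    if (is.null(filters$object) && is.null(filters$subject)) {
      stop("predicate filter needs a subject or an object", call. = FALSE)
    }
    eds <- active_edges(store, as_of, predicates = filters$predicate)
    if (!is.null(filters$object)) {
      eds <- Filter(function(e) e$object == filters$object, eds)
      ids <- intersect(ids, vapply(eds, `[[`, "", "subject"))
    } else {
      eds <- Filter(function(e) e$subject == filters$subject, eds)
      ids <- intersect(ids, vapply(eds, `[[`, "", "object"))
    }
    used_edges <- eds
  }
  ids <- sort(unique(as.character(ids)))
  prov <- if (length(used_edges)) {
    edge_doc_ids(Filter(function(e)
      e$subject %in% ids | e$object %in% ids, used_edges))
  } else {
    sort(unique(vapply(store$nodes[ids],
                       function(n) n$created_by$doc_id, "")))
  }
  query_result("entity", node_ids = ids, provenance = prov, as_of = as_of)
}

#' Path queries
#'
#' All simple directed paths (no repeated nodes) from `source` to `target`
#' using at most `max_hops` edges that are active at `as_of` and whose
#' predicate is allowed. Paths are ordered deterministically by length,
#' then lexicographically by their node-id sequence.
#'
#' @param store A `kg_store`.
#' @param source,target Node ids (must exist).
#' @param max_hops Maximum number of edges per path (>= 1).
#' @param predicates Optional allowed predicate set.
#' @param as_of Optional ISO date.
#' @return A `kg_query_result`; each path is a list with `nodes` (node-id
#'   vector) and `edges` (edge-id vector).
#' @export
path_query <- function(store, source, target, max_hops,
                       predicates = NULL, as_of = NULL) {
  if (is.null(store$nodes[[source]]) || is.null(store$nodes[[target]])) {
    kg_error("kg_entity_error", "path endpoints must exist in the store")
  }
  stopifnot(max_hops >= 1L)
  eds <- active_edges(store, as_of, predicates)
  adj <- list()
  for (e in eds) adj[[e$subject]] <- c(adj[[e$subject]], list(e))
  paths <- list()
  walk <- function(node, nodes, edges) {
    if (node == target && length(edges)) {
      paths[[length(paths) + 1L]] <<- list(nodes = nodes, edges = edges)
      return()
    }
    if (length(edges) >= max_hops) return()
    for (e in adj[[node]] %||% list()) {
      if (e$object %in% nodes) next  # simple paths only
      walk(e$object, c(nodes, e$object), c(edges, e$edge_id))
    }
  }
  walk(source, source, character())
  if (length(paths)) {
    keys <- vapply(paths, function(p)
      sprintf("%03d|%s", length(p$edges),
              paste(p$nodes, collapse = "->")), "")
    paths <- paths[order(keys)]
  }
  prov <- edge_doc_ids(lapply(unique(unlist(lapply(paths, `[[`, "edges"))),
                              function(id) store$edges[[id]]))
  query_result("path", paths = paths, provenance = prov, as_of = as_of)
}

#' Subgraph extraction
#'
#' Returns the subgraph induced by all nodes within `radius` hops
#' (following active edges in either direction) of the seed nodes: the
#' selected nodes plus *all* active edges among them, with full provenance.
#' Radius 0 returns the seeds only. The result's `subgraph` is itself a
#' `kg_store`, so extracting the same neighborhood again is a fixed point.
#'
#' @param store A `kg_store`.
#' @param seeds Character vector of node ids (must exist).
#' @param radius Hop radius (>= 0).
#' @param filters Optional list; `filters$semantic_type` restricts which
#'   node types the expansion may pull in (seeds are always kept).
#' @param as_of Optional ISO date.
#' @return A `kg_query_result` whose `subgraph` is a `kg_store`.
#' @export
subgraph_query <- function(store, seeds, radius, filters = NULL,
                           as_of = NULL) {
  missing <- seeds[!seeds %in% names(store$nodes)]
  if (length(missing)) {
    kg_error("kg_entity_error", paste(
      "seed node(s) not in store:", paste(missing, collapse = ", ")))
  }
  stopifnot(radius >= 0L)
  eds <- active_edges(store, as_of)
  keep_type <- function(id) {
    is.null(filters$semantic_type) ||
      store$nodes[[id]]$semantic_type %in% filters$semantic_type
  }
  selected <- unique(seeds)
  frontier <- selected
  for (hop in seq_len(radius)) {
    nxt <- character()
    for (e in eds) {
      if (e$subject %in% frontier && !e$object %in% selected &&
          keep_type(e$object)) {
        nxt <- c(nxt, e$object)
      }
      if (e$object %in% frontier && !e$subject %in% selected &&
          keep_type(e$subject)) {
        nxt <- c(nxt, e$subject)
      }
    }
    nxt <- unique(nxt)
    if (!length(nxt)) break
    selected <- c(selected, nxt)
    frontier <- nxt
  }
  selected <- sort(unique(selected))
  sub <- kg_store()
  for (id in selected) sub$nodes[[id]] <- store$nodes[[id]]
  induced <- if (radius == 0L) list() else
    Filter(function(e) e$subject %in% selected && e$object %in% selected,
           eds)
  for (e in induced) sub$edges[[e$edge_id]] <- e
  sub$idx <- rebuild_indices(sub)
  query_result("subgraph", node_ids = selected, subgraph = sub,
               provenance = edge_doc_ids(induced), as_of = as_of)
}

#' Render a query result as text
#'
#' The template renderer lists the matched preferred names sorted
#' lexicographically and appends the provenance document ids; an empty
#' result renders the fixed sentence
#' `"no supporting evidence in graph"`. A pluggable generator backend
#' (`renderer(store, result, question)`) replaces the template; its output
#' is passed through unmodified, still accompanied by the provenance.
#'
#' @param result A `kg_query_result`.
#' @param store The `kg_store` the query ran against.
#' @param renderer Optional generator backend.
#' @param question Optional question text handed to the backend.
#' @return List with `text` and `provenance`.
#' @export
render_answer <- function(result, store, renderer = NULL, question = NULL) {
  if (!is.null(renderer)) {
    return(list(text = renderer(store, result, question),
                provenance = result$provenance))
  }
  empty <- switch(result$kind,
                  entity = length(result$node_ids) == 0L,
                  path = length(result$paths) == 0L,
                  subgraph = length(result$subgraph$nodes) == 0L)
  if (empty) {
    return(list(text = "no supporting evidence in graph",
                provenance = character()))
  }
  name_of <- function(id) store$nodes[[id]]$preferred_name %||% id
  text <- switch(result$kind,
    entity = paste0(
      paste(sort(vapply(result$node_ids, name_of, "")), collapse = "; ")),
    path = paste(vapply(result$paths, function(p)
      paste(vapply(p$nodes, name_of, ""), collapse = " -> "), ""),
      collapse = " | "),
    subgraph = paste0(
      paste(sort(vapply(names(result$subgraph$nodes), name_of, "")),
            collapse = "; "))
  )
  list(text = sprintf("%s. [sources: %s]", text,
                      paste(result$provenance, collapse = ", ")),
       provenance = result$provenance)
}
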