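# Serialization: two JSON-Lines files (nodes.jsonl, edges.jsonl) with keys
# emitted in sorted order and records sorted by id, so two serializations of
# the same store are byte-identical. The change log is in-memory bookkeeping
# and is not persisted.

sorted_record_json <- function(rec) {
  rec <- rec[!vapply(rec, is.null, logical(1L))]
  rec <- rec[order(names(rec))]
  rec <- lapply(rec, function(v) {
    if (is.list(v) && length(v) && !is.null(names(v))) {
      v[order(names(v))]
    } else v
  })
  jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Serialize a store to JSON-Lines files
#'
#' Writes `nodes.jsonl` and `edges.jsonl` (one UTF-8 JSON record per line,
#' ISO-8601 dates, keys in sorted order, records sorted by id). The
#' round-trip through [kg_deserialize()] reproduces the node/edge multisets,
#' properties, provenance and validity intervals exactly, and serializing
#' again yields byte-identical files.
#'
#' @param store A `kg_store`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
kg_serialize <- function(store, dir) {
  stopifnot(inherits(store, "kg_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  node_ids <- sort(names(store$nodes))
  node_lines <- vapply(node_ids, function(id) {
    as.character(sorted_record_json(store$nodes[[id]]))
  }, "")
  edge_ids <- sort(names(store$edges))
  edge_lines <- vapply(edge_ids, function(id) {
    rec <- store$edges[[id]]
    rec$provenance <- lapply(rec$provenance, function(p) p[order(names(p))])
    as.character(sorted_record_json(rec))
  }, "")
  writeLines(node_lines, file.path(dir, "nodes.jsonl"), useBytes = TRUE)
  writeLines(edge_lines, file.path(dir, "edges.jsonl"), useBytes = TRUE)
  invisible(dir)
}

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop("parse error in ", basename(path), " at line ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  })
}

#' Deserialize a store from JSON-Lines files
#'
#' @param dir Directory holding `nodes.jsonl` and `edges.jsonl`.
#' @return A `kg_store` with rebuilt indices. Malformed lines raise a parse
#'   error naming the file and line.
#' @export
kg_deserialize <- function(dir) {
  store <- kg_store()
  for (rec in read_jsonl(file.path(dir, "nodes.jsonl"))) {
    rec$concept_ids <- as.character(unlist(rec$concept_ids %||% list()))
    store$nodes[[rec$node_id]] <- rec
  }
  for (rec in read_jsonl(file.path(dir, "edges.jsonl"))) {
    rec$confidence <- as.numeric(rec$confidence)
    store$edges[[rec$edge_id]] <- rec
  }
  store$idx <- rebuild_indices(store)
  store
}

#' Export the graph as a Cypher script
#'
#' Writes `MERGE` statements for every node and `CREATE` statements for
#' every edge, suitable for loading into an external graph database. This
#' is an export only; nothing is ever executed by this package.
#'
#' @param store A `kg_store`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
kg_export_cypher <- function(store, path) {
  esc <- function(x) gsub("'", "\\\\'", as.character(x))
  lines <- character()
  for (id in sort(names(store$nodes))) {
    n <- store$nodes[[id]]
    lines <- c(lines, sprintf(
      "MERGE (n:%s {node_id: '%s'}) SET n.name = '%s', n.codes = '%s';",
      n$semantic_type, esc(id), esc(n$preferred_name %||% ""),
      esc(paste(n$concept_ids, collapse = ","))))
  }
  for (id in sort(names(store$edges))) {
    e <- store$edges[[id]]
    lines <- c(lines, sprintf(
      paste0("MATCH (a {node_id: '%s'}), (b {node_id: '%s'}) ",
             "CREATE (a)-[:%s {confidence: %s, valid_from: '%s'%s}]->(b);"),
      esc(e$subject), esc(e$object), e$predicate,
      format(e$confidence), esc(e$valid_from),
      if (is.null(e$valid_to)) "" else
        sprintf(", valid_to: '%s'", esc(e$valid_to))))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
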