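#' Knowledge-graph container
#'
#' A `knowledge_graph` holds a typed, directed multigraph as a triple table
#' (head, relation, tail) plus an entity registry with one node-type label per
#' entity (e.g. `"Drug"`, `"Protein"`, `"Pathology"`). Duplicate triples are
#' collapsed into a `count` column by default, so embedding training can treat
#' repetition as weight while reporting stays faithful to the multiset.
#'
#' @param triples data.frame with character columns `head`, `relation`, `tail`
#'   (an optional `count` column of positive integers is honoured).
#' @param entity_type optional named character vector mapping entity -> type
#'   label; entities absent from it get type `"Unknown"`.
#' @param dedup collapse duplicated (head, relation, tail) rows into counts
#'   (default `TRUE`). With `dedup = FALSE` duplicates are kept as rows with
#'   `count = 1`.
#' @return object of class `knowledge_graph` with elements `triples`
#'   (data.frame head/relation/tail/count), `entities`, `entity_type`,
#'   `relations` (sorted relation vocabulary).
#' @examples
#' tr <- data.frame(head = c("A", "B"), relation = c("up", "down"),
#'                  tail = c("B", "C"))
#' kg <- knowledge_graph(tr, entity_type = c(A = "Drug", B = "Protein"))
#' kg_stats(kg)
#' @export
knowledge_graph <- function(triples, entity_type = NULL, dedup = TRUE) {
  stopifnot(is.data.frame(triples))
  need <- c("head", "relation", "tail")
  if (!all(need %in% names(triples)))
    abort("triple table must have columns head, relation, tail")
  tr <- data.frame(head = as.character(triples$head),
                   relation = as.character(triples$relation),
                   tail = as.character(triples$tail),
                   count = if ("count" %in% names(triples))
                     as.integer(triples$count) else rep(1L, nrow(triples)),
                   stringsAsFactors = FALSE)
  if (nrow(tr) && any(!is.finite(tr$count) | tr$count < 1L))
    abort("triple counts must be positive integers")
  if (dedup && nrow(tr)) {
    key <- paste(tr$head, tr$relation, tr$tail, sep = "\r")
    agg <- rowsum(tr$count, group = key, reorder = FALSE)
    first <- !duplicated(key)
    tr <- tr[first, , drop = FALSE]
    tr$count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
    rownames(tr) <- NULL
  }
  entities <- sort(unique(c(tr$head, tr$tail)))
  types <- setNames(rep("Unknown", length(entities)), entities)
  if (!is.null(entity_type)) {
    entity_type <- setNames(as.character(entity_type), names(entity_type))
    hit <- intersect(names(entity_type), entities)
    types[hit] <- entity_type[hit]
  }
  structure(list(triples = tr, entities = entities, entity_type = types,
                 relations = sort(unique(tr$relation))),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  s <- kg_stats(x)
  cat(sprintf("Knowledge graph: %d entities (%d types), %d triples (%d unique), %d relation types\n",
              s$n_entities, s$n_node_types, s$n_triples, s$n_unique_triples,
              s$n_relations))
  invisible(x)
}

#' @export
summary.knowledge_graph <- function(object, ...) {
  s <- kg_stats(object)
  cat(sprintf("Entities: %d\nTriples:  %d (%d unique)\nRelations: %d\n",
              s$n_entities, s$n_triples, s$n_unique_triples, s$n_relations))
  cat("Node types:\n")
  print(s$type_counts)
  invisible(s)
}

#' Basic node/edge statistics of a knowledge graph
#'
#' @param kg a [knowledge_graph()].
#' @return list with `n_entities`, `n_triples` (multiset size), and
#'   `n_unique_triples`, `n_relations`, `n_node_types`, `type_counts`.
#' @export
kg_stats <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  list(n_entities = length(kg$entities),
       n_triples = sum(kg$triples$count),
       n_unique_triples = nrow(kg$triples),
       n_relations = length(kg$relations),
       n_node_types = length(unique(kg$entity_type)),
       type_counts = sort(table(kg$entity_type), decreasing = TRUE))
}

#' Read a knowledge graph from an edge-list TSV
#'
#' The dialect is three mandatory tab-separated columns (source, relation,
#' target); node types come from a companion two-column labels TSV
#' (node `\t` type). Rows with a different field count raise a parse error
#' naming the offending line.
#'
#' @param path edge-list TSV path.
#' @param labels_path optional labels TSV path (node, type); entities named in
#'   the label table but absent from the graph trigger a warning.
#' @param has_header whether the first line of each file is a header.
#' @param dedup collapse duplicate triples (default `TRUE`).
#' @return a [knowledge_graph()].
#' @export
read_kg_tsv <- function(path, labels_path = NULL, has_header = FALSE,
                        dedup = TRUE) {
  if (!file.exists(path)) abort("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  first_data <- if (has_header) 2L else 1L
  if (length(nf) >= first_data) {
    bad <- which(nf[first_data:length(nf)] < 3L)
    if (length(bad))
      abort("malformed row at line %d of %s: expected >= 3 tab-separated fields, found %d",
            bad[1L] + first_data - 1L, path, nf[bad[1L] + first_data - 1L])
  }
  tr <- read.delim(path, header = has_header, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) abort("empty edge list: %s", path)
  tr <- tr[, 1:3]
  names(tr) <- c("head", "relation", "tail")
  types <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path)) abort("no such file: %s", labels_path)
    lab <- read.delim(labels_path, header = has_header, sep = "\t", quote = "",
                      colClasses = "character", stringsAsFactors = FALSE)
    if (ncol(lab) < 2L) abort("labels table needs two columns (node, type)")
    types <- setNames(lab[[2L]], lab[[1L]])
    known <- unique(c(tr$head, tr$tail))
    stray <- setdiff(names(types), known)
    if (length(stray))
      warn("%d labelled entit%s not present in the edge list (type kept, node ignored)",
           length(stray), if (length(stray) == 1L) "y" else "ies")
  }
  knowledge_graph(tr, entity_type = types, dedup = dedup)
}

#' Write a knowledge graph to the edge-list TSV dialect
#'
#' Duplicate triples are expanded back to one row each, so a
#' read -> write -> read round trip reproduces the triple multiset. Output is
#' UTF-8 with LF line endings.
#'
#' @param kg a [knowledge_graph()].
#' @param path output edge-list TSV.
#' @param labels_path optional output path for the node/type labels TSV.
#' @return `path`, invisibly.
#' @export
write_kg_tsv <- function(kg, path, labels_path = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  idx <- rep(seq_len(nrow(kg$triples)), kg$triples$count)
  out <- kg$triples[idx, c("head", "relation", "tail")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  if (!is.null(labels_path)) {
    lab <- data.frame(node = names(kg$entity_type), type = unname(kg$entity_type))
    write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}
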