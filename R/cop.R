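# Causal-only pharmacome construction: whitelist causal relations, sweep
# isolated nodes, remove hub nodes.

CAUSAL_WHITELIST <- c("increases", "decreases", "causes_no_change")

#' Keep only whitelisted (causal) relations
#'
#' Removes every triple whose relation is not in the whitelist; the entity
#' registry is untouched at this step (isolated entities are swept separately
#' by [drop_isolated()]).
#'
#' @param kg a [knowledge_graph()].
#' @param whitelist relation labels to keep (default
#'   increases/decreases/causes_no_change). Labels absent from the graph's
#'   vocabulary trigger a warning.
#' @return filtered [knowledge_graph()] (with the full entity registry).
#' @export
filter_causal <- function(kg, whitelist = CAUSAL_WHITELIST) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (length(whitelist) == 0L) abort("whitelist must be non-empty")
  unknown <- setdiff(whitelist, kg$relations)
  if (length(unknown))
    warn("whitelist label(s) not in relation vocabulary: %s",
         paste(unknown, collapse = ", "))
  tr <- kg$triples[kg$triples$relation %in% whitelist, , drop = FALSE]
  if (nrow(tr) == 0L)
    abort("no triples survive the causal whitelist (over-aggressive whitelist?)")
  out <- knowledge_graph(tr, entity_type = kg$entity_type)
  # keep the original registry: entities may be isolated at this stage
  out$entities <- kg$entities
  out$entity_type <- kg$entity_type
  out
}

#' Drop entities with no incident triples
#'
#' @param kg a [knowledge_graph()].
#' @return graph with zero-degree entities removed; idempotent.
#' @export
drop_isolated <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  connected <- unique(c(kg$triples$head, kg$triples$tail))
  out <- kg
  out$entities <- intersect(kg$entities, sort(connected))
  out$entity_type <- kg$entity_type[out$entities]
  out
}

#' Remove hub nodes (by node type and/or degree threshold)
#'
#' Deletes nodes matching the hub rule together with their incident triples,
#' then sweeps newly isolated nodes. By default the rule targets disease
#' (`"Pathology"`) nodes, the dominant hubs of a pharmacome; an optional
#' degree threshold additionally removes any node whose undirected degree
#' (counting multiplicity) exceeds it.
#'
#' @param kg a [knowledge_graph()].
#' @param hub_types node-type labels to remove (default `"Pathology"`; use
#'   `character(0)` for none).
#' @param degree_threshold optional numeric; nodes with degree strictly above
#'   it are removed.
#' @return pruned graph with attribute `removal_log`, a data.frame of
#'   (node, reason, degree).
#' @export
remove_hubs <- function(kg, hub_types = "Pathology", degree_threshold = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (!is.null(degree_threshold) && degree_threshold <= 0)
    abort("degree_threshold must be positive")
  deg_tab <- rowsum(c(kg$triples$count, kg$triples$count),
                    group = c(kg$triples$head, kg$triples$tail))
  deg <- setNames(deg_tab[, 1L], rownames(deg_tab))
  degree_of <- function(v) ifelse(is.na(deg[v]), 0, deg[v])
  by_type <- kg$entities[kg$entity_type[kg$entities] %in% hub_types]
  by_deg <- if (!is.null(degree_threshold))
    names(deg)[deg > degree_threshold] else character(0)
  hubs <- union(by_type, by_deg)
  if (length(hubs) == 0L) {
    out <- kg
    attr(out, "removal_log") <- data.frame(node = character(),
                                           reason = character(),
                                           degree = numeric())
    return(out)
  }
  tr <- kg$triples[!(kg$triples$head %in% hubs | kg$triples$tail %in% hubs), ,
                   drop = FALSE]
  if (nrow(tr) == 0L) abort("hub removal would empty the graph")
  keep_entities <- setdiff(kg$entities, hubs)
  out <- knowledge_graph(tr, entity_type = kg$entity_type[keep_entities])
  out$entities <- keep_entities
  out$entity_type <- kg$entity_type[keep_entities]
  out <- drop_isolated(out)
  attr(out, "removal_log") <- data.frame(
    node = hubs,
    reason = ifelse(hubs %in% by_type & hubs %in% by_deg, "type+degree",
                    ifelse(hubs %in% by_type, "type", "degree")),
    degree = as.numeric(degree_of(hubs)))
  out
}

#' Build the causal-only pharmacome (COP)
#'
#' Fixed pipeline: [filter_causal()] -> [drop_isolated()] -> [remove_hubs()]
#' (which re-sweeps isolated nodes). A disease-retained companion copy — the
#' same graph without the hub-removal step — is produced in the same run for
#' pathway confirmation, so the two versions always share provenance.
#'
#' @param kg a [knowledge_graph()].
#' @param whitelist causal relation whitelist.
#' @param hub_types,degree_threshold hub rule, see [remove_hubs()].
#' @return list with `cop`, `cop_with_disease` (hub nodes retained) and
#'   `removal_log`.
#' @export
build_cop <- function(kg, whitelist = CAUSAL_WHITELIST,
                      hub_types = "Pathology", degree_threshold = NULL) {
  causal <- drop_isolated(filter_causal(kg, whitelist))
  cop <- remove_hubs(causal, hub_types = hub_types,
                     degree_threshold = degree_threshold)
  list(cop = cop, cop_with_disease = causal,
       removal_log = attr(cop, "removal_log"))
}
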