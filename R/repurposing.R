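# Repurposing: synergistic partners of anchor drugs, safety filter, shared
# pathway evidence in the disease-retained causal graph.

#' Ranked synergistic partners per anchor drug
#'
#' For each anchor (a drug commonly prescribed for the target disease), lists
#' the drugs predicted to be its synergistic partners, sorted by the pair's
#' synergy score descending. Partners on the safety exclusion list are
#' flagged `safety_pass = FALSE` but retained with their rank, so the report
#' stays auditable.
#'
#' @param synergy_set the `synergism` data.frame from [segregate()] (columns
#'   `drug_a`, `drug_b`, `pair_score`).
#' @param anchors character vector of anchor drugs.
#' @param exclusion character vector of unsafe drugs.
#' @return data.frame: `anchor`, `candidate`, `pair_score`, `rank` (per
#'   anchor), `safety_pass`. Anchors with no predicted partners contribute no
#'   rows (with a warning).
#' @export
candidate_partners <- function(synergy_set, anchors, exclusion = character(0)) {
  stopifnot(is.data.frame(synergy_set))
  if (length(anchors) == 0L) abort("no anchor drugs supplied")
  out <- list()
  for (anchor in anchors) {
    hit_a <- synergy_set$drug_a == anchor
    hit_b <- synergy_set$drug_b == anchor
    d <- synergy_set[hit_a | hit_b, , drop = FALSE]
    if (nrow(d) == 0L) {
      warn("anchor %s has no predicted synergistic partners", anchor)
      next
    }
    partner <- ifelse(d$drug_a == anchor, d$drug_b, d$drug_a)
    sc <- if ("pair_score" %in% names(d)) d$pair_score
          else pmin(d$forward_score, d$reverse_score)
    ord <- order(-sc, partner)
    out[[anchor]] <- data.frame(anchor = anchor, candidate = partner[ord],
                                pair_score = sc[ord],
                                rank = seq_along(ord),
                                safety_pass = !(partner[ord] %in% exclusion))
  }
  if (length(out) == 0L)
    return(data.frame(anchor = character(), candidate = character(),
                      pair_score = numeric(), rank = integer(),
                      safety_pass = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared pathways between two drugs and a disease
#'
#' Enumerates simple paths (no repeated nodes) from each drug to the disease
#' node, up to `max_len` edges, traversing causal edges direction-agnostically
#' while recording the relation of every step. Pairs of paths — one per drug —
#' that share at least one interior node are returned sorted by combined
#' length ascending. A disease absent from the graph is reported as
#' `"no_disease_node"`, distinct from a present-but-unreachable disease
#' (`"no_connecting_pathways"`).
#'
#' @param kg the disease-retained causal [knowledge_graph()].
#' @param drug_a,drug_b the two drugs of a predicted synergistic combination
#'   (typically anchor and candidate).
#' @param disease disease node identifier.
#' @param max_len maximum path length in edges (>= 2; default 4).
#' @return list with `status` (`"ok"`, `"no_disease_node"`,
#'   `"no_connecting_pathways"`) and `pairings`: a list of
#'   `list(path_a, path_b, shared)` where each path is a data.frame of steps
#'   (`from`, `relation`, `to`) and `shared` is the common interior node set.
#' @export
shared_pathways <- function(kg, drug_a, drug_b, disease, max_len = 4L) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (max_len < 2L) abort("max_len must be >= 2")
  if (!disease %in% kg$entities)
    return(list(status = "no_disease_node", pairings = list()))
  for (d in c(drug_a, drug_b))
    if (!d %in% kg$entities) abort("drug not in graph: %s", d)
  g <- kg_igraph(kg)
  paths_of <- function(drug) {
    ps <- igraph::all_simple_paths(g, from = drug, to = disease,
                                   cutoff = max_len)
    lapply(ps, function(p) igraph::V(g)$name[as.integer(p)])
  }
  pa <- paths_of(drug_a)
  pb <- paths_of(drug_b)
  if (length(pa) == 0L || length(pb) == 0L)
    return(list(status = "no_connecting_pathways", pairings = list()))
  annotate <- function(nodes) {
    n <- length(nodes)
    steps <- data.frame(from = nodes[-n], to = nodes[-1L])
    steps$relation <- vapply(seq_len(n - 1L), function(i) {
      hit <- kg$triples$relation[
        (kg$triples$head == nodes[i] & kg$triples$tail == nodes[i + 1L]) |
        (kg$triples$head == nodes[i + 1L] & kg$triples$tail == nodes[i])]
      hit[1L]
    }, character(1))
    steps[, c("from", "relation", "to")]
  }
  pairings <- list()
  for (i in seq_along(pa)) {
    ia <- pa[[i]][-c(1L, length(pa[[i]]))]
    for (j in seq_along(pb)) {
      ib <- pb[[j]][-c(1L, length(pb[[j]]))]
      shared <- intersect(ia, ib)
      if (length(shared))
        pairings[[length(pairings) + 1L]] <-
          list(path_a = pa[[i]], path_b = pb[[j]], shared = shared,
               total_len = (length(pa[[i]]) - 1L) + (length(pb[[j]]) - 1L))
    }
  }
  if (length(pairings) == 0L)
    return(list(status = "ok", pairings = list()))
  ord <- order(vapply(pairings, `[[`, numeric(1), "total_len"))
  pairings <- lapply(pairings[ord], function(p)
    list(path_a = annotate(p$path_a), path_b = annotate(p$path_b),
         shared = p$shared))
  list(status = "ok", pairings = pairings)
}

#' Assemble the candidate repurposing report
#'
#' Joins per-anchor synergy ranks with pathway evidence and assigns each
#' candidate a verdict: `"excluded"` when the safety filter fails (regardless
#' of pathways), `"pathway_supported"` when safe with at least one shared
#' pathway to the disease, `"synergy_only"` when safe but without pathway
#' evidence.
#'
#' @param candidates output of [candidate_partners()].
#' @param pathway_results named list keyed `"anchor||candidate"` (see
#'   [pair_key()]-style keys built as `paste(anchor, candidate, sep = "||")`)
#'   of [shared_pathways()] results; entries may be missing (treated as no
#'   evidence).
#' @param disease disease identifier recorded in the report.
#' @return data.frame of class `candidate_report`: `disease`, `anchor`,
#'   `candidate`, `pair_score`, `rank`, `safety_pass`, `n_pathways`,
#'   `pathway_status`, `verdict`; the evidence lists are attached as attribute
#'   `evidence`.
#' @export
build_report <- function(candidates, pathway_results, disease = NA_character_) {
  stopifnot(is.data.frame(candidates))
  key <- paste(candidates$anchor, candidates$candidate, sep = "||")
  n_path <- vapply(key, function(k) {
    pr <- pathway_results[[k]]
    if (is.null(pr)) 0L else length(pr$pairings)
  }, integer(1))
  status <- vapply(key, function(k) {
    pr <- pathway_results[[k]]
    if (is.null(pr)) "not_searched" else pr$status
  }, character(1))
  verdict <- ifelse(!candidates$safety_pass, "excluded",
                    ifelse(n_path > 0L, "pathway_supported", "synergy_only"))
  out <- data.frame(disease = rep(disease, length.out = nrow(candidates)),
                    anchor = candidates$anchor,
                    candidate = candidates$candidate,
                    pair_score = candidates$pair_score,
                    rank = candidates$rank,
                    safety_pass = candidates$safety_pass,
                    n_pathways = unname(n_path),
                    pathway_status = unname(status),
                    verdict = unname(verdict))
  attr(out, "evidence") <- pathway_results
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' One-call repurposing nomination
#'
#' Convenience wrapper chaining [candidate_partners()], [shared_pathways()]
#' per (anchor, candidate) pair and [build_report()].
#'
#' @param synergy_set segregated synergism predictions (see [segregate()]).
#' @param anchors anchor drugs for the disease.
#' @param exclusion safety exclusion list.
#' @param kg disease-retained causal [knowledge_graph()].
#' @param disease disease node identifier.
#' @param max_len maximum pathway length in edges.
#' @return a `candidate_report` (see [build_report()]).
#' @export
nominate_candidates <- function(synergy_set, anchors, exclusion, kg, disease,
                                max_len = 4L) {
  cand <- candidate_partners(synergy_set, anchors, exclusion)
  pw <- list()
  for (i in seq_len(nrow(cand))) {
    k <- paste(cand$anchor[i], cand$candidate[i], sep = "||")
    pw[[k]] <- shared_pathways(kg, cand$anchor[i], cand$candidate[i],
                               disease, max_len = max_len)
  }
  build_report(cand, pw, disease = disease)
}
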