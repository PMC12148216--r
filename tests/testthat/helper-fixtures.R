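# Shared fixture builders. Everything is generated in code at test time.

toy_triples <- function() {
  data.frame(head = c("A", "B"), relation = c("up", "down"),
             tail = c("B", "C"))
}

# A small typed graph with drugs, proteins and a pathology hub, mixing causal
# and noncausal relations.
schema_kg <- function() {
  tr <- data.frame(
    head = c("drugA", "drugA", "drugB", "prot1", "prot2", "gene1",
             "drugA", "drugB", "prot1", "prot2"),
    relation = c("increases", "decreases", "increases", "decreases",
                 "causes_no_change", "increases",
                 "association", "in_complex_with", "association",
                 "association"),
    tail = c("prot1", "prot2", "prot2", "gene1", "gene1", "disease1",
             "prot2", "prot1", "disease1", "disease1"))
  types <- c(drugA = "Drug", drugB = "Drug", prot1 = "Protein",
             prot2 = "Protein", gene1 = "Gene", disease1 = "Pathology")
  knowledge_graph(tr, entity_type = types)
}

# Small planted KG reused across embedding tests (cheap: 30 entities).
small_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_planted_kg(synthetic_spec(
        n_entities = 30L, n_relations = 3L, n_drugs = 10L,
        embedding_dim = 8L, triple_budget = 100L, seed = 0L))
    cache
  }
})

# A tiny trained model over a graph containing combination relations, for
# pair-prediction plumbing tests.
tiny_combo_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(42)
      drugs <- paste0("D", 1:6)
      prot <- paste0("P", 1:4)
      tr <- rbind(
        data.frame(head = c("D1", "D2", "D3", "D4"),
                   relation = "has_synergism_with",
                   tail = c("D2", "D1", "D4", "D3")),
        data.frame(head = c("D5", "D6"), relation = "has_antagonism_with",
                   tail = c("D6", "D5")),
        data.frame(head = sample(drugs, 12, TRUE), relation = "targets",
                   tail = sample(prot, 12, TRUE)))
      tr <- tr[!(tr$head == tr$tail), ]
      kg <- knowledge_graph(tr, entity_type = setNames(
        c(rep("Drug", 6), rep("Protein", 4)), c(drugs, prot)))
      cache <<- list(kg = kg,
                     fit = kge(kg, model = "TransE", dim = 8, epochs = 30,
                               batch_size = 16, seed = 7))
    }
    cache
  }
})

# Independent trapezoidal ROC-AUC oracle (kept deliberately different from
# the package's Mann-Whitney implementation).
trapezoid_auc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(scores[labels == 1] >= s),
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(s) mean(scores[labels == 0] >= s),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive simple-path enumerator (undirected, <= max_len edges).
brute_simple_paths <- function(edges, from, to, max_len) {
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == to && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (nxt in unique(adj[[cur]]))
      if (!nxt %in% path) walk(c(path, nxt))
  }
  walk(from)
  out
}

# Synthetic separable pair-feature set for classifier tests: the class is a
# function of the first two features, the rest are distractors.
separable_features <- function(n = 300, p = 10, noise = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  lin <- x[, 1] - x[, 2]
  y <- ifelse(lin + rnorm(n, sd = noise) > 0, "synergism", "antagonism")
  list(x = x, y = y)
}
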