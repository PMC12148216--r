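syn_set <- function() {
  data.frame(drug_a = c("anchor1", "anchor1", "anchor1", "anchor2"),
             drug_b = c("cand1", "cand2", "cand3", "cand1"),
             pair_score = c(-1, -2, -3, -0.5))
}

test_that("candidate partners are ranked per anchor with safety flags", {
  cand <- candidate_partners(syn_set(), c("anchor1", "anchor2"),
                             exclusion = "cand2")
  a1 <- cand[cand$anchor == "anchor1", ]
  expect_equal(nrow(a1), 3L)
  expect_equal(a1$candidate, c("cand1", "cand2", "cand3"))
  expect_equal(a1$rank, 1:3)
  expect_equal(a1$safety_pass, c(TRUE, FALSE, TRUE))
  # a partner synergistic with two anchors appears under both, ranked per anchor
  expect_equal(cand$rank[cand$anchor == "anchor2" &
                         cand$candidate == "cand1"], 1L)
  # empty synergy set -> empty report (with a warning about the anchor)
  expect_warning(empty <- candidate_partners(syn_set()[0, ], "anchor1"),
                 "no predicted")
  expect_equal(nrow(empty), 0L)
  expect_warning(candidate_partners(syn_set(), "ghost"), "no predicted")
})

pathway_kg <- function() {
  tr <- data.frame(
    head = c("A", "P1", "B", "P1", "B", "P2", "C"),
    relation = "increases",
    tail = c("P1", "Dis", "P1", "Dis", "P2", "Dis", "P3"))
  knowledge_graph(tr, entity_type = c(A = "Drug", B = "Drug", C = "Drug",
                                      P1 = "Protein", P2 = "Protein",
                                      P3 = "Protein", Dis = "Pathology"))
}

test_that("shared pathways find converging interior nodes", {
  kg <- pathway_kg()
  res <- shared_pathways(kg, "A", "B", "Dis", max_len = 3)
  expect_equal(res$status, "ok")
  expect_gte(length(res$pairings), 1L)
  expect_true("P1" %in% res$pairings[[1]]$shared)
  # each path is annotated with per-step relations
  expect_named(res$pairings[[1]]$path_a, c("from", "relation", "to"))
  # drug with no route inside max_len -> no pairings
  res2 <- shared_pathways(kg, "A", "C", "Dis", max_len = 2)
  expect_equal(res2$status, "no_connecting_pathways")
  # disease absent from the graph is distinguished from unreachable
  res3 <- shared_pathways(kg, "A", "B", "COVID", max_len = 3)
  expect_equal(res3$status, "no_disease_node")
  expect_error(shared_pathways(kg, "A", "B", "Dis", max_len = 1), ">= 2")
})

test_that("emitted paths are simple and bounded, matching brute-force search", {
  set.seed(77)
  for (i in 1:5) {
    n <- 12
    ed <- data.frame(head = paste0("n", sample(n, 18, TRUE)),
                     relation = "increases",
                     tail = paste0("n", sample(n, 18, TRUE)))
    ed <- ed[ed$head != ed$tail, ]
    types <- setNames(rep("Protein", n), paste0("n", 1:n))
    types[c("n1", "n2")] <- "Drug"
    types["n3"] <- "Pathology"
    kg <- knowledge_graph(ed, entity_type = types)
    if (!all(c("n1", "n2", "n3") %in% kg$entities)) next
    res <- shared_pathways(kg, "n1", "n2", "n3", max_len = 4)
    edges <- unique(kg$triples[, c("head", "tail")])
    names(edges) <- c("from", "to")
    brute_a <- brute_simple_paths(edges, "n1", "n3", 4)
    brute_b <- brute_simple_paths(edges, "n2", "n3", 4)
    if (res$status == "no_connecting_pathways")
      expect_true(length(brute_a) == 0 || length(brute_b) == 0)
    for (p in res$pairings) {
      nodes_a <- c(p$path_a$from, p$path_a$to[nrow(p$path_a)])
      expect_equal(anyDuplicated(nodes_a), 0L)
      expect_lte(nrow(p$path_a), 4L)
      expect_true(any(vapply(brute_a, function(bp)
        identical(bp, nodes_a), logical(1))))
    }
    # pairing count equals the brute-force count of interior-sharing pairs
    n_pairings <- sum(outer(seq_along(brute_a), seq_along(brute_b),
                            Vectorize(function(i, j) {
      ia <- brute_a[[i]][-c(1, length(brute_a[[i]]))]
      ib <- brute_b[[j]][-c(1, length(brute_b[[j]]))]
      length(intersect(ia, ib)) > 0
    })))
    expect_equal(length(res$pairings), n_pairings)
  }
})

test_that("verdicts are a total function of safety and evidence", {
  cand <- candidate_partners(syn_set(), "anchor1", exclusion = "cand2")
  pw <- list()
  pw[["anchor1||cand1"]] <- list(status = "ok",
                                 pairings = list(list(path_a = NULL,
                                                      path_b = NULL,
                                                      shared = "P1")))
  pw[["anchor1||cand2"]] <- pw[["anchor1||cand1"]]  # excluded regardless
  pw[["anchor1||cand3"]] <- list(status = "no_connecting_pathways",
                                 pairings = list())
  rep <- build_report(cand, pw, disease = "Dis")
  v <- setNames(rep$verdict, rep$candidate)
  expect_equal(unname(v["cand1"]), "pathway_supported")
  expect_equal(unname(v["cand2"]), "excluded")
  expect_equal(unname(v["cand3"]), "synergy_only")
})

test_that("one-call nomination is deterministic and schema-stable", {
  kg <- pathway_kg()
  syn <- data.frame(drug_a = c("A", "A"), drug_b = c("B", "C"),
                    pair_score = c(-1, -2))
  r1 <- nominate_candidates(syn, anchors = "A", exclusion = character(0),
                            kg = kg, disease = "Dis", max_len = 3)
  r2 <- nominate_candidates(syn, anchors = "A", exclusion = character(0),
                            kg = kg, disease = "Dis", max_len = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_setequal(r1$verdict[r1$candidate == "B"], "pathway_supported")
  expect_setequal(r1$verdict[r1$candidate == "C"], "synergy_only")
})
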