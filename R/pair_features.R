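#' KG topology features for a drug pair
#'
#' Computes the network-derived block of the pair feature vector on the
#' knowledge graph viewed as an undirected simple graph: per-drug node degree,
#' local clustering coefficient and PageRank (damping 0.85), plus the
#' shortest-path length between the two drugs and the cosine similarity of
#' their adjacency indicator vectors. If the drugs are disconnected, the
#' shortest-path length is the largest finite distance observed in the graph
#' plus one, which keeps the feature finite and monotone.
#'
#' @param kg a [knowledge_graph()].
#' @param drug_a,drug_b entity identifiers present in the graph.
#' @return named numeric vector: `degree_a`, `degree_b`, `clustering_a`,
#'   `clustering_b`, `pagerank_a`, `pagerank_b`, `shortest_path`,
#'   `cosine_similarity`.
#' @export
topology_features <- function(kg, drug_a, drug_b) {
  stopifnot(inherits(kg, "knowledge_graph"))
  for (d in c(drug_a, drug_b))
    if (!d %in% kg$entities) abort("drug not in knowledge graph: %s", d)
  g <- kg_igraph(kg)
  deg <- unname(igraph::degree(g, v = c(drug_a, drug_b)))
  cl <- unname(igraph::transitivity(g, type = "local",
                                    vids = c(drug_a, drug_b)))
  cl[is.na(cl)] <- 0
  pr <- unname(igraph::page_rank(g, damping = 0.85)$vector[c(drug_a, drug_b)])
  sp <- igraph::distances(g, v = drug_a, to = drug_b)[1L, 1L]
  if (!is.finite(sp)) {
    dm <- igraph::distances(g)
    sp <- max(dm[is.finite(dm)]) + 1
  }
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  va <- A[drug_a, ]
  vb <- A[drug_b, ]
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  cos_sim <- if (denom > 0) sum(va * vb) / denom else 0
  c(degree_a = unname(deg[1L]), degree_b = unname(deg[2L]),
    clustering_a = cl[1L], clustering_b = cl[2L],
    pagerank_a = unname(pr[1L]), pagerank_b = unname(pr[2L]),
    shortest_path = sp, cosine_similarity = cos_sim)
}

# Undirected simple igraph view of a knowledge graph (all entities kept as
# vertices, including isolated ones).
kg_igraph <- function(kg) {
  ed <- unique(kg$triples[, c("head", "tail")])
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = kg$entities)
  igraph::simplify(g)
}

#' Tanimoto coefficient of two bit fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits; accepts either integer
#' vectors of on-bit positions or logical bit vectors. Two all-zero
#' fingerprints give 0 with a warning.
#'
#' @param fp_a,fp_b fingerprints.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (is.logical(fp_a)) fp_a <- which(fp_a)
  if (is.logical(fp_b)) fp_b <- which(fp_b)
  u <- length(union(fp_a, fp_b))
  if (u == 0L) {
    warn("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(fp_a, fp_b)) / u
}

PHYSCHEM_COLS <- c("mw", "logp", "tpsa", "hbd", "hba", "rotatable")

#' Build an order-invariant feature vector for a drug pair
#'
#' Assembles the feature blocks used for synergism/antagonism classification.
#' The two drugs are placed in canonical (lexicographic) order before any
#' per-drug block is laid out, so `build_pair_features(A, B, ...)` and
#' `build_pair_features(B, A, ...)` are elementwise identical.
#'
#' Blocks by `mode`:
#' \describe{
#'   \item{handcrafted}{KG topology (see [topology_features()]), per-drug
#'     physicochemical descriptors (molecular weight, logP, TPSA, H-bond
#'     donors/acceptors, rotatable bonds; missing values mean-imputed with the
#'     imputation mask recorded), and — when fingerprints are supplied — the
#'     pair's Tanimoto coefficient plus the elementwise OR and AND of the two
#'     Morgan bit vectors (symmetric by construction).}
#'   \item{embedding}{the two entity embedding vectors of a fitted [kge()]
#'     model concatenated in canonical order (real and imaginary parts for
#'     complex models).}
#'   \item{both}{both of the above.}
#' }
#'
#' @param drug_a,drug_b drug identifiers.
#' @param kg [knowledge_graph()] (needed for handcrafted/both).
#' @param physchem data.frame with a `drug` column and the descriptor columns
#'   `mw`, `logp`, `tpsa`, `hbd`, `hba`, `rotatable`.
#' @param fingerprints optional named list of fingerprints (on-bit integer
#'   vectors) per drug; `nbits` gives the bit-vector length for the OR/AND
#'   blocks.
#' @param mode `"handcrafted"`, `"embedding"` or `"both"`.
#' @param embeddings fitted [kge()] model (needed for embedding/both).
#' @param nbits fingerprint length (default 1024).
#' @return named numeric feature vector with attribute `imputed` (names of
#'   mean-imputed descriptor cells).
#' @export
build_pair_features <- function(drug_a, drug_b, kg = NULL, physchem = NULL,
                                fingerprints = NULL,
                                mode = c("handcrafted", "embedding", "both"),
                                embeddings = NULL, nbits = 1024L) {
  mode <- match.arg(mode)
  p <- canonical_pair(drug_a, drug_b)
  d1 <- p$a; d2 <- p$b
  out <- numeric(0)
  imputed <- character(0)
  if (mode %in% c("handcrafted", "both")) {
    if (is.null(kg)) abort("handcrafted mode requires a knowledge graph")
    if (is.null(physchem)) abort("handcrafted mode requires a physicochemical table")
    topo <- topology_features(kg, d1, d2)
    pc <- lapply(c(d1, d2), function(d) {
      row <- physchem[physchem$drug == d, , drop = FALSE]
      if (nrow(row) == 0L) abort("drug missing from property table: %s", d)
      v <- as.numeric(row[1L, PHYSCHEM_COLS])
      names(v) <- PHYSCHEM_COLS
      miss <- !is.finite(v)
      if (any(miss)) {
        col_means <- vapply(PHYSCHEM_COLS, function(cc)
          mean(physchem[[cc]], na.rm = TRUE), numeric(1))
        v[miss] <- col_means[miss]
        imputed <<- c(imputed, paste(d, PHYSCHEM_COLS[miss], sep = "."))
      }
      v
    })
    out <- c(topo,
             setNames(pc[[1L]], paste0(PHYSCHEM_COLS, "_a")),
             setNames(pc[[2L]], paste0(PHYSCHEM_COLS, "_b")))
    if (!is.null(fingerprints)) {
      fa <- fingerprints[[d1]]; fb <- fingerprints[[d2]]
      if (is.null(fa) || is.null(fb))
        abort("fingerprint missing for %s", if (is.null(fa)) d1 else d2)
      if (length(c(fa, fb)) && max(c(fa, fb)) > nbits)
        abort("fingerprint bit index exceeds nbits = %d", nbits)
      ba <- bb <- logical(nbits)
      ba[fa] <- TRUE; bb[fb] <- TRUE
      out <- c(out, tanimoto = tanimoto(fa, fb),
               setNames(as.numeric(ba | bb), paste0("fp_or_", seq_len(nbits))),
               setNames(as.numeric(ba & bb), paste0("fp_and_", seq_len(nbits))))
    }
  }
  if (mode %in% c("embedding", "both")) {
    if (is.null(embeddings) || !inherits(embeddings, "kge"))
      abort("embedding mode requires a fitted kge model")
    em <- coef(embeddings)$entities
    for (d in c(d1, d2))
      if (!d %in% rownames(em)) abort("drug missing from embedding: %s", d)
    vecs <- lapply(c(d1, d2), function(d) {
      v <- em[d, ]
      if (is.complex(v)) c(Re(v), Im(v)) else as.numeric(v)
    })
    out <- c(out,
             setNames(vecs[[1L]], paste0("emb_a_", seq_along(vecs[[1L]]))),
             setNames(vecs[[2L]], paste0("emb_b_", seq_along(vecs[[2L]]))))
  }
  attr(out, "imputed") <- imputed
  out
}
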