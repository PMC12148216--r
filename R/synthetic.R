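# Synthetic-data generators: planted-embedding KGs, combination-screen tables
# with cell-line replicates and controlled inconsistency, and drug-property
# tables. Every pipeline stage is testable from these without any download.

#' Specification for the synthetic study conditions
#'
#' Defaults describe the reference synthetic pharmacome used across the test
#' suite: 500 entities, 8 relation types, 5000 triples planted from a
#' ground-truth TransE embedding, 60 drugs, synergy screens over 3 cell lines
#' with class means +/-15 ZIP units and measurement noise sd 2 (a 2.5-sigma
#' margin against the +/-10 classification thresholds), a 10% additive rate
#' and a 10% rate of deliberately inconsistent (mixed-sign) pairs.
#'
#' @param n_entities,n_relations,n_drugs graph dimensions.
#' @param embedding_dim dimension of the ground-truth embeddings.
#' @param generator_model `"TransE"`, `"RotatE"` or `"HolE"`.
#' @param triple_budget number of triples to plant.
#' @param n_pairs drug pairs per synergy table.
#' @param inconsistency_rate fraction of non-additive pairs given mixed-sign
#'   cell lines.
#' @param additive_rate fraction of pairs with a latent additive class.
#' @param n_cell_lines replicate cell lines per pair.
#' @param noise_sd ZIP measurement noise (ZIP units).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_entities = 500L, n_relations = 8L, n_drugs = 60L,
                           embedding_dim = 16L, generator_model = "TransE",
                           triple_budget = 5000L, n_pairs = 500L,
                           inconsistency_rate = 0.1, additive_rate = 0.1,
                           n_cell_lines = 3L, noise_sd = 2, seed = 0L) {
  generator_model <- match.arg(generator_model, c("TransE", "RotatE", "HolE"))
  rates <- c(inconsistency_rate, additive_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (triple_budget < 1L) abort("triple_budget must be positive")
  structure(list(n_entities = as.integer(n_entities),
                 n_relations = as.integer(n_relations),
                 n_drugs = as.integer(n_drugs),
                 embedding_dim = as.integer(embedding_dim),
                 generator_model = generator_model,
                 triple_budget = as.integer(triple_budget),
                 n_pairs = as.integer(n_pairs),
                 inconsistency_rate = inconsistency_rate,
                 additive_rate = additive_rate,
                 n_cell_lines = as.integer(n_cell_lines),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

SYN_NODE_TYPES <- c("Protein", "Gene", "BiologicalProcess", "Pathology")

#' Generate a knowledge graph planted from ground-truth embeddings
#'
#' Samples ground-truth entity and relation embeddings under the chosen
#' generator model, scores every candidate triple (h, r, t), h != t, and emits
#' the `triple_budget` highest-scoring candidates as the true graph.
#'
#' Ground-truth entities are drawn around a set of cluster centroids (about
#' two clusters per relation) and each relation embedding is constructed to
#' connect one ordered centroid pair — the translation between the centroids
#' for TransE, the elementwise phase difference for RotatE, the centroids'
#' circular correlation for HolE. The planted graph therefore carries the
#' community structure typical of biomedical knowledge graphs (relations link
#' entity neighbourhoods, not arbitrary point pairs), which is what makes
#' held-out relation recovery a meaningful target for any embedding family
#' rather than only for the generator's own.
#'
#' Entities are typed with a Drug subset (the first `n_drugs`) and the
#' remaining nodes cycled over Protein/Gene/BiologicalProcess/Pathology. The
#' ground truth is returned so recovery can be tested.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `kg` (a [knowledge_graph()]) and `truth` (ground-truth
#'   embeddings, generator model, and the planted triples' scores).
#' @export
generate_planted_kg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_e <- spec$n_entities; n_r <- spec$n_relations; d <- spec$embedding_dim
  if (spec$triple_budget > n_e * (n_e - 1L) * n_r)
    abort("triple_budget exceeds candidate space")
  set.seed(spec$seed)
  ent_ids <- sprintf("E%04d", seq_len(n_e))
  rel_ids <- sprintf("rel_%02d", seq_len(n_r))
  model <- spec$generator_model
  # cluster scaffold shared by all generator models
  n_cl <- max(3L, min(2L * n_r, n_e))
  centroids <- matrix(rnorm(n_cl * d), n_cl)
  centroids <- centroids / sqrt(rowSums(centroids^2))
  cl_of <- sample(rep_len(seq_len(n_cl), n_e))
  pair_pool <- expand.grid(a = seq_len(n_cl), b = seq_len(n_cl))
  pair_pool <- pair_pool[pair_pool$a != pair_pool$b, ]
  rel_pairs <- pair_pool[sample.int(nrow(pair_pool), n_r), ]
  noise <- function(sd_) matrix(rnorm(n_e * d, sd = sd_), n_e)
  truth <- switch(model,
    TransE = {
      E <- centroids[cl_of, ] + noise(0.08)
      R <- centroids[rel_pairs$b, ] - centroids[rel_pairs$a, ]
      list(E = E, R = R)
    },
    RotatE = {
      Ec <- (centroids[cl_of, ] + noise(0.08)) +
        1i * (centroids[(cl_of %% n_cl) + 1L, ] + noise(0.08))
      Ca <- centroids[rel_pairs$a, ] + 1i * centroids[(rel_pairs$a %% n_cl) + 1L, ]
      Cb <- centroids[rel_pairs$b, ] + 1i * centroids[(rel_pairs$b %% n_cl) + 1L, ]
      list(E = Ec, theta = Arg(Cb / Ca))
    },
    HolE = {
      E <- centroids[cl_of, ] + noise(0.08)
      R <- t(vapply(seq_len(n_r), function(j) {
        cc <- ccorr_slow(centroids[rel_pairs$a[j], ], centroids[rel_pairs$b[j], ])
        cc / sqrt(sum(cc^2))
      }, numeric(d)))
      list(E = E, R = R)
    })
  truth$clusters <- cl_of
  truth$rel_pairs <- rel_pairs
  score_rel <- function(j) {
    switch(model,
      TransE = {
        A <- truth$E + matrix(truth$R[j, ], n_e, d, byrow = TRUE)
        cross <- A %*% t(truth$E)
        -sqrt(pmax(outer(rowSums(A^2), rowSums(truth$E^2), `+`) - 2 * cross, 0))
      },
      RotatE = {
        r <- cos(truth$theta[j, ]) + 1i * sin(truth$theta[j, ])
        A <- truth$E * matrix(r, n_e, d, byrow = TRUE)
        cross <- Re(A %*% Conj(t(truth$E)))
        -sqrt(pmax(outer(rowSums(Mod(A)^2), rowSums(Mod(truth$E)^2), `+`) -
                     2 * cross, 0))
      },
      HolE = {
        Fe <- row_fft(truth$E)
        Fr <- stats::fft(truth$R[j, ])
        M1 <- Fe * matrix(Fr, n_e, d, byrow = TRUE)
        Re(M1 %*% Conj(t(Fe))) / d
      })
  }
  all_scores <- vector("list", n_r)
  for (j in seq_len(n_r)) {
    S <- score_rel(j)
    diag(S) <- -Inf  # no self-loops
    all_scores[[j]] <- S
  }
  flat <- unlist(all_scores, use.names = FALSE)
  k <- spec$triple_budget
  ord <- order(flat, decreasing = TRUE)[seq_len(k)]
  per_rel <- n_e * n_e
  rel_idx <- (ord - 1L) %/% per_rel + 1L
  within <- (ord - 1L) %% per_rel
  h_idx <- within %% n_e + 1L       # row index (head)
  t_idx <- within %/% n_e + 1L      # column index (tail)
  triples <- data.frame(head = ent_ids[h_idx],
                        relation = rel_ids[rel_idx],
                        tail = ent_ids[t_idx])
  types <- c(rep("Drug", spec$n_drugs),
             rep_len(SYN_NODE_TYPES, n_e - spec$n_drugs))
  kg <- knowledge_graph(triples, entity_type = setNames(types, ent_ids))
  list(kg = kg,
       truth = list(model = model, embeddings = truth,
                    entities = ent_ids, relations = rel_ids,
                    min_planted_score = flat[ord[k]],
                    scores = flat[ord]))
}

#' Generate a synthetic drug-combination screen
#'
#' Samples `n_pairs` distinct unordered drug pairs, draws a latent class per
#' pair (`additive` with probability `additive_rate`, otherwise synergism or
#' antagonism equiprobably) and emits one ZIP measurement per cell line:
#' class mean (+15 / -15 / 0 ZIP units) plus Gaussian noise. A
#' `inconsistency_rate` fraction of non-additive pairs has the class-mean sign
#' flipped for a random proper subset of cell lines, planting the mixed-sign
#' pairs that the consistency filter must drop.
#'
#' @param spec a [synthetic_spec()].
#' @param drugs drug identifiers (>= 2).
#' @return data.frame of records (`drug_a`, `drug_b`, `cell_line`, `zip`) with
#'   attribute `truth`: per-pair `latent_label` and `inconsistent` flag.
#' @export
generate_synergy_table <- function(spec, drugs) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) < 2L) abort("need at least 2 drugs")
  set.seed(spec$seed + 1L)
  all_pairs <- utils::combn(drugs, 2L)
  n_avail <- ncol(all_pairs)
  n_pairs <- min(spec$n_pairs, n_avail)
  sel <- all_pairs[, sample.int(n_avail, n_pairs), drop = FALSE]
  lat <- ifelse(runif(n_pairs) < spec$additive_rate, "additive",
                ifelse(runif(n_pairs) < 0.5, "synergism", "antagonism"))
  mu <- c(synergism = 15, antagonism = -15, additive = 0)[lat]
  inconsistent <- lat != "additive" & spec$n_cell_lines >= 2L &
    runif(n_pairs) < spec$inconsistency_rate
  cls <- sprintf("CL%02d", seq_len(spec$n_cell_lines))
  rec <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    means <- rep(mu[i], spec$n_cell_lines)
    if (inconsistent[i]) {
      n_flip <- sample.int(spec$n_cell_lines - 1L, 1L)
      means[sample.int(spec$n_cell_lines, n_flip)] <- -mu[i]
    }
    rec[[i]] <- data.frame(drug_a = sel[1L, i], drug_b = sel[2L, i],
                           cell_line = cls,
                           zip = means + rnorm(spec$n_cell_lines,
                                               sd = spec$noise_sd))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(drug_a = sel[1L, ], drug_b = sel[2L, ],
                                   latent_label = unname(lat),
                                   inconsistent = unname(inconsistent))
  out
}

#' Generate a synthetic drug-property table and fingerprints
#'
#' Descriptors are drawn uniformly from plausible medicinal-chemistry ranges
#' (MW 100-900 Da, logP -2..7, TPSA 0-200 A^2, 0-10 H-bond donors, 0-12
#' acceptors, 0-15 rotatable bonds). Fingerprints are random 1024-bit vectors
#' with ~64 on-bits; pairs listed in `similar_pairs` share most of their bits,
#' planting Tanimoto similarity above 0.6.
#'
#' @param drugs drug identifiers.
#' @param seed integer seed.
#' @param n_bits fingerprint length.
#' @param n_on approximate on-bits per fingerprint.
#' @param similar_pairs optional 2-column matrix/data.frame of drug pairs to
#'   make structurally similar.
#' @return list with `properties` (data.frame `drug`, `mw`, `logp`, `tpsa`,
#'   `hbd`, `hba`, `rotatable`) and `fingerprints` (named list of on-bit
#'   integer vectors).
#' @export
generate_drug_properties <- function(drugs, seed = 0L, n_bits = 1024L,
                                     n_on = 64L, similar_pairs = NULL) {
  drugs <- as.character(drugs)
  set.seed(as.integer(seed))
  n <- length(drugs)
  props <- data.frame(drug = drugs,
                      mw = runif(n, 100, 900),
                      logp = runif(n, -2, 7),
                      tpsa = runif(n, 0, 200),
                      hbd = sample(0:10, n, replace = TRUE),
                      hba = sample(0:12, n, replace = TRUE),
                      rotatable = sample(0:15, n, replace = TRUE))
  fps <- lapply(seq_len(n), function(i) sort(sample.int(n_bits, n_on)))
  names(fps) <- drugs
  if (!is.null(similar_pairs)) {
    sp <- as.matrix(similar_pairs)
    for (i in seq_len(nrow(sp))) {
      a <- sp[i, 1L]; b <- sp[i, 2L]
      base <- fps[[a]]
      n_shared <- ceiling(0.85 * length(base))
      shared <- sample(base, n_shared)
      extra <- sample(setdiff(seq_len(n_bits), shared),
                      length(base) - n_shared)
      fps[[b]] <- sort(c(shared, extra))
    }
  }
  list(properties = props, fingerprints = fps)
}

#' Write the four-file synthetic input bundle
#'
#' Materialises a full synthetic study as the four plain-text inputs the
#' pipeline consumes: `kg.tsv` (edge list), `KG_labels.tsv` (node types),
#' `Drugs.csv` (properties) and `Drug_combinations.csv` (synergy screen).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly; ground
#'   truth is attached as attribute `truth`.
#' @export
simulate_kg_files <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  planted <- generate_planted_kg(spec)
  drugs <- planted$kg$entities[planted$kg$entity_type[planted$kg$entities] == "Drug"]
  combos <- generate_synergy_table(spec, drugs)
  props <- generate_drug_properties(drugs, seed = spec$seed + 2L)
  paths <- c(kg = file.path(dir, "kg.tsv"),
             labels = file.path(dir, "KG_labels.tsv"),
             drugs = file.path(dir, "Drugs.csv"),
             combinations = file.path(dir, "Drug_combinations.csv"))
  write_kg_tsv(planted$kg, paths[["kg"]], labels_path = paths[["labels"]])
  utils::write.csv(props$properties, paths[["drugs"]], row.names = FALSE)
  utils::write.csv(combos, paths[["combinations"]], row.names = FALSE)
  out <- invisible(paths)
  attr(out, "truth") <- list(planted = planted$truth,
                             synergy = attr(combos, "truth"))
  invisible(out)
}
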