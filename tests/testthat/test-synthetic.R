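test_that("planted graphs are deterministic and respect their budget", {
  spec <- synthetic_spec(n_entities = 30L, n_relations = 3L, n_drugs = 10L,
                         embedding_dim = 8L, triple_budget = 100L, seed = 0L)
  p1 <- generate_planted_kg(spec)
  p2 <- generate_planted_kg(spec)
  expect_identical(p1$kg$triples, p2$kg$triples)
  expect_equal(kg_stats(p1$kg)$n_triples, 100L)
  expect_error(synthetic_spec(triple_budget = 0), "positive")
  expect_error(generate_planted_kg(
    synthetic_spec(n_entities = 4L, n_relations = 2L, n_drugs = 2L,
                   embedding_dim = 4L, triple_budget = 10000L)),
    "candidate space")
})

test_that("every planted triple outscores every non-emitted candidate", {
  for (gm in c("TransE", "RotatE", "HolE")) {
    spec <- synthetic_spec(n_entities = 20L, n_relations = 3L, n_drugs = 6L,
                           embedding_dim = 6L, triple_budget = 60L, seed = 2L,
                           generator_model = gm)
    pl <- generate_planted_kg(spec)
    e <- pl$truth$embeddings
    params <- switch(gm,
      TransE = list(E = e$E, R = e$R),
      RotatE = list(E_re = Re(e$E), E_im = Im(e$E), theta = e$theta),
      HolE = list(E = e$E, R = e$R))
    n_e <- spec$n_entities; n_r <- spec$n_relations
    grid <- expand.grid(h = seq_len(n_e), t = seq_len(n_e),
                        r = seq_len(n_r))
    grid <- grid[grid$h != grid$t, ]
    all_sc <- kgsynergy:::kge_score_batch(gm, params, grid$h, grid$r, grid$t)
    key <- paste(pl$truth$entities[grid$h], pl$truth$relations[grid$r],
                 pl$truth$entities[grid$t])
    planted_key <- paste(pl$kg$triples$head, pl$kg$triples$relation,
                         pl$kg$triples$tail)
    in_planted <- key %in% planted_key
    expect_equal(sum(in_planted), 60L)
    expect_gte(min(all_sc[in_planted]), max(all_sc[!in_planted]) - 1e-9)
    # generator's own reported scores agree with the model scorer
    expect_equal(sort(all_sc[in_planted], decreasing = TRUE),
                 pl$truth$scores, tolerance = 1e-8)
  }
})

test_that("synergy tables plant recoverable class structure", {
  spec <- synthetic_spec(n_drugs = 40L, n_pairs = 200L,
                         inconsistency_rate = 0, additive_rate = 0.2,
                         noise_sd = 1, seed = 0L)
  drugs <- sprintf("D%02d", 1:40)
  tab <- generate_synergy_table(spec, drugs)
  truth <- attr(tab, "truth")
  expect_equal(nrow(truth), 200L)
  expect_equal(nrow(tab), 200L * spec$n_cell_lines)
  out <- consistency_filter(tab)
  # with no planted inconsistency and 1-sigma noise, labels match the latent
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(out$drug_a, out$drug_b), key(truth$drug_a, truth$drug_b))
  expect_identical(out$label, truth$latent_label[m])
  non_additive <- sum(truth$latent_label != "additive")
  expect_gte(nrow(out) / non_additive, 0.95)
})

test_that("fully inconsistent tables are fully dropped; one cell line is trivially unanimous", {
  drugs <- sprintf("D%02d", 1:20)
  spec1 <- synthetic_spec(n_pairs = 50L, inconsistency_rate = 1,
                          additive_rate = 0, seed = 1L)
  tab1 <- generate_synergy_table(spec1, drugs)
  expect_equal(nrow(consistency_filter(tab1)), 0L)
  spec2 <- synthetic_spec(n_pairs = 50L, inconsistency_rate = 1,
                          additive_rate = 0, n_cell_lines = 1L, seed = 1L)
  tab2 <- generate_synergy_table(spec2, drugs)
  # a single cell line cannot be inconsistent with itself
  expect_gte(nrow(consistency_filter(tab2)) / 50, 0.95)
})

test_that("drug property tables are deterministic, in range, and plant similarity", {
  drugs <- sprintf("D%02d", 1:15)
  p1 <- generate_drug_properties(drugs, seed = 4)
  p2 <- generate_drug_properties(drugs, seed = 4)
  expect_identical(p1$properties, p2$properties)
  expect_identical(p1$fingerprints, p2$fingerprints)
  pr <- p1$properties
  expect_true(all(pr$mw >= 100 & pr$mw <= 900))
  expect_true(all(pr$logp >= -2 & pr$logp <= 7))
  expect_true(all(pr$tpsa >= 0 & pr$tpsa <= 200))
  expect_true(all(pr$hbd %in% 0:10 & pr$hba %in% 0:12 &
                    pr$rotatable %in% 0:15))
  sim <- generate_drug_properties(drugs, seed = 4,
                                  similar_pairs = cbind("D01", "D02"))
  expect_gt(tanimoto(sim$fingerprints[["D01"]], sim$fingerprints[["D02"]]),
            0.6)
})

test_that("the four-file bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_entities = 40L, n_relations = 4L, n_drugs = 12L,
                         embedding_dim = 8L, triple_budget = 150L,
                         n_pairs = 30L, seed = 6L)
  paths <- simulate_kg_files(spec, dir)
  expect_true(all(file.exists(paths)))
  kg <- read_kg_tsv(paths[["kg"]], labels_path = paths[["labels"]])
  expect_equal(kg_stats(kg)$n_triples, 150L)
  combos <- read.csv(paths[["combinations"]])
  expect_true(all(c("drug_a", "drug_b", "cell_line", "zip") %in%
                    names(combos)))
  drugs <- read.csv(paths[["drugs"]])
  # drug roster consistent across the bundle (drugs occurring in the graph)
  expect_equal(sum(kg$entity_type == "Drug"), nrow(drugs))
  expect_gte(nrow(drugs), 2L)
  expect_true(all(c(combos$drug_a, combos$drug_b) %in% drugs$drug))
})
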