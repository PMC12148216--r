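test_that("harmonize merges orientations and replicates by averaging", {
  rec <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "A"),
                    cell_line = "CL1", zip = c(10, 20))
  h <- harmonize_synergy(rec)
  expect_equal(nrow(h), 1L)
  expect_equal(h$zip, 15)
  expect_equal(h$drug_a, "A")
  # single record unchanged; distinct cell lines stay distinct
  one <- data.frame(drug_a = "A", drug_b = "B", cell_line = "CL1", zip = 7)
  expect_equal(harmonize_synergy(one)$zip, 7)
  two <- data.frame(drug_a = "A", drug_b = "B", cell_line = c("CL1", "CL2"),
                    zip = c(5, 5))
  expect_equal(nrow(harmonize_synergy(two)), 2L)
})

test_that("harmonize is idempotent and drops missing scores with a warning", {
  rec <- data.frame(drug_a = c("A", "B", "C"), drug_b = c("B", "A", "D"),
                    cell_line = c("CL1", "CL1", "CL2"), zip = c(1, 3, NA))
  expect_warning(h1 <- harmonize_synergy(rec), "non-finite")
  expect_identical(harmonize_synergy(h1), h1)
})

test_that("ZIP labelling uses an inclusive dead band", {
  expect_equal(label_from_zip(12), "synergism")
  expect_equal(label_from_zip(0), "additive")
  expect_equal(label_from_zip(-10), "antagonism")
  expect_equal(label_from_zip(10), "synergism")
  expect_error(label_from_zip(NaN), "non-finite")
  expect_error(label_from_zip(5, thresholds = c(-10, 10)), "t_ant < t_syn")
})

test_that("consistency filter keeps unanimous non-additive pairs only", {
  rec <- data.frame(
    drug_a = c("A", "A", "C", "C", "E"),
    drug_b = c("B", "B", "D", "D", "F"),
    cell_line = c("CL1", "CL2", "CL1", "CL2", "CL1"),
    zip = c(12, 15, 12, -11, 2))
  out <- consistency_filter(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$label, "synergism")
  expect_equal(out$mean_zip, 13.5)
  expect_equal(out$n_cell_lines, 2L)
  expect_equal(attr(out, "n_dropped_mixed"), 1L)
  expect_equal(attr(out, "n_dropped_additive"), 1L)
})

test_that("consistency filter is invariant to record order and orientation", {
  set.seed(4)
  rec <- data.frame(
    drug_a = rep(c("A", "C", "E"), each = 3),
    drug_b = rep(c("B", "D", "F"), each = 3),
    cell_line = rep(c("CL1", "CL2", "CL3"), 3),
    zip = c(12, 14, 16, -12, -15, -13, 12, -12, 1))
  base <- consistency_filter(rec)
  for (i in 1:5) {
    perm <- rec[sample.int(nrow(rec)), ]
    flip <- sample(c(TRUE, FALSE), nrow(perm), TRUE)
    tmp <- perm$drug_a[flip]
    perm$drug_a[flip] <- perm$drug_b[flip]
    perm$drug_b[flip] <- tmp
    expect_equal(consistency_filter(perm), base, ignore_attr = TRUE)
  }
})

test_that("enrichment adds reciprocal edges for retained pairs only", {
  kg <- schema_kg()
  labels <- data.frame(drug_a = "drugA", drug_b = "drugB",
                       label = "synergism", mean_zip = 14, n_cell_lines = 2)
  enr <- enrich_kg(kg, labels)
  expect_equal(kg_stats(enr)$n_triples, kg_stats(kg)$n_triples + 2L)
  expect_true("has_synergism_with" %in% enr$relations)
  both <- enr$triples[enr$triples$relation == "has_synergism_with", ]
  expect_setequal(both$head, c("drugA", "drugB"))
  # empty label list is the identity
  empty <- labels[0, ]
  expect_equal(kg_stats(enrich_kg(kg, empty))$n_triples,
               kg_stats(kg)$n_triples)
  # unresolvable drug skipped with a warning
  ghost <- data.frame(drug_a = "nope", drug_b = "drugA", label = "antagonism",
                      mean_zip = -12, n_cell_lines = 1)
  expect_warning(enr2 <- enrich_kg(kg, ghost), "skipping 1")
  expect_equal(kg_stats(enr2)$n_triples, kg_stats(kg)$n_triples)
  expect_equal(attr(enr2, "n_skipped"), 1L)
})

test_that("enrichment adds exactly 2 x retained resolvable pairs", {
  kg <- schema_kg()
  labels <- data.frame(drug_a = c("drugA", "drugA", "nope"),
                       drug_b = c("drugB", "prot1", "drugB"),
                       label = c("synergism", "antagonism", "synergism"),
                       mean_zip = c(14, -13, 12), n_cell_lines = 1)
  expect_warning(enr <- enrich_kg(kg, labels))
  retained_resolvable <- 2L  # drugA-drugB and drugA-prot1 resolve; "nope" not
  expect_equal(kg_stats(enr)$n_triples,
               kg_stats(kg)$n_triples + 2L * retained_resolvable)
})
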