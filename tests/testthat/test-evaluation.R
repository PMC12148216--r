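# Helpers to synthesise relation rankings without a trained model.
make_ranking <- function(head, tail, relations, scores) {
  ord <- order(-scores, seq_along(relations))
  out <- data.frame(relation = relations[ord], score = scores[ord],
                    rank = seq_along(relations))
  attr(out, "head") <- head
  attr(out, "tail") <- tail
  class(out) <- c("relation_ranking", "data.frame")
  out
}

test_that("rank-k true-prediction percentage counts hits per rank", {
  rels <- c("r1", "r2", "r3")
  rk <- list(
    make_ranking("a", "b", rels, c(3, 2, 1)),   # rank1 = r1
    make_ranking("c", "d", rels, c(3, 2, 1)),   # rank1 = r1
    make_ranking("e", "f", rels, c(1, 3, 2)),   # rank1 = r2
    make_ranking("g", "h", rels, c(3, 1, 2)))   # rank1 = r1
  truth <- data.frame(head = c("a", "c", "e", "g"),
                      tail = c("b", "d", "f", "h"),
                      relation = c("r1", "r1", "r1", "r1"))
  res <- true_prediction_percentage(rk, truth, k = 1:3)
  expect_equal(res$percentage[1], 75)
  expect_equal(res$n_true[1], 3)
  # the r1-truth for pair (e,f) sits at rank 2 (score 3 > 2 > 1 -> r2,r3,r1?)
  # scores (1,3,2): order r2(3), r3(2), r1(1) -> r1 at rank 3
  expect_equal(res$n_true[3], 1)
  # counts over all ranks sum to the number of pairs
  expect_equal(sum(res$n_true), length(rk))
  # all-correct upper bound
  truth2 <- truth
  truth2$relation <- vapply(rk, function(r) r$relation[1], character(1))
  expect_equal(true_prediction_percentage(rk, truth2, k = 1)$percentage, 100)
})

test_that("rank evaluation rejects missing truth and empty inputs", {
  rels <- c("r1", "r2")
  rk <- list(make_ranking("a", "b", rels, c(2, 1)))
  expect_error(true_prediction_percentage(list(), data.frame()), "no rankings")
  truth <- data.frame(head = "x", tail = "y", relation = "r1")
  expect_error(true_prediction_percentage(rk, truth), "no truth entry")
  good <- data.frame(head = "a", tail = "b", relation = "r1")
  expect_error(true_prediction_percentage(rk, good, k = 5), "outside")
})

test_that("binary AUC equals concordance counting, with ties at half", {
  expect_equal(binary_roc_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(binary_roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 0.75)
  expect_equal(binary_roc_auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_error(binary_roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC complements exactly under score negation", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n, 1, 0.4))
    s <- round(rnorm(n + 2), sample(0:2, 1))  # rounding forces ties
    expect_identical(binary_roc_auc(y, s) + binary_roc_auc(y, -s), 1)
  }
})

test_that("Mann-Whitney AUC agrees with the trapezoid oracle and pROC", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    y <- c(0, 1, rbinom(n, 1, 0.5))
    s <- round(rnorm(n + 2), sample(1:3, 1))
    expect_equal(binary_roc_auc(y, s), trapezoid_auc(y, s),
                 tolerance = 1e-12)
  }
  y <- c(0, 1, rbinom(80, 1, 0.5))
  s <- rnorm(82)
  expect_equal(binary_roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("macro multiclass AUC averages one-vs-rest AUCs", {
  # two types: one perfectly ranked, one at chance
  truth <- c("a", "a", "b", "b")
  sm <- cbind(a = c(4, 3, 2, 1), b = c(1, 1, 1, 1))
  res <- multiclass_roc_auc(truth, sm)
  expect_equal(unname(res$per_type_auc["a"]), 1.0)
  expect_equal(unname(res$per_type_auc["b"]), 0.5)
  expect_equal(res$macro_auc, 0.75)
  # perfectly separable 3-type toy
  truth3 <- rep(c("x", "y", "z"), each = 3)
  sm3 <- cbind(x = rep(c(1, 0, 0), each = 3), y = rep(c(0, 1, 0), each = 3),
               z = rep(c(0, 0, 1), each = 3))
  expect_equal(multiclass_roc_auc(truth3, sm3)$macro_auc, 1.0)
  # consistent row permutation leaves the result unchanged
  perm <- sample(length(truth3))
  expect_equal(multiclass_roc_auc(truth3[perm], sm3[perm, ])$macro_auc, 1.0)
  expect_error(multiclass_roc_auc(rep("a", 4), sm), "at least 2")
  sm_extra <- cbind(sm, c = rnorm(4))
  expect_warning(multiclass_roc_auc(truth, sm_extra), "excluded")
})
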