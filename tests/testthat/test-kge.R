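score1 <- function(model, params, h, r, t)
  kgsynergy:::kge_score_batch(model, params, h, r, t)

test_that("score functions reproduce hand-computed values", {
  # TransE: h + r = t gives the maximal score 0
  ps <- list(E = rbind(c(0, 0), c(1, 1)), R = rbind(c(1, 1)))
  expect_equal(score1("TransE", ps, 1L, 1L, 2L), 0, tolerance = 1e-5)
  # HolE: (1,2) star (3,4) = (11,10); dot with (1,0) = 11
  ph <- list(E = rbind(c(1, 2), c(3, 4)), R = rbind(c(1, 0)))
  expect_equal(score1("HolE", ph, 1L, 1L, 2L), 11)
  # ComplEx: Re((1+1i)(2+0i)(1+1i)) = Re(2(1+1i)^2) = 0
  pc <- list(E_re = rbind(1, 1), E_im = rbind(1, -1),
             R_re = rbind(2), R_im = rbind(0))
  expect_equal(score1("ComplEx", pc, 1L, 1L, 2L), 0)
})

test_that("HolE equals the double-loop circular-correlation oracle", {
  set.seed(10)
  for (d in c(2, 5, 8, 16)) {
    h <- rnorm(d); t_ <- rnorm(d); r <- rnorm(d)
    ps <- list(E = rbind(h, t_), R = rbind(r))
    expect_equal(score1("HolE", ps, 1L, 1L, 2L),
                 sum(r * kgsynergy:::ccorr_slow(h, t_)), tolerance = 1e-10)
  }
})

test_that("ComplEx is symmetric for real relations, antisymmetric for imaginary", {
  set.seed(11)
  d <- 6
  E_re <- matrix(rnorm(2 * d), 2); E_im <- matrix(rnorm(2 * d), 2)
  real_rel <- list(E_re = E_re, E_im = E_im,
                   R_re = matrix(rnorm(d), 1), R_im = matrix(0, 1, d))
  expect_equal(score1("ComplEx", real_rel, 1L, 1L, 2L),
               score1("ComplEx", real_rel, 2L, 1L, 1L))
  imag_rel <- list(E_re = E_re, E_im = E_im,
                   R_re = matrix(0, 1, d), R_im = matrix(rnorm(d), 1))
  expect_equal(score1("ComplEx", imag_rel, 1L, 1L, 2L),
               -score1("ComplEx", imag_rel, 2L, 1L, 1L))
})

test_that("RotatE with phase pi scores symmetrically in (h, t)", {
  set.seed(12)
  d <- 5
  ps <- list(E_re = matrix(rnorm(4 * d), 4), E_im = matrix(rnorm(4 * d), 4),
             theta = matrix(pi, 1, d))
  for (pair in list(c(1L, 2L), c(3L, 4L), c(1L, 4L)))
    expect_equal(score1("RotatE", ps, pair[1], 1L, pair[2]),
                 score1("RotatE", ps, pair[2], 1L, pair[1]),
                 tolerance = 1e-10)
})

test_that("TransE scores are invariant to translating all entities", {
  set.seed(13)
  d <- 6
  E <- matrix(rnorm(5 * d), 5); R <- matrix(rnorm(2 * d), 2)
  shift <- matrix(rnorm(d), 5, d, byrow = TRUE)
  a <- score1("TransE", list(E = E, R = R), 1:4, c(1L, 2L, 1L, 2L), c(2:5))
  b <- score1("TransE", list(E = E + shift, R = R), 1:4, c(1L, 2L, 1L, 2L),
              c(2:5))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("negative sampling corrupts exactly one slot, deterministically", {
  tr <- toy_triples()
  ents <- c("A", "B", "C", "D")
  n1 <- sample_negatives(tr, ents, k = 1, seed = 3)
  expect_equal(nrow(n1), 2L)
  for (i in 1:2) {
    diff <- sum(n1$head[i] != tr$head[i], n1$relation[i] != tr$relation[i],
                n1$tail[i] != tr$tail[i])
    expect_lte(diff, 1L)  # uniform draw may coincide with the original
    expect_equal(n1$relation[i], tr$relation[i])
  }
  expect_identical(sample_negatives(tr, ents, k = 1, seed = 3), n1)
  expect_equal(nrow(sample_negatives(tr, ents, k = 5, seed = 1)), 10L)
  expect_error(sample_negatives(tr, "A", k = 1), "at least 2")
  expect_error(sample_negatives(tr, ents, k = 0), "positive integer")
})

test_that("training validates its configuration", {
  kg <- knowledge_graph(toy_triples())
  expect_error(kge(kg, model = "TransE", negatives = 0), ">= 1")
  expect_error(kge(kg, model = "TransE", learning_rate = -1), "positive")
})

test_that("training is reproducible and its smoothed loss decreases", {
  kg <- small_planted()$kg
  f1 <- kge(kg, model = "TransE", dim = 16, epochs = 30, batch_size = 64,
            seed = 0)
  f2 <- kge(kg, model = "TransE", dim = 16, epochs = 30, batch_size = 64,
            seed = 0)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_trajectory, f2$loss_trajectory)
  ma <- stats::filter(f1$loss_trajectory, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-8))
})

test_that("TransE entities stay unit-norm and RotatE relations unit-modulus", {
  kg <- small_planted()$kg
  fe <- kge(kg, model = "TransE", dim = 8, epochs = 5, seed = 1)
  expect_equal(unname(sqrt(rowSums(coef(fe)$entities^2))),
               rep(1, length(fe$entities)), tolerance = 1e-8)
  fr <- kge(kg, model = "RotatE", dim = 8, epochs = 5, seed = 1)
  expect_equal(unname(as.vector(Mod(coef(fr)$relations))),
               rep(1, 3 * 8), tolerance = 1e-12)
})

test_that("relation ranking covers the vocabulary once with stable tie-breaks", {
  fit <- tiny_combo_model()$fit
  rk <- rank_relations(fit, "D1", "D2")
  expect_setequal(rk$relation, fit$relations)
  expect_equal(rk$rank, seq_along(fit$relations))
  expect_true(all(diff(rk$score) <= 0))
  expect_identical(rank_relations(fit, "D1", "D2"), rk)
  # singleton vocabulary trivially ranks first
  kg1 <- knowledge_graph(data.frame(head = c("a", "b", "c"), relation = "r",
                                    tail = c("b", "c", "a")))
  f1 <- kge(kg1, model = "TransE", dim = 4, epochs = 3, seed = 1)
  expect_equal(rank_relations(f1, "a", "b")$rank, 1L)
  # unknown lookups fail loudly
  expect_error(rank_relations(fit, "nope", "D2"), "unknown entity")
  expect_error(score_triples(fit, data.frame(head = "D1", relation = "zzz",
                                             tail = "D2")),
               "unknown relation")
})

test_that("diverged parameters are refused at prediction time", {
  fit <- tiny_combo_model()$fit
  broken <- fit
  broken$params[[1]][1, 1] <- NaN
  expect_error(rank_relations(broken, "D1", "D2"), "non-finite")
})
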