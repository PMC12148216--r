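#' Stratified train/validation/test split of KG triples
#'
#' Triples are split per relation stratum so that every relation label in the
#' graph is guaranteed to occur in the training set: within each stratum the
#' test share is `floor(n * test_frac)` (a single-triple stratum goes entirely
#' to train), the remainder stays on the train side, and the train side is
#' split again the same way into training and validation. Identical seeds give
#' identical splits.
#'
#' @param kg a [knowledge_graph()].
#' @param test_frac fraction of triples held out for testing (default 0.2).
#' @param val_frac fraction of the remaining train-side triples held out for
#'   validation (default 0.2).
#' @param seed integer seed controlling the within-stratum shuffles.
#' @return object of class `kg_split`: list with triple tables `train`,
#'   `validation`, `test`, and `drug_drug_test` (the test triples whose head
#'   and tail are both Drug-typed).
#' @export
split_triples <- function(kg, test_frac = 0.2, val_frac = 0.2, seed = 1L) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (nrow(kg$triples) == 0L) abort("cannot split an empty graph")
  if (!(test_frac > 0 && test_frac < 1) || !(val_frac >= 0 && val_frac < 1))
    abort("fractions must lie in (0, 1)")
  tr <- kg$triples
  n <- nrow(tr)
  test_idx <- integer(0)
  val_idx <- integer(0)
  set.seed(as.integer(seed))
  for (rel in kg$relations) {
    rows <- which(tr$relation == rel)
    m <- length(rows)
    rows <- rows[sample.int(m)]
    n_test <- if (m <= 1L) 0L else floor(m * test_frac)
    test_idx <- c(test_idx, rows[seq_len(n_test)])
    rest <- rows[setdiff(seq_len(m), seq_len(n_test))]
    k <- length(rest)
    n_val <- if (k <= 1L) 0L else floor(k * val_frac)
    val_idx <- c(val_idx, rest[seq_len(n_val)])
  }
  train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  if (!setequal(unique(tr$relation[train_idx]), kg$relations))
    abort("internal error: a relation label is missing from the training split")
  split <- list(train = tr[sort(train_idx), , drop = FALSE],
                validation = tr[sort(val_idx), , drop = FALSE],
                test = tr[sort(test_idx), , drop = FALSE])
  split <- lapply(split, function(d) { rownames(d) <- NULL; d })
  split$drug_drug_test <- drug_drug_subset(split, kg)
  structure(split, class = "kg_split")
}

#' @export
print.kg_split <- function(x, ...) {
  cat(sprintf("KG split: %d train / %d validation / %d test (%d drug-drug test)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test),
              nrow(x$drug_drug_test)))
  invisible(x)
}

#' Drug-drug subset of a test split
#'
#' Returns exactly those test triples whose head and tail are both typed
#' `"Drug"` in the graph's entity registry; used to evaluate a model
#' specifically on drug-drug relation prediction.
#'
#' @param split a `kg_split` (or any list with a `test` triple table).
#' @param kg the [knowledge_graph()] supplying entity types.
#' @return triple data.frame (possibly empty).
#' @export
drug_drug_subset <- function(split, kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  te <- split$test
  keep <- kg$entity_type[te$head] == "Drug" & kg$entity_type[te$tail] == "Drug"
  keep[is.na(keep)] <- FALSE
  out <- te[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
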