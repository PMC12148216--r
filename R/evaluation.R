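#' Percentage of true predictions at a given rank
#'
#' For a set of relation rankings (one per entity pair) and the known true
#' relation of each pair, counts how many rankings place the true relation at
#' exactly rank `k` and reports `100 * n_true / n_total`, where the
#' denominator is the number of evaluated pairs (each pair contributes one
#' prediction per rank).
#'
#' @param rankings list of `relation_ranking` objects (see
#'   [rank_relations()]).
#' @param truth named character vector mapping `"head||tail"` pair keys (see
#'   below) to the true relation, or a data.frame with columns `head`, `tail`,
#'   `relation`. Pair keys are `paste(head, tail, sep = "|>")` — orientation
#'   matters.
#' @param k rank(s) to evaluate (default `1:3`).
#' @return data.frame with one row per rank: `rank`, `n_true`, `n_total`,
#'   `percentage`.
#' @export
true_prediction_percentage <- function(rankings, truth, k = 1:3) {
  if (length(rankings) == 0L) abort("no rankings to evaluate")
  if (is.data.frame(truth))
    truth <- setNames(as.character(truth$relation),
                      paste(truth$head, truth$tail, sep = "|>"))
  keys <- vapply(rankings, function(r)
    paste(attr(r, "head"), attr(r, "tail"), sep = "|>"), character(1))
  if (anyNA(truth[keys]))
    abort("no truth entry for pair(s): %s",
          paste(head(keys[is.na(truth[keys])], 3L), collapse = ", "))
  n_rel <- nrow(rankings[[1L]])
  if (any(k < 1L | k > n_rel)) abort("rank k outside 1..%d", n_rel)
  true_rel <- unname(truth[keys])
  rel_at <- function(r, kk) r$relation[r$rank == kk]
  out <- data.frame(rank = as.integer(k))
  out$n_true <- vapply(k, function(kk) {
    sum(vapply(seq_along(rankings), function(i)
      rel_at(rankings[[i]], kk) == true_rel[i], logical(1)))
  }, numeric(1))
  out$n_total <- length(rankings)
  out$percentage <- 100 * out$n_true / out$n_total
  out
}

#' Binary ROC-AUC via the Mann-Whitney statistic
#'
#' Computes the area under the ROC curve as the concordance probability
#' \eqn{P(s_1 > s_0) + 0.5 P(s_1 = s_0)} using midranks, which handles score
#' ties exactly.
#'
#' @param labels 0/1 (or logical/two-level) vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
binary_roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  if (length(labels) != length(scores)) abort("labels and scores differ in length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest multiclass ROC-AUC
#'
#' For each relation type present in the truth, binarises the truth
#' one-vs-rest, takes that type's score column and computes the binary AUC;
#' the result is the unweighted mean over types (macro average). Score
#' columns for types never observed in the truth are excluded from the mean
#' with a warning.
#'
#' @param truth character/factor vector of true relation types per pair.
#' @param score_matrix numeric matrix, one row per pair, columns named by
#'   relation type.
#' @return list with `macro_auc` and the named `per_type_auc` vector.
#' @export
multiclass_roc_auc <- function(truth, score_matrix) {
  truth <- as.character(truth)
  stopifnot(is.matrix(score_matrix), nrow(score_matrix) == length(truth))
  if (is.null(colnames(score_matrix)))
    abort("score_matrix needs relation-type column names")
  types <- unique(truth)
  if (length(types) < 2L) abort("need at least 2 relation types in truth")
  missing_cols <- setdiff(types, colnames(score_matrix))
  if (length(missing_cols))
    abort("no score column for type(s): %s", paste(missing_cols, collapse = ", "))
  unused <- setdiff(colnames(score_matrix), types)
  if (length(unused))
    warn("%d score column(s) for types absent from truth excluded from the macro mean",
         length(unused))
  per_type <- vapply(sort(types), function(ty)
    binary_roc_auc(truth == ty, score_matrix[, ty]), numeric(1))
  list(macro_auc = mean(per_type), per_type_auc = per_type)
}
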