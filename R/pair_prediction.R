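COMBINATION_RELATIONS <- c("has_synergism_with", "has_antagonism_with")

#' Predict the top relation for every drug pair in both orientations
#'
#' For every unordered drug pair (optionally excluding already-known
#' combinations), ranks all relation types in the forward orientation
#' (a as head, b as tail) and the reverse orientation, and stores the rank-1
#' relation and score of each.
#'
#' @param object fitted [kge()] model.
#' @param drugs character vector of drug entities (>= 2).
#' @param known_pairs optional data.frame (`drug_a`, `drug_b`) of pairs to
#'   exclude, orientation-insensitive.
#' @return data.frame of class `pair_predictions`: `drug_a`, `drug_b` in
#'   canonical order, `forward_relation`, `forward_score`, `reverse_relation`,
#'   `reverse_score`, `consistent` (rank-1 agreement on a combination
#'   relation), `final_label` (`"synergism"`/`"antagonism"`/`NA`).
#' @export
predict_all_pairs <- function(object, drugs, known_pairs = NULL) {
  stopifnot(inherits(object, "kge"))
  check_trained(object)
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) < 2L) abort("need at least 2 drugs")
  missing <- setdiff(drugs, object$entities)
  if (length(missing)) abort("drug(s) not in model: %s",
                             paste(head(missing, 3L), collapse = ", "))
  cmb <- utils::combn(drugs, 2L)
  a <- cmb[1L, ]; b <- cmb[2L, ]
  if (!is.null(known_pairs) && nrow(known_pairs)) {
    known <- pair_key(as.character(known_pairs$drug_a),
                      as.character(known_pairs$drug_b))
    keep <- !(pair_key(a, b) %in% known)
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  n_r <- length(object$relations)
  top1 <- function(h, t) {
    hi <- match(h, object$entities); ti <- match(t, object$entities)
    sc <- matrix(kge_score_batch(object$model, object$params,
                                 rep(hi, each = n_r),
                                 rep(seq_len(n_r), length(hi)),
                                 rep(ti, each = n_r)),
                 nrow = n_r)
    best <- apply(sc, 2L, which.max)  # ties: lowest vocabulary index
    list(relation = object$relations[best],
         score = sc[cbind(best, seq_along(hi))])
  }
  if (n == 0L) {
    out <- data.frame(drug_a = character(), drug_b = character(),
                      forward_relation = character(), forward_score = numeric(),
                      reverse_relation = character(), reverse_score = numeric(),
                      consistent = logical(), final_label = character())
  } else {
    fw <- top1(a, b)
    rv <- top1(b, a)
    consistent <- fw$relation == rv$relation &
      fw$relation %in% COMBINATION_RELATIONS
    final <- ifelse(consistent,
                    ifelse(fw$relation == "has_synergism_with",
                           "synergism", "antagonism"), NA_character_)
    out <- data.frame(drug_a = a, drug_b = b,
                      forward_relation = fw$relation, forward_score = fw$score,
                      reverse_relation = rv$relation, reverse_score = rv$score,
                      consistent = consistent, final_label = final)
  }
  class(out) <- c("pair_predictions", "data.frame")
  out
}

#' Mutual-consistency filter on pair predictions
#'
#' Retains only pairs whose forward and reverse rank-1 relations agree on the
#' same drug-combination relation (mutual synergism or mutual antagonism).
#' Dropped rows get a reason code: `"nonmutual"` when the orientations
#' disagree, `"no_combination_call"` when both agree on a non-combination
#' relation.
#'
#' @param preds output of [predict_all_pairs()].
#' @return retained subset (same columns) with attribute `reasons`, a table of
#'   drop reason codes.
#' @export
mutual_filter <- function(preds) {
  stopifnot(is.data.frame(preds))
  agree <- preds$forward_relation == preds$reverse_relation
  comb <- preds$forward_relation %in% COMBINATION_RELATIONS
  reason <- ifelse(preds$consistent, NA_character_,
                   ifelse(agree & !comb, "no_combination_call", "nonmutual"))
  out <- preds[preds$consistent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reasons") <- table(reason, useNA = "no")
  out
}

#' Segregate mutually consistent pairs into synergism and antagonism sets
#'
#' Partitions retained predictions by final label; each set is sorted by the
#' pair's weaker orientation score (`min(forward, reverse)`) descending, with
#' ties broken by the pair identifiers.
#'
#' @param retained output of [mutual_filter()].
#' @return list with data.frames `synergism` and `antagonism`.
#' @export
segregate <- function(retained) {
  stopifnot(is.data.frame(retained))
  if (nrow(retained) && any(!retained$consistent))
    abort("segregate expects mutually consistent predictions only")
  pick <- function(lbl) {
    d <- retained[!is.na(retained$final_label) & retained$final_label == lbl, ,
                  drop = FALSE]
    if (nrow(d)) {
      s <- pmin(d$forward_score, d$reverse_score)
      d <- d[order(-s, d$drug_a, d$drug_b), , drop = FALSE]
      d$pair_score <- sort(s, decreasing = TRUE)
      rownames(d) <- NULL
    } else d$pair_score <- numeric(0)
    d
  }
  list(synergism = pick("synergism"), antagonism = pick("antagonism"))
}
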