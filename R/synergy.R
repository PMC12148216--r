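#' Harmonize raw drug-combination records
#'
#' Deduplicates combination-screen exports down to one record per unordered
#' drug pair and cell line, averaging replicate ZIP scores on the way. Pair
#' orientation is canonicalized lexicographically, so (A,B) and (B,A)
#' measurements of the same combination are merged. Records with a missing or
#' non-finite ZIP score are dropped with a warning.
#'
#' @param records data.frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   `zip` (other score columns such as `hsa`, `bliss`, `loewe` are carried
#'   through averaged the same way).
#' @return data.frame with one row per (pair, cell line), drugs in canonical
#'   order, scores averaged; idempotent.
#' @export
harmonize_synergy <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("drug_a", "drug_b", "cell_line", "zip")
  if (!all(need %in% names(records)))
    abort("combination table must have columns drug_a, drug_b, cell_line, zip")
  rec <- records
  drop <- !is.finite(rec$zip)
  if (any(drop)) {
    warn("dropping %d record(s) with missing or non-finite zip score", sum(drop))
    rec <- rec[!drop, , drop = FALSE]
  }
  if (nrow(rec) == 0L)
    return(data.frame(drug_a = character(), drug_b = character(),
                      cell_line = character(), zip = numeric()))
  p <- canonical_pair(as.character(rec$drug_a), as.character(rec$drug_b))
  rec$drug_a <- p$a
  rec$drug_b <- p$b
  score_cols <- intersect(c("zip", "hsa", "bliss", "loewe"), names(rec))
  key <- paste(rec$drug_a, rec$drug_b, rec$cell_line, sep = "\r")
  first <- !duplicated(key)
  out <- rec[first, c("drug_a", "drug_b", "cell_line", score_cols)]
  for (sc in score_cols) {
    m <- tapply(rec[[sc]], key, mean)
    out[[sc]] <- as.numeric(m[key[first]])
  }
  out <- out[order(out$drug_a, out$drug_b, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a ZIP score into synergism / antagonism / additive
#'
#' Positive ZIP indicates synergy, negative antagonism; a dead band between
#' the two thresholds is called additive. Thresholds are inclusive.
#'
#' @param zip numeric vector of ZIP scores.
#' @param thresholds length-2 numeric `c(t_syn, t_ant)` with `t_ant < t_syn`;
#'   default `c(10, -10)`.
#' @return character vector in `{"synergism", "antagonism", "additive"}`.
#' @export
label_from_zip <- function(zip, thresholds = c(10, -10)) {
  t_syn <- thresholds[1L]; t_ant <- thresholds[2L]
  if (!(t_ant < t_syn)) abort("thresholds require t_ant < t_syn")
  if (any(!is.finite(zip))) abort("non-finite zip score")
  ifelse(zip >= t_syn, "synergism",
         ifelse(zip <= t_ant, "antagonism", "additive"))
}

#' Cross-cell-line consistency filter
#'
#' Labels each harmonized record per cell line, then keeps a drug pair only
#' when its per-cell-line labels are unanimous and not additive — the same
#' combination showing synergism in one cell line and antagonism (or no
#' interaction) in another carries no usable class signal. Emitted pairs carry
#' the mean ZIP over cell lines.
#'
#' @param records harmonized combination table (see [harmonize_synergy()]).
#' @param thresholds passed to [label_from_zip()].
#' @return data.frame of class labels per retained pair: `drug_a`, `drug_b`,
#'   `label` (`"synergism"`/`"antagonism"`), `mean_zip`, `n_cell_lines`; the
#'   numbers of pairs dropped for mixed or all-additive labels are attached as
#'   attributes `n_dropped_mixed` and `n_dropped_additive`.
#' @export
consistency_filter <- function(records, thresholds = c(10, -10)) {
  rec <- harmonize_synergy(records)
  if (nrow(rec) == 0L) {
    out <- data.frame(drug_a = character(), drug_b = character(),
                      label = character(), mean_zip = numeric(),
                      n_cell_lines = integer())
    attr(out, "n_dropped_mixed") <- 0L
    attr(out, "n_dropped_additive") <- 0L
    return(out)
  }
  rec$label <- label_from_zip(rec$zip, thresholds)
  key <- paste(rec$drug_a, rec$drug_b, sep = "\r")
  pairs <- split(rec, key)
  lab <- vapply(pairs, function(d) {
    u <- unique(d$label)
    if (length(u) > 1L) "mixed" else u
  }, character(1))
  keep <- lab %in% c("synergism", "antagonism")
  kept <- pairs[keep]
  out <- data.frame(
    drug_a = vapply(kept, function(d) d$drug_a[1L], character(1)),
    drug_b = vapply(kept, function(d) d$drug_b[1L], character(1)),
    label = unname(lab[keep]),
    mean_zip = vapply(kept, function(d) mean(d$zip), numeric(1)),
    n_cell_lines = vapply(kept, nrow, integer(1)))
  out <- out[order(out$drug_a, out$drug_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_mixed") <- sum(lab == "mixed")
  attr(out, "n_dropped_additive") <- sum(lab == "additive")
  out
}

#' Enrich a knowledge graph with drug-combination edges
#'
#' Adds one reciprocal pair of triples (`A -> B` and `B -> A`) per retained
#' pair label, using relation `has_synergism_with` or `has_antagonism_with`.
#' Additive pairs are excluded by default: they are vanishingly rare in
#' combination screens and would only add class imbalance. Pairs whose drugs
#' cannot be resolved to graph entities are skipped and counted.
#'
#' @param kg a [knowledge_graph()].
#' @param labels pair-label table from [consistency_filter()].
#' @param include_additive also add `has_additive_effect_with` edges for
#'   additive labels (default `FALSE`).
#' @return enriched [knowledge_graph()] with attribute `n_skipped` (pairs with
#'   unresolvable drugs).
#' @export
enrich_kg <- function(kg, labels, include_additive = FALSE) {
  stopifnot(inherits(kg, "knowledge_graph"), is.data.frame(labels))
  rel_of <- c(synergism = "has_synergism_with",
              antagonism = "has_antagonism_with",
              additive = "has_additive_effect_with")
  lab <- labels
  if (!include_additive) lab <- lab[lab$label != "additive", , drop = FALSE]
  resolvable <- lab$drug_a %in% kg$entities & lab$drug_b %in% kg$entities
  n_skipped <- sum(!resolvable)
  if (n_skipped)
    warn("skipping %d pair(s) whose drugs are not graph entities", n_skipped)
  lab <- lab[resolvable, , drop = FALSE]
  if (nrow(lab)) {
    new_tr <- data.frame(
      head = c(lab$drug_a, lab$drug_b),
      relation = rep(unname(rel_of[lab$label]), 2L),
      tail = c(lab$drug_b, lab$drug_a))
    out <- knowledge_graph(rbind(kg$triples[, c("head", "relation", "tail")][
      rep(seq_len(nrow(kg$triples)), kg$triples$count), ], new_tr),
      entity_type = kg$entity_type)
  } else {
    out <- kg
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
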