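#' Fit a knowledge-graph embedding model
#'
#' Learns entity and relation embeddings from the triples of a knowledge graph
#' under the stochastic local closed-world assumption (SLCWA): each observed
#' triple is a positive example, and negatives are drawn by randomly
#' corrupting its head or tail with a uniformly sampled entity. Training
#' minimises either a margin-ranking loss over positive/negative score pairs
#' (the convention for the translational/rotational models TransE, TransR and
#' RotatE) or a softplus (logistic) loss over signed scores (the convention
#' for the bilinear models ComplEx and HolE) by mini-batch Adam.
#'
#' Score functions (higher = more plausible):
#' \describe{
#'   \item{TransE}{\eqn{-\lVert h + r - t \rVert_2}; entity vectors are
#'     renormalised to unit length after every step.}
#'   \item{TransR}{\eqn{-\lVert M_r h + r - M_r t \rVert_2^2} with a
#'     per-relation projection matrix \eqn{M_r}.}
#'   \item{RotatE}{\eqn{-\lVert h \circ r - t \rVert} with complex embeddings
#'     and unit-modulus relations, stored as phase angles so the constraint
#'     holds exactly.}
#'   \item{ComplEx}{\eqn{\mathrm{Re}(\sum_i h_i r_i \bar t_i)} with complex
#'     embeddings.}
#'   \item{HolE}{\eqn{r \cdot (h \star t)} where \eqn{\star} is circular
#'     correlation, computed via FFT.}
#' }
#'
#' @param x a [knowledge_graph()] or a triple data.frame with columns
#'   `head`, `relation`, `tail` (optional `count` repeats a triple).
#' @param model one of `"TransE"`, `"TransR"`, `"RotatE"`, `"ComplEx"`,
#'   `"HolE"`.
#' @param dim embedding dimension (default 64).
#' @param epochs number of passes over the training triples.
#' @param batch_size positives per mini-batch.
#' @param negatives corrupted triples sampled per positive (k >= 1).
#' @param learning_rate Adam step size.
#' @param margin margin of the ranking loss (ignored for softplus).
#' @param loss `"margin_ranking"` or `"softplus"`; default follows the model
#'   convention above.
#' @param relation_corruption fraction of negatives corrupting the relation
#'   slot instead of an entity slot (default 1/3 when the graph has more than
#'   one relation type, else 0). Entity corruption alone never penalises a
#'   wrong relation on a true entity pair, so a model trained that way ranks
#'   relations poorly; mixing in relation corruptions supplies that training
#'   signal directly, which matters because relation ranking between fixed
#'   entity pairs is the downstream prediction task.
#' @param filter_negatives drop sampled corruptions that happen to be observed
#'   triples (default `FALSE`, plain SLCWA).
#' @param seed integer seed; identical config + seed gives identical
#'   parameters.
#' @param verbose print per-epoch losses.
#' @return object of class `kge`: model name, entity/relation vocabularies,
#'   parameter matrices, config and per-epoch mean loss trajectory.
#' @seealso [rank_relations()], [score_triples()], [predict.kge()]
#' @examples
#' kg <- knowledge_graph(data.frame(
#'   head = c("a", "b", "c"), relation = "r", tail = c("b", "c", "a")))
#' fit <- kge(kg, model = "TransE", dim = 8, epochs = 5, seed = 1)
#' rank_relations(fit, "a", "b")
#' @export
kge <- function(x, model = c("TransE", "TransR", "RotatE", "ComplEx", "HolE"),
                dim = 64L, epochs = 100L, batch_size = 256L, negatives = 4L,
                learning_rate = 0.01, margin = 1.0, loss = NULL,
                relation_corruption = NULL, filter_negatives = FALSE,
                seed = 1L, verbose = FALSE) {
  model <- match.arg(model)
  tr <- if (inherits(x, "knowledge_graph")) x$triples else {
    stopifnot(is.data.frame(x))
    knowledge_graph(x)$triples
  }
  if (nrow(tr) == 0L) abort("no training triples")
  if (!is_count(negatives)) abort("negatives per positive must be >= 1")
  if (!is_count(epochs) || !is_count(batch_size)) abort("epochs and batch_size must be positive integers")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (is.null(loss))
    loss <- if (model %in% c("ComplEx", "HolE")) "softplus" else "margin_ranking"
  loss <- match.arg(loss, c("margin_ranking", "softplus"))

  entities <- sort(unique(c(tr$head, tr$tail)))
  relations <- sort(unique(tr$relation))
  n_e <- length(entities)
  n_r <- length(relations)
  if (n_e < 2L) abort("need at least 2 entities to sample negatives")
  if (is.null(relation_corruption))
    relation_corruption <- if (n_r > 1L) 1 / 3 else 0
  if (relation_corruption < 0 || relation_corruption >= 1)
    abort("relation_corruption must lie in [0, 1)")
  rel_frac <- if (n_r > 1L) relation_corruption else 0
  hi0 <- match(tr$head, entities)
  ri0 <- match(tr$relation, relations)
  ti0 <- match(tr$tail, entities)
  rep_idx <- rep(seq_len(nrow(tr)), tr$count)
  hi0 <- hi0[rep_idx]; ri0 <- ri0[rep_idx]; ti0 <- ti0[rep_idx]
  n_pos <- length(hi0)
  observed <- NULL
  if (filter_negatives)
    observed <- paste(hi0, ri0, ti0, sep = ".")

  set.seed(as.integer(seed))
  params <- kge_init_params(model, n_e, n_r, dim)
  params <- kge_apply_constraints(model, params, model == "TransE")
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  k <- as.integer(negatives)
  loss_traj <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_pos)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n_pos, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_pos)]
      b <- length(idx)
      ph <- hi0[idx]; pr <- ri0[idx]; pt <- ti0[idx]
      # SLCWA corruption: replicate each positive k times, corrupt head or
      # tail by coin flip with a uniform entity
      nh <- rep(ph, k); nr <- rep(pr, k); nt <- rep(pt, k)
      slot <- runif(b * k)
      corrupt_rel <- slot < rel_frac
      corrupt_head <- !corrupt_rel & slot < rel_frac + (1 - rel_frac) / 2
      corrupt_tail <- !corrupt_rel & !corrupt_head
      repl <- sample.int(n_e, b * k, replace = TRUE)
      nh[corrupt_head] <- repl[corrupt_head]
      nt[corrupt_tail] <- repl[corrupt_tail]
      if (any(corrupt_rel))
        nr[corrupt_rel] <- sample.int(n_r, sum(corrupt_rel), replace = TRUE)
      if (filter_negatives) {
        hit <- paste(nh, nr, nt, sep = ".") %in% observed
        guard <- 0L
        while (any(hit) && guard < 100L) {
          ch <- corrupt_head & hit; ct <- corrupt_tail & hit
          cr <- corrupt_rel & hit
          nh[ch] <- sample.int(n_e, sum(ch), replace = TRUE)
          nt[ct] <- sample.int(n_e, sum(ct), replace = TRUE)
          nr[cr] <- sample.int(n_r, sum(cr), replace = TRUE)
          hit <- paste(nh, nr, nt, sep = ".") %in% observed
          guard <- guard + 1L
        }
      }
      s_pos <- kge_score_batch(model, params, ph, pr, pt)
      s_neg <- kge_score_batch(model, params, nh, nr, nt)
      if (loss == "margin_ranking") {
        viol <- margin - rep(s_pos, k) + s_neg
        active <- viol > 0
        batch_loss <- sum(pmax(viol, 0)) / (b * k)
        ds_neg <- as.numeric(active) / (b * k)
        ds_pos_rep <- -as.numeric(active) / (b * k)
        ds_pos <- rowsum(matrix(ds_pos_rep, ncol = 1),
                         group = rep(seq_len(b), k))[, 1L]
      } else {
        sp <- function(z) ifelse(z > 30, z, log1p(exp(z)))
        sig <- function(z) 1 / (1 + exp(-z))
        n_tot <- b + b * k
        batch_loss <- (sum(sp(-s_pos)) + sum(sp(s_neg))) / n_tot
        ds_pos <- -sig(-s_pos) / n_tot
        ds_neg <- sig(s_neg) / n_tot
      }
      if (!is.finite(batch_loss))
        abort("NaN/Inf loss at epoch %d: learning rate likely too high", ep)
      g_pos <- kge_grad_batch(model, params, ph, pr, pt, ds_pos)
      g_neg <- kge_grad_batch(model, params, nh, nr, nt, ds_neg)
      step <- step + 1L
      bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
      for (nm in names(params)) {
        g <- g_pos[[nm]] + g_neg[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        params[[nm]] <- params[[nm]] - learning_rate *
          (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + adam_eps)
      }
      params <- kge_apply_constraints(model, params, model == "TransE")
      ep_loss <- ep_loss + batch_loss * b
      ep_n <- ep_n + b
    }
    loss_traj[ep] <- ep_loss / ep_n
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, loss_traj[ep]))
  }

  structure(list(model = model, dim = as.integer(dim), entities = entities,
                 relations = relations, params = params,
                 config = list(epochs = as.integer(epochs),
                               batch_size = as.integer(batch_size),
                               negatives = k, learning_rate = learning_rate,
                               margin = margin, loss = loss,
                               relation_corruption = rel_frac,
                               filter_negatives = filter_negatives,
                               seed = as.integer(seed)),
                 loss_trajectory = loss_traj, call = match.call()),
            class = "kge")
}

#' @export
print.kge <- function(x, ...) {
  cat(sprintf("%s knowledge-graph embedding (d = %d): %d entities, %d relations\n",
              x$model, x$dim, length(x$entities), length(x$relations)))
  cat(sprintf("trained %d epochs (%s loss), final mean loss %.5f\n",
              x$config$epochs, x$config$loss,
              x$loss_trajectory[length(x$loss_trajectory)]))
  invisible(x)
}

#' @export
summary.kge <- function(object, ...) {
  print(object)
  cat(sprintf("config: batch %d, %d negatives/positive, lr %g, seed %d\n",
              object$config$batch_size, object$config$negatives,
              object$config$learning_rate, object$config$seed))
  invisible(object)
}

#' @export
plot.kge <- function(x, ...) {
  plot(seq_along(x$loss_trajectory), x$loss_trajectory, type = "l",
       xlab = "epoch", ylab = "mean loss",
       main = sprintf("%s training loss", x$model), ...)
  invisible(x)
}

#' Extract embedding vectors from a fitted model
#'
#' @param object a fitted [kge()] model.
#' @param ... unused.
#' @return list with `entities` and `relations` matrices (complex for RotatE
#'   and ComplEx; RotatE relations are reassembled from their phases, so every
#'   coordinate has unit modulus). TransR additionally returns the projection
#'   array `relation_projections`.
#' @export
coef.kge <- function(object, ...) {
  p <- object$params
  out <- switch(object$model,
    TransE = , HolE = list(entities = p$E, relations = p$R),
    TransR = list(entities = p$E, relations = p$R,
                  relation_projections = p$M),
    RotatE = list(entities = p$E_re + 1i * p$E_im,
                  relations = cos(p$theta) + 1i * sin(p$theta)),
    ComplEx = list(entities = p$E_re + 1i * p$E_im,
                   relations = p$R_re + 1i * p$R_im))
  rownames(out$entities) <- object$entities
  rownames(out$relations) <- object$relations
  out
}

check_trained <- function(object) {
  if (!all(vapply(object$params, function(p) all(is.finite(p)), logical(1))))
    abort("model parameters contain non-finite values (untrained or diverged)")
}

#' Score (head, relation, tail) triples under a fitted model
#'
#' @param object fitted [kge()] model.
#' @param triples data.frame with columns `head`, `relation`, `tail`.
#' @return numeric score vector (higher = more plausible).
#' @export
score_triples <- function(object, triples) {
  stopifnot(inherits(object, "kge"), is.data.frame(triples))
  check_trained(object)
  hi <- match(as.character(triples$head), object$entities)
  ri <- match(as.character(triples$relation), object$relations)
  ti <- match(as.character(triples$tail), object$entities)
  if (anyNA(hi) || anyNA(ti))
    abort("unknown entity: %s",
          paste(unique(c(triples$head[is.na(hi)], triples$tail[is.na(ti)])),
                collapse = ", "))
  if (anyNA(ri))
    abort("unknown relation: %s",
          paste(unique(triples$relation[is.na(ri)]), collapse = ", "))
  kge_score_batch(object$model, object$params, hi, ri, ti)
}

#' Rank all relation types between a fixed entity pair
#'
#' Scores every relation label for the directed pair (head, tail) and sorts
#' descending; exact score ties are broken by relation vocabulary order, so
#' the ranking is deterministic.
#'
#' @param object fitted [kge()] model.
#' @param head,tail entity identifiers.
#' @return object of class `relation_ranking`: data.frame with columns
#'   `relation`, `score`, `rank` covering the full vocabulary exactly once.
#' @export
rank_relations <- function(object, head, tail) {
  stopifnot(inherits(object, "kge"), length(head) == 1L, length(tail) == 1L)
  check_trained(object)
  hi <- match(as.character(head), object$entities)
  ti <- match(as.character(tail), object$entities)
  if (is.na(hi)) abort("unknown entity: %s", head)
  if (is.na(ti)) abort("unknown entity: %s", tail)
  n_r <- length(object$relations)
  sc <- kge_score_batch(object$model, object$params,
                        rep(hi, n_r), seq_len(n_r), rep(ti, n_r))
  ord <- order(-sc, seq_len(n_r))
  out <- data.frame(relation = object$relations[ord], score = sc[ord],
                    rank = seq_len(n_r))
  attr(out, "head") <- as.character(head)
  attr(out, "tail") <- as.character(tail)
  class(out) <- c("relation_ranking", "data.frame")
  out
}

#' Predict relation rankings or triple scores from a fitted embedding
#'
#' With `type = "relations"` returns the full relation ranking for the pair
#' (`head`, `tail`); with `type = "score"` scores the triples in `newdata`.
#'
#' @param object fitted [kge()] model.
#' @param newdata triple data.frame (for `type = "score"`).
#' @param head,tail entity identifiers (for `type = "relations"`).
#' @param type `"relations"` or `"score"`.
#' @param ... unused.
#' @return a `relation_ranking` or a numeric score vector.
#' @export
predict.kge <- function(object, newdata = NULL, head = NULL, tail = NULL,
                        type = c("relations", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") return(score_triples(object, newdata))
  rank_relations(object, head, tail)
}

#' Sample SLCWA negative triples
#'
#' Each positive triple yields `k` corruptions; a fair coin picks head or tail
#' and the chosen slot is replaced by a uniformly sampled entity. Under plain
#' SLCWA a corruption may coincide with an observed triple; set
#' `filter = TRUE` to resample such collisions.
#'
#' @param triples positive triple data.frame (`head`, `relation`, `tail`).
#' @param entities entity vocabulary to sample replacements from.
#' @param k corruptions per positive (>= 1).
#' @param seed integer seed.
#' @param filter resample corruptions that equal an observed triple.
#' @return data.frame of `nrow(triples) * k` corrupted triples.
#' @export
sample_negatives <- function(triples, entities, k = 1L, seed = 1L,
                             filter = FALSE) {
  stopifnot(is.data.frame(triples))
  if (!is_count(k)) abort("k must be a positive integer")
  if (length(entities) < 2L) abort("need at least 2 entities to corrupt triples")
  set.seed(as.integer(seed))
  n <- nrow(triples)
  h <- rep(as.character(triples$head), k)
  r <- rep(as.character(triples$relation), k)
  t_ <- rep(as.character(triples$tail), k)
  corrupt_head <- runif(n * k) < 0.5
  repl <- sample(entities, n * k, replace = TRUE)
  h[corrupt_head] <- repl[corrupt_head]
  t_[!corrupt_head] <- repl[!corrupt_head]
  if (filter) {
    obs <- paste(triples$head, triples$relation, triples$tail, sep = "\r")
    hit <- paste(h, r, t_, sep = "\r") %in% obs
    guard <- 0L
    while (any(hit) && guard < 1000L) {
      repl2 <- sample(entities, sum(hit), replace = TRUE)
      ch <- corrupt_head[hit]
      h[hit][ch] <- repl2[ch]
      t_[hit][!ch] <- repl2[!ch]
      hit <- paste(h, r, t_, sep = "\r") %in% obs
      guard <- guard + 1L
    }
  }
  data.frame(head = h, relation = r, tail = t_)
}
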