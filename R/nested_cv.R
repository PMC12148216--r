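# Nested cross-validated benchmark of classical synergy classifiers.

#' Stratified holdout split
#'
#' Splits indices into a retained portion and a holdout of exactly
#' `floor(n * frac)` samples, allocated per class by floor-plus-largest-
#' remainder so class proportions stay within one sample of the stratified
#' ideal.
#'
#' @param y class vector.
#' @param frac holdout fraction.
#' @return list with integer index vectors `keep` and `holdout`.
#' @export
stratified_holdout <- function(y, frac = 0.1) {
  n <- length(y)
  n_hold <- floor(n * frac)
  cls <- split(seq_len(n), y)
  exact <- vapply(cls, length, numeric(1)) * frac
  base <- pmin(floor(exact), vapply(cls, length, numeric(1)))
  rem <- n_hold - sum(base)
  if (rem > 0) {
    extra <- order(exact - floor(exact), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  hold <- unlist(lapply(seq_along(cls), function(i) {
    idx <- cls[[i]]
    idx[sample.int(length(idx), base[i])]
  }), use.names = FALSE)
  list(keep = setdiff(seq_len(n), hold), holdout = sort(hold))
}

# --- classifier wrappers ----------------------------------------------------
# Each wrapper exposes fit(x, y01, params) and prob(fit, x); y01 is 0/1.

cv_learners <- function() {
  list(
    logistic_regression = list(
      fit = function(x, y, params) {
        df <- as.data.frame(x)
        stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial(),
                   control = list(maxit = 50))
      },
      prob = function(fit, x) as.numeric(predict(fit, as.data.frame(x),
                                                 type = "response"))),
    elastic_net = list(
      fit = function(x, y, params)
        glmnet::glmnet(as.matrix(x), y, family = "binomial",
                       alpha = params$alpha, lambda = params$lambda),
      prob = function(fit, x) as.numeric(predict(fit, as.matrix(x),
                                                 type = "response"))),
    gradient_boosting = list(
      fit = function(x, y, params)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = params$max_depth, eta = params$eta,
                        nthread = 1),
          data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
          nrounds = params$nrounds, verbose = 0),
      prob = function(fit, x)
        as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(x))))),
    random_forest = list(
      fit = function(x, y, params)
        randomForest::randomForest(as.matrix(x), factor(y, levels = c(0, 1)),
                                   ntree = params$ntree,
                                   mtry = min(params$mtry, ncol(x))),
      prob = function(fit, x)
        predict(fit, as.matrix(x), type = "prob")[, "1"]),
    svm = list(
      fit = function(x, y, params)
        e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                   cost = params$cost, kernel = "radial", probability = TRUE,
                   scale = apply(x, 2, function(col) stats::sd(col) > 0)),
      prob = function(fit, x) {
        p <- predict(fit, as.matrix(x), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }))
}

#' Default hyperparameter grids for the five classifiers
#'
#' Small fixed grids per learner; each grid is a list of parameter lists.
#'
#' @param p number of features (used to scale the random-forest `mtry` grid).
#' @return named list of grids.
#' @export
default_grids <- function(p) {
  list(
    logistic_regression = list(list()),
    elastic_net = lapply(expand_grid_list(alpha = c(0.2, 0.5, 0.8),
                                          lambda = c(0.01, 0.1)), identity),
    gradient_boosting = expand_grid_list(nrounds = 50,
                                         max_depth = c(2, 4),
                                         eta = c(0.1, 0.3)),
    random_forest = expand_grid_list(ntree = 200,
                                     mtry = unique(pmax(1, round(c(sqrt(p), p / 3))))),
    svm = expand_grid_list(cost = c(0.1, 1, 10)))
}

# cross of named value vectors -> list of parameter lists
expand_grid_list <- function(...) {
  g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Nested cross-validated classifier benchmark for drug pairs
#'
#' Reproduces the nested scheme used to benchmark synergism/antagonism
#' classifiers: the data is first split into a stratified retained portion
#' (90%) and a hold-out test set (10%). Then `inner_loops` (default 10)
#' stratified 90/10 splits of the retained portion drive a grid search: each
#' loop picks the grid point with the best validation ROC-AUC. Finally one
#' model instance per loop is refit on the whole retained portion with that
#' loop's best parameters and evaluated on the hold-out by ROC-AUC.
#'
#' @param features numeric matrix/data.frame, one row per drug pair.
#' @param labels vector in `{"synergism", "antagonism"}` (synergism is the
#'   positive class) or 0/1.
#' @param models subset of `c("logistic_regression", "elastic_net",
#'   "gradient_boosting", "random_forest", "svm")`.
#' @param grids named list of hyperparameter grids (default
#'   [default_grids()]).
#' @param inner_loops number of inner HPO loops, hence refit instances.
#' @param holdout_frac,inner_frac holdout/validation fractions (default 0.1).
#' @param seed integer seed controlling all splits.
#' @return object of class `cv_report`: per model, the hold-out ROC-AUC of
#'   each refit instance, the chosen parameters per loop, and the split sizes.
#' @export
nested_cv <- function(features, labels,
                      models = c("logistic_regression", "elastic_net",
                                 "gradient_boosting", "random_forest", "svm"),
                      grids = NULL, inner_loops = 10L, holdout_frac = 0.1,
                      inner_frac = 0.1, seed = 1L) {
  x <- as.matrix(features)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("synergism", "antagonism"))
    if (length(bad)) abort("unexpected label(s): %s", paste(bad, collapse = ", "))
    y <- as.integer(labels == "synergism")
  } else y <- as.integer(labels)
  n <- length(y)
  if (n < 20L) abort("need at least 20 pairs")
  if (length(unique(y)) < 2L) abort("both classes must be present")
  models <- match.arg(models, several.ok = TRUE)
  learners <- cv_learners()
  if (is.null(grids)) grids <- default_grids(ncol(x))
  for (m in models)
    if (is.null(grids[[m]]) || length(grids[[m]]) == 0L)
      abort("empty hyperparameter grid for %s", m)

  set.seed(as.integer(seed))
  outer <- stratified_holdout(y, holdout_frac)
  x_tr <- x[outer$keep, , drop = FALSE]; y_tr <- y[outer$keep]
  x_ho <- x[outer$holdout, , drop = FALSE]; y_ho <- y[outer$holdout]

  report <- list()
  for (m in models) {
    lr <- learners[[m]]
    grid <- grids[[m]]
    best_params <- vector("list", inner_loops)
    for (loop in seq_len(inner_loops)) {
      inner <- stratified_holdout(y_tr, inner_frac)
      xi <- x_tr[inner$keep, , drop = FALSE]; yi <- y_tr[inner$keep]
      xv <- x_tr[inner$holdout, , drop = FALSE]; yv <- y_tr[inner$holdout]
      val_auc <- vapply(grid, function(params) {
        fit <- lr$fit(xi, yi, params)
        binary_roc_auc(yv, lr$prob(fit, xv))
      }, numeric(1))
      best_params[[loop]] <- grid[[which.max(val_auc)]]
    }
    holdout_auc <- vapply(seq_len(inner_loops), function(loop) {
      fit <- lr$fit(x_tr, y_tr, best_params[[loop]])
      binary_roc_auc(y_ho, lr$prob(fit, x_ho))
    }, numeric(1))
    report[[m]] <- list(holdout_auc = holdout_auc, best_params = best_params)
  }
  structure(list(models = report,
                 sizes = list(n = n, n_train = length(outer$keep),
                              n_holdout = length(outer$holdout),
                              n_inner_train = length(y_tr) - floor(length(y_tr) * inner_frac),
                              n_inner_val = floor(length(y_tr) * inner_frac)),
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Nested CV: %d pairs -> %d train / %d holdout\n",
              x$sizes$n, x$sizes$n_train, x$sizes$n_holdout))
  for (m in names(x$models)) {
    a <- x$models[[m]]$holdout_auc
    cat(sprintf("  %-20s holdout ROC-AUC %.3f (min %.3f, max %.3f, %d instances)\n",
                m, mean(a), min(a), max(a), length(a)))
  }
  invisible(x)
}
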