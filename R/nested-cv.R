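#' Fit one-vs-rest DOE models under nested cross-validation
#'
#' The central fitting function of the package. For each DOE class a binary
#' gradient-boosted model is trained one-vs-rest under a nested
#' \code{k_outer} x \code{k_inner} cross-validation: within each outer round,
#' \code{k_inner} models are trained on the inner training folds with early
#' stopping on their inner validation fold, each predicts the outer holdout
#' set, and the holdout probability is the arithmetic mean of the inner
#' models' probabilities. Every item therefore receives exactly one holdout
#' prediction per class, produced only by models that never saw its row in
#' training or early-stopping validation. Missing feature values are passed
#' natively to the tree learner; no imputation or normalization is applied.
#'
#' @param x Numeric design matrix (rows = items; \code{NA} allowed).
#' @param y Logical/0-1 matrix or data frame of labels, one column per DOE
#'   class, rows aligned with \code{x}.
#' @param plan A [make_cv_plan()] object for \code{rownames(x)} (built
#'   automatically from \code{seed} when omitted).
#' @param config A [doe_model_config()].
#' @param seed Seed used when building the plan.
#' @param classes Class names (defaults to \code{colnames(y)}).
#' @param keep_models Keep the trained boosters (needed by \code{predict}
#'   and [feature_attribution()]).
#' @return Object of class \code{doe_nested_cv} with elements
#'   \code{predictions} (data frame: item, class, probability, outer_fold,
#'   n_inner_models), \code{plan}, \code{config}, \code{classes},
#'   \code{y}, \code{feature_names}, and (if kept) \code{models} plus
#'   per-model training-row bookkeeping in \code{train_index}.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_genes = 200, seed = 5, embed_dim_gene = 8,
#'                   embed_dim_protein = 8, n_tabular = 6)
#' u <- generate_gene_universe(cfg)
#' x <- as.matrix(u$features[, -1]); rownames(x) <- u$features$gene_id
#' y <- u$labels[, -1] * 1
#' fit <- doe_nested_cv(x, y, seed = 5, config = doe_model_config(nrounds = 10))
#' print(fit)
#' }
#' @export
doe_nested_cv <- function(x, y, plan = NULL, config = doe_model_config(),
                          seed = 1L, classes = NULL, keep_models = TRUE) {
  x <- as.matrix(x)
  if (is.data.frame(y)) y <- as.matrix(y)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L, dimnames = list(NULL, "class1"))
  storage.mode(y) <- "double"
  stopifnot(nrow(x) == nrow(y))
  classes <- classes %||% colnames(y) %||% paste0("class", seq_len(ncol(y)))
  colnames(y) <- classes
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  if (is.null(plan)) plan <- make_cv_plan(ids, seed = seed)
  stopifnot(length(plan$ids) == nrow(x))

  models <- list(); train_index <- list(); preds <- list()
  for (cls in classes) {
    lab <- y[, cls]
    cls_models <- list(); cls_train <- list()
    prob <- rep(NA_real_, nrow(x)); fold_of <- rep(NA_integer_, nrow(x))
    for (o in seq_len(plan$k_outer)) {
      hold <- which(plan$outer == o)
      d_hold <- xgboost::xgb.DMatrix(x[hold, , drop = FALSE])
      acc <- 0
      for (i in seq_len(plan$k_inner)) {
        tr <- which(plan$outer != o & plan$inner[, o] != i)
        va <- which(plan$outer != o & plan$inner[, o] == i)
        if (length(unique(lab[tr])) < 2L)
          stop("class '", cls, "' absent from inner training fold (outer ", o,
               ", inner ", i, "); consider the strata argument of ",
               "make_cv_plan or larger folds")
        booster <- train_booster(x[tr, , drop = FALSE], lab[tr],
                                 x[va, , drop = FALSE], lab[va], config)
        acc <- acc + predict(booster, d_hold)
        cls_models[[paste(o, i, sep = ".")]] <- booster
        cls_train[[paste(o, i, sep = ".")]] <- c(tr, va)
      }
      prob[hold] <- acc / plan$k_inner
      fold_of[hold] <- o
    }
    preds[[cls]] <- data.frame(item = ids, class = cls, probability = prob,
                               outer_fold = fold_of,
                               n_inner_models = plan$k_inner,
                               stringsAsFactors = FALSE)
    models[[cls]] <- cls_models
    train_index[[cls]] <- cls_train
  }

  structure(list(
    predictions = do.call(rbind, c(preds, list(make.row.names = FALSE))),
    plan = plan, config = config, classes = classes, y = y, x = x,
    feature_names = colnames(x),
    models = if (keep_models) models,
    train_index = train_index
  ), class = "doe_nested_cv")
}

train_booster <- function(x_tr, y_tr, x_va, y_va, config) {
  params <- unclass(config)
  nrounds <- params$nrounds %||% 100L
  esr <- params$early_stopping_rounds %||% 10L
  params$nrounds <- params$early_stopping_rounds <- NULL
  d_tr <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
  d_va <- xgboost::xgb.DMatrix(x_va, label = y_va)
  xgboost::xgb.train(params = params, data = d_tr, nrounds = nrounds,
                     evals = list(valid = d_va),
                     early_stopping_rounds = esr, verbose = 0)
}

#' @export
print.doe_nested_cv <- function(x, ...) {
  cat(sprintf("Nested %dx%d CV DOE model: %d items, %d features, classes: %s\n",
              x$plan$k_outer, x$plan$k_inner, length(x$plan$ids),
              length(x$feature_names), paste(x$classes, collapse = ", ")))
  cat("Holdout probability summary by class:\n")
  for (cls in x$classes) {
    p <- x$predictions$probability[x$predictions$class == cls]
    cat(sprintf("  %-10s mean %.3f  [%.3f, %.3f]  prevalence %.3f\n",
                cls, mean(p), min(p), max(p), mean(x$y[, cls])))
  }
  invisible(x)
}

#' @export
fitted.doe_nested_cv <- function(object, ...) {
  out <- sapply(object$classes, function(cls)
    object$predictions$probability[object$predictions$class == cls])
  rownames(out) <- object$plan$ids
  out
}

#' @export
residuals.doe_nested_cv <- function(object, ...) {
  object$y - fitted(object)
}

#' Evaluate nested-CV holdout predictions
#'
#' @param object A [doe_nested_cv()] fit.
#' @param beta F-beta weight for cutoff selection.
#' @param n_boot Bootstrap iterations for AUROC confidence intervals.
#' @param seed Bootstrap seed.
#' @param ... Unused.
#' @return A [evaluation_report()] object.
#' @export
summary.doe_nested_cv <- function(object, beta = 1, n_boot = 1000L,
                                  seed = 1L, ...) {
  p <- fitted(object)
  evaluation_report(
    scores_by_class = lapply(object$classes, function(cls) p[, cls]) |>
      stats::setNames(object$classes),
    labels_by_class = lapply(object$classes, function(cls) object$y[, cls]) |>
      stats::setNames(object$classes),
    beta = beta, n_boot = n_boot, seed = seed)
}

#' Predict DOE probabilities for new items
#'
#' Averages the probabilities of every inner-fold model from every outer
#' round (\code{k_outer * k_inner} models per class).
#'
#' @param object A [doe_nested_cv()] fit with kept models.
#' @param newdata Numeric matrix with the same feature columns as training.
#' @param ... Unused.
#' @return Matrix of probabilities, one column per class.
#' @export
predict.doe_nested_cv <- function(object, newdata, ...) {
  if (is.null(object$models))
    stop("models were not kept; refit with keep_models = TRUE")
  newdata <- as.matrix(newdata)
  d <- xgboost::xgb.DMatrix(newdata[, object$feature_names, drop = FALSE])
  out <- sapply(object$classes, function(cls) {
    ms <- object$models[[cls]]
    Reduce(`+`, lapply(ms, function(m) predict(m, d))) / length(ms)
  })
  rownames(out) <- rownames(newdata)
  out
}

#' Plot calibration of holdout predictions
#'
#' @param x A [doe_nested_cv()] fit.
#' @param n_bins Calibration bins.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.doe_nested_cv <- function(x, n_bins = 10L, ...) {
  p <- fitted(x)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "Mean predicted probability",
                 ylab = "Observed positive rate", ...)
  cols <- seq_along(x$classes) + 1L
  for (k in seq_along(x$classes)) {
    cal <- calibration(p[, x$classes[k]], x$y[, x$classes[k]], n_bins = n_bins)
    graphics::lines(cal$curve$mean_pred, cal$curve$obs_rate, type = "b",
                    col = cols[k], pch = 19)
  }
  graphics::legend("topleft", legend = x$classes, col = cols, pch = 19, bty = "n")
  invisible(x)
}

#' Additive feature attributions for holdout predictions
#'
#' Computes per-item, per-feature additive contributions (plus a bias term)
#' for each item's own outer-holdout rows, averaged over the same inner
#' models whose probabilities were averaged. The attributions satisfy local
#' additivity: bias + sum of contributions equals the (averaged) model
#' margin for that row. Global importance is the mean absolute contribution
#' per feature.
#'
#' @param object A [doe_nested_cv()] fit with kept models.
#' @param class DOE class to attribute (default first).
#' @return List: \code{contributions} (items x features matrix),
#'   \code{bias} (per-item), \code{importance} (named vector, mean
#'   |contribution|), \code{margin} (per-item averaged margin).
#' @export
feature_attribution <- function(object, class = object$classes[1L]) {
  if (is.null(object$models))
    stop("models were not kept; refit with keep_models = TRUE")
  plan <- object$plan
  n <- length(plan$ids)
  p <- length(object$feature_names)
  contrib <- matrix(NA_real_, n, p, dimnames = list(plan$ids, object$feature_names))
  bias <- rep(NA_real_, n)
  for (o in seq_len(plan$k_outer)) {
    hold <- which(plan$outer == o)
    d <- xgboost::xgb.DMatrix(object$x[hold, , drop = FALSE])
    acc <- 0
    for (i in seq_len(plan$k_inner)) {
      m <- object$models[[class]][[paste(o, i, sep = ".")]]
      acc <- acc + predict(m, d, predcontrib = TRUE)
    }
    acc <- acc / plan$k_inner
    contrib[hold, ] <- acc[, seq_len(p), drop = FALSE]
    bias[hold] <- acc[, p + 1L]
  }
  list(contributions = contrib, bias = bias,
       importance = colMeans(abs(contrib)),
       margin = bias + rowSums(contrib))
}
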