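#' Train on well-characterized genes, predict the least-characterized
#'
#' Generalization check for undercharacterized targets: items are ranked by a
#' publication-novelty score, the top \code{holdout_fraction} is held out
#' entirely (ties broken by item id for determinism), and the remaining
#' items are trained with \code{k}-fold cross-validation — each fold model
#' early-stops on its own fold and predicts the holdout, and the holdout
#' probability is the average over the \code{k} fold models. The reference
#' procedure uses the bottom 7/8 for training with a 1/8 holdout; a 1/2
#' holdout variant is used when positive examples are scarce.
#'
#' @param x Design matrix.
#' @param y Label matrix/data frame, one column per class.
#' @param novelty Numeric novelty score per row (higher = less
#'   characterized).
#' @param holdout_fraction Fraction held out from the top of the novelty
#'   ranking, in (0, 1).
#' @param k Folds within the training portion.
#' @param config A [doe_model_config()].
#' @param seed Seed for fold assignment.
#' @return List: \code{predictions} (data frame item, class, probability),
#'   \code{holdout_ids}, \code{train_ids}.
#' @export
novelty_split_cv <- function(x, y, novelty, holdout_fraction = 1 / 8, k = 8L,
                             config = doe_model_config(), seed = 1L) {
  if (!is.numeric(holdout_fraction) || holdout_fraction <= 0 ||
      holdout_fraction >= 1)
    stop("holdout_fraction must lie strictly between 0 and 1")
  x <- as.matrix(x)
  if (is.data.frame(y)) y <- as.matrix(y)
  storage.mode(y) <- "double"
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  stopifnot(length(novelty) == nrow(x))

  n_hold <- round(nrow(x) * holdout_fraction)
  o <- order(-novelty, ids)
  hold <- o[seq_len(n_hold)]
  train <- setdiff(seq_len(nrow(x)), hold)

  folds <- with_substream(seed, "novelty_folds",
                          sample(rep_len(seq_len(k), length(train))))
  d_hold <- xgboost::xgb.DMatrix(x[hold, , drop = FALSE])
  classes <- colnames(y) %||% paste0("class", seq_len(ncol(y)))
  preds <- lapply(classes, function(cls) {
    acc <- 0
    for (f in seq_len(k)) {
      tr <- train[folds != f]; va <- train[folds == f]
      if (length(unique(y[tr, cls])) < 2L)
        stop("class '", cls, "' absent from a training fold")
      booster <- train_booster(x[tr, , drop = FALSE], y[tr, cls],
                               x[va, , drop = FALSE], y[va, cls], config)
      acc <- acc + predict(booster, d_hold)
    }
    data.frame(item = ids[hold], class = cls, probability = acc / k,
               stringsAsFactors = FALSE)
  })
  list(predictions = do.call(rbind, c(preds, list(make.row.names = FALSE))),
       holdout_ids = ids[hold], train_ids = ids[train])
}
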