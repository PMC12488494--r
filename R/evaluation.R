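#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half — computed from midranks in
#' O(n log n).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.1, 0.4, 0.8), c(0, 1, 1))
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Reverse-percentile bootstrap confidence interval
#'
#' Resamples (score, label) rows with replacement and returns the
#' reverse-percentile (basic) interval
#' \eqn{[2\hat\theta - q_{1-\alpha/2},\; 2\hat\theta - q_{\alpha/2}]} of the
#' bootstrap distribution. Resamples on which the metric is undefined (for
#' AUROC, a single-class resample) are redrawn, up to \code{max_retry}
#' attempts each, keeping the number of bootstrap iterations fixed.
#'
#' @param metric Function of \code{(scores, labels)} returning a scalar.
#' @param scores,labels The data, resampled jointly by row.
#' @param n_boot Number of bootstrap iterations (the reference analysis uses
#'   1000).
#' @param level Confidence level.
#' @param seed Integer seed for the resampling.
#' @param max_retry Redraw cap per iteration.
#' @return List: \code{point}, \code{lower}, \code{upper}, \code{n_boot}.
#' @examples
#' set.seed(1)
#' s <- runif(100); y <- rbinom(100, 1, s)
#' bootstrap_ci(auroc, s, y, n_boot = 100, seed = 2)
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 1000L, level = 0.95,
                         seed = 1L, max_retry = 100L) {
  n <- length(scores)
  stopifnot(n == length(labels), n > 0)
  point <- metric(scores, labels)
  boot <- numeric(n_boot)
  with_substream(seed, "bootstrap", {
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (r in seq_len(max_retry)) {
        i <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric(scores[i], labels[i]), error = function(e) NA_real_)
        if (!is.na(val)) break
      }
      if (is.na(val))
        stop("metric undefined after ", max_retry, " redraws of a bootstrap resample")
      boot[b] <- val
    }
  })
  alpha <- 1 - level
  q <- stats::quantile(boot, c(1 - alpha / 2, alpha / 2), names = FALSE)
  list(point = point, lower = 2 * point - q[1], upper = 2 * point - q[2],
       n_boot = n_boot)
}

#' Macro- and micro-averaged metrics over classes
#'
#' Macro-averaging computes the metric per class and takes the unweighted
#' mean; micro-averaging pools the per-class (score, one-vs-rest label) rows
#' — each item contributing once per class — and computes the metric once on
#' the pooled set.
#'
#' @param scores_by_class Named list of score vectors, one per class.
#' @param labels_by_class Named list of binary label vectors, parallel.
#' @param metric Metric function (default [auroc()]).
#' @return List: \code{macro}, \code{micro}, \code{per_class}.
#' @export
macro_micro <- function(scores_by_class, labels_by_class, metric = auroc) {
  stopifnot(length(scores_by_class) >= 1,
            length(scores_by_class) == length(labels_by_class))
  per_class <- mapply(metric, scores_by_class, labels_by_class)
  list(macro = mean(per_class),
       micro = metric(unlist(scores_by_class, use.names = FALSE),
                      unlist(labels_by_class, use.names = FALSE)),
       per_class = per_class)
}

#' Calibration curve and weighted calibration fit
#'
#' Bins predictions into \code{n_bins} equal-width bins on [0, 1] and
#' reports, per non-empty bin, the mean prediction, the observed positive
#' rate and the count, plus the slope and intercept of a count-weighted
#' least-squares fit of observed rate on mean prediction. Perfectly
#' calibrated predictions give slope 1 and intercept 0. With fewer than two
#' non-empty bins the regression is undefined and flagged.
#'
#' @param predictions Probabilities in [0, 1].
#' @param labels Binary labels.
#' @param n_bins Number of equal-width bins.
#' @return Object of class \code{doe_calibration}: list with \code{curve}
#'   (data frame bin, mean_pred, obs_rate, count), \code{slope},
#'   \code{intercept}, \code{degenerate} flag.
#' @export
calibration <- function(predictions, labels, n_bins = 10L) {
  stopifnot(all(predictions >= 0 & predictions <= 1))
  labels <- as.numeric(as.logical(labels))
  bin <- pmin(pmax(ceiling(predictions * n_bins), 1L), n_bins)
  idx <- sort(unique(bin))
  curve <- data.frame(
    bin = idx,
    mean_pred = vapply(idx, function(b) mean(predictions[bin == b]), 0),
    obs_rate = vapply(idx, function(b) mean(labels[bin == b]), 0),
    count = vapply(idx, function(b) sum(bin == b), 0L))
  degenerate <- nrow(curve) < 2L
  if (degenerate) {
    slope <- intercept <- NA_real_
  } else {
    fit <- stats::lm(obs_rate ~ mean_pred, data = curve, weights = curve$count)
    intercept <- unname(stats::coef(fit)[1L])
    slope <- unname(stats::coef(fit)[2L])
  }
  structure(list(curve = curve, slope = slope, intercept = intercept,
                 n_bins = n_bins, degenerate = degenerate),
            class = "doe_calibration")
}

#' @export
print.doe_calibration <- function(x, ...) {
  if (x$degenerate) {
    cat("Calibration: degenerate (all predictions in one bin)\n")
  } else {
    cat(sprintf("Calibration: slope %.3f, intercept %.3f over %d bins (n = %d)\n",
                x$slope, x$intercept, nrow(x$curve), sum(x$curve$count)))
  }
  invisible(x)
}

#' F-beta-optimal classification cutoff
#'
#' Scans every distinct prediction value as a candidate threshold
#' (classifying positive when prediction >= threshold) and returns the
#' threshold maximizing
#' \eqn{F_\beta = (1+\beta^2) P R / (\beta^2 P + R)}. Small \eqn{\beta}
#' favors precision (the gene-disease models use \eqn{\beta = 0.2}); ties
#' are broken toward the smallest threshold, which maximizes recall at equal
#' F.
#'
#' @param predictions Numeric scores.
#' @param labels Binary labels; at least one positive required.
#' @param beta F-beta weight (default 1).
#' @return List: \code{threshold}, \code{f_beta}, \code{precision},
#'   \code{recall}.
#' @examples
#' optimal_cutoff(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), beta = 1)
#' @export
optimal_cutoff <- function(predictions, labels, beta = 1) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) stop("optimal_cutoff requires at least one positive label")
  o <- order(predictions, decreasing = TRUE)
  p_sorted <- predictions[o]
  tp_cum <- cumsum(labels[o])
  # last index of each distinct descending value = all items >= that value
  last <- which(!duplicated(p_sorted, fromLast = TRUE))
  thr <- p_sorted[last]
  tp <- tp_cum[last]
  pred_pos <- last
  precision <- tp / pred_pos
  recall <- tp / n_pos
  f <- ifelse(precision + recall == 0, 0,
              (1 + beta^2) * precision * recall / (beta^2 * precision + recall))
  # thr is descending; among ties on F pick the smallest threshold
  best <- length(f) + 1L - which.max(rev(f))
  list(threshold = thr[best], f_beta = f[best],
       precision = precision[best], recall = recall[best])
}

#' Full evaluation report for multi-class holdout predictions
#'
#' Computes, per DOE class, the AUROC with a reverse-percentile bootstrap
#' confidence interval, the calibration fit, and the F-beta-optimal cutoff,
#' plus macro- and micro-averaged AUROC across classes.
#'
#' @param scores_by_class Named list of holdout probability vectors.
#' @param labels_by_class Named list of binary label vectors.
#' @param beta F-beta weight for cutoff selection (1 for gene-level models,
#'   0.2 for gene-disease models).
#' @param n_boot Bootstrap iterations (0 skips the CI).
#' @param n_bins Calibration bins.
#' @param seed Seed for the bootstrap.
#' @return Object of class \code{doe_evaluation}.
#' @export
evaluation_report <- function(scores_by_class, labels_by_class, beta = 1,
                              n_boot = 1000L, n_bins = 10L, seed = 1L) {
  classes <- names(scores_by_class)
  per_class <- lapply(classes, function(cls) {
    s <- scores_by_class[[cls]]; y <- labels_by_class[[cls]]
    ci <- if (n_boot > 0) bootstrap_ci(auroc, s, y, n_boot = n_boot, seed = seed)
          else list(point = auroc(s, y), lower = NA_real_, upper = NA_real_)
    list(class = cls, auroc = ci$point, ci_lower = ci$lower, ci_upper = ci$upper,
         calibration = calibration(s, y, n_bins = n_bins),
         cutoff = optimal_cutoff(s, y, beta = beta),
         n = length(y), prevalence = mean(as.logical(y)))
  })
  names(per_class) <- classes
  mm <- macro_micro(scores_by_class, labels_by_class)
  structure(list(per_class = per_class, macro_auroc = mm$macro,
                 micro_auroc = mm$micro, beta = beta),
            class = "doe_evaluation")
}

#' @export
print.doe_evaluation <- function(x, ...) {
  cat("DOE model evaluation\n")
  for (pc in x$per_class) {
    ci <- if (is.na(pc$ci_lower)) "" else
      sprintf(" (95%% CI %.3f-%.3f)", pc$ci_lower, pc$ci_upper)
    cat(sprintf("  %-10s AUROC %.3f%s  cutoff %.3f  F%.1f %.3f  P %.3f  R %.3f  n=%d\n",
                pc$class, pc$auroc, ci, pc$cutoff$threshold, x$beta,
                pc$cutoff$f_beta, pc$cutoff$precision, pc$cutoff$recall, pc$n))
  }
  cat(sprintf("  macro AUROC %.3f  micro AUROC %.3f\n",
              x$macro_auroc, x$micro_auroc))
  invisible(x)
}
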