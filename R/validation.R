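#' Clinical phase-transition outcomes
#'
#' Labels analysis units (targets, target-DOE pairs, or target-DOE-disease
#' triplets) for a phase transition X to Y: a unit is a success if any of its
#' drugs reached at least phase Y; a failure if some drug reached at least
#' phase X, none reached Y, and none of the qualifying drugs remains in
#' active development; otherwise it is excluded (still active). Active
#' development statuses are: recruiting; active, not recruiting; not yet
#' recruiting; enrolling by invitation. A drug's development activity is
#' judged from its highest-phase records (the closest available proxy for
#' its latest status); unknown statuses are treated as inactive.
#'
#' @param records Data frame with columns \code{drug_id}, \code{gene_id},
#'   \code{doe}, \code{max_phase} (integer 1-4), \code{status}, and
#'   optionally \code{disease_code}.
#' @param from_phase,to_phase The transition, \code{from_phase < to_phase}.
#' @param unit One of \code{"target"}, \code{"target-doe"},
#'   \code{"target-doe-disease"}.
#' @return Data frame of unit keys plus \code{outcome} in
#'   \{success, failure, excluded\}.
#' @export
phase_outcomes <- function(records, from_phase, to_phase,
                           unit = c("target", "target-doe",
                                    "target-doe-disease")) {
  unit <- match.arg(unit)
  stopifnot(from_phase < to_phase)
  keys <- switch(unit,
    "target" = "gene_id",
    "target-doe" = c("gene_id", "doe"),
    "target-doe-disease" = c("gene_id", "doe", "disease_code"))
  if (!all(keys %in% names(records)))
    stop("records lack required columns: ", paste(keys, collapse = ", "))

  active_statuses <- c("recruiting", "active, not recruiting",
                       "not yet recruiting", "enrolling by invitation")
  known <- c(active_statuses, "completed", "terminated", "withdrawn",
             "suspended", "approved", "no longer available", "unknown")
  odd <- setdiff(unique(tolower(records$status)), known)
  if (length(odd))
    message("treating unrecognized status(es) as inactive: ",
            paste(odd, collapse = "; "))

  # per drug within unit: top phase, and activity at that phase
  rec_key <- do.call(paste, c(records[keys], sep = "\r"))
  drug_key <- paste(rec_key, records$drug_id, sep = "\r")
  o <- order(drug_key, -records$max_phase)
  r <- records[o, , drop = FALSE]
  dk <- drug_key[o]; uk <- rec_key[o]
  top <- r$max_phase[!duplicated(dk)]
  # a drug is active if any record at its top phase has an active status
  at_top <- r$max_phase == stats::ave(r$max_phase, dk, FUN = max)
  act <- tapply(tolower(r$status) %in% active_statuses & at_top, dk, any)
  unit_of_drug <- uk[!duplicated(dk)]

  per_unit <- function(f) as.vector(tapply(f, unit_of_drug, any))
  units <- sort(unique(unit_of_drug))
  reached_y <- per_unit(top >= to_phase)
  reached_x <- per_unit(top >= from_phase)
  qualifying <- top >= from_phase & top < to_phase
  active_any <- vapply(units, function(u) {
    i <- unit_of_drug == u
    any(qualifying[i] & as.vector(act)[i])
  }, TRUE)

  outcome <- ifelse(reached_y, "success",
                    ifelse(reached_x & !active_any, "failure", "excluded"))
  parts <- strsplit(units, "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- keys
  out$outcome <- outcome
  rownames(out) <- NULL
  out
}

#' Enrichment odds ratio above a score percentile
#'
#' Dichotomizes a continuous score at a percentile (nearest-rank, computed
#' on the analyzed population) or an explicit cutoff and reports the odds
#' ratio of a binary outcome from the resulting 2x2 table with a Wald 95%
#' confidence interval on the log odds ratio — numerically identical to a
#' single-covariate logistic regression on the dichotomized score. Zero
#' cells receive the Haldane-Anscombe 0.5 correction with a warning.
#'
#' @param score Numeric score vector.
#' @param outcome Binary outcome vector (both levels must be present).
#' @param percentile Percentile threshold in (0, 1) (e.g. 0.9 compares the
#'   top decile to the rest). Ignored when \code{cutoff} is given.
#' @param cutoff Explicit score cutoff (score >= cutoff is "high").
#' @param level Confidence level.
#' @return Object of class \code{enrichment_result}: list with \code{or},
#'   \code{ci_lower}, \code{ci_upper}, \code{counts} (2x2), \code{cutoff}.
#' @examples
#' enrichment_or(c(rnorm(50), rnorm(50, 2)), rep(c(0, 1), each = 50),
#'               percentile = 0.5)
#' @export
enrichment_or <- function(score, outcome, percentile = 0.9, cutoff = NULL,
                          level = 0.95) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2L)
    stop("both outcome levels must be present")
  if (is.null(cutoff)) {
    stopifnot(percentile > 0, percentile < 1)
    cutoff <- sort(score)[max(1L, ceiling(percentile * length(score)))]
    high <- score > cutoff
  } else {
    high <- score >= cutoff
  }
  a <- sum(high & outcome); b <- sum(high & !outcome)
  c_ <- sum(!high & outcome); d <- sum(!high & !outcome)
  counts <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                   dimnames = list(c("high", "low"), c("event", "no_event")))
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) {
    warning("zero cell in 2x2 table; applying Haldane-Anscombe 0.5 correction")
    cells <- cells + 0.5
  }
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(or = or, ci_lower = exp(log(or) - z * se),
                 ci_upper = exp(log(or) + z * se), counts = counts,
                 cutoff = cutoff),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), cutoff %.4g\n",
              x$or, x$ci_lower, x$ci_upper, x$cutoff))
  print(x$counts)
  invisible(x)
}

#' Two-score logistic enrichment
#'
#' Multivariable extension of [enrichment_or()]: a logistic regression of the
#' outcome on two (dichotomized or continuous) scores jointly, returning
#' per-score odds ratios with Wald confidence intervals.
#'
#' @param scores Data frame or matrix of two (or more) score columns.
#' @param outcome Binary outcome.
#' @param level Confidence level.
#' @return Data frame: term, or, ci_lower, ci_upper.
#' @export
enrichment_logistic <- function(scores, outcome, level = 0.95) {
  df <- as.data.frame(scores)
  df$.outcome <- as.numeric(as.logical(outcome))
  fit <- stats::glm(.outcome ~ ., data = df, family = stats::binomial())
  est <- stats::coef(fit)[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(est), or = exp(est),
             ci_lower = exp(est - z * se), ci_upper = exp(est + z * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect gene-level and gene-disease-level DOE predictions
#'
#' Flags, per (gene, disease, class), whether the gene-level prediction
#' clears its threshold, whether the gene-disease prediction clears its
#' threshold, and their conjunction, then computes the enrichment odds ratio
#' of each flag against the observed labels. Pairs whose gene lacks a
#' gene-level prediction are skipped and counted.
#'
#' @param gene_preds Data frame: gene_id, class, probability.
#' @param pair_preds Data frame: gene_id, disease_code, class, probability.
#' @param labels Data frame: gene_id, disease_code, class, label (0/1).
#' @param gene_threshold,pair_threshold Named numeric (per class) or scalar
#'   thresholds.
#' @return List: \code{flags} (per-pair flag table), \code{enrichment}
#'   (per class x flag type, when computable), \code{n_skipped}.
#' @export
intersect_predictions <- function(gene_preds, pair_preds, labels,
                                  gene_threshold, pair_threshold) {
  thr <- function(th, cls) if (length(th) > 1L) th[[cls]] else th
  m <- merge(pair_preds, gene_preds, by = c("gene_id", "class"),
             suffixes = c("_pair", "_gene"), all.x = TRUE)
  n_skipped <- sum(is.na(m$probability_gene))
  if (n_skipped) m <- m[!is.na(m$probability_gene), , drop = FALSE]
  m$flag_gene <- m$flag_pair <- m$flag_both <- NA
  for (cls in unique(m$class)) {
    i <- m$class == cls
    m$flag_gene[i] <- m$probability_gene[i] >= thr(gene_threshold, cls)
    m$flag_pair[i] <- m$probability_pair[i] >= thr(pair_threshold, cls)
  }
  m$flag_both <- m$flag_gene & m$flag_pair
  m <- merge(m, labels, by = c("gene_id", "disease_code", "class"))

  enr <- list()
  for (cls in unique(m$class)) {
    i <- m$class == cls
    for (fl in c("flag_gene", "flag_pair", "flag_both")) {
      res <- if (length(unique(m[[fl]][i])) < 2L ||
                 length(unique(m$label[i])) < 2L) {
        NULL  # degenerate flag set; enrichment undefined
      } else {
        enrichment_or(as.numeric(m[[fl]][i]), m$label[i], cutoff = 1)
      }
      enr[[paste(cls, fl, sep = ".")]] <- res
    }
  }
  list(flags = m, enrichment = enr, n_skipped = n_skipped)
}
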