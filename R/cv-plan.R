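#' Nested cross-validation plan
#'
#' Randomly partitions items into \code{k_outer} outer folds and, within each
#' outer training set, into \code{k_inner} inner folds. The outer folds
#' partition the items; for every outer round, the inner folds partition that
#' round's training items. Splitting is purely random (no stratification),
#' seeded and fully deterministic.
#'
#' @param ids Character or integer vector of item identifiers (unique).
#' @param k_outer,k_inner Fold counts (default 8 and 8).
#' @param seed Integer seed.
#' @param strata Optional factor of length \code{length(ids)}; when given,
#'   outer folds are drawn within strata (off by default — the reference
#'   procedure splits purely at random).
#' @return Object of class \code{cv_plan}: list with \code{ids},
#'   \code{outer} (outer fold per item), \code{inner} (items x k_outer
#'   matrix; \code{inner[i, o]} is item i's inner fold in outer round o, NA
#'   when i is in round o's holdout), \code{k_outer}, \code{k_inner},
#'   \code{seed}.
#' @examples
#' plan <- make_cv_plan(sprintf("g%02d", 1:64), seed = 1)
#' table(plan$outer)
#' @export
make_cv_plan <- function(ids, k_outer = 8L, k_inner = 8L, seed = 1L,
                         strata = NULL) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("item ids must be unique")
  minimum <- k_outer * k_inner
  if (n < minimum)
    stop("nested ", k_outer, "x", k_inner, " cross-validation needs at least ",
         minimum, " items; got ", n)
  with_substream(seed, "cv_plan", {
    outer <- if (is.null(strata)) {
      sample(rep_len(seq_len(k_outer), n))
    } else {
      out <- integer(n)
      for (lev in split(seq_len(n), strata))
        out[lev] <- sample(rep_len(seq_len(k_outer), length(lev)))
      out
    }
    inner <- matrix(NA_integer_, n, k_outer)
    for (o in seq_len(k_outer)) {
      train <- which(outer != o)
      inner[train, o] <- sample(rep_len(seq_len(k_inner), length(train)))
    }
    structure(list(ids = ids, outer = outer, inner = inner,
                   k_outer = k_outer, k_inner = k_inner, seed = seed),
              class = "cv_plan")
  })
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Nested %dx%d CV plan for %d items (seed %d)\n",
              x$k_outer, x$k_inner, length(x$ids), x$seed))
  cat("  outer fold sizes:", paste(tabulate(x$outer, x$k_outer), collapse = " "), "\n")
  invisible(x)
}

#' Gradient-boosting model configuration
#'
#' Returns the frozen training configuration: binary log-loss objective,
#' \code{min_child_weight = 10} to prevent overly complex splits, early
#' stopping after 10 rounds without validation improvement, and library
#' defaults for everything else. The defaults are recorded in a JSON lockfile
#' shipped with the package so the exact hyperparameters of any run are
#' reproducible.
#'
#' @param ... Overrides of individual entries (e.g. \code{nrounds = 20} for
#'   quick experiments).
#' @return List of class \code{doe_model_config}.
#' @export
doe_model_config <- function(...) {
  path <- system.file("extdata", "model_config.json", package = "doepred")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "doe_model_config")
}
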