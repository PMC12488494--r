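#' @keywords internal
"_PACKAGE"

# Deterministic substream seeding: every generator derives its RNG state from
# the root seed plus a fixed per-stream offset, so adding or reordering
# generation steps does not perturb unrelated streams. Offsets are hashed from
# the stream name so the scheme survives refactors; results stay < 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) + 1103L * h) %% .Machine$integer.max)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("doepred_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(name, " must be a proportion in [0, 1], got ", format(x))
  x
}

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < if (positive) 1 else 0)
    stop_config(name, " must be a ", if (positive) "positive " else "non-negative ",
                "integer, got ", format(x))
  as.integer(x)
}
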