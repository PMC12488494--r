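#' Read and write tab-separated tables with tri-state missingness
#'
#' All tables in this package travel as TSV with a header row. An empty field
#' means *missing* (untested); a literal \code{"0"} is an observed zero (tested,
#' not significant). These helpers preserve that distinction: \code{NA} in
#' memory round-trips to an empty field on disk and back.
#'
#' @param x A data frame.
#' @param path File path.
#' @return \code{read_doe_tsv} returns a data frame with \code{NA} for empty
#'   fields; \code{write_doe_tsv} returns \code{path} invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_doe_tsv(data.frame(g = "G1", v = NA_real_, z = 0), tf)
#' read_doe_tsv(tf)
#' @export
write_doe_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_doe_tsv
#' @export
read_doe_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
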