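#' Truncate gene embeddings to their leading dimensions
#'
#' Gene embeddings produced by Matryoshka-style representation learning
#' concentrate information in their earlier coordinates, so dimensionality is
#' reduced by keeping the first \code{d} dimensions in order.
#'
#' @param x Numeric vector, or matrix with one embedding per row.
#' @param d Number of leading dimensions to keep (default 256).
#' @return Truncated vector or matrix.
#' @examples
#' truncate_gene_embedding(c(5, 4, 3), d = 2)
#' @export
truncate_gene_embedding <- function(x, d = 256L) {
  d <- check_count(d, "d", positive = TRUE)
  len <- if (is.matrix(x)) ncol(x) else length(x)
  if (len < d)
    stop("embedding has ", len, " dimensions; cannot truncate to ", d)
  if (is.matrix(x)) x[, seq_len(d), drop = FALSE] else x[seq_len(d)]
}

#' Fit a PCA projection for protein embeddings
#'
#' Reduces raw protein language-model embeddings to \code{d} dimensions by
#' principal component analysis of the mean-centered matrix. Components are
#' ordered by decreasing explained variance, and each component's sign is
#' fixed deterministically so that its largest-magnitude loading is positive.
#' The projection is fit once on all genes: it is label-free, so no
#' information about the prediction targets can leak through it into
#' cross-validation folds.
#'
#' @param x Numeric matrix, one embedding per row, no missing values.
#' @param d Number of components (default 128).
#' @return Object of class \code{protein_projection}: list with
#'   \code{rotation} (loadings), \code{center}, \code{sdev},
#'   \code{explained_variance} (ratios), \code{d}.
#' @examples
#' x <- matrix(rnorm(300), 30, 10)
#' proj <- fit_protein_projection(x, d = 3)
#' sum(proj$explained_variance)
#' @export
fit_protein_projection <- function(x, d = 128L) {
  d <- check_count(d, "d", positive = TRUE)
  x <- as.matrix(x)
  if (anyNA(x)) stop("protein embeddings must not contain missing values")
  if (nrow(x) < d + 1L)
    stop("need at least d + 1 = ", d + 1L, " rows to fit a rank-", d, " projection")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank_x <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (d > rank_x)
    stop("d = ", d, " exceeds the rank of the centered matrix (", rank_x, ")")
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(d)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, center = pc$center,
                 sdev = pc$sdev[seq_len(d)],
                 explained_variance = pc$sdev[seq_len(d)]^2 / sum(pc$sdev^2),
                 d = d),
            class = "protein_projection")
}

#' @export
print.protein_projection <- function(x, ...) {
  cat(sprintf("PCA protein-embedding projection: %d -> %d dims, %.1f%% variance retained\n",
              nrow(x$rotation), x$d, 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project embeddings with a fitted projection
#'
#' @param object A \code{protein_projection}.
#' @param newdata Matrix of raw embeddings (rows = genes).
#' @param ... Unused.
#' @return Matrix of projected coordinates (\code{d} columns).
#' @export
predict.protein_projection <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$center) %*% object$rotation
}

#' Assemble the gene-level design matrix
#'
#' Binds the tabular feature block (schema order), the truncated gene
#' embedding, and the PCA-projected protein embedding into one numeric design
#' matrix, together with a column manifest. Missing tabular values propagate
#' as \code{NA}: the downstream tree learner handles missing values natively
#' and no imputation or normalization is applied. Embeddings are dense by
#' construction; genes lacking an embedding row are dropped (with a message
#' reporting the count) rather than zero-imputed, because an all-zero vector
#' would be far outside the embedding distribution.
#'
#' @param features Data frame with \code{gene_id} plus tabular columns.
#' @param gene_embedding Matrix with gene_id rownames.
#' @param protein_embedding Raw protein embedding matrix, gene_id rownames.
#' @param projection A fitted [fit_protein_projection()] object.
#' @param schema Tabular schema (see [gene_feature_schema()]); fixes the
#'   tabular column order.
#' @param d_gene Gene-embedding truncation dimension.
#' @return List with \code{x} (numeric matrix, gene_id rownames),
#'   \code{manifest} (data frame: column, block, index), and
#'   \code{dropped} (gene ids without embeddings).
#' @examples
#' cfg <- sim_config(n_genes = 40, seed = 1, embed_dim_gene = 8,
#'                   embed_dim_protein = 8)
#' u <- generate_gene_universe(cfg)
#' proj <- fit_protein_projection(u$protein_embedding, d = 4)
#' des <- assemble_design(u$features, u$gene_embedding, u$protein_embedding,
#'                        proj, u$schema, d_gene = 8)
#' dim(des$x)
#' @export
assemble_design <- function(features, gene_embedding, protein_embedding,
                            projection, schema = gene_feature_schema(),
                            d_gene = 256L) {
  if (anyDuplicated(features$gene_id))
    stop("duplicate gene_id in feature table")
  missing_cols <- setdiff(schema$name, names(features))
  if (length(missing_cols))
    stop("feature table lacks schema columns: ",
         paste(missing_cols, collapse = ", "))

  ids <- features$gene_id
  keep <- ids %in% rownames(gene_embedding) & ids %in% rownames(protein_embedding)
  dropped <- ids[!keep]
  if (length(dropped))
    message(length(dropped), " gene(s) dropped for lacking embeddings")
  ids <- ids[keep]

  tab <- as.matrix(features[keep, schema$name, drop = FALSE])
  storage.mode(tab) <- "double"
  ge <- truncate_gene_embedding(
    gene_embedding[ids, , drop = FALSE], d = d_gene)
  pe <- predict(projection, protein_embedding[ids, , drop = FALSE])

  colnames(ge) <- sprintf("gene_emb_%03d", seq_len(ncol(ge)))
  colnames(pe) <- sprintf("prot_pc_%03d", seq_len(ncol(pe)))
  x <- cbind(tab, ge, pe)
  rownames(x) <- ids

  manifest <- data.frame(
    column = colnames(x),
    block = rep(c("tabular", "gene_embedding", "protein_pca"),
                c(ncol(tab), ncol(ge), ncol(pe))),
    index = c(seq_len(ncol(tab)), seq_len(ncol(ge)), seq_len(ncol(pe))),
    stringsAsFactors = FALSE)

  list(x = x, manifest = manifest, dropped = dropped)
}

#' Write or read a design-matrix column manifest
#'
#' @param manifest Manifest data frame from [assemble_design()].
#' @param path JSON file path.
#' @return \code{read_manifest} returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
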