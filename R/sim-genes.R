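#' Generate a synthetic gene universe
#'
#' Emits the inputs of the gene-level models: a tabular feature table, a gene
#' embedding matrix, a raw protein embedding matrix, and the latent multi-label
#' DOE flags that downstream labels are checked against. Continuous features
#' are Gaussian with class-shifted means; binary features are Bernoulli with
#' class-shifted log-odds; shift magnitudes scale linearly with
#' \code{cfg$signal_strength}. Embeddings are isotropic Gaussian noise around
#' per-class centroids drawn once per run; centroid separation decays
#' geometrically across dimensions so that earlier dimensions carry more
#' information (the Matryoshka property), which is what makes leading-dimension
#' truncation sensible downstream. Missingness is applied completely at random
#' to tabular columns only.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements \code{features} (data frame, \code{gene_id} +
#'   tabular columns, \code{NA} = missing), \code{gene_embedding} and
#'   \code{protein_embedding} (numeric matrices with gene_id rownames),
#'   \code{labels} (data frame of latent DOE flags), \code{schema} (the
#'   tabular schema used), and \code{novelty} (a publication-novelty-style
#'   score, label-independent, used by generalization splits).
#' @examples
#' sim <- generate_gene_universe(sim_config(n_genes = 20, seed = 7))
#' dim(sim$gene_embedding)
#' @export
generate_gene_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  ids <- sim_gene_ids(n)
  schema <- gene_feature_schema(cfg$n_tabular)

  labels <- with_substream(cfg$seed, "gene_labels", draw_doe_flags(n, cfg))
  labels <- cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE), labels)
  y <- as.matrix(labels[, c("is_activator", "is_inhibitor", "is_other")]) * 1

  # Per-feature, per-class effect weights drawn once; sd 0.3 makes a single
  # feature weakly informative and the full matrix strongly informative at
  # signal_strength = 1.
  w <- with_substream(cfg$seed, "gene_weights",
                      matrix(stats::rnorm(cfg$n_tabular * 3L, sd = 0.3),
                             cfg$n_tabular, 3L))
  shift <- if (n > 0) cfg$signal_strength * (y %*% t(w)) else
    matrix(0, 0, cfg$n_tabular)

  tab <- with_substream(cfg$seed, "gene_tabular", {
    m <- matrix(NA_real_, n, cfg$n_tabular, dimnames = list(NULL, schema$name))
    for (j in seq_len(cfg$n_tabular)) {
      m[, j] <- if (schema$kind[j] == "continuous") {
        stats::rnorm(n, mean = shift[, j])
      } else {
        as.numeric(stats::runif(n) < stats::plogis(stats::qlogis(0.3) + shift[, j]))
      }
    }
    m
  })

  tab <- with_substream(cfg$seed, "gene_missing", {
    if (n > 0 && cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(n * cfg$n_tabular) < cfg$missing_rate,
                     n, cfg$n_tabular)
      tab[drop] <- NA_real_
    }
    tab
  })

  gene_emb <- with_substream(cfg$seed, "gene_embedding",
                             sim_embedding(y, cfg$embed_dim_gene,
                                           cfg$signal_strength, decay = 0.97))
  prot_emb <- with_substream(cfg$seed, "protein_embedding",
                             sim_embedding(y, cfg$embed_dim_protein,
                                           cfg$signal_strength, decay = 0.99))
  rownames(gene_emb) <- rownames(prot_emb) <- ids

  novelty <- with_substream(cfg$seed, "novelty", stats::runif(n))

  list(features = cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE),
                        as.data.frame(tab)),
       gene_embedding = gene_emb,
       protein_embedding = prot_emb,
       labels = labels,
       schema = schema,
       novelty = novelty)
}

# Class centroids are N(0, 0.3^2) per dimension, attenuated geometrically so
# earlier dimensions separate classes more than later ones.
sim_embedding <- function(y, d, signal, decay) {
  n <- nrow(y)
  centroids <- matrix(stats::rnorm(3L * d, sd = 0.3), 3L, d)
  centroids <- sweep(centroids, 2L, decay^(seq_len(d) - 1L), `*`)
  noise <- matrix(stats::rnorm(n * d), n, d)
  noise + signal * (y %*% centroids)
}

#' Tabular gene feature schema
#'
#' Returns the schema (feature name + kind) for the tabular block of the
#' gene-level design matrix. With the default 41 features the shipped schema
#' file is used; other sizes get generic alternating names. The schema file is
#' user-replaceable: real-data users can point [assemble_design()] at their
#' own copy.
#'
#' @param n_tabular Number of tabular features.
#' @return Data frame with columns \code{name} and
#'   \code{kind} (\code{"binary"} or \code{"continuous"}).
#' @export
gene_feature_schema <- function(n_tabular = 41L) {
  path <- system.file("extdata", "gene_feature_schema.tsv", package = "doepred")
  schema <- read_doe_tsv(path)
  if (n_tabular == nrow(schema)) return(schema)
  data.frame(name = sprintf("feat_%03d", seq_len(n_tabular)),
             kind = rep_len(c("continuous", "binary"), n_tabular),
             stringsAsFactors = FALSE)
}
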