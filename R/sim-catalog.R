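#' Generate a synthetic multi-source drug catalog
#'
#' Emits the three inputs of the drug-catalog module: an identifier link
#' table, per-source mechanism annotations, and a drug-disease indication
#' table. Each drug appears in 1 to \code{n_sources} source records; records
#' of the same drug are tied together through a shared identifier alias with
#' probability \code{cfg$alias_overlap}, so the generated link graph has
#' known connected components (returned as ground truth). Mechanism raw terms
#' are drawn from the term family of the gene's latent DOE; a fraction
#' \code{cfg$discrepancy_frac} of drug-gene pairs receives one discrepant
#' annotation from a lower-tier source.
#'
#' @param cfg A [sim_config()].
#' @param gene_labels Latent gene DOE flags, as returned in
#'   \code{generate_gene_universe()$labels}.
#' @return List with \code{links} (record_id, namespace, value),
#'   \code{mechanisms} (record_id, source, gene_id, raw_term),
#'   \code{indications} (record_id, disease_code), and \code{truth}: the
#'   planted component map (record_id, component), resolved drug-gene DOEs,
#'   gene-level and gene-disease-level label tables.
#' @examples
#' cfg <- sim_config(n_genes = 30, n_drugs = 20, n_diseases = 5, seed = 2)
#' uni <- generate_gene_universe(cfg)
#' cat <- generate_drug_catalog(cfg, uni$labels)
#' head(cat$links)
#' @export
generate_drug_catalog <- function(cfg, gene_labels) {
  stopifnot(inherits(cfg, "sim_config"))
  flags <- as.matrix(gene_labels[, c("is_activator", "is_inhibitor", "is_other")])
  druggable <- gene_labels$gene_id[rowSums(flags) > 0]
  sources <- sim_source_names(cfg$n_sources)

  empty <- list(
    links = data.frame(record_id = character(0), namespace = character(0),
                       value = character(0), stringsAsFactors = FALSE),
    mechanisms = data.frame(record_id = character(0), source = character(0),
                            gene_id = character(0), raw_term = character(0),
                            stringsAsFactors = FALSE),
    indications = data.frame(record_id = character(0), disease_code = character(0),
                             stringsAsFactors = FALSE),
    truth = list(components = data.frame(record_id = character(0),
                                         component = character(0),
                                         stringsAsFactors = FALSE),
                 drug_doe = data.frame(drug = character(0), gene_id = character(0),
                                       doe = character(0), stringsAsFactors = FALSE),
                 gene_labels = empty_gene_label_table(),
                 pair_labels = empty_pair_label_table())
  )
  if (cfg$n_drugs == 0 || length(druggable) == 0) return(empty)

  diseases <- sim_disease_codes(cfg$n_diseases)
  with_substream(cfg$seed, "drug_catalog", {
    links <- list(); mechs <- list(); inds <- list(); comp <- list()
    drug_doe <- list(); rec_map <- list()
    rec_counter <- 0L
    n_src_prob <- rev(seq_len(cfg$n_sources))  # most drugs in few sources

    for (d in seq_len(cfg$n_drugs)) {
      drug <- sprintf("D%05d", d)
      k <- sample.int(cfg$n_sources, 1L, prob = n_src_prob)
      src <- sources[sort(sample.int(cfg$n_sources, k))]
      rec <- sprintf("R%06d", rec_counter + seq_len(k))
      rec_counter <- rec_counter + k
      rec_map[[d]] <- data.frame(record_id = rec, drug = drug,
                                 stringsAsFactors = FALSE)

      # Shared alias chains the drug's records into one component; each
      # subsequent record joins with probability alias_overlap.
      has_alias <- c(TRUE, stats::runif(k - 1L) < cfg$alias_overlap)
      shared <- data.frame(record_id = rec[has_alias], namespace = "cid",
                           value = paste0("CID", d), stringsAsFactors = FALSE)
      own <- data.frame(record_id = rec,
                        namespace = paste0(src, "_id"),
                        value = paste0(toupper(src), d, "_", seq_len(k)),
                        stringsAsFactors = FALSE)
      links[[d]] <- rbind(own, shared)
      comp[[d]] <- data.frame(
        record_id = rec,
        component = ifelse(has_alias, rec[1L], rec),
        stringsAsFactors = FALSE)

      n_targets <- 1L + (stats::runif(1) > 0.55 && length(druggable) > 1L)
      genes <- sample(druggable, n_targets)
      pair_mechs <- lapply(genes, function(g) {
        g_flags <- doe_classes()[flags[match(g, gene_labels$gene_id), ] > 0]
        doe <- if (length(g_flags) == 1L) g_flags else sample(g_flags, 1L)
        terms <- sample(sim_term_family(doe), k, replace = TRUE)
        # One discrepant annotation from a tier-2 source, when one exists.
        tier2 <- which(!src %in% c("chembl", "drugbank"))
        if (length(tier2) > 0 && stats::runif(1) < cfg$discrepancy_frac) {
          i <- if (length(tier2) == 1L) tier2 else sample(tier2, 1L)
          terms[i] <- sample(sim_term_family(sample(setdiff(doe_classes(), doe), 1L)), 1L)
        }
        list(mech = data.frame(record_id = rec, source = src, gene_id = g,
                               raw_term = terms, stringsAsFactors = FALSE),
             doe = data.frame(drug = drug, gene_id = g, doe = doe,
                              stringsAsFactors = FALSE))
      })
      mechs[[d]] <- do.call(rbind, lapply(pair_mechs, `[[`, "mech"))
      drug_doe[[d]] <- do.call(rbind, lapply(pair_mechs, `[[`, "doe"))

      if (length(diseases) > 0) {
        n_ind <- sample.int(min(3L, length(diseases)), 1L)
        inds[[d]] <- data.frame(record_id = rec[1L],
                                disease_code = sample(diseases, n_ind),
                                stringsAsFactors = FALSE)
      }
    }

    links <- do.call(rbind, links)
    mechanisms <- do.call(rbind, mechs)
    indications <- if (length(inds)) do.call(rbind, inds) else empty$indications
    drug_doe <- do.call(rbind, drug_doe)
    rownames(links) <- rownames(mechanisms) <- rownames(indications) <-
      rownames(drug_doe) <- NULL

    truth <- list(
      components = do.call(rbind, comp),
      drug_doe = drug_doe,
      gene_labels = truth_gene_labels(drug_doe),
      pair_labels = truth_pair_labels(drug_doe, indications,
                                      do.call(rbind, rec_map))
    )
    rownames(truth$components) <- NULL
    list(links = links, mechanisms = mechanisms, indications = indications,
         truth = truth)
  })
}

sim_source_names <- function(n) {
  base <- c("chembl", "drugbank", "otp", "gtop", "curated")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("source_%d", seq_len(n - length(base))))
}

sim_term_family <- function(doe) {
  switch(doe,
    activator = c("agonist", "partial agonist", "activator",
                  "positive allosteric modulator", "opener", "inducer"),
    inhibitor = c("antagonist", "inhibitor", "blocker",
                  "negative allosteric modulator", "inverse agonist", "degrader"),
    other = c("binding agent", "mixed agonist/antagonist", "modulator",
              "chelator", "substrate", "replacement therapy"))
}

truth_gene_labels <- function(drug_doe) {
  if (nrow(drug_doe) == 0) return(empty_gene_label_table())
  genes <- sort(unique(drug_doe$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cls in doe_classes()) {
    out[[paste0("is_", cls, "_target")]] <-
      genes %in% drug_doe$gene_id[drug_doe$doe == cls]
  }
  out
}

truth_pair_labels <- function(drug_doe, indications, rec_map) {
  if (nrow(indications) == 0 || nrow(drug_doe) == 0)
    return(empty_pair_label_table())
  ind <- merge(indications, rec_map, by = "record_id")
  pairs <- merge(ind[, c("drug", "disease_code")], drug_doe, by = "drug")
  key <- unique(pairs[, c("gene_id", "disease_code")])
  out <- key[order(key$gene_id, key$disease_code), , drop = FALSE]
  for (cls in doe_classes()) {
    hit <- pairs[pairs$doe == cls, c("gene_id", "disease_code")]
    out[[paste0("is_", cls, "_target")]] <-
      paste(out$gene_id, out$disease_code) %in% paste(hit$gene_id, hit$disease_code)
  }
  rownames(out) <- NULL
  out
}

empty_gene_label_table <- function() {
  data.frame(gene_id = character(0), is_activator_target = logical(0),
             is_inhibitor_target = logical(0), is_other_target = logical(0),
             stringsAsFactors = FALSE)
}

empty_pair_label_table <- function() {
  data.frame(gene_id = character(0), disease_code = character(0),
             is_activator_target = logical(0), is_inhibitor_target = logical(0),
             is_other_target = logical(0), stringsAsFactors = FALSE)
}
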