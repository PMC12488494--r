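# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: BFS instead of union-find, O(n^2) pair counting
# instead of ranks, a dense threshold grid instead of the distinct-value scan.

# Connected components of a record-identifier graph by breadth-first search.
bfs_components <- function(links) {
  records <- sort(unique(links$record_id))
  key <- paste(tolower(links$namespace), tolower(links$value))
  adj <- lapply(split(links$record_id, key), unique)
  neighbours <- new.env()
  for (grp in adj) for (r in grp)
    assign(r, union(get0(r, neighbours, ifnotfound = character(0)), grp),
           neighbours)
  comp <- setNames(rep(NA_character_, length(records)), records)
  for (start in records) {
    if (!is.na(comp[start])) next
    queue <- start
    members <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% members) next
      members <- c(members, v)
      queue <- c(queue, setdiff(get0(v, neighbours, ifnotfound = v), members))
    }
    comp[members] <- min(members)
  }
  data.frame(record_id = records, drug_id = unname(comp),
             stringsAsFactors = FALSE)
}

# AUROC by exhaustive pair enumeration, ties counted one half.
auroc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Best F-beta over a dense grid of thresholds (classify positive if >= t).
grid_cutoff_oracle <- function(predictions, labels, beta, grid) {
  labels <- as.logical(labels)
  sp <- sort(predictions)
  spos <- sort(predictions[labels])
  n_pos <- length(spos)
  pred_pos <- length(sp) - findInterval(grid, sp, left.open = TRUE)
  tp <- n_pos - findInterval(grid, spos, left.open = TRUE)
  precision <- ifelse(pred_pos == 0, 0, tp / pred_pos)
  recall <- tp / n_pos
  f <- ifelse(precision + recall == 0, 0,
              (1 + beta^2) * precision * recall / (beta^2 * precision + recall))
  max(f)
}

# Small standard synthetic run shared by several tests.
small_universe <- function(seed = 42, n_genes = 200) {
  cfg <- sim_config(n_genes = n_genes, n_drugs = 100, n_diseases = 10,
                    seed = seed, n_tabular = 8, embed_dim_gene = 8,
                    embed_dim_protein = 8)
  list(cfg = cfg, universe = generate_gene_universe(cfg))
}
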