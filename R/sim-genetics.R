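#' Generate gene-disease pair labels
#'
#' Draws a table of gene-disease pairs with multi-label DOE flags at the
#' configured class fractions, for use as the planting target of
#' [generate_genetic_associations()] when no drug catalog is in play.
#'
#' @param cfg A [sim_config()].
#' @param n_pairs Number of distinct gene-disease pairs.
#' @return Data frame: gene_id, disease_code, is_activator_target,
#'   is_inhibitor_target, is_other_target.
#' @export
generate_pair_labels <- function(cfg, n_pairs) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (n_pairs == 0) return(empty_pair_label_table())
  n_dis <- max(cfg$n_diseases, 1L)
  n_gen <- ceiling(n_pairs / n_dis)
  grid <- expand.grid(disease_code = sim_disease_codes(n_dis),
                      gene_id = sim_gene_ids(n_gen),
                      stringsAsFactors = FALSE)[seq_len(n_pairs), 2:1]
  flags <- with_substream(cfg$seed, "pair_labels", draw_doe_flags(n_pairs, cfg))
  names(flags) <- paste0(names(flags), "_target")
  out <- cbind(grid, flags)
  rownames(out) <- NULL
  out
}

#' Generate synthetic genetic association evidence
#'
#' Emits the inputs of the gene-disease feature builder: a variant association
#' table (common GWAS and rare coding variants), an eQTL link table, a
#' gene-burden table, a Locus2gene score table, and a complementary clinical
#' evidence table. For inhibitor-labelled pairs the planted signal follows the
#' gain/loss-of-function framework: risk-increasing GOF variants,
#' risk-decreasing high-confidence LOF variants, beta/eQTL sign-concordant
#' common variants, and negative LOF-like burden betas; activator-labelled
#' pairs carry the mirrored pattern. Label-independent noise associations are
#' emitted at \code{cfg$noise_rate} per tested pair-dataset, and each
#' pair-dataset is tested at all only with the configured availability
#' (untested means downstream features stay missing, not zero). With
#' \code{signal_strength = 0} no signal records are emitted and every
#' association is noise.
#'
#' @param cfg A [sim_config()].
#' @param pair_labels Data frame of gene-disease DOE flags, from
#'   [generate_pair_labels()] or a drug catalog's ground truth.
#' @return List of data frames: \code{associations}, \code{eqtl},
#'   \code{burden}, \code{l2g}, \code{complementary}, plus \code{pairs}
#'   (the labels used).
#' @examples
#' cfg <- sim_config(n_genes = 10, n_diseases = 4, seed = 3)
#' ga <- generate_genetic_associations(cfg, generate_pair_labels(cfg, 50))
#' head(ga$associations)
#' @export
generate_genetic_associations <- function(cfg, pair_labels) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(pair_labels)
  act <- pair_labels$is_activator_target
  inh <- pair_labels$is_inhibitor_target
  # Probability a labelled pair receives a planted record per tested channel.
  p_sig <- 1 - exp(-0.8 * cfg$signal_strength)

  with_substream(cfg$seed, "genetics", {
    vc <- new.env(); vc$i <- 0L
    next_vid <- function(k) {
      ids <- sprintf("V%07d", vc$i + seq_len(k)); vc$i <- vc$i + k; ids
    }

    assoc <- list(); eqtl <- list(); l2g <- list()

    ## Common-variant channel: GWAS datasets intersected with eQTLs.
    for (ds in c("finngen", "mvp", "panukb")) {
      tested <- stats::runif(n) < cfg$avail_common
      nz <- stats::rpois(n, cfg$noise_rate) * tested
      idx <- rep(seq_len(n), nz)
      if (length(idx)) {
        vid <- next_vid(length(idx))
        sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
        assoc[[paste0(ds, "_noise")]] <- data.frame(
          variant_id = vid, gene_id = pair_labels$gene_id[idx],
          disease_code = pair_labels$disease_code[idx], dataset = ds,
          af_bin = "common", beta_sign = sgn,
          p_value = stats::runif(length(idx)),
          functional_class = NA_character_, missense_score = NA_real_,
          stringsAsFactors = FALSE)
        has_eqtl <- stats::runif(length(idx)) < 0.8
        eqtl[[paste0(ds, "_noise")]] <- data.frame(
          variant_id = vid[has_eqtl],
          gene_id = pair_labels$gene_id[idx][has_eqtl],
          eqtl_sign = sample(c(-1, 1), sum(has_eqtl), replace = TRUE),
          significant = TRUE,
          distance = stats::runif(sum(has_eqtl), 0, 5e4),
          stringsAsFactors = FALSE)
      }
      for (mech in c("activator", "inhibitor")) {
        lab <- if (mech == "activator") act else inh
        hit <- which(tested & lab & stats::runif(n) < p_sig)
        if (!length(hit)) next
        vid <- next_vid(length(hit))
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        assoc[[paste0(ds, "_", mech)]] <- data.frame(
          variant_id = vid, gene_id = pair_labels$gene_id[hit],
          disease_code = pair_labels$disease_code[hit], dataset = ds,
          af_bin = "common", beta_sign = sgn,
          p_value = 10^-stats::runif(length(hit), 1.4, 6),
          functional_class = NA_character_, missense_score = NA_real_,
          stringsAsFactors = FALSE)
        # same-sign eQTL implies inhibition; opposite-sign implies activation
        eqtl[[paste0(ds, "_", mech)]] <- data.frame(
          variant_id = vid, gene_id = pair_labels$gene_id[hit],
          eqtl_sign = if (mech == "inhibitor") sgn else -sgn,
          significant = TRUE,
          distance = stats::runif(length(hit), 0, 2e4),
          stringsAsFactors = FALSE)
      }
    }

    ## Rare coding variant channel.
    rare_classes <- c("GOF", "LOF_hc", "LOF_lc", "missense_other", "other", "unknown")
    for (ds in c("finngen", "genebass")) {
      tested <- stats::runif(n) < cfg$avail_rare
      nz <- stats::rpois(n, cfg$noise_rate) * tested
      idx <- rep(seq_len(n), nz)
      if (length(idx)) {
        cls <- sample(rare_classes, length(idx), replace = TRUE,
                      prob = c(0.1, 0.2, 0.1, 0.35, 0.15, 0.1))
        ms <- ifelse(cls == "missense_other", stats::runif(length(idx)), NA_real_)
        assoc[[paste0("rare_", ds, "_noise")]] <- data.frame(
          variant_id = next_vid(length(idx)), gene_id = pair_labels$gene_id[idx],
          disease_code = pair_labels$disease_code[idx], dataset = ds,
          af_bin = "rare",
          beta_sign = sample(c(-1, 1), length(idx), replace = TRUE),
          p_value = stats::runif(length(idx)),
          functional_class = cls, missense_score = ms,
          stringsAsFactors = FALSE)
      }
      for (mech in c("activator", "inhibitor")) {
        lab <- if (mech == "activator") act else inh
        hit <- which(tested & lab & stats::runif(n) < p_sig)
        if (!length(hit)) next
        use_gof <- stats::runif(length(hit)) < 0.5
        cls <- ifelse(use_gof, "GOF", "LOF_hc")
        # GOF risk / LOF protective -> inhibitor; mirrored for activator
        sgn <- ifelse(use_gof, 1, -1) * (if (mech == "inhibitor") 1 else -1)
        assoc[[paste0("rare_", ds, "_", mech)]] <- data.frame(
          variant_id = next_vid(length(hit)), gene_id = pair_labels$gene_id[hit],
          disease_code = pair_labels$disease_code[hit], dataset = ds,
          af_bin = "rare", beta_sign = sgn,
          p_value = 10^-stats::runif(length(hit), 1.4, 5),
          functional_class = cls, missense_score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }

    ## Gene-burden channel (aggregated ultrarare LOF-like masks).
    burden <- list()
    masks <- c("plof", "missense", "plof_missense")
    for (ds in c("finngen", "genebass", "meta")) {
      tested <- which(stats::runif(n) < cfg$avail_burden)
      if (!length(tested)) next
      idx <- rep(tested, each = length(masks))
      b <- data.frame(
        gene_id = pair_labels$gene_id[idx],
        disease_code = pair_labels$disease_code[idx], dataset = ds,
        mask = rep(masks, times = length(tested)),
        beta_sign = sample(c(-1, 1), length(idx), replace = TRUE),
        p_value = stats::runif(length(idx)), stringsAsFactors = FALSE)
      for (mech in c("activator", "inhibitor")) {
        lab <- if (mech == "activator") act else inh
        hit <- lab[idx] & b$mask == "plof" & stats::runif(length(idx)) < p_sig
        # LOF-like burden: protective (-) supports inhibition, risk (+) activation
        b$beta_sign[hit] <- if (mech == "inhibitor") -1 else 1
        b$p_value[hit] <- 10^-stats::runif(sum(hit), 1.4, 5)
      }
      burden[[ds]] <- b
    }

    ## Locus2gene scores tagged with their concordance-predicted mechanism.
    tested <- stats::runif(n) < cfg$avail_common * 0.5
    nz <- (1L + stats::rpois(n, 1)) * tested
    idx <- rep(seq_len(n), nz)
    if (length(idx)) {
      l2g[["noise"]] <- data.frame(
        gene_id = pair_labels$gene_id[idx],
        disease_code = pair_labels$disease_code[idx],
        variant_id = next_vid(length(idx)),
        mechanism = sample(c("activator", "inhibitor"), length(idx), replace = TRUE),
        score = stats::runif(length(idx), 0, 0.6), stringsAsFactors = FALSE)
    }
    for (mech in c("activator", "inhibitor")) {
      lab <- if (mech == "activator") act else inh
      hit <- which(tested & lab & stats::runif(n) < p_sig)
      if (!length(hit)) next
      l2g[[mech]] <- data.frame(
        gene_id = pair_labels$gene_id[hit],
        disease_code = pair_labels$disease_code[hit],
        variant_id = next_vid(length(hit)), mechanism = mech,
        score = stats::runif(length(hit), 0.5, 1), stringsAsFactors = FALSE)
    }

    ## Complementary clinical evidence (sparse).
    comp <- list()
    comp_sem <- c(clinvar_gof = "gof", clinvar_lof = "lof",
                  mouse_ko = "lof", expression_dir = "lof")
    for (f in names(comp_sem)) {
      tested <- stats::runif(n) < 0.05
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      p <- stats::runif(n)
      for (mech in c("activator", "inhibitor")) {
        lab <- if (mech == "activator") act else inh
        hit <- tested & lab & stats::runif(n) < p_sig * 0.5
        flip <- if (comp_sem[[f]] == "gof") 1 else -1
        sgn[hit] <- flip * (if (mech == "inhibitor") 1 else -1)
        p[hit] <- 10^-stats::runif(sum(hit), 1.4, 4)
      }
      comp[[f]] <- data.frame(
        gene_id = pair_labels$gene_id[tested],
        disease_code = pair_labels$disease_code[tested], feature = f,
        beta_sign = sgn[tested], p_value = p[tested], stringsAsFactors = FALSE)
    }

    bind <- function(x, proto) {
      out <- if (length(x)) do.call(rbind, x) else proto
      rownames(out) <- NULL
      out
    }
    list(
      associations = bind(assoc, data.frame(
        variant_id = character(0), gene_id = character(0),
        disease_code = character(0), dataset = character(0),
        af_bin = character(0), beta_sign = numeric(0), p_value = numeric(0),
        functional_class = character(0), missense_score = numeric(0),
        stringsAsFactors = FALSE)),
      eqtl = bind(eqtl, data.frame(
        variant_id = character(0), gene_id = character(0),
        eqtl_sign = numeric(0), significant = logical(0), distance = numeric(0),
        stringsAsFactors = FALSE)),
      burden = bind(burden, data.frame(
        gene_id = character(0), disease_code = character(0),
        dataset = character(0), mask = character(0), beta_sign = numeric(0),
        p_value = numeric(0), stringsAsFactors = FALSE)),
      l2g = bind(l2g, data.frame(
        gene_id = character(0), disease_code = character(0),
        variant_id = character(0), mechanism = character(0), score = numeric(0),
        stringsAsFactors = FALSE)),
      complementary = bind(comp, data.frame(
        gene_id = character(0), disease_code = character(0),
        feature = character(0), beta_sign = numeric(0), p_value = numeric(0),
        stringsAsFactors = FALSE)),
      pairs = pair_labels
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Serializes every table of a synthetic run as TSV (empty field = missing,
#' literal 0 = observed zero) next to a JSON manifest recording the
#' configuration, seed, and file paths of the ground-truth label tables.
#'
#' @param universe Output of [generate_gene_universe()].
#' @param catalog Output of [generate_drug_catalog()] (optional).
#' @param genetics Output of [generate_genetic_associations()] (optional).
#' @param cfg The [sim_config()] that produced them.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_sim_outputs <- function(universe, cfg, dir, catalog = NULL,
                              genetics = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  put <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    write_doe_tsv(x, p)
    paths[[name]] <<- basename(p)
  }
  put(universe$features, "gene_features")
  put(data.frame(gene_id = rownames(universe$gene_embedding),
                 universe$gene_embedding, check.names = FALSE), "gene_embedding")
  put(data.frame(gene_id = rownames(universe$protein_embedding),
                 universe$protein_embedding, check.names = FALSE),
      "protein_embedding")
  put(universe$labels, "truth_gene_labels")
  if (!is.null(catalog)) {
    put(catalog$links, "links")
    put(catalog$mechanisms, "mechanisms")
    put(catalog$indications, "indications")
    put(catalog$truth$components, "truth_components")
    put(catalog$truth$pair_labels, "truth_pair_labels")
  }
  if (!is.null(genetics)) {
    for (nm in c("associations", "eqtl", "burden", "l2g", "complementary", "pairs"))
      put(genetics[[nm]], nm)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(cfg), seed = cfg$seed, files = paths,
         truth_files = paths[grep("^truth|^pairs$", names(paths))]),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
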