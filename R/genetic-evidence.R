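#' Encode a genetic association as a signed -log10 p value
#'
#' Associations are encoded as \code{beta_sign * -log10(p)} so that models can
#' weight more significant associations more heavily, with a strict inclusion
#' threshold: associations with \code{p >= 0.05} encode to an observed zero
#' (tested, not significant). The boundary \code{p = 0.05} is excluded.
#'
#' @param p_value Numeric vector of p values in (0, 1].
#' @param beta_sign Numeric vector of effect signs (+1 / -1).
#' @return Numeric vector of signed encodings (0 where not significant).
#' @examples
#' encode_association(c(0.01, 0.2, 0.05), c(-1, 1, 1))
#' @export
encode_association <- function(p_value, beta_sign) {
  if (any(is.na(p_value)) || any(p_value <= 0) || any(p_value > 1))
    stop("p values must lie in (0, 1]")
  ifelse(p_value < 0.05, beta_sign * -log10(p_value), 0)
}

#' Missense deleteriousness score
#'
#' Proportion of prediction algorithms calling a variant deleterious, over
#' the algorithms that returned a prediction. Qualitative tools count as
#' deleterious on a "D" call ("H" for MutationAssessor-style tools, "R" or
#' "D" for Aloft-style tools); quantitative tools count as deleterious when
#' their rank score exceeds 0.9 (strictly). The score is reported only when
#' at least \code{min_predictions} (default 8) tools returned a prediction;
#' otherwise it is missing.
#'
#' @param calls Data frame with columns \code{kind}
#'   (\code{"qualitative"}/\code{"quantitative"}) and \code{value}
#'   (call string or rank score); one row per tool that returned a
#'   prediction.
#' @param min_predictions Minimum number of returned predictions.
#' @return Proportion in [0, 1], or \code{NA} if too few predictions.
#' @examples
#' calls <- data.frame(kind = rep("qualitative", 10),
#'                     value = rep(c("D", "T"), 5))
#' missense_score(calls)
#' @export
missense_score <- function(calls, min_predictions = 8L) {
  if (is.null(calls) || nrow(calls) < min_predictions) return(NA_real_)
  qual <- calls$kind == "qualitative"
  del <- logical(nrow(calls))
  del[qual] <- toupper(as.character(calls$value[qual])) %in% c("D", "H", "R")
  del[!qual] <- suppressWarnings(as.numeric(calls$value[!qual])) > 0.9
  mean(del)
}

#' Gene-disease feature schema
#'
#' The 31-feature schema for gene-disease-specific DOE prediction: 4 common
#' variant features (eQTL sign concordance and Locus2gene, one per
#' mechanism), 14 rare-variant categories (7 functional classes crossed with
#' 2 datasets), 9 gene-burden features (3 datasets crossed with 3 variant
#' masks), and 4 complementary clinical features. Each feature carries its
#' group, the allele-frequency bin it contributes support to, and its
#' directional semantics (\code{gof}: positive values support inhibition;
#' \code{lof}: positive values support activation; \code{mechanism_*}: any
#' nonzero value supports the named mechanism; \code{none}: no direction).
#' The schema ships as an editable TSV so real-data users can rebind names.
#'
#' @return Data frame: feature, group, af_bin, semantics.
#' @export
pair_feature_schema <- function() {
  read_doe_tsv(system.file("extdata", "pair_feature_schema.tsv",
                           package = "doepred"))
}

pair_key <- function(gene, disease) paste(gene, disease, sep = "\r")

# Encode the minimum-p row per group with deterministic tie-breaks
# (smaller p, then variant order).
min_p_encode <- function(df, group) {
  o <- order(group, df$p_value, df$variant_id %||% seq_len(nrow(df)))
  first <- !duplicated(group[o])
  data.frame(group = group[o][first],
             value = encode_association(df$p_value[o][first],
                                        df$beta_sign[o][first]),
             stringsAsFactors = FALSE)
}

#' eQTL direction-concordance features
#'
#' Intersects common-variant disease associations with significant eQTL
#' links. A variant with eQTLs to several genes is attributed to the closest
#' gene only (ties broken toward the lexicographically smaller gene id). The
#' variant's effect sign and its eQTL sign agreeing predicts an inhibitor
#' mechanism (raising expression raises risk, or lowering expression lowers
#' risk); opposite signs predict an activator mechanism. Within each
#' direction the most significant association per gene-disease pair is
#' retained and encoded with [encode_association()].
#'
#' @param associations Common-variant association rows (variant_id,
#'   disease_code, beta_sign, p_value).
#' @param eqtl eQTL link rows (variant_id, gene_id, eqtl_sign, significant,
#'   distance).
#' @return Data frame: gene_id, disease_code, eqtl_inhibitor, eqtl_activator
#'   (one row per pair with at least one intersected variant; a direction
#'   with no variants or no significant ones is an observed 0).
#' @export
eqtl_direction_features <- function(associations, eqtl) {
  out_proto <- data.frame(gene_id = character(0), disease_code = character(0),
                          eqtl_inhibitor = numeric(0), eqtl_activator = numeric(0),
                          stringsAsFactors = FALSE)
  eqtl <- eqtl[eqtl$significant, , drop = FALSE]
  if (nrow(associations) == 0 || nrow(eqtl) == 0) return(out_proto)
  # closest-gene rule per variant
  o <- order(eqtl$variant_id, eqtl$distance, eqtl$gene_id)
  eqtl <- eqtl[o, , drop = FALSE]
  eqtl <- eqtl[!duplicated(eqtl$variant_id), , drop = FALSE]

  m <- merge(associations[, c("variant_id", "disease_code", "beta_sign", "p_value")],
             eqtl[, c("variant_id", "gene_id", "eqtl_sign")], by = "variant_id")
  if (nrow(m) == 0) return(out_proto)
  m$key <- pair_key(m$gene_id, m$disease_code)
  m$direction <- ifelse(m$beta_sign == m$eqtl_sign, "inhibitor", "activator")

  keys <- sort(unique(m$key))
  out <- data.frame(key = keys, eqtl_inhibitor = 0, eqtl_activator = 0,
                    stringsAsFactors = FALSE)
  for (dir in c("inhibitor", "activator")) {
    sub <- m[m$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0) next
    enc <- min_p_encode(sub, sub$key)
    out[[paste0("eqtl_", dir)]][match(enc$group, out$key)] <- enc$value
  }
  parts <- strsplit(out$key, "\r", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             disease_code = vapply(parts, `[`, "", 2L),
             eqtl_inhibitor = out$eqtl_inhibitor,
             eqtl_activator = out$eqtl_activator, stringsAsFactors = FALSE)
}

#' Normalized harmonic sum of Locus2gene scores
#'
#' For scores \eqn{s_{(1)} \ge s_{(2)} \ge \dots} the harmonic sum is
#' \eqn{H = \sum_i s_{(i)}/i^2 / \sum_i 1/i^2}, so a single score encodes to
#' itself and a run of maximal scores to 1. Scores are grouped by their
#' concordance-predicted mechanism per gene-disease pair; the larger sum is
#' retained in its mechanism's feature slot (ties go to activator for
#' determinism), the other slot is an observed 0.
#'
#' @param l2g Data frame: gene_id, disease_code, mechanism
#'   (\code{"activator"}/\code{"inhibitor"}), score in [0, 1].
#' @return Data frame: gene_id, disease_code, l2g_inhibitor, l2g_activator.
#' @export
l2g_harmonic_features <- function(l2g) {
  proto <- data.frame(gene_id = character(0), disease_code = character(0),
                      l2g_inhibitor = numeric(0), l2g_activator = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(l2g) == 0) return(proto)
  stopifnot(all(l2g$score >= 0 & l2g$score <= 1))
  grp <- paste(pair_key(l2g$gene_id, l2g$disease_code), l2g$mechanism, sep = "\r")
  o <- order(grp, -l2g$score)
  s <- l2g$score[o]; g <- grp[o]
  i <- stats::ave(s, g, FUN = seq_along)
  num <- tapply(s / i^2, g, sum)
  den <- tapply(1 / i^2, g, sum)
  H <- as.numeric(num / den)
  gparts <- strsplit(names(num), "\r", fixed = TRUE)
  hdf <- data.frame(key = vapply(gparts, function(p) paste(p[1], p[2], sep = "\r"), ""),
                    mechanism = vapply(gparts, `[`, "", 3L), H = H,
                    stringsAsFactors = FALSE)
  oo <- order(hdf$key, -hdf$H, hdf$mechanism)
  win <- hdf[oo, ][!duplicated(hdf$key[oo]), , drop = FALSE]
  out <- data.frame(key = win$key, l2g_inhibitor = 0, l2g_activator = 0,
                    stringsAsFactors = FALSE)
  out$l2g_inhibitor[win$mechanism == "inhibitor"] <-
    win$H[win$mechanism == "inhibitor"]
  out$l2g_activator[win$mechanism == "activator"] <-
    win$H[win$mechanism == "activator"]
  parts <- strsplit(out$key, "\r", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             disease_code = vapply(parts, `[`, "", 2L),
             l2g_inhibitor = out$l2g_inhibitor,
             l2g_activator = out$l2g_activator, stringsAsFactors = FALSE)
}

# Map functional class + missense score to a rare-variant category suffix.
rare_category <- function(functional_class, missense_score) {
  cls <- ifelse(is.na(functional_class), "other", functional_class)
  out <- rep("other", length(cls))
  out[cls == "GOF"] <- "gof"
  out[cls == "LOF_hc"] <- "lof_hc"
  out[cls == "LOF_lc"] <- "lof_lc"
  out[cls == "unknown"] <- "unknown"
  mis <- cls == "missense_other"
  out[mis & !is.na(missense_score) & missense_score > 0.5] <- "missense_damaging"
  out[mis & !is.na(missense_score) & missense_score <= 0.5] <- "missense_benign"
  out[mis & is.na(missense_score)] <- "unknown"
  out
}

#' Build the 31 gene-disease genetic-evidence features
#'
#' Assembles the full feature matrix with tri-state semantics: a feature is
#' missing (\code{NA}) when the pair was untested in the corresponding
#' dataset/channel, an observed 0 when tested without a significant
#' association, and a signed \code{-log10 p} encoding otherwise. A pair
#' counts as tested in a dataset when the dataset contributes at least one
#' summary-statistic row for it. Rare-variant categories take the most
#' significant variant per category; burden features one result per mask;
#' common features come from [eqtl_direction_features()] and
#' [l2g_harmonic_features()]; complementary clinical features are encoded
#' directly.
#'
#' @param genetics List of evidence tables as produced by
#'   [generate_genetic_associations()] (associations, eqtl, burden, l2g,
#'   complementary).
#' @param pairs Data frame with gene_id, disease_code rows to assemble.
#' @param schema Feature schema, see [pair_feature_schema()].
#' @return Data frame: gene_id, disease_code, then the 31 feature columns in
#'   schema order.
#' @export
build_pair_features <- function(genetics, pairs, schema = pair_feature_schema()) {
  n <- nrow(pairs)
  key <- pair_key(pairs$gene_id, pairs$disease_code)
  f <- matrix(NA_real_, n, nrow(schema),
              dimnames = list(NULL, schema$feature))

  fill <- function(col, enc_key, values) {
    i <- match(enc_key, key)
    ok <- !is.na(i)
    f[i[ok], col] <<- values[ok]
  }
  mark_tested <- function(cols, tested_key) {
    i <- match(unique(tested_key), key)
    i <- i[!is.na(i)]
    f[i, cols] <<- 0
  }

  assoc <- genetics$associations
  ## rare-variant categories
  rare <- assoc[assoc$af_bin %in% c("rare", "ultrarare"), , drop = FALSE]
  for (ds in c("finngen", "genebass")) {
    sub <- rare[rare$dataset == ds, , drop = FALSE]
    if (nrow(sub) == 0) next
    cols <- grep(paste0("^rare_", ds, "_"), schema$feature, value = TRUE)
    k <- pair_key(sub$gene_id, sub$disease_code)
    mark_tested(cols, k)
    cat_col <- paste0("rare_", ds, "_", rare_category(sub$functional_class,
                                                      sub$missense_score))
    grp <- paste(k, cat_col, sep = "\r")
    enc <- min_p_encode(sub, grp)
    parts <- strsplit(enc$group, "\r", fixed = TRUE)
    ek <- vapply(parts, function(p) paste(p[1], p[2], sep = "\r"), "")
    ec <- vapply(parts, `[`, "", 3L)
    keep <- ec %in% cols
    for (cc in unique(ec[keep]))
      fill(cc, ek[keep & ec == cc], enc$value[keep & ec == cc])
  }

  ## burden features
  burden <- genetics$burden
  for (ds in unique(burden$dataset)) {
    sub <- burden[burden$dataset == ds, , drop = FALSE]
    cols <- grep(paste0("^burden_", ds, "_"), schema$feature, value = TRUE)
    if (!length(cols)) next
    k <- pair_key(sub$gene_id, sub$disease_code)
    mark_tested(cols, k)
    sub$variant_id <- seq_len(nrow(sub))
    grp <- paste(k, paste0("burden_", ds, "_", sub$mask), sep = "\r")
    enc <- min_p_encode(sub, grp)
    parts <- strsplit(enc$group, "\r", fixed = TRUE)
    ek <- vapply(parts, function(p) paste(p[1], p[2], sep = "\r"), "")
    ec <- vapply(parts, `[`, "", 3L)
    keep <- ec %in% cols
    for (cc in unique(ec[keep]))
      fill(cc, ek[keep & ec == cc], enc$value[keep & ec == cc])
  }

  ## common-variant eQTL concordance
  common <- assoc[!is.na(assoc$af_bin) & assoc$af_bin == "common", , drop = FALSE]
  ef <- eqtl_direction_features(common, genetics$eqtl)
  if (nrow(ef)) {
    ek <- pair_key(ef$gene_id, ef$disease_code)
    fill("eqtl_inhibitor", ek, ef$eqtl_inhibitor)
    fill("eqtl_activator", ek, ef$eqtl_activator)
  }

  ## Locus2gene harmonic sums
  lf <- l2g_harmonic_features(genetics$l2g)
  if (nrow(lf)) {
    lk <- pair_key(lf$gene_id, lf$disease_code)
    fill("l2g_inhibitor", lk, lf$l2g_inhibitor)
    fill("l2g_activator", lk, lf$l2g_activator)
  }

  ## complementary clinical evidence
  comp <- genetics$complementary
  if (!is.null(comp) && nrow(comp)) {
    for (fname in intersect(unique(comp$feature), schema$feature)) {
      sub <- comp[comp$feature == fname, , drop = FALSE]
      fill(fname, pair_key(sub$gene_id, sub$disease_code),
           encode_association(sub$p_value, sub$beta_sign))
    }
  }

  cbind(pairs[, c("gene_id", "disease_code")], as.data.frame(f))
}

#' Count allele-frequency bins supporting a mechanism
#'
#' A bin (common, rare, ultrarare) supports the inhibitor mechanism when any
#' of its features shows an inhibition-implying pattern: a positive
#' gain-of-function encoding (GOF raises risk), a negative loss-of-function
#' encoding (LOF protects), or a nonzero value in an inhibitor-concordance
#' feature. Activator support is the mirror image. Missing and zero values
#' never support either mechanism.
#'
#' @param features Data frame from [build_pair_features()] (feature columns
#'   in schema order), or a single named numeric vector.
#' @param mechanism \code{"activator"} or \code{"inhibitor"}.
#' @param schema Feature schema.
#' @return Integer vector of support counts in 0..3.
#' @export
bin_support_counts <- function(features, mechanism = c("inhibitor", "activator"),
                               schema = pair_feature_schema()) {
  mechanism <- match.arg(mechanism)
  if (!is.data.frame(features))
    features <- as.data.frame(as.list(features))
  counts <- integer(nrow(features))
  for (bin in c("common", "rare", "ultrarare")) {
    sch <- schema[schema$af_bin == bin, , drop = FALSE]
    support <- matrix(FALSE, nrow(features), nrow(sch))
    for (j in seq_len(nrow(sch))) {
      v <- features[[sch$feature[j]]]
      if (is.null(v)) next
      support[, j] <- switch(sch$semantics[j],
        gof = if (mechanism == "inhibitor") !is.na(v) & v > 0 else !is.na(v) & v < 0,
        lof = if (mechanism == "inhibitor") !is.na(v) & v < 0 else !is.na(v) & v > 0,
        mechanism_inhibitor = (mechanism == "inhibitor") & !is.na(v) & v != 0,
        mechanism_activator = (mechanism == "activator") & !is.na(v) & v != 0,
        none = FALSE)
    }
    counts <- counts + as.integer(rowSums(support) > 0)
  }
  counts
}
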