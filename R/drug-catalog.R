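#' Unify drug records across sources by shared identifiers
#'
#' Resolves one drug entity per connected component of the record-identifier
#' graph, using a disjoint-set (union-find) structure: two records belong to
#' the same drug if and only if they are connected through shared
#' (namespace, value) identifier pairs, directly or transitively. Identifier
#' namespaces and values are case-normalized before joining. The unified
#' drug_id is the lexicographically smallest member record_id, which makes
#' the mapping deterministic across runs and platforms.
#'
#' @param links Data frame with columns \code{record_id},
#'   \code{namespace}, \code{value}; one row per identifier carried by a
#'   record. Every record must carry at least one identifier.
#' @return Data frame with columns \code{record_id}, \code{drug_id}.
#' @examples
#' links <- data.frame(record_id = c("A", "B", "B", "C"),
#'                     namespace = "cid", value = c("x", "x", "y", "y"))
#' unify_drugs(links)  # A, B, C collapse to one drug
#' @export
unify_drugs <- function(links) {
  required <- c("record_id", "namespace", "value")
  if (!is.data.frame(links) || !all(required %in% names(links)))
    stop("links must be a data frame with columns record_id, namespace, value")
  bad <- which(is.na(links$record_id) | is.na(links$namespace) |
                 is.na(links$value) | links$record_id == "" | links$value == "")
  if (length(bad))
    stop("malformed link rows at lines: ", paste(utils::head(bad, 10), collapse = ", "))
  if (nrow(links) == 0)
    return(data.frame(record_id = character(0), drug_id = character(0),
                      stringsAsFactors = FALSE))

  records <- sort(unique(as.character(links$record_id)))
  key <- paste(tolower(trimws(links$namespace)), tolower(trimws(links$value)),
               sep = "\r")
  rec_idx <- match(as.character(links$record_id), records)

  parent <- seq_along(records)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  # union all records sharing an identifier key
  for (grp in split(rec_idx, key)) {
    grp <- unique(grp)
    for (j in grp[-1L]) {
      r <- find(grp[1L])
      rj <- find(j)
      if (rj != r) parent[max(r, rj)] <- min(r, rj)
    }
  }
  root <- vapply(seq_along(records), find, 1L)
  # smallest member record_id names the drug; records are sorted so the
  # minimal index within each component is the minimal id
  drug_of_root <- tapply(seq_along(records), root, function(m) records[min(m)])
  data.frame(record_id = records,
             drug_id = as.character(drug_of_root[as.character(root)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map raw mechanism terms to direction-of-effect classes
#'
#' Classifies free-text mechanism-of-action terms into the three DOE classes
#' \code{activator}, \code{inhibitor}, \code{other}. Matching is
#' case-insensitive on the trimmed term. Terms absent from the map fall back
#' to \code{other}; the unmapped terms are attached as the
#' \code{"unmapped"} attribute so callers can log them. The shipped map is a
#' reconstruction covering the agonist/antagonist/activator/inhibitor/
#' blocker/allosteric-modulator/binding-agent families and is user-extensible
#' via \code{term_map}.
#'
#' @param raw_term Character vector of raw mechanism terms.
#' @param term_map Data frame with columns \code{raw_term}, \code{doe};
#'   defaults to the shipped map.
#' @return Character vector in \{activator, inhibitor, other\}, same length
#'   as \code{raw_term}, with attribute \code{"unmapped"}.
#' @examples
#' classify_mechanism(c("agonist", "antagonist", "binding agent", "weird"))
#' @export
classify_mechanism <- function(raw_term, term_map = default_term_map()) {
  stopifnot(all(c("raw_term", "doe") %in% names(term_map)))
  norm <- tolower(trimws(raw_term))
  hit <- match(norm, tolower(trimws(term_map$raw_term)))
  out <- term_map$doe[hit]
  unmapped <- sort(unique(raw_term[is.na(hit) & !is.na(raw_term)]))
  out[is.na(hit)] <- "other"
  structure(out, unmapped = unmapped)
}

#' @rdname classify_mechanism
#' @export
default_term_map <- function() {
  read_doe_tsv(system.file("extdata", "mechanism_term_map.tsv",
                           package = "doepred"))
}

#' Resolve discrepant mechanism annotations for one drug-gene pair
#'
#' Applies the lexicographic priority used to merge multi-source annotations:
#' tier-1 sources (ChEMBL, DrugBank) outrank all others, and within the
#' winning tier an activator or inhibitor annotation outranks \code{other}.
#' If the surviving annotations still disagree between activator and
#' inhibitor, the pair is flagged unresolved (\code{NA} class) rather than
#' guessed.
#'
#' @param doe Character vector of DOE classes for one drug-gene pair.
#' @param source Character vector of source names, parallel to \code{doe}.
#' @param tier1 Sources treated as tier 1.
#' @return Length-1 character: the resolved class, or \code{NA} if
#'   unresolved.
#' @examples
#' resolve_discrepancies(c("inhibitor", "activator"), c("chembl", "otp"))
#' resolve_discrepancies(c("other", "activator"), c("chembl", "chembl"))
#' @export
resolve_discrepancies <- function(doe, source,
                                  tier1 = c("chembl", "drugbank")) {
  if (length(doe) == 0) stop("resolve_discrepancies requires >= 1 annotation")
  stopifnot(length(doe) == length(source))
  is_t1 <- tolower(source) %in% tolower(tier1)
  pool <- if (any(is_t1)) doe[is_t1] else doe
  directional <- pool[pool != "other"]
  pool <- if (length(directional)) directional else pool
  u <- unique(pool)
  if (length(u) == 1L) u else NA_character_
}

#' Derive gene-level and gene-disease-level DOE labels
#'
#' Runs the full catalog pipeline: unifies records into drugs, classifies raw
#' mechanism terms, resolves per-(drug, gene) discrepancies by source tier
#' and directionality, then takes unions: a gene's flags are the union of its
#' drugs' resolved DOEs, and a (gene, disease) pair's flags are the union
#' over drugs indicated for that disease that target that gene. Unresolved
#' activator-versus-inhibitor conflicts are excluded and reported in the
#' \code{unresolved} element; indications referencing records absent from the
#' mechanism table are skipped with a warning.
#'
#' @param links Identifier link table (see [unify_drugs()]).
#' @param mechanisms Data frame: record_id, source, gene_id, raw_term.
#' @param indications Data frame: record_id, disease_code.
#' @param term_map Mechanism term map (see [classify_mechanism()]).
#' @return List with \code{gene_labels}, \code{pair_labels} (both keyed
#'   uniquely), \code{drug_doe} (resolved per drug-gene), and
#'   \code{unresolved} (excluded drug-gene pairs).
#' @export
build_labels <- function(links, mechanisms, indications = NULL,
                         term_map = default_term_map()) {
  mapping <- unify_drugs(links)
  m <- merge(mechanisms, mapping, by = "record_id")
  m$doe <- as.character(classify_mechanism(m$raw_term, term_map))

  keys <- interaction(m$drug_id, m$gene_id, drop = TRUE)
  resolved <- lapply(split(m, keys), function(g) {
    data.frame(drug_id = g$drug_id[1L], gene_id = g$gene_id[1L],
               doe = resolve_discrepancies(g$doe, g$source),
               stringsAsFactors = FALSE)
  })
  resolved <- do.call(rbind, c(resolved, list(make.row.names = FALSE)))
  if (is.null(resolved)) resolved <- data.frame(
    drug_id = character(0), gene_id = character(0), doe = character(0))
  unresolved <- resolved[is.na(resolved$doe), c("drug_id", "gene_id")]
  drug_doe <- resolved[!is.na(resolved$doe), , drop = FALSE]

  gene_labels <- label_union(drug_doe, "gene_id")

  pair_labels <- empty_pair_label_table()
  if (!is.null(indications) && nrow(indications) > 0 && nrow(drug_doe) > 0) {
    ind <- merge(indications, mapping, by = "record_id")
    unknown <- setdiff(ind$drug_id, drug_doe$drug_id)
    if (length(unknown))
      warning(length(unknown), " indication drug(s) without resolved mechanisms; skipped")
    ind <- unique(ind[, c("drug_id", "disease_code")])
    pairs <- merge(ind, drug_doe, by = "drug_id")
    if (nrow(pairs) > 0)
      pair_labels <- label_union(pairs, c("gene_id", "disease_code"))
  }

  list(gene_labels = gene_labels, pair_labels = pair_labels,
       drug_doe = drug_doe, unresolved = unresolved)
}

label_union <- function(df, keys) {
  key_df <- unique(df[, keys, drop = FALSE])
  key_df <- key_df[do.call(order, key_df), , drop = FALSE]
  id <- do.call(paste, c(df[keys], sep = "\r"))
  key_id <- do.call(paste, c(key_df[keys], sep = "\r"))
  for (cls in doe_classes()) {
    key_df[[paste0("is_", cls, "_target")]] <-
      key_id %in% id[df$doe == cls]
  }
  rownames(key_df) <- NULL
  key_df
}
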