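test_that("records without shared identifiers stay separate drugs", {
  links <- data.frame(record_id = c("A", "B"), namespace = "cid",
                      value = c("x", "y"))
  map <- unify_drugs(links)
  expect_equal(length(unique(map$drug_id)), 2)
})

test_that("shared identifiers merge transitively", {
  links <- data.frame(record_id = c("A", "B", "B", "C"),
                      namespace = "cid", value = c("x", "x", "y", "y"))
  map <- unify_drugs(links)
  expect_equal(unique(map$drug_id), "A")
})

test_that("identifier matching is case-normalized and namespace-scoped", {
  links <- data.frame(record_id = c("A", "B", "C"),
                      namespace = c("CID", "cid", "name"),
                      value = c("X1", "x1", "x1"))
  map <- unify_drugs(links)
  # A and B share cid/x1 despite case; C's name/x1 is a different namespace
  expect_equal(map$drug_id[map$record_id %in% c("A", "B")], c("A", "A"))
  expect_equal(map$drug_id[map$record_id == "C"], "C")
})

test_that("malformed link rows fail with their line numbers", {
  links <- data.frame(record_id = c("A", NA), namespace = "cid",
                      value = c("x", "y"))
  expect_error(unify_drugs(links), "line")
})

test_that("unification equals BFS connected components on random link graphs", {
  set.seed(99)
  for (rep in 1:100) {
    n_rec <- sample(5:40, 1)
    n_ids <- sample(3:15, 1)
    links <- data.frame(
      record_id = sprintf("R%02d", sample.int(n_rec, n_rec * 2, replace = TRUE)),
      namespace = sample(c("cid", "name"), n_rec * 2, replace = TRUE),
      value = sprintf("v%02d", sample.int(n_ids, n_rec * 2, replace = TRUE)))
    expect_identical(unify_drugs(links), bfs_components(links))
  }
})

test_that("refining the link set never merges more records", {
  set.seed(7)
  links <- data.frame(
    record_id = sprintf("R%02d", sample.int(20, 60, replace = TRUE)),
    namespace = "cid", value = sprintf("v%d", sample.int(8, 60, replace = TRUE)))
  full <- unify_drugs(links)
  refined <- unify_drugs(links[1:30, ])
  # partition property: the refined (smaller) link set is a refinement
  agree <- merge(full, refined, by = "record_id")
  same_refined <- outer(agree$drug_id.y, agree$drug_id.y, "==")
  same_full <- outer(agree$drug_id.x, agree$drug_id.x, "==")
  expect_true(all(same_full[same_refined]))
})

test_that("mechanism terms map to their DOE classes with other as fallback", {
  cls <- classify_mechanism(c("agonist", "Antagonist", "binding agent",
                              "  AGONIST ", "frobnicator"))
  expect_equal(as.character(cls),
               c("activator", "inhibitor", "other", "activator", "other"))
  expect_equal(attr(cls, "unmapped"), "frobnicator")
})

test_that("discrepancy resolution honors source tier then directionality", {
  # tier-1 beats tier-2 regardless of class
  expect_equal(resolve_discrepancies(c("inhibitor", "activator"),
                                     c("chembl", "otp")), "inhibitor")
  # within a tier, directional classes beat other
  expect_equal(resolve_discrepancies(c("other", "activator"),
                                     c("chembl", "chembl")), "activator")
  # single annotation returns itself
  expect_equal(resolve_discrepancies("other", "gtop"), "other")
  # unresolved activator-vs-inhibitor tie at equal tier is flagged
  expect_true(is.na(resolve_discrepancies(c("activator", "inhibitor"),
                                          c("otp", "gtop"))))
  expect_error(resolve_discrepancies(character(0), character(0)), ">= 1")
})

test_that("resolution reproduces the priority rules on all 2-source cases", {
  classes <- c("activator", "inhibitor", "other")
  sources <- c(t1 = "chembl", t2 = "otp")
  for (c1 in classes) for (c2 in classes) for (s1 in sources) for (s2 in sources) {
    got <- resolve_discrepancies(c(c1, c2), c(s1, s2))
    tiers <- c(s1, s2) == "chembl"
    pool <- if (any(tiers)) c(c1, c2)[tiers] else c(c1, c2)
    directional <- setdiff(pool, "other")
    pool <- if (length(directional)) directional else pool
    want <- if (length(unique(pool)) == 1) unique(pool) else NA_character_
    expect_identical(got, want)
  }
})

test_that("resolution is order-independent", {
  doe <- c("other", "activator", "inhibitor", "activator")
  src <- c("chembl", "otp", "gtop", "chembl")
  base <- resolve_discrepancies(doe, src)
  set.seed(3)
  for (i in 1:10) {
    p <- sample(4)
    expect_identical(resolve_discrepancies(doe[p], src[p]), base)
  }
})

test_that("built labels match generator ground truth without discrepancies", {
  cfg <- sim_config(n_genes = 120, n_drugs = 80, n_diseases = 8, seed = 21,
                    discrepancy_frac = 0, n_tabular = 4,
                    embed_dim_gene = 2, embed_dim_protein = 2)
  u <- generate_gene_universe(cfg)
  cat <- generate_drug_catalog(cfg, u$labels)
  built <- build_labels(cat$links, cat$mechanisms, cat$indications)
  expect_equal(built$gene_labels, cat$truth$gene_labels)
  expect_equal(built$pair_labels, cat$truth$pair_labels)
  expect_equal(nrow(built$unresolved), 0)
})

test_that("label tables have unique keys and flag unions over drugs", {
  links <- data.frame(record_id = c("r1", "r2"), namespace = "cid",
                      value = c("a", "b"))
  mechanisms <- data.frame(record_id = c("r1", "r2"), source = "chembl",
                           gene_id = "G1", raw_term = c("agonist", "antagonist"))
  built <- build_labels(links, mechanisms)
  expect_equal(nrow(built$gene_labels), 1)
  expect_true(built$gene_labels$is_activator_target)
  expect_true(built$gene_labels$is_inhibitor_target)
  expect_false(built$gene_labels$is_other_target)
  expect_equal(nrow(built$pair_labels), 0)
})

test_that("indications referencing unknown drugs are skipped with a warning", {
  links <- data.frame(record_id = c("r1", "r9"), namespace = "cid",
                      value = c("a", "z"))
  mechanisms <- data.frame(record_id = "r1", source = "chembl",
                           gene_id = "G1", raw_term = "agonist")
  indications <- data.frame(record_id = c("r1", "r9"),
                            disease_code = c("A01", "B02"))
  expect_warning(built <- build_labels(links, mechanisms, indications),
                 "skipped")
  expect_equal(built$pair_labels$disease_code, "A01")
})
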