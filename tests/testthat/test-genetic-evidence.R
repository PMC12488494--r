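test_that("association encoding applies the strict p < 0.05 rule", {
  expect_equal(encode_association(0.01, -1), -2)
  expect_equal(encode_association(0.2, 1), 0)
  expect_equal(encode_association(0.05, 1), 0)   # boundary excluded
  expect_equal(encode_association(1e-4, 1), 4)
  expect_error(encode_association(0, 1), "0, 1")
  expect_error(encode_association(-0.1, 1), "0, 1")
})

test_that("encoding magnitude is monotone in significance", {
  set.seed(5)
  p <- sort(runif(50, 1e-10, 0.049))
  v <- abs(encode_association(p, 1))
  expect_true(all(diff(v) <= 0))
})

test_that("missense score counts deleterious calls over returned predictions", {
  calls <- data.frame(kind = rep("qualitative", 30),
                      value = rep(c("D", "T"), 15))
  expect_equal(missense_score(calls), 0.5)
  # fewer than 8 returned predictions -> missing
  expect_true(is.na(missense_score(calls[1:7, ])))
  # quantitative rank score: strictly greater than 0.9
  quant <- data.frame(kind = rep("quantitative", 8),
                      value = c(0.95, 0.9, 0.91, 0.1, 0.89, 0.99, 0.9, 0.5))
  expect_equal(missense_score(quant), 3 / 8)
})

test_that("eQTL concordance features encode direction and the closest gene wins", {
  assoc <- data.frame(variant_id = c("v1", "v2", "v3"),
                      disease_code = "A01",
                      beta_sign = c(1, -1, 1),
                      p_value = c(1e-3, 1e-4, 1e-2))
  eqtl <- data.frame(variant_id = c("v1", "v2", "v3", "v3"),
                     gene_id = c("G1", "G1", "G1", "G2"),
                     eqtl_sign = c(1, 1, 1, 1),
                     significant = TRUE,
                     distance = c(100, 100, 50000, 5000))
  f <- eqtl_direction_features(assoc, eqtl)
  g1 <- f[f$gene_id == "G1", ]
  # v1: risk allele raises expression -> inhibitor support, encoded +3
  expect_equal(g1$eqtl_inhibitor, 3)
  # v2: protective allele raises expression -> activator support, encoded -4
  expect_equal(g1$eqtl_activator, -4)
  # v3 belongs to G2 (5 kb < 50 kb): only the closest gene receives it
  expect_equal(f$eqtl_inhibitor[f$gene_id == "G2"], 2)
})

test_that("per-direction features keep the most significant association", {
  assoc <- data.frame(variant_id = c("v1", "v2"), disease_code = "A01",
                      beta_sign = c(1, 1), p_value = c(1e-3, 1e-5))
  eqtl <- data.frame(variant_id = c("v1", "v2"), gene_id = "G1",
                     eqtl_sign = c(1, 1), significant = TRUE, distance = 1)
  f <- eqtl_direction_features(assoc, eqtl)
  expect_equal(f$eqtl_inhibitor, 5)
})

test_that("harmonic Locus2gene sum normalizes to identity and maximum", {
  one <- data.frame(gene_id = "G1", disease_code = "A01",
                    mechanism = "inhibitor", score = 0.37)
  expect_equal(l2g_harmonic_features(one)$l2g_inhibitor, 0.37)
  ones <- data.frame(gene_id = "G1", disease_code = "A01",
                     mechanism = "activator", score = rep(1, 7))
  expect_equal(l2g_harmonic_features(ones)$l2g_activator, 1)
  both <- rbind(data.frame(gene_id = "G1", disease_code = "A01",
                           mechanism = "inhibitor", score = 0.4),
                data.frame(gene_id = "G1", disease_code = "A01",
                           mechanism = "activator", score = 0.6))
  f <- l2g_harmonic_features(both)
  expect_equal(f$l2g_activator, 0.6)  # larger sum retained with its direction
  expect_equal(f$l2g_inhibitor, 0)
})

test_that("rare-variant categories take the most significant variant", {
  mk_assoc <- function(...) {
    base <- data.frame(variant_id = NA, gene_id = "G1", disease_code = "A01",
                       dataset = "finngen", af_bin = "rare", beta_sign = 1,
                       p_value = NA, functional_class = NA,
                       missense_score = NA_real_, stringsAsFactors = FALSE)
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      out <- base; out[names(r)] <- r; out
    }))
  }
  ga <- list(associations = mk_assoc(
               list(variant_id = "v1", p_value = 1e-4, functional_class = "GOF"),
               list(variant_id = "v2", p_value = 1e-3, functional_class = "LOF_hc",
                    beta_sign = -1),
               list(variant_id = "v3", p_value = 1e-5, functional_class = "LOF_hc",
                    beta_sign = -1),
               list(variant_id = "v4", p_value = 1e-2,
                    functional_class = "missense_other", missense_score = 0.8),
               list(variant_id = "v5", p_value = 1e-2, functional_class = "banana")),
             eqtl = data.frame(), burden = data.frame(
               gene_id = character(0), disease_code = character(0),
               dataset = character(0), mask = character(0),
               beta_sign = numeric(0), p_value = numeric(0)),
             l2g = data.frame(), complementary = data.frame())
  pairs <- data.frame(gene_id = "G1", disease_code = "A01")
  f <- build_pair_features(ga, pairs)
  expect_equal(f$rare_finngen_gof, 4)
  expect_equal(f$rare_finngen_lof_hc, -5)        # min-p variant wins
  expect_equal(f$rare_finngen_missense_damaging, 2)
  expect_equal(f$rare_finngen_other, 2)          # unknown class falls back
  expect_equal(f$rare_finngen_missense_benign, 0)  # tested dataset, no hit
  expect_true(is.na(f$rare_genebass_gof))        # untested dataset stays missing
})

test_that("burden features encode signed log p with tri-state semantics", {
  ga <- list(associations = data.frame(
               variant_id = character(0), gene_id = character(0),
               disease_code = character(0), dataset = character(0),
               af_bin = character(0), beta_sign = numeric(0),
               p_value = numeric(0), functional_class = character(0),
               missense_score = numeric(0)),
             eqtl = data.frame(),
             burden = data.frame(gene_id = "G1", disease_code = "A01",
                                 dataset = "finngen",
                                 mask = c("plof", "missense"),
                                 beta_sign = c(-1, 1),
                                 p_value = c(0.04, 0.06)),
             l2g = data.frame(), complementary = data.frame())
  f <- build_pair_features(ga, data.frame(gene_id = "G1", disease_code = "A01"))
  expect_equal(f$burden_finngen_plof, -1 * -log10(0.04))  # approx -1.3979
  expect_equal(f$burden_finngen_missense, 0)       # tested, p >= 0.05
  expect_equal(f$burden_finngen_plof_missense, 0)  # tested dataset, mask absent
  expect_true(is.na(f$burden_genebass_plof))       # untested dataset
})

test_that("feature vectors have 31 features in groups of 4/14/9/4", {
  sch <- pair_feature_schema()
  expect_equal(nrow(sch), 31)
  expect_equal(unname(table(sch$group)[c("common", "rare", "burden", "complementary")]),
               c(4L, 14L, 9L, 4L), ignore_attr = TRUE)
})

test_that("tri-state semantics survive a file round-trip", {
  cfg <- sim_config(n_genes = 20, n_diseases = 5, seed = 17)
  pl <- generate_pair_labels(cfg, 150)
  ga <- generate_genetic_associations(cfg, pl)
  f <- build_pair_features(ga, pl)
  path <- tempfile(fileext = ".tsv")
  write_doe_tsv(f, path)
  back <- read_doe_tsv(path)
  for (col in pair_feature_schema()$feature) {
    expect_identical(is.na(back[[col]]), is.na(f[[col]]), label = col)
    expect_identical(back[[col]] == 0, f[[col]] == 0, label = col)
    expect_equal(back[[col]], f[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("flipping every beta sign mirrors features and swaps support", {
  cfg <- sim_config(n_genes = 30, n_diseases = 8, seed = 23)
  pl <- generate_pair_labels(cfg, 1000)
  ga <- generate_genetic_associations(cfg, pl)
  f <- build_pair_features(ga, pl)

  flipped <- ga
  flipped$associations$beta_sign <- -flipped$associations$beta_sign
  flipped$burden$beta_sign <- -flipped$burden$beta_sign
  flipped$complementary$beta_sign <- -flipped$complementary$beta_sign
  flipped$l2g$mechanism <- c(activator = "inhibitor",
                             inhibitor = "activator")[flipped$l2g$mechanism]
  f2 <- build_pair_features(flipped, pl)

  sch <- pair_feature_schema()
  signed <- sch$feature[sch$semantics %in% c("gof", "lof", "none") &
                          sch$group != "common"]
  for (col in signed)
    expect_equal(f2[[col]], -f[[col]], label = col)
  # concordance flips when beta flips: the eQTL pair swaps and negates
  expect_equal(f2$eqtl_inhibitor, -f$eqtl_activator)
  expect_equal(f2$eqtl_activator, -f$eqtl_inhibitor)
  # L2G sums are unsigned; their mechanism slots swap
  expect_equal(f2$l2g_inhibitor, f$l2g_activator)
  expect_equal(f2$l2g_activator, f$l2g_inhibitor)
  # support counts swap between mechanisms
  expect_equal(bin_support_counts(f2, "inhibitor"),
               bin_support_counts(f, "activator"))
  expect_equal(bin_support_counts(f2, "activator"),
               bin_support_counts(f, "inhibitor"))
})

test_that("bin support counts follow the direction framework", {
  sch <- pair_feature_schema()
  empty <- setNames(rep(NA_real_, nrow(sch)), sch$feature)
  expect_equal(bin_support_counts(empty, "inhibitor"), 0L)
  zero <- setNames(rep(0, nrow(sch)), sch$feature)
  expect_equal(bin_support_counts(zero, "inhibitor"), 0L)
  expect_equal(bin_support_counts(zero, "activator"), 0L)
  # common inhibitor concordance + rare GOF risk -> two supporting bins
  v <- empty
  v["eqtl_inhibitor"] <- 2.5
  v["rare_finngen_gof"] <- 3.1
  expect_equal(bin_support_counts(v, "inhibitor"), 2L)
  expect_equal(bin_support_counts(v, "activator"), 0L)
  # protective LOF burden supports inhibition in the ultrarare bin
  v["burden_meta_plof"] <- -2
  expect_equal(bin_support_counts(v, "inhibitor"), 3L)
})
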