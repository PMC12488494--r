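#' Simulation configuration
#'
#' Builds the configuration object that drives every synthetic-data generator
#' in the package. The defaults encode the statistical structure the analysis
#' assumes on real data: a druggable genome where roughly 76% of targets are
#' inhibited, 23% activated and 43% modulated by other mechanisms (labels are
#' multi-label: one gene may carry several), five partially overlapping drug
#' annotation sources, and sparse gene-disease genetic evidence. One knob,
#' \code{signal_strength}, scales how far class-conditional feature
#' distributions separate; \code{signal_strength = 0} produces pure noise.
#'
#' All randomness derives from \code{seed} through fixed per-stream offsets,
#' so generating one table never perturbs another and identical configurations
#' give byte-identical outputs.
#'
#' @param n_genes,n_drugs,n_diseases Number of genes, drugs and disease codes.
#' @param n_sources Number of drug annotation sources (first two are treated
#'   as tier-1 by discrepancy resolution downstream).
#' @param frac_activator,frac_inhibitor,frac_other Marginal probability that a
#'   gene is an activator / inhibitor / other-mechanism target. Defaults match
#'   the observed fractions among druggable genes (0.232, 0.759, 0.429).
#' @param signal_strength Non-negative scaling of class separation in features
#'   and of planted genetic evidence. 1 is a moderate, clearly learnable
#'   signal; 0 is the null.
#' @param missing_rate Completely-at-random missingness rate applied to
#'   tabular gene features only (embeddings are never missing).
#' @param n_tabular Number of tabular gene features (41 uses the shipped
#'   schema names; other values generate a generic schema).
#' @param embed_dim_gene,embed_dim_protein Dimensions of the generated gene
#'   embedding and the raw (pre-reduction) protein embedding.
#' @param discrepancy_frac Fraction of drug-gene pairs receiving a discrepant
#'   mechanism annotation from a lower-tier source.
#' @param alias_overlap Probability that consecutive source records of the
#'   same drug share an identifier alias; 1 links every drug into a single
#'   connected component, 0 leaves every record isolated.
#' @param avail_common,avail_rare,avail_burden Probability that a gene-disease
#'   pair is tested (per dataset) in the common-variant, rare-variant and
#'   gene-burden channels.
#' @param noise_rate Expected number of label-independent noise associations
#'   per tested pair-dataset.
#' @param seed Integer root seed.
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, n_drugs = 50, n_diseases = 10, seed = 1)
#' cfg$frac_inhibitor
#' @export
sim_config <- function(n_genes, n_drugs = 2L * n_genes, n_diseases = 50L,
                       n_sources = 5L,
                       frac_activator = 0.232, frac_inhibitor = 0.759,
                       frac_other = 0.429,
                       signal_strength = 1, missing_rate = 0.07,
                       n_tabular = 41L,
                       embed_dim_gene = 256L, embed_dim_protein = 256L,
                       discrepancy_frac = 0.02, alias_overlap = 1,
                       avail_common = 0.6, avail_rare = 0.4,
                       avail_burden = 0.4, noise_rate = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_drugs = check_count(n_drugs, "n_drugs"),
    n_diseases = check_count(n_diseases, "n_diseases"),
    n_sources = check_count(n_sources, "n_sources", positive = TRUE),
    frac_activator = check_proportion(frac_activator, "frac_activator"),
    frac_inhibitor = check_proportion(frac_inhibitor, "frac_inhibitor"),
    frac_other = check_proportion(frac_other, "frac_other"),
    signal_strength = signal_strength,
    missing_rate = check_proportion(missing_rate, "missing_rate"),
    n_tabular = check_count(n_tabular, "n_tabular", positive = TRUE),
    embed_dim_gene = check_count(embed_dim_gene, "embed_dim_gene", positive = TRUE),
    embed_dim_protein = check_count(embed_dim_protein, "embed_dim_protein", positive = TRUE),
    discrepancy_frac = check_proportion(discrepancy_frac, "discrepancy_frac"),
    alias_overlap = check_proportion(alias_overlap, "alias_overlap"),
    avail_common = check_proportion(avail_common, "avail_common"),
    avail_rare = check_proportion(avail_rare, "avail_rare"),
    avail_burden = check_proportion(avail_burden, "avail_burden"),
    noise_rate = noise_rate,
    seed = as.integer(seed)
  )
  if (!is.numeric(signal_strength) || signal_strength < 0)
    stop_config("signal_strength must be non-negative")
  if (!is.numeric(noise_rate) || noise_rate < 0)
    stop_config("noise_rate must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  genes: %d  drugs: %d  diseases: %d  sources: %d\n",
              x$n_genes, x$n_drugs, x$n_diseases, x$n_sources))
  cat(sprintf("  DOE fractions (act/inh/other): %.3f / %.3f / %.3f\n",
              x$frac_activator, x$frac_inhibitor, x$frac_other))
  cat(sprintf("  signal_strength: %g  missing_rate: %g  seed: %d\n",
              x$signal_strength, x$missing_rate, x$seed))
  invisible(x)
}

doe_classes <- function() c("activator", "inhibitor", "other")

sim_gene_ids <- function(n) if (n > 0) sprintf("G%05d", seq_len(n)) else character(0)

sim_disease_codes <- function(n) {
  if (n == 0) return(character(0))
  i <- seq_len(n) - 1L
  paste0(LETTERS[(i %/% 100L) + 1L], sprintf("%02d", i %% 100L))
}

# Multi-label DOE draw shared by gene-level and pair-level generators.
draw_doe_flags <- function(n, cfg) {
  data.frame(
    is_activator = stats::runif(n) < cfg$frac_activator,
    is_inhibitor = stats::runif(n) < cfg$frac_inhibitor,
    is_other     = stats::runif(n) < cfg$frac_other
  )
}
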