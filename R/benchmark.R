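#' Compendium-scale JL fidelity benchmark
#'
#' End-to-end measurement of how well a 1000-dimensional random subspace
#' preserves the sample-correlation structure of a full-transcriptome
#' compendium: generates a clustered synthetic compendium (34,198 genes x
#' 2,000 samples in 20 tissue-like clusters by default, module
#' correlation 0.7, noise sd 1), quantile-normalizes and log2-transforms
#' the counts, projects with a Gaussian JL matrix and returns
#' [evaluate_fidelity()] between the original-space and projected-space
#' sample correlations.
#'
#' @param n_genes,n_samples Compendium dimensions (defaults 34198, 2000).
#' @param k Projection dimension (default 1000).
#' @param n_gene_modules Number of broad expression programs (default 4;
#'   at compendium scale a handful of major axes dominate global
#'   sample-sample structure).
#' @param n_sample_clusters Number of tissue-like clusters (default 20).
#' @param seed Seed for the compendium; the projection uses `seed + 1`.
#' @return The fidelity value (Pearson correlation of the two
#'   sample-correlation upper triangles).
#' @export
jl_fidelity_benchmark <- function(n_genes = 34198, n_samples = 2000,
                                  k = 1000, n_gene_modules = 4,
                                  n_sample_clusters = 20, seed = 1) {
  cfg <- synthetic_config(
    n_genes = n_genes, n_samples = n_samples,
    n_gene_modules = n_gene_modules, n_sample_clusters = n_sample_clusters,
    module_corr = 0.7, noise_sd = 1, seed = seed
  )
  sim <- generate_compendium(cfg)
  m <- sim$compendium$expression
  rm(sim); gc(FALSE)
  m <- log2_transform(quantile_normalize(m))
  gc(FALSE)
  p <- build_projection(n_genes, k = k, seed = seed + 1)
  evaluate_fidelity(m, p)
}
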