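# Internal constants of the generative model. The gene-level variance
# splits into a shared per-module factor (calibrated so within-module
# correlation equals module_corr) and independent noise; a fraction
# share_delta of the factor variance is tied to sample-cluster means,
# which is what separates tissue-like clusters without inducing
# between-module gene correlations beyond realized-overlap noise.
.syn_baseline_sd <- 1.5     # sd of per-gene log2 baseline abundance
.syn_share_delta <- 0.25    # cluster-mean share of the module factor
.syn_noise_het <- 0.3       # half-width of per-sample noise-scale spread

.syn_tissues <- c(
  "liver", "brain cortex", "heart", "kidney", "lung", "pancreatic islet",
  "skeletal muscle", "spleen", "embryonic stem cell", "dendritic cell",
  "thymus", "testis", "retina", "adipose", "bone marrow", "colon",
  "skin fibroblast", "mammary gland", "placenta", "whole blood"
)

#' Configuration of the synthetic compendium generator
#'
#' Bundles and validates the knobs of the generative model: genes belong
#' to co-expressed modules, samples to tissue-like clusters; log2-scale
#' expression is gene baseline + a shared per-module factor (scaled so
#' within-module correlation is `module_corr`, with a fraction of the
#' factor variance tied to cluster means) + Gaussian noise; counts are
#' rounded exponentiated values with a multiplicative gamma overdispersion
#' (`count_dispersion`).
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_gene_modules Number of co-expression modules (genes assigned
#'   cyclically, so module sizes differ by at most one).
#' @param n_sample_clusters Number of tissue-like sample clusters.
#' @param module_corr Target within-module expression correlation, in
#'   (0, 1) (default 0.7).
#' @param noise_sd Gene-level log2 noise standard deviation (default 1).
#' @param count_mean Typical count scale: gene baselines are centered at
#'   `log2(count_mean)` (default 500).
#' @param count_dispersion Overdispersion of the count layer; 0 disables
#'   it (default 0.05).
#' @param seed Integer seed; all outputs are byte-identical given the
#'   same configuration.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200, n_samples = 500,
                             n_gene_modules = 10, n_sample_clusters = 5,
                             module_corr = 0.7, noise_sd = 1,
                             count_mean = 500, count_dispersion = 0.05,
                             seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_gene_modules = as.integer(n_gene_modules),
    n_sample_clusters = as.integer(n_sample_clusters),
    module_corr = module_corr, noise_sd = noise_sd,
    count_mean = count_mean, count_dispersion = count_dispersion,
    seed = as.integer(seed)
  )
  check <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  check(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  check(cfg$n_samples >= 1, "n_samples", "must be >= 1")
  check(cfg$n_gene_modules >= 1 && cfg$n_gene_modules <= cfg$n_genes,
        "n_gene_modules", "must be in [1, n_genes]")
  check(cfg$n_sample_clusters >= 1 && cfg$n_sample_clusters <= cfg$n_samples,
        "n_sample_clusters", "must be in [1, n_samples]")
  check(cfg$module_corr > 0 && cfg$module_corr < 1,
        "module_corr", "must be in (0, 1)")
  check(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  check(cfg$count_mean > 0, "count_mean", "must be > 0")
  check(cfg$count_dispersion >= 0, "count_dispersion", "must be >= 0")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_genes, " genes in ", x$n_gene_modules,
      " modules x ", x$n_samples, " samples in ", x$n_sample_clusters,
      " clusters; module_corr ", x$module_corr, ", noise_sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic expression compendium
#'
#' Simulates a count compendium with planted structure: each gene belongs
#' to one co-expression module and each sample to one tissue-like cluster.
#' On the log2 scale, expression is the sum of a per-gene baseline, a
#' shared per-module factor whose variance is calibrated so that genes of
#' the same module correlate at `module_corr` (a fraction of that factor
#' follows cluster-specific means, separating the clusters), and Gaussian
#' noise whose scale varies mildly from sample to sample (emulating
#' library-quality differences). Counts are the rounded exponentiated
#' values, optionally with multiplicative gamma overdispersion. Metadata
#' fields are populated with cluster-derived tissue names and synthetic
#' series ids; ground-truth labels are returned alongside, never inside,
#' the compendium.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with elements `compendium` (a [compendium()]) and
#'   `labels` (list with `gene_module`, `sample_cluster`, `gene_symbols`,
#'   `sample_ids` and the `config`).
#' @examples
#' sim <- generate_compendium(synthetic_config(n_genes = 50, n_samples = 30,
#'   n_gene_modules = 5, n_sample_clusters = 3, seed = 42))
#' sim$compendium
#' table(sim$labels$gene_module)
#' @export
generate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_genes
  m <- cfg$n_samples
  k <- cfg$n_gene_modules
  cl <- cfg$n_sample_clusters
  gene_module <- ((seq_len(n) - 1L) %% k) + 1L
  sample_cluster <- ((seq_len(m) - 1L) %% cl) + 1L
  rho <- cfg$module_corr
  # Total log2-scale noise variance includes the count-overdispersion
  # layer (log2 of a mean-1 gamma multiplier); the shared-factor scale is
  # calibrated against it so that genes of one module correlate at
  # module_corr on the log2(count) scale.
  disp_var <- if (cfg$count_dispersion > 0) {
    trigamma(1 / cfg$count_dispersion) / log(2)^2
  } else 0
  noise_var <- cfg$noise_sd^2 + disp_var
  phi <- sqrt(noise_var * rho / (1 - rho))

  counts <- .with_seed(cfg$seed, {
    baseline <- rnorm(n, mean = log2(cfg$count_mean), sd = .syn_baseline_sd)
    delta <- matrix(rnorm(k * cl), k, cl)          # module x cluster means
    u <- matrix(rnorm(k * m), k, m)                # module x sample factors
    f <- sqrt(.syn_share_delta) * delta[, sample_cluster, drop = FALSE] +
      sqrt(1 - .syn_share_delta) * u
    het <- runif(m, 1 - .syn_noise_het, 1 + .syn_noise_het)
    het <- het / sqrt(mean(het^2))                 # keep E[noise var] fixed
    x <- matrix(rnorm(n * m), n, m)
    x <- x * rep(cfg$noise_sd * het, each = n)
    x <- x + phi * f[gene_module, , drop = FALSE]
    x <- x + baseline
    x <- 2^x
    if (cfg$count_dispersion > 0) {
      shape <- 1 / cfg$count_dispersion
      x <- x * matrix(rgamma(n * m, shape = shape, rate = shape), n, m)
    }
    round(x)
  })

  gene_symbols <- sprintf("G%0*d", nchar(n), seq_len(n))
  sample_ids <- sprintf("SAMP%0*d", nchar(m), seq_len(m))
  tissue <- rep_len(.syn_tissues, cl)[sample_cluster]
  # each cluster contributes two series, emulating multiple studies per tissue
  within_cluster_ord <- (seq_len(m) - 1L) %/% cl
  series_no <- (sample_cluster - 1L) * 2L + (within_cluster_ord %% 2L) + 1L
  metadata <- data.frame(
    sample_id = sample_ids,
    series_id = sprintf("SER%04d", series_no),
    title = paste0(tissue, " sample ", seq_len(m)),
    source = tissue,
    characteristics = paste0("tissue: ", tissue),
    organism = "synthetic",
    instrument = "in silico simulator",
    submission_date = "2026-01-01",
    institute = "synthetic compendium generator",
    stringsAsFactors = FALSE
  )
  cpd <- compendium(counts, gene_symbols, sample_ids, metadata)
  labels <- list(
    gene_module = gene_module,
    sample_cluster = sample_cluster,
    gene_symbols = gene_symbols,
    sample_ids = sample_ids,
    config = cfg
  )
  list(compendium = cpd, labels = labels)
}

#' Generate gene-set libraries with planted truth
#'
#' Builds `n_true` sets drawn from single gene modules, each with a
#' `contamination` fraction of members replaced by off-module genes, plus
#' `n_decoy` size-matched sets drawn uniformly from all genes. True sets
#' should be recoverable from co-expression; decoys calibrate the null.
#' Per-set provenance (type and source module) is recorded in the
#' `provenance` attribute.
#'
#' @param labels Ground-truth labels from [generate_compendium()].
#' @param n_true,n_decoy Number of module-derived and random sets.
#' @param contamination Fraction of each true set drawn off-module, in
#'   `[0, 1]`.
#' @param set_size Members per set (default 10, capped at available
#'   genes).
#' @param seed Integer seed.
#' @return A `gene_set_library` with attribute `provenance` (tibble with
#'   columns `set`, `type`, `module`).
#' @export
generate_gene_sets <- function(labels, n_true = 20, n_decoy = 20,
                               contamination = 0, set_size = 10, seed = 1) {
  stopifnot(contamination >= 0, contamination <= 1,
            n_true + n_decoy >= 1)
  modules <- labels$gene_module
  symbols <- labels$gene_symbols
  k <- max(modules)
  .with_seed(seed, {
    sets <- list()
    prov <- list()
    for (i in seq_len(n_true)) {
      mod <- ((i - 1L) %% k) + 1L
      pool_in <- which(modules == mod)
      pool_out <- which(modules != mod)
      size <- min(set_size, length(pool_in) + length(pool_out))
      n_out <- min(round(contamination * size), length(pool_out))
      n_in <- min(size - n_out, length(pool_in))
      members <- c(pool_in[sample.int(length(pool_in), n_in)],
                   if (n_out > 0) pool_out[sample.int(length(pool_out), n_out)])
      nm <- sprintf("true_mod%02d_%03d", mod, i)
      sets[[nm]] <- symbols[members]
      prov[[nm]] <- tibble::tibble(set = nm, type = "true", module = mod)
    }
    for (i in seq_len(n_decoy)) {
      nm <- sprintf("decoy_%03d", i)
      sets[[nm]] <- symbols[sample(length(symbols), min(set_size, length(symbols)))]
      prov[[nm]] <- tibble::tibble(set = nm, type = "decoy", module = NA_integer_)
    }
    lib <- gene_set_library(sets, name = "synthetic_modules")
    attr(lib, "provenance") <- do.call(rbind, prov)
    lib
  })
}

#' Generate a PPI network with planted module structure
#'
#' Draws an undirected network over the labelled genes: an edge connects
#' two genes with probability `p_within` when they share a module and
#' `p_between` otherwise; no self-loops. With `p_between` near zero the
#' network's edges align with the co-expression modules and interactions
#' are predictable from correlation; with `p_within == p_between` the
#' network is structureless.
#'
#' @param labels Ground-truth labels from [generate_compendium()].
#' @param p_within,p_between Edge probabilities within and between
#'   modules.
#' @param seed Integer seed.
#' @return A `ppi_network`. Errors when no edge is drawn.
#' @export
generate_ppi <- function(labels, p_within = 0.3, p_between = 0.01, seed = 1) {
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1)
  modules <- labels$gene_module
  symbols <- labels$gene_symbols
  n <- length(symbols)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- modules[pairs[, 1]] == modules[pairs[, 2]]
  prob <- ifelse(same, p_within, p_between)
  keep <- .with_seed(seed, rbinom(nrow(pairs), 1, prob) == 1)
  if (!any(keep)) {
    stop("no edges drawn; increase p_within/p_between", call. = FALSE)
  }
  ppi_network(symbols[pairs[keep, 1]], symbols[pairs[keep, 2]])
}

#' Write ground-truth labels to a sidecar TSV
#'
#' Labels travel next to, never inside, the compendium file so that the
#' compendium format carries no oracle information.
#'
#' @param labels Labels from [generate_compendium()].
#' @param path Output TSV path (gene table); a second file
#'   `<path>.samples.tsv` receives the sample clusters.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(
    data.frame(gene_symbol = labels$gene_symbols,
               module = labels$gene_module),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(
    data.frame(sample_id = labels$sample_ids,
               cluster = labels$sample_cluster),
    paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
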