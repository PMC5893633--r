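#' Build a Johnson-Lindenstrauss projection matrix
#'
#' A random Gaussian projection from gene space to a k-dimensional
#' subspace: entries are i.i.d. Normal(0, 1/k), so inner products (and
#' hence covariances and correlations between samples) are preserved in
#' expectation with relative error on the order of 1/sqrt(k). A
#' 1000-dimensional subspace is the default working size for signature
#' search over a full transcriptome.
#'
#' @param n_genes Dimension of the original gene space.
#' @param k Target dimension (default 1000); must satisfy `1 <= k < n_genes`.
#' @param seed Integer seed; the matrix is reproducible from
#'   `(n_genes, k, seed)`.
#' @return An object of class `projection_matrix`: list with `values`
#'   (k x n_genes), `k`, `n_genes`, `seed`.
#' @export
build_projection <- function(n_genes, k = 1000, seed = 1) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k >= n_genes) {
    stop("k (", k, ") must be smaller than the number of genes (", n_genes,
         "); skip the projection for such low-dimensional data",
         call. = FALSE)
  }
  values <- .with_seed(seed, matrix(rnorm(k * n_genes, sd = sqrt(1 / k)),
                                    nrow = k, ncol = n_genes))
  structure(
    list(values = values, k = as.integer(k), n_genes = as.integer(n_genes),
         seed = as.integer(seed)),
    class = "projection_matrix"
  )
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("<projection_matrix> ", x$k, " x ", x$n_genes, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Project expression data into the JL subspace
#'
#' Applies the linear map `p$values %*% m`. The operation is exactly
#' linear, so signatures and compendium columns projected with the same
#' matrix remain comparable in the reduced space.
#'
#' @param m Numeric matrix over the gene index (genes x samples) or a
#'   numeric vector of length `n_genes`.
#' @param p A `projection_matrix` whose `n_genes` matches `nrow(m)`.
#' @param sample_ids Optional column labels for the projected matrix;
#'   defaults to `colnames(m)`.
#' @return For matrix input, an object of class `projected_compendium`
#'   (list with `values` k x M, `sample_ids`, `k`, `seed`); for vector
#'   input, a length-k numeric vector.
#' @export
project <- function(m, p, sample_ids = NULL) {
  stopifnot(inherits(p, "projection_matrix"))
  vec <- is.null(dim(m))
  if (vec) {
    if (length(m) != p$n_genes) {
      stop("dimension mismatch: signature has length ", length(m),
           " but the projection expects ", p$n_genes, " genes",
           call. = FALSE)
    }
    return(drop(p$values %*% m))
  }
  if (nrow(m) != p$n_genes) {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but the projection is ", p$k, " x ", p$n_genes, call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- colnames(m)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(m)))
  values <- p$values %*% m
  colnames(values) <- sample_ids
  structure(
    list(values = values, sample_ids = sample_ids, k = p$k, seed = p$seed),
    class = "projected_compendium"
  )
}

#' @export
print.projected_compendium <- function(x, ...) {
  cat("<projected_compendium> ", x$k, " x ", ncol(x$values),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Encode an up/down gene signature
#'
#' Turns lists of up- and down-regulated gene symbols into a numeric
#' vector over the compendium's gene index: +1 at up genes, -1 at down
#' genes, 0 elsewhere. Symbols are matched case-insensitively; unmapped
#' symbols are reported in the `unmapped` attribute.
#'
#' @param up,down Character vectors of gene symbols (either may be empty,
#'   but not both after mapping; they must not overlap).
#' @param gene_index Character vector of the compendium's gene symbols.
#' @return A numeric vector of length `length(gene_index)` with class
#'   `expr_signature` and attribute `unmapped`.
#' @export
encode_signature <- function(up, down = character(), gene_index) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  overlap <- intersect(toupper(up), toupper(down))
  if (length(overlap)) {
    stop("genes in both up and down lists: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  iu <- .match_symbols(up, gene_index)
  id <- .match_symbols(down, gene_index)
  unmapped <- c(up[is.na(iu)], down[is.na(id)])
  sig <- numeric(length(gene_index))
  sig[iu[!is.na(iu)]] <- 1
  sig[id[!is.na(id)]] <- -1
  if (all(sig == 0)) {
    stop("no signature gene maps to the compendium's gene index",
         call. = FALSE)
  }
  names(sig) <- gene_index
  structure(sig, unmapped = unmapped, class = "expr_signature")
}

#' @export
print.expr_signature <- function(x, ...) {
  cat("<expr_signature> ", sum(x > 0), " up, ", sum(x < 0), " down over ",
      length(x), " genes (", length(attr(x, "unmapped")), " unmapped)\n",
      sep = "")
  invisible(x)
}

#' Signature similarity search in the projected space
#'
#' Projects the signature with the same matrix as the compendium and
#' scores every sample by the Pearson correlation between the projected
#' signature and the sample's projected column. Because the projection
#' approximately preserves covariances, this ranking approximates a
#' full-space correlation search at a fraction of the cost. Hits are
#' sorted by decreasing score, ties broken by sample id.
#'
#' @param sig An `expr_signature` (or numeric vector over the gene index).
#' @param pc A `projected_compendium`.
#' @param p The `projection_matrix` used to build `pc`.
#' @param top_n Number of hits to return (default 10).
#' @return A tibble with columns `rank`, `sample_id`, `score`.
#' @export
search_signature <- function(sig, pc, p, top_n = 10) {
  stopifnot(inherits(pc, "projected_compendium"),
            inherits(p, "projection_matrix"))
  if (top_n < 1) stop("top_n must be at least 1", call. = FALSE)
  if (pc$seed != p$seed || pc$k != p$k) {
    stop("projected compendium and projection matrix do not match ",
         "(different seed or dimension)", call. = FALSE)
  }
  if (all(pc$values == 0)) {
    stop("projected compendium is all zeros; nothing to search",
         call. = FALSE)
  }
  s_hat <- project(as.numeric(sig), p)
  score <- suppressWarnings(as.numeric(cor(s_hat, pc$values)))
  ord <- order(-score, pc$sample_ids, method = "radix", na.last = TRUE)
  ord <- head(ord, top_n)
  tibble::tibble(
    rank = seq_along(ord),
    sample_id = pc$sample_ids[ord],
    score = score[ord]
  )
}

#' Correlation-structure fidelity of a projection
#'
#' Measures how well the JL subspace preserves the compendium's global
#' structure: the Pearson correlation between the upper-triangle entries
#' of the sample-sample correlation matrix computed in the original gene
#' space and the one computed after projection. A value of 1 means the
#' projected space reproduces the sample correlation structure exactly.
#'
#' Samples are centered (per sample, across genes) before projection and
#' similarity is the normalized inner product of the centered profiles:
#' in the original space this is exactly the Pearson correlation between
#' samples, and it is the quantity a JL map preserves (an orthonormal
#' square projection gives fidelity 1 exactly).
#'
#' @param m Numeric matrix, genes x samples (at least 3 samples).
#' @param p A `projection_matrix` over `nrow(m)` genes.
#' @return A single numeric fidelity value in `[-1, 1]`.
#' @export
evaluate_fidelity <- function(m, p) {
  if (ncol(m) < 3) {
    stop("fidelity needs at least 3 samples (2 distinct sample pairs)",
         call. = FALSE)
  }
  mc <- scale(m, center = TRUE, scale = FALSE)  # center each sample
  orig <- .cosine_columns(mc)                   # == cor(m)
  proj <- .cosine_columns(project(mc, p)$values)
  ut <- upper.tri(orig)
  cor(orig[ut], proj[ut])
}

# Normalized column inner products via BLAS; on column-centered input
# this equals cor(m) but is much faster at compendium scale.
.cosine_columns <- function(m) {
  cp <- crossprod(m)
  d <- sqrt(diag(cp))
  d[d == 0] <- 1
  cp / tcrossprod(d)
}

# Sample-sample Pearson correlation of a matrix (genes x samples).
.sample_correlation <- function(m) {
  .cosine_columns(scale(m, center = TRUE, scale = FALSE))
}

#' Build a signature-search index from a compendium
#'
#' One-call pipeline for interactive search: quantile-normalizes and
#' log2-transforms the counts, z-scores each gene across samples (so a
#' +1/-1 signature correlates with relative over/under-expression), builds
#' the Gaussian projection and projects the samples.
#'
#' @param c A `compendium`.
#' @param k Projection dimension (default 1000).
#' @param seed Projection seed (persisted in the index so searches are
#'   reproducible).
#' @return A list of class `search_index` with elements `projection`,
#'   `projected` and `gene_index`.
#' @examples
#' cpd <- generate_compendium(synthetic_config(n_genes = 300, n_samples = 40,
#'   n_gene_modules = 5, n_sample_clusters = 4, seed = 7))$compendium
#' idx <- build_search_index(cpd, k = 50, seed = 7)
#' hits <- search_index(idx, up = cpd$gene_symbols[1:10], top_n = 3)
#' @export
build_search_index <- function(c, k = 1000, seed = 1) {
  validate_compendium(c)
  m <- log2_transform(quantile_normalize(c$expression))
  m <- zscore_genes(m)
  p <- build_projection(nrow(m), k = k, seed = seed)
  pc <- project(m, p, sample_ids = c$sample_ids)
  structure(
    list(projection = p, projected = pc, gene_index = c$gene_symbols),
    class = "search_index"
  )
}

#' @export
print.search_index <- function(x, ...) {
  cat("<search_index> k=", x$projection$k, " over ",
      length(x$gene_index), " genes, ", ncol(x$projected$values),
      " samples\n", sep = "")
  invisible(x)
}

#' Search an index with up/down gene lists
#'
#' @param index A `search_index` from [build_search_index()].
#' @param up,down Character vectors of gene symbols.
#' @param top_n Number of hits to return.
#' @return A tibble of ranked hits, see [search_signature()].
#' @export
search_index <- function(index, up, down = character(), top_n = 10) {
  stopifnot(inherits(index, "search_index"))
  sig <- encode_signature(up, down, index$gene_index)
  search_signature(sig, index$projected, index$projection, top_n = top_n)
}
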