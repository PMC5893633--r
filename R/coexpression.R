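# Runs code with a private RNG stream so package functions are
# reproducible from an explicit seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Randomly subsample compendium columns
#'
#' Draws `min(n, M)` distinct sample indices uniformly without
#' replacement. Large compendia are correlated on a random subset of
#' samples (10,000 by default) because co-expression estimates saturate
#' well below the full collection size.
#'
#' @param c A `compendium`, or the number of samples `M` directly.
#' @param n Number of samples to draw (default 10000; must be >= 2).
#' @param seed Integer seed making the draw reproducible.
#' @return Sorted integer vector of column indices.
#' @export
subsample_samples <- function(c, n = 10000, seed = 1) {
  m_total <- if (inherits(c, "compendium")) ncol(c$expression) else as.integer(c)
  if (n < 2) stop("cannot subsample fewer than 2 samples", call. = FALSE)
  if (n >= m_total) return(seq_len(m_total))
  sort(.with_seed(seed, sample.int(m_total, n)))
}

#' Gene-gene Pearson correlation matrix
#'
#' Computes the full symmetric matrix of pairwise gene correlations across
#' samples, the object underlying guilt-by-association prediction of gene
#' function and protein interactions. Rows are processed in chunks of
#' `chunk_size` genes so memory stays bounded; the result is independent
#' of the chunking. Genes with zero variance across samples are retained
#' (so gene indexing stays stable) with correlation 0 to every other gene
#' and a unit diagonal, and are flagged in the result.
#'
#' @param m Numeric matrix, genes x samples (at least 3 samples), usually
#'   quantile-normalized log2 counts.
#' @param chunk_size Number of gene rows per block (default 2000).
#' @param method `"pearson"` (default) or `"spearman"` (Pearson on ranks).
#' @param gene_symbols Gene labels; defaults to `rownames(m)`.
#' @param n_samples_used,seed Bookkeeping recorded in the result when the
#'   matrix came from a subsampled compendium.
#' @return An object of class `correlation_matrix`: list with `values`
#'   (N x N), `gene_symbols`, `zero_variance` (logical flags),
#'   `n_samples_used` and `seed`.
#' @examples
#' m <- matrix(rnorm(60), nrow = 4)
#' m[2, ] <- m[1, ]  # duplicated gene
#' gene_correlation_matrix(m, chunk_size = 2)$values[1, 2]
#' @export
gene_correlation_matrix <- function(m, chunk_size = 2000,
                                    method = c("pearson", "spearman"),
                                    gene_symbols = rownames(m),
                                    n_samples_used = ncol(m), seed = NA_integer_) {
  method <- match.arg(method)
  m <- as.matrix(m)
  n_samples <- ncol(m)
  if (n_samples < 3) {
    stop("correlation needs at least 3 samples", call. = FALSE)
  }
  if (chunk_size < 1) stop("chunk_size must be >= 1", call. = FALSE)
  n_genes <- nrow(m)
  if (is.null(gene_symbols)) gene_symbols <- paste0("G", seq_len(n_genes))
  if (method == "spearman") {
    m <- t(apply(m, 1, rank, ties.method = "average"))
  }
  mu <- rowMeans(m)
  z <- m - mu
  ss <- sqrt(rowSums(z^2))
  zero_var <- ss == 0
  z <- z / ifelse(ss > 0, ss, 1)
  z[zero_var, ] <- 0
  values <- matrix(0, n_genes, n_genes)
  starts <- seq(1L, n_genes, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n_genes)
    values[idx, ] <- tcrossprod(z[idx, , drop = FALSE], z)
  }
  values <- (values + t(values)) / 2     # exact symmetry
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  dimnames(values) <- list(gene_symbols, gene_symbols)
  structure(
    list(
      values = values,
      gene_symbols = as.character(gene_symbols),
      zero_variance = zero_var,
      n_samples_used = as.integer(n_samples_used),
      seed = as.integer(seed),
      method = method
    ),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", length(x$gene_symbols), " genes (",
      x$method, "), ", x$n_samples_used, " samples",
      if (!is.na(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  invisible(x)
}

#' Co-expression matrix of a compendium
#'
#' End-to-end convenience wrapper: subsamples the compendium's columns,
#' normalizes (quantile normalization of the counts followed by log2, by
#' default) and computes the chunked gene-gene correlation matrix with the
#' subsampling seed recorded in the result.
#'
#' @param c A `compendium`.
#' @param n_samples Number of samples to subsample (default 10000).
#' @param seed Subsampling seed.
#' @param chunk_size Row-block size for the correlation pass.
#' @param normalize One of `"log2qn"` (quantile normalization then log2;
#'   default), `"qn"` (quantile normalization only) or `"none"`.
#' @param method Correlation type, see [gene_correlation_matrix()].
#' @return A `correlation_matrix`.
#' @export
correlate_compendium <- function(c, n_samples = 10000, seed = 1,
                                 chunk_size = 2000,
                                 normalize = c("log2qn", "qn", "none"),
                                 method = c("pearson", "spearman")) {
  validate_compendium(c)
  normalize <- match.arg(normalize)
  idx <- subsample_samples(c, n = n_samples, seed = seed)
  m <- c$expression[, idx, drop = FALSE]
  if (normalize %in% c("log2qn", "qn")) m <- quantile_normalize(m)
  if (normalize == "log2qn") m <- log2_transform(m)
  gene_correlation_matrix(
    m, chunk_size = chunk_size, method = method,
    gene_symbols = c$gene_symbols, n_samples_used = length(idx), seed = seed
  )
}
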