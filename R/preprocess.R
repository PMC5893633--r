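# Appends a step to a matrix's provenance attribute (ordered record of
# the transforms applied so far).
.add_provenance <- function(m, step) {
  attr(m, "provenance") <- c(attr(m, "provenance"), step)
  m
}

#' Quantile-normalize a matrix across samples
#'
#' Forces every column (sample) to share the same value distribution: the
#' reference distribution is the mean, across columns, of each column's
#' sorted values, and each value is replaced by the reference value at its
#' within-column rank. Tied values receive the mean of the reference
#' values spanning their rank range (the "average ties" rule). This is the
#' standard normalization applied to gene counts before co-expression
#' analysis and embedding.
#'
#' @param m Numeric matrix (genes x samples) with at least one column and
#'   finite entries.
#' @return A matrix of the same shape and dimnames; every column holds the
#'   same multiset of values, and within-column rank order is preserved.
#' @examples
#' m <- cbind(c(5, 2, 3), c(4, 1, 6))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) stop("cannot quantile-normalize an empty matrix", call. = FALSE)
  if (!all(is.finite(m))) stop("matrix contains non-finite values", call. = FALSE)
  n <- nrow(m)
  p <- ncol(m)
  # reference distribution: mean of per-column order statistics
  ref <- numeric(n)
  for (j in seq_len(p)) ref <- ref + sort.int(m[, j], method = "radix")
  ref <- ref / p
  cs <- c(0, cumsum(ref))
  out <- m
  for (j in seq_len(p)) {
    x <- m[, j]
    rmin <- rank(x, ties.method = "min")
    rmax <- rank(x, ties.method = "max")
    # mean of ref[rmin..rmax]: handles ties of any span
    out[, j] <- (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  }
  .add_provenance(out, "quantile_normalize")
}

#' Log2-transform expression values
#'
#' Elementwise `log2(x + pseudocount)`, the variance-stabilizing transform
#' applied to counts after quantile normalization.
#'
#' @param m Numeric matrix with non-negative entries.
#' @param pseudocount Non-negative offset added before taking logs
#'   (default 1, so zero counts map to zero).
#' @return The transformed matrix.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) {
    stop("matrix contains negative values; log2 transform expects counts",
         call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  out <- log2(m + pseudocount)
  .add_provenance(out, sprintf("log2_transform(pseudocount=%g)", pseudocount))
}

#' Z-score genes across samples
#'
#' Centers and scales every row (gene) to mean 0 and unit sample variance
#' (denominator n-1). Constant rows, which carry no signal, map to all
#' zeros rather than NaN.
#'
#' @param m Numeric matrix (genes x samples) with at least two columns.
#' @return The row-standardized matrix.
#' @export
zscore_genes <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    stop("z-scoring needs at least two samples per gene", call. = FALSE)
  }
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  .add_provenance(out, "zscore_genes")
}

#' Select the most variable genes
#'
#' Ranks genes by the variance of their `log2(x + 1)` values across
#' samples (the scale on which expression heatmaps and embeddings are
#' built) and returns the indices of the top `n`, most variable first.
#' Equal variances are broken by gene-symbol lexicographic order so the
#' selection is reproducible.
#'
#' @param m Numeric matrix (genes x samples) of non-negative values.
#' @param n Number of genes to return (default 500).
#' @param gene_symbols Symbols used for tie-breaking; defaults to
#'   `rownames(m)` or the row index when unnamed.
#' @return Integer vector of row indices, in decreasing order of variance.
#' @export
top_variable_genes <- function(m, n = 500, gene_symbols = rownames(m)) {
  m <- as.matrix(m)
  if (n > nrow(m)) {
    stop("requested ", n, " genes but the matrix has only ", nrow(m),
         call. = FALSE)
  }
  if (is.null(gene_symbols)) {
    gene_symbols <- sprintf(paste0("%0", nchar(nrow(m)), "d"), seq_len(nrow(m)))
  }
  lm <- log2(m + 1)
  v <- rowSums((lm - rowMeans(lm))^2) / (ncol(m) - 1)
  ord <- order(-v, gene_symbols, method = "radix")
  head(ord, n)
}
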