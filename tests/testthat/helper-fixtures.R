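# Small fixtures built in code; no files ship with the tests.

# 3 genes x 5 samples with hand-written metadata: two adult-liver samples
# in one series, the rest spread over two further series.
toy_compendium <- function() {
  expr <- matrix(c(
    10, 0, 3, 7, 2,
    5, 1, 0, 2, 9,
    0, 4, 8, 1, 6
  ), nrow = 3, byrow = TRUE)
  compendium(
    expression = expr,
    gene_symbols = c("TP53", "GAPDH", "ACTB"),
    sample_ids = paste0("GSM", 1:5),
    metadata = data.frame(
      sample_id = paste0("GSM", 1:5),
      series_id = c("GSE1", "GSE1", "GSE2", "GSE3", "GSE3"),
      title = c("hepatocyte rep1", "hepatocyte rep2", "Pancreatic beta",
                "islet of Langerhans", "cortex neuron"),
      source = c("adult liver", "adult liver", "pancreas", "Pancreatic Islet",
                 "brain"),
      organism = "Homo sapiens",
      stringsAsFactors = FALSE
    )
  )
}

# Correlation-matrix object with prescribed values, for prediction tests
# that need exact correlations.
manual_corr <- function(values, genes = colnames(values)) {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  dimnames(values) <- list(genes, genes)
  structure(
    list(values = values, gene_symbols = genes,
         zero_variance = rep(FALSE, length(genes)),
         n_samples_used = NA_integer_, seed = NA_integer_,
         method = "pearson"),
    class = "correlation_matrix"
  )
}

# O(n^2) Mann-Whitney oracle: pairwise comparison count with 1/2 for
# ties; NA scores treated as below every defined score (tied together).
brute_force_auc <- function(score, member) {
  x <- score
  x[is.na(x)] <- -Inf
  pos <- x[member]
  neg <- x[!member]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent quantile-normalization oracle: sort each column, average
# across columns per rank, re-assign by rank; ties get the mean of the
# reference values over their rank span.
brute_force_qn <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ord <- order(x)
    sorted <- x[ord]
    assigned <- numeric(length(x))
    i <- 1
    while (i <= length(x)) {
      span <- which(sorted == sorted[i])
      assigned[span] <- mean(ref[span])
      i <- max(span) + 1
    }
    out[ord, j] <- assigned
  }
  out
}
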