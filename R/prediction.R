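# Maps gene symbols onto a correlation matrix's gene index,
# case-insensitively. Returns integer indices with NA for absent symbols.
.match_symbols <- function(symbols, gene_symbols) {
  match(toupper(symbols), toupper(gene_symbols))
}

#' Score genes against gene sets by mean co-expression
#'
#' The guilt-by-association score: for gene i and set j, the mean
#' correlation of gene i with the set's members, excluding gene i itself
#' when it belongs to the set (so known memberships cannot leak into their
#' own prediction). Set members absent from the correlation matrix are
#' ignored; a set with no mappable members other than gene i yields a
#' missing (NA) score.
#'
#' @param corr A `correlation_matrix`.
#' @param lib A `gene_set_library`; at least one member of some set must
#'   be present in the correlation matrix.
#' @return An object of class `prediction_matrix`: list with `scores`
#'   (genes x sets, NA where undefined), `gene_symbols`, `set_names` and
#'   `membership` (logical genes x sets matrix of known annotations).
#' @examples
#' m <- matrix(rnorm(300), nrow = 10,
#'             dimnames = list(paste0("G", 1:10), NULL))
#' corr <- gene_correlation_matrix(m)
#' lib <- gene_set_library(list(s1 = c("G1", "G2"), s2 = c("G3", "G4", "G5")))
#' score_gene_sets(corr, lib)$scores["G1", ]
#' @export
score_gene_sets <- function(corr, lib) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(lib, "gene_set_library"))
  genes <- corr$gene_symbols
  n_genes <- length(genes)
  n_sets <- length(lib$sets)
  # genes x sets membership indicator over mappable members
  member <- matrix(FALSE, n_genes, n_sets,
                   dimnames = list(genes, names(lib$sets)))
  for (j in seq_len(n_sets)) {
    idx <- .match_symbols(lib$sets[[j]], genes)
    member[idx[!is.na(idx)], j] <- TRUE
  }
  if (!any(member)) {
    stop("no gene set member maps to the correlation matrix", call. = FALSE)
  }
  ind <- member + 0
  sums <- corr$values %*% ind               # includes self-correlation
  counts <- matrix(colSums(ind), n_genes, n_sets, byrow = TRUE)
  # remove the scored gene's own (unit) diagonal term where it is a member
  sums <- sums - member
  counts <- counts - member
  scores <- sums / counts
  scores[counts == 0] <- NA_real_
  structure(
    list(
      scores = scores,
      gene_symbols = genes,
      set_names = names(lib$sets),
      membership = member
    ),
    class = "prediction_matrix"
  )
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat("<prediction_matrix> ", length(x$gene_symbols), " genes x ",
      length(x$set_names), " sets; ",
      sum(is.na(x$scores)), " undefined score(s)\n", sep = "")
  invisible(x)
}

# Mann-Whitney AUC of `member` under descending `score`; NA scores rank
# below all defined scores (absence of evidence must not inflate AUC) and
# ties take the midrank convention, so the value equals the trapezoidal
# area under the normalized cumulative membership indicator.
.rank_auc <- function(score, member) {
  x <- score
  x[is.na(x)] <- -Inf
  r <- rank(x, ties.method = "average")
  n_pos <- sum(member)
  n_neg <- length(member) - n_pos
  (sum(r[member]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Membership AUC of a prediction matrix
#'
#' Benchmarks co-expression scores against known annotations. In the
#' default per-gene direction, each gene's sets are ranked by score
#' (missing scores last) and the AUC is the probability that a set the
#' gene is known to belong to outranks one it does not, computed as the
#' trapezoidal area under the cumulative membership indicator -- the
#' Mann-Whitney statistic, with tied scores contributing 1/2. Genes whose
#' defined scores are all-member or all-non-member carry no signal and are
#' excluded (and counted). The per-set direction transposes the roles and
#' asks how well each set's members are ranked among genes.
#'
#' @param gm A `prediction_matrix` from [score_gene_sets()].
#' @param lib Optional `gene_set_library`; defaults to the membership
#'   recorded in `gm`.
#' @param direction `"gene"` (default): one AUC per gene across sets;
#'   `"set"`: one AUC per set across genes.
#' @return An object of class `auc_report`: list with `values` (tibble of
#'   unit, auc, n_member, n_nonmember), `n_excluded` and `direction`.
#'   Use [tidy()]/[glance()] for tabular access.
#' @export
membership_auc <- function(gm, lib = NULL, direction = c("gene", "set")) {
  stopifnot(inherits(gm, "prediction_matrix"))
  direction <- match.arg(direction)
  member <- gm$membership
  scores <- gm$scores
  if (!is.null(lib)) {
    stopifnot(inherits(lib, "gene_set_library"))
    member <- matrix(FALSE, nrow(scores), ncol(scores),
                     dimnames = dimnames(scores))
    for (j in seq_along(gm$set_names)) {
      set <- lib$sets[[gm$set_names[[j]]]]
      idx <- .match_symbols(set, gm$gene_symbols)
      member[idx[!is.na(idx)], j] <- TRUE
    }
  }
  if (direction == "set") {
    scores <- t(scores)
    member <- t(member)
    units <- gm$set_names
  } else {
    units <- gm$gene_symbols
  }
  n_units <- nrow(scores)
  auc <- rep(NA_real_, n_units)
  n_member <- integer(n_units)
  n_nonmember <- integer(n_units)
  for (i in seq_len(n_units)) {
    sc <- scores[i, ]
    mb <- member[i, ]
    defined <- !is.na(sc)
    n_pos_def <- sum(mb[defined])
    if (n_pos_def == 0 || n_pos_def == sum(defined)) next
    auc[[i]] <- .rank_auc(sc, mb)
    n_member[[i]] <- sum(mb)
    n_nonmember[[i]] <- length(mb) - sum(mb)
  }
  keep <- !is.na(auc)
  excluded <- sum(!keep)
  values <- tibble::tibble(
    unit = units[keep], auc = auc[keep],
    n_member = n_member[keep], n_nonmember = n_nonmember[keep]
  )
  structure(
    list(values = values, n_excluded = excluded, direction = direction),
    class = "auc_report"
  )
}

#' @export
print.auc_report <- function(x, ...) {
  cat("<auc_report> ", nrow(x$values), " ", x$direction, "(s), median AUC ",
      if (nrow(x$values)) sprintf("%.3f", median(x$values$auc)) else "NA",
      "; ", x$n_excluded, " excluded\n", sep = "")
  invisible(x)
}

#' @rdname tidy.auc_report
#' @export
tidy.auc_report <- function(x, ...) x$values

#' Tidy and summarize AUC reports
#'
#' `tidy()` returns the per-unit AUC table; `glance()` returns a one-row
#' summary (median, mean, sd, n, n_excluded).
#'
#' @param x An `auc_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.auc_report <- function(x, ...) {
  tibble::tibble(
    median = if (nrow(x$values)) median(x$values$auc) else NA_real_,
    mean = if (nrow(x$values)) mean(x$values$auc) else NA_real_,
    sd = if (nrow(x$values) > 1) sd(x$values$auc) else NA_real_,
    n = nrow(x$values),
    n_excluded = x$n_excluded
  )
}

#' Compare two AUC reports
#'
#' The comparison used to benchmark co-expression data sources against
#' each other: the difference in median AUC and a Welch two-sample t-test
#' on the AUC means. Comparing a report with itself gives a median
#' difference of 0 and a p-value of 1.
#'
#' @param a,b `auc_report` objects with at least two values each.
#' @return A one-row tibble with `delta_median` (median of `b` minus
#'   median of `a`), `p_value`, and the per-report medians, means and
#'   sizes.
#' @export
compare_auc_reports <- function(a, b) {
  stopifnot(inherits(a, "auc_report"), inherits(b, "auc_report"))
  if (nrow(a$values) < 2 || nrow(b$values) < 2) {
    stop("both reports need at least 2 AUC values", call. = FALSE)
  }
  av <- a$values$auc
  bv <- b$values$auc
  p <- t.test(bv, av, var.equal = FALSE)$p.value
  tibble::tibble(
    delta_median = median(bv) - median(av),
    p_value = p,
    median_a = median(av), median_b = median(bv),
    mean_a = mean(av), mean_b = mean(bv),
    n_a = length(av), n_b = length(bv)
  )
}

#' Convert a PPI network to a gene-set library
#'
#' Represents an interaction network as one set per protein containing its
#' interaction partners, so that interaction prediction can reuse the
#' gene-set machinery. Set sizes equal node degrees and membership is
#' symmetric: A is in B's set exactly when B is in A's set.
#'
#' @param net A `ppi_network`.
#' @return A `gene_set_library` with one set per node of degree >= 1.
#' @export
ppi_to_gene_sets <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  ends <- c(net$edges$a, net$edges$b)
  partners <- c(net$edges$b, net$edges$a)
  sets <- split(partners, toupper(ends))
  # keep each node's first-seen spelling as the set name
  first_spelling <- ends[!duplicated(toupper(ends))]
  names(sets) <- first_spelling[match(names(sets), toupper(first_spelling))]
  gene_set_library(sets, name = "ppi_partners")
}

#' Predict protein-protein interactions from co-expression
#'
#' Composition of [ppi_to_gene_sets()], [score_gene_sets()] and
#' [membership_auc()]: each protein's candidate interactors are ranked by
#' their mean correlation with the protein's known partners, and the AUC
#' measures how well known interactions are recovered.
#'
#' @param corr A `correlation_matrix`.
#' @param net A `ppi_network`.
#' @param direction Passed to [membership_auc()].
#' @return An `auc_report`.
#' @export
predict_ppi_auc <- function(corr, net, direction = c("gene", "set")) {
  lib <- ppi_to_gene_sets(net)
  gm <- score_gene_sets(corr, lib)
  membership_auc(gm, direction = match.arg(direction))
}

#' Quantile of correlations over interacting pairs
#'
#' The right-tail summary used to compare PPI resources: the q-quantile
#' (linear interpolation) of the expression correlation across all network
#' edges whose endpoints both map to the correlation matrix.
#'
#' @param corr A `correlation_matrix`.
#' @param net A `ppi_network` with at least one mappable edge.
#' @param q Quantile in `[0, 1]` (default 0.75).
#' @return A single numeric value.
#' @export
interaction_correlation_quantile <- function(corr, net, q = 0.75) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(net, "ppi_network"))
  ia <- .match_symbols(net$edges$a, corr$gene_symbols)
  ib <- .match_symbols(net$edges$b, corr$gene_symbols)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) {
    stop("no network edge maps to the correlation matrix", call. = FALSE)
  }
  vals <- corr$values[cbind(ia[ok], ib[ok])]
  unname(quantile(vals, probs = q, type = 7))
}
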