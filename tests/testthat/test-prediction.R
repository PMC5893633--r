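test_that("gene-set scoring excludes self and averages member correlations", {
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.8
  v[1, 3] <- v[3, 1] <- 0.4
  v[2, 3] <- v[3, 2] <- 0.1
  corr <- manual_corr(v, c("A", "B", "C"))

  lib <- gene_set_library(list(only_a = "A", bc = c("B", "C")))
  gm <- score_gene_sets(corr, lib)
  expect_true(is.na(gm$scores["A", "only_a"]))   # empty mean after self-exclusion
  expect_equal(gm$scores["A", "bc"], 0.6)        # (0.8 + 0.4) / 2
  expect_equal(gm$scores["B", "only_a"], 0.8)
  expect_equal(gm$scores["B", "bc"], 0.1)        # self excluded, C remains

  # members absent from the correlation matrix are ignored
  lib2 <- gene_set_library(list(s = c("B", "NOT_THERE")))
  expect_equal(score_gene_sets(corr, lib2)$scores["A", "s"], 0.8)
  expect_error(score_gene_sets(corr, gene_set_library(list(s = "NOPE"))),
               "no gene set member maps")
})

test_that("gene-set scoring equals a per-entry loop oracle", {
  set.seed(11)
  m <- matrix(rnorm(10 * 40), 10, 40,
              dimnames = list(paste0("G", 1:10), NULL))
  corr <- gene_correlation_matrix(m)
  sets <- lapply(1:5, function(i) sample(paste0("G", 1:10), sample(2:6, 1)))
  names(sets) <- paste0("s", 1:5)
  lib <- gene_set_library(sets)
  gm <- score_gene_sets(corr, lib)
  for (i in 1:10) for (j in 1:5) {
    members <- setdiff(sets[[j]], paste0("G", i))
    expected <- if (length(members)) {
      mean(corr$values[paste0("G", i), members])
    } else NA_real_
    expect_equal(gm$scores[i, j], expected, tolerance = 1e-12)
  }

  # invariant to member ordering and duplication
  sets_shuffled <- lapply(sets, function(s) sample(rep(s, 2)))
  gm2 <- score_gene_sets(corr, gene_set_library(sets_shuffled))
  expect_equal(gm$scores, gm2$scores, tolerance = 1e-14)
})

test_that("membership AUC equals the O(n^2) Mann-Whitney oracle", {
  # extremes
  expect_equal(compendex:::.rank_auc(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(compendex:::.rank_auc(c(1, 2, 9, 8), c(TRUE, TRUE, FALSE, FALSE)), 0)

  set.seed(23)
  for (rep in 1:200) {
    n <- sample(c(20, 200), 1)
    score <- rnorm(n)
    if (rep %% 3 == 0) score <- round(score)                 # ties
    if (rep %% 4 == 0) score[sample(n, 3)] <- NA             # missing
    member <- runif(n) < 0.3
    if (!any(member)) member[1] <- TRUE
    if (all(member)) member[1] <- FALSE
    expect_equal(compendex:::.rank_auc(score, member),
                 brute_force_auc(score, member), tolerance = 1e-9)
  }
})

test_that("membership AUC report excludes uninformative genes", {
  v <- diag(4)
  v[upper.tri(v)] <- c(0.9, 0.1, 0.2, 0.3, 0.4, 0.5)
  v <- v + t(v) - diag(diag(v))
  corr <- manual_corr(v, c("A", "B", "C", "D"))
  # gene D belongs to every set -> excluded; A to none -> excluded
  lib <- gene_set_library(list(s1 = c("B", "D"), s2 = c("C", "D")))
  rep <- membership_auc(score_gene_sets(corr, lib))
  expect_setequal(rep$values$unit, c("B", "C"))
  expect_identical(rep$n_excluded, 2L)
  expect_true(all(rep$values$auc >= 0 & rep$values$auc <= 1))
  # summary recomputable from the values
  g <- glance(rep)
  expect_equal(g$median, median(rep$values$auc))
  expect_equal(g$n, nrow(rep$values))
})

test_that("per-set AUC direction ranks genes within each set", {
  set.seed(2)
  m <- matrix(rnorm(12 * 30), 12, 30,
              dimnames = list(paste0("G", 1:12), NULL))
  corr <- gene_correlation_matrix(m)
  lib <- gene_set_library(list(a = paste0("G", 1:4), b = paste0("G", 5:9)))
  rep <- membership_auc(score_gene_sets(corr, lib), direction = "set")
  expect_setequal(rep$values$unit, c("a", "b"))
  expect_identical(rep$direction, "set")
})

test_that("AUC report comparison reproduces the Welch t-test", {
  mk <- function(auc) {
    structure(list(values = tibble::tibble(
      unit = paste0("g", seq_along(auc)), auc = auc,
      n_member = 1L, n_nonmember = 1L
    ), n_excluded = 0L, direction = "gene"), class = "auc_report")
  }
  set.seed(6)
  a <- mk(runif(50, 0.4, 0.9))
  self <- compare_auc_reports(a, a)
  expect_equal(self$delta_median, 0)
  expect_equal(self$p_value, 1)

  b <- mk(a$values$auc + 0.1)
  expect_equal(compare_auc_reports(a, b)$delta_median, 0.1)

  # textbook Welch oracle
  x <- rnorm(40, 0.6, 0.05); y <- rnorm(35, 0.63, 0.08)
  got <- compare_auc_reports(mk(x), mk(y))
  s2x <- var(x) / 40; s2y <- var(y) / 35
  tstat <- (mean(y) - mean(x)) / sqrt(s2x + s2y)
  df <- (s2x + s2y)^2 / (s2x^2 / 39 + s2y^2 / 34)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-8)

  expect_error(compare_auc_reports(mk(c(0.5)), a), "at least 2")
})

test_that("PPI-to-gene-set conversion mirrors node degrees", {
  net <- ppi_network(c("A", "A", "A"), c("B", "C", "D"))
  lib <- ppi_to_gene_sets(net)
  expect_setequal(lib$sets$A, c("B", "C", "D"))
  expect_identical(lib$sets$B, "A")
  expect_identical(lengths(lib$sets)[["A"]], 3L)

  # random graph: set sizes equal the degree sequence; membership symmetric
  set.seed(14)
  n <- 30
  pairs <- t(combn(paste0("P", 1:n), 2))
  keep <- runif(nrow(pairs)) < 0.1
  net2 <- ppi_network(pairs[keep, 1], pairs[keep, 2])
  lib2 <- ppi_to_gene_sets(net2)
  deg <- table(c(net2$edges$a, net2$edges$b))
  expect_equal(lengths(lib2$sets)[names(deg)], as.integer(deg),
               ignore_attr = TRUE)
  for (nm in names(lib2$sets)) {
    for (partner in lib2$sets[[nm]]) {
      expect_true(nm %in% lib2$sets[[partner]])
    }
  }
})

test_that("interaction correlation quantile interpolates linearly", {
  v <- diag(5)
  genes <- LETTERS[1:5]
  # plant correlations 0.1..0.4 on edges A-B, A-C, A-D, A-E
  vals <- c(0.1, 0.2, 0.3, 0.4)
  v[1, 2:5] <- vals; v[2:5, 1] <- vals
  corr <- manual_corr(v, genes)
  net <- ppi_network(rep("A", 4), genes[2:5])
  expect_equal(interaction_correlation_quantile(corr, net, 0.75), 0.325)
  expect_equal(interaction_correlation_quantile(corr, net, 0), 0.1)

  # perfectly correlated endpoints
  v2 <- matrix(1, 3, 3)
  corr2 <- manual_corr(v2, c("X", "Y", "Z"))
  expect_equal(interaction_correlation_quantile(corr2,
    ppi_network(c("X", "Y"), c("Y", "Z"))), 1)

  expect_error(interaction_correlation_quantile(corr,
    ppi_network("Q1", "Q2")), "no network edge maps")
})

test_that("network overlap partitions the edge union", {
  n1 <- ppi_network(c("A", "B", "C"), c("B", "C", "D"))
  same <- network_overlap(list(x = n1, y = n1))
  expect_equal(same$count[same$region == "x&y"], 3)
  expect_equal(sum(same$count), 3)

  n2 <- ppi_network(c("E", "F"), c("F", "G"))
  disj <- network_overlap(list(x = n1, y = n2))
  expect_equal(disj$count[disj$region == "x&y"], 0)
  expect_equal(sum(disj$count), 5)

  # three random networks vs an independent set-algebra oracle
  set.seed(19)
  mk <- function() {
    pairs <- t(combn(paste0("N", 1:12), 2))
    keep <- runif(nrow(pairs)) < 0.3
    ppi_network(pairs[keep, 1], pairs[keep, 2])
  }
  nets <- list(a = mk(), b = mk(), c = mk())
  ov <- network_overlap(nets)
  key <- function(net) paste(pmin(net$edges$a, net$edges$b),
                             pmax(net$edges$a, net$edges$b))
  ka <- key(nets$a); kb <- key(nets$b); kc <- key(nets$c)
  expect_equal(ov$count[ov$region == "a&b&c"],
               length(intersect(intersect(ka, kb), kc)))
  expect_equal(ov$count[ov$region == "a"],
               length(setdiff(setdiff(ka, kb), kc)))
  expect_equal(sum(ov$count), length(union(union(ka, kb), kc)))
  expect_error(network_overlap(list(n1, n1, n2, n2)), "2 or 3")
})

test_that("perfectly correlated interactors dominate the PPI ranking", {
  set.seed(8)
  base <- rnorm(20)
  m <- rbind(base, base * 2 + 3, base - 1, matrix(rnorm(5 * 20), 5, 20))
  rownames(m) <- c("X1", "X2", "X3", paste0("D", 1:5))
  corr <- gene_correlation_matrix(m)

  # a gene whose only partner's set contains just itself has no defined
  # member score after self-exclusion, so it is excluded (and counted)
  # (a perfect matching leaves every gene without a defined member score)
  single <- ppi_network(c("X1", "D1", "D2"), c("X2", "D3", "D4"))
  rep1 <- predict_ppi_auc(corr, single)
  expect_identical(nrow(rep1$values), 0L)
  expect_identical(rep1$n_excluded, 8L)

  # a perfectly correlated triangle plus decoy edges: every member set of
  # X1/X2/X3 scores ~1 while decoy sets score near 0; the only competing
  # non-member (the gene's own partner set) also scores ~1, so the
  # midrank AUC is at least (2*0.5 + 2*4) / (2*5) = 0.9
  tri <- ppi_network(c("X1", "X1", "X2", "D1", "D2"),
                     c("X2", "X3", "X3", "D3", "D4"))
  rep2 <- predict_ppi_auc(corr, tri)
  xs <- rep2$values$auc[rep2$values$unit %in% c("X1", "X2", "X3")]
  expect_length(xs, 3)
  expect_gte(min(xs), 0.9)
})

test_that("shuffled-edge networks predict at chance level", {
  sim <- generate_compendium(synthetic_config(
    n_genes = 100, n_samples = 200, n_gene_modules = 5,
    n_sample_clusters = 2, seed = 3
  ))
  corr <- correlate_compendium(sim$compendium, n_samples = 200, seed = 3)
  # structureless network: edges independent of modules
  shuffled <- sim$labels
  shuffled$gene_module <- compendex:::.with_seed(99,
    sample(sim$labels$gene_module))
  net <- generate_ppi(shuffled, p_within = 0.15, p_between = 0.15, seed = 4)
  rep <- predict_ppi_auc(corr, net)
  se <- sd(rep$values$auc) / sqrt(nrow(rep$values))
  expect_lt(abs(mean(rep$values$auc) - 0.5), 3 * se + 0.02)
})
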