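test_that("HDF5 write/read round-trips a compendium exactly", {
  cpd <- toy_compendium()
  f <- withr::local_tempfile(fileext = ".h5")
  write_compendium(cpd, f)
  back <- read_compendium(f)
  expect_identical(back$expression, cpd$expression)
  expect_identical(back$gene_symbols, cpd$gene_symbols)
  expect_identical(back$sample_ids, cpd$sample_ids)
  expect_identical(as.data.frame(back$metadata), as.data.frame(cpd$metadata))

  # non-integral counts survive bit-exactly through the double path
  cpd$expression[1, 1] <- 10.25
  write_compendium(cpd, f)
  expect_identical(read_compendium(f)$expression, cpd$expression)
})

test_that("constructor rejects invariant violations by name", {
  expr <- matrix(1:6, nrow = 3)
  meta <- data.frame(sample_id = c("S1", "S1"))
  expect_error(
    compendium(expr, c("A", "B", "C"), c("S1", "S1"), meta),
    "duplicate sample_id"
  )
  expect_error(
    compendium(expr, c("A", "B"), c("S1", "S2"),
               data.frame(sample_id = c("S1", "S2"))),
    "gene symbols"
  )
  expect_error(
    compendium(matrix(c(-1, 1, 2, 3, 4, 5), nrow = 3), c("A", "B", "C"),
               c("S1", "S2"), data.frame(sample_id = c("S1", "S2"))),
    "negative"
  )
  expect_error(
    compendium(expr, c("tp53", "TP53", "B"), c("S1", "S2"),
               data.frame(sample_id = c("S1", "S2"))),
    "case-folding"
  )
})

test_that("written file has the declared on-disk shape (independent dump)", {
  sim <- generate_compendium(synthetic_config(
    n_genes = 500, n_samples = 100, n_gene_modules = 10,
    n_sample_clusters = 5, seed = 5
  ))
  f <- withr::local_tempfile(fileext = ".h5")
  write_compendium(sim$compendium, f)
  dump <- system2("h5dump", c("-H", "-d", "/data/expression", f),
                  stdout = TRUE)
  space <- grep("DATASPACE", dump, value = TRUE)
  dims <- as.integer(regmatches(space, gregexpr("[0-9]+", space))[[1]][1:2])
  # rhdf5 stores column-major R matrices with C-order dims reversed,
  # so a 500-gene x 100-sample matrix appears as (100, 500) on disk
  expect_identical(dims, c(100L, 500L))
})

test_that("malformed files produce format errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5createGroup(f, "data")
  rhdf5::h5write(matrix(1:6, 2), f, "data/expression")
  rhdf5::h5closeAll()
  expect_error(read_compendium(f), "meta/genes/gene_symbol")

  # shape mismatch: 3 columns of expression vs 2 sample ids
  f2 <- withr::local_tempfile(fileext = ".h5")
  cpd <- toy_compendium()
  write_compendium(cpd, f2)
  rhdf5::h5delete(f2, "meta/samples/sample_id")
  rhdf5::h5write(c("S1", "S2"), f2, "meta/samples/sample_id")
  rhdf5::h5closeAll()
  expect_error(read_compendium(f2), "sample ids")
})

test_that("metadata search matches an exhaustive per-record oracle", {
  cpd <- toy_compendium()

  hits <- search_metadata(cpd, "liver", fields = "source")
  expect_identical(hits$sample_ids, c("GSM1", "GSM2"))
  expect_identical(hits$series_ids, "GSE1")

  # token conjunction across one field
  hits <- search_metadata(cpd, "Pancreatic Islet")
  expect_true("GSM4" %in% hits$sample_ids)
  expect_false("GSM3" %in% hits$sample_ids)  # has "Pancreatic" only

  expect_length(search_metadata(cpd, "zebrafish")$sample_ids, 0)
  expect_error(search_metadata(cpd, "x", fields = "bogus"), "valid fields")
  expect_error(search_metadata(cpd, "  "), "non-empty")

  # randomized oracle equivalence: brute-force substring scan per record
  set.seed(31)
  words <- c("liver", "brain", "islet", "adult", "fetal", "tumor")
  n <- 40
  meta <- data.frame(
    sample_id = paste0("S", seq_len(n)),
    series_id = paste0("SER", sample(1:6, n, TRUE)),
    title = replicate(n, paste(sample(words, 3), collapse = " ")),
    source = replicate(n, paste(sample(words, 2), collapse = " ")),
    stringsAsFactors = FALSE
  )
  rnd <- compendium(matrix(1, 2, n), c("A", "B"), meta$sample_id, meta)
  for (q in c("liver", "adult brain", "islet tumor fetal")) {
    toks <- strsplit(q, " ")[[1]]
    concat <- tolower(paste(meta$title, meta$source))
    expected <- meta$sample_id[
      vapply(concat, function(s) all(vapply(toks, grepl, TRUE, s, fixed = TRUE)), TRUE)
    ]
    got <- search_metadata(rnd, q, fields = c("title", "source"))$sample_ids
    expect_identical(got, expected)
  }
})

test_that("GMT parsing dedupes members and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "# a comment",
    "setA\tdesc\tG1\tG2\tG2",
    "setC\tdesc\tTp53\tTP53\tACTB"
  ), f)
  lib <- read_gmt(f)
  expect_identical(lib$sets$setA, c("G1", "G2"))
  expect_identical(lib$sets$setC, c("Tp53", "ACTB"))  # case-fold dedupe

  writeLines(c("setA\tdesc\tG1", "setB\tdesc"), f)
  expect_error(read_gmt(f), "line 2")

  expect_error(gene_set_library(list(a = character())), "empty")
})

test_that("GMT round-trip is the identity up to member ordering", {
  sim <- generate_compendium(synthetic_config(
    n_genes = 50, n_samples = 20, n_gene_modules = 5, n_sample_clusters = 2,
    seed = 8
  ))
  lib <- generate_gene_sets(sim$labels, n_true = 6, n_decoy = 4,
                            set_size = 7, seed = 8)
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, f)
  back <- read_gmt(f)
  expect_setequal(names(back$sets), names(lib$sets))
  for (nm in names(lib$sets)) {
    expect_setequal(back$sets[[nm]], lib$sets[[nm]])
  }
})

test_that("edge lists collapse duplicates and drop self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "c\tC", "B\tC"), f)
  net <- read_edge_list(f)
  expect_equal(nrow(net$edges), 2)  # A-B (deduped), B-C; c-C self-loop gone
  keys <- paste(pmin(toupper(net$edges$a), toupper(net$edges$b)),
                pmax(toupper(net$edges$a), toupper(net$edges$b)))
  expect_setequal(keys, c("A B", "B C"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f2)
  back <- read_edge_list(f2)
  keys2 <- paste(pmin(toupper(back$edges$a), toupper(back$edges$b)),
                 pmax(toupper(back$edges$a), toupper(back$edges$b)))
  expect_setequal(keys2, keys)
})

test_that("series export restricts columns to the series, in order", {
  cpd <- toy_compendium()
  tsv <- export_series_matrix(cpd, "GSE3")
  lines <- strsplit(tsv, "\n")[[1]]
  header <- strsplit(lines[1], "\t")[[1]]
  # oracle: metadata scan
  expected <- cpd$metadata$sample_id[cpd$metadata$series_id == "GSE3"]
  expect_identical(header, c("gene_symbol", expected))
  expect_length(lines, 1 + 3)
  row1 <- strsplit(lines[2], "\t")[[1]]
  expect_identical(row1[1], "TP53")
  expect_equal(as.numeric(row1[-1]), cpd$expression[1, 4:5])

  # a series holding every sample reproduces the full matrix
  one <- cpd
  one$metadata$series_id <- "ALL"
  full <- export_series_matrix(one, "ALL")
  vals <- utils::read.delim(text = full, row.names = 1)
  expect_equal(unname(as.matrix(vals)), unname(cpd$expression))

  expect_error(export_series_matrix(cpd, "GSE99"), "available series")
})
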