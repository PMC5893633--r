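#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rnorm runif rbinom rgamma sd var cor t.test
#' @importFrom utils head write.table
NULL

# Metadata fields every compendium carries; sample_id is the join key.
.metadata_fields <- c(
  "sample_id", "series_id", "title", "source", "characteristics",
  "organism", "instrument", "submission_date", "institute"
)

#' Assemble an expression compendium
#'
#' A compendium bundles a gene-by-sample matrix of non-negative expression
#' values (typically raw counts) with its gene symbols and a per-sample
#' metadata table, mirroring how large uniformly processed RNA-seq
#' collections are distributed as single HDF5 files.
#'
#' @param expression Numeric matrix, genes in rows, samples in columns.
#'   All values must be finite and non-negative.
#' @param gene_symbols Character vector of row labels, unique after
#'   upper-casing (human/mouse symbols differ only by case).
#' @param sample_ids Character vector of unique column labels.
#' @param metadata Data frame with one row per sample. Must contain a
#'   `sample_id` column matching `sample_ids`; the remaining fields
#'   (`series_id`, `title`, `source`, `characteristics`, `organism`,
#'   `instrument`, `submission_date`, `institute`) are filled with empty
#'   strings when absent.
#'
#' @return An object of class `compendium`: a list with elements
#'   `expression`, `gene_symbols`, `sample_ids` and `metadata` (a tibble).
#' @examples
#' cpd <- compendium(
#'   expression = matrix(0:5, nrow = 3, ncol = 2),
#'   gene_symbols = c("TP53", "GAPDH", "ACTB"),
#'   sample_ids = c("S1", "S2"),
#'   metadata = data.frame(sample_id = c("S1", "S2"), series_id = "GSX1")
#' )
#' cpd
#' @export
compendium <- function(expression, gene_symbols, sample_ids, metadata) {
  expression <- as.matrix(expression)
  gene_symbols <- as.character(gene_symbols)
  sample_ids <- as.character(sample_ids)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  for (f in .metadata_fields) {
    if (!f %in% names(metadata)) metadata[[f]] <- ""
    metadata[[f]] <- as.character(metadata[[f]])
    metadata[[f]][is.na(metadata[[f]])] <- ""
  }
  metadata <- as_tibble(metadata[, .metadata_fields])
  obj <- structure(
    list(
      expression = expression,
      gene_symbols = gene_symbols,
      sample_ids = sample_ids,
      metadata = metadata
    ),
    class = "compendium"
  )
  validate_compendium(obj)
  obj
}

#' Validate a compendium against its invariants
#'
#' Checks the structural invariants of the container: matching dimensions,
#' uniqueness of gene symbols (after case-folding) and sample ids, a
#' one-to-one correspondence between metadata records and samples, and
#' finite non-negative expression values.
#'
#' @param c A `compendium`.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_compendium <- function(c) {
  stopifnot(inherits(c, "compendium"))
  if (nrow(c$expression) != length(c$gene_symbols)) {
    stop("invariant violated: expression has ", nrow(c$expression),
         " rows but there are ", length(c$gene_symbols), " gene symbols",
         call. = FALSE)
  }
  if (ncol(c$expression) != length(c$sample_ids)) {
    stop("invariant violated: expression has ", ncol(c$expression),
         " columns but there are ", length(c$sample_ids), " sample ids",
         call. = FALSE)
  }
  if (anyDuplicated(toupper(c$gene_symbols))) {
    stop("invariant violated: gene symbols not unique after case-folding",
         call. = FALSE)
  }
  if (anyDuplicated(c$sample_ids)) {
    stop("invariant violated: duplicate sample_id", call. = FALSE)
  }
  if (!setequal(c$metadata$sample_id, c$sample_ids) ||
      nrow(c$metadata) != length(c$sample_ids)) {
    stop("invariant violated: metadata sample_id set does not match sample_ids",
         call. = FALSE)
  }
  if (!all(is.finite(c$expression))) {
    stop("invariant violated: expression contains non-finite values",
         call. = FALSE)
  }
  if (any(c$expression < 0)) {
    stop("invariant violated: expression contains negative values",
         call. = FALSE)
  }
  invisible(c)
}

#' @export
print.compendium <- function(x, ...) {
  cat("<compendium> ", nrow(x$expression), " genes x ",
      ncol(x$expression), " samples, ",
      length(unique(x$metadata$series_id)), " series\n", sep = "")
  invisible(x)
}

#' @export
dim.compendium <- function(x) dim(x$expression)

#' Write a compendium to an HDF5 file
#'
#' Persists the expression matrix, gene symbols and per-sample metadata in
#' a fixed HDF5 layout: `/data/expression` (genes x samples),
#' `/meta/genes/gene_symbol`, one `/meta/samples/<field>` dataset per
#' metadata field, and root attributes `version`, `species` and `created`.
#' Counts that are integral and below 2^31 are stored as 32-bit integers,
#' otherwise as doubles; the chosen mode is recorded in the root attribute
#' `storage_mode` so round-trips are bit-exact.
#'
#' @param c A valid `compendium`.
#' @param path Output file path (overwritten if present).
#' @param species Free-text species label stored as a root attribute.
#' @return `path`, invisibly.
#' @seealso [read_compendium()]
#' @export
write_compendium <- function(c, path, species = "synthetic") {
  validate_compendium(c)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) stop("cannot create HDF5 file at '", path, "'", call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "data")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "meta/genes")
  rhdf5::h5createGroup(path, "meta/samples")

  expr <- c$expression
  dimnames(expr) <- NULL
  integral <- all(expr == round(expr)) && max(expr) < 2^31
  storage_mode <- if (integral) "integer32" else "double"
  if (integral) storage.mode(expr) <- "integer"
  rhdf5::h5write(expr, path, "data/expression")
  rhdf5::h5write(c$gene_symbols, path, "meta/genes/gene_symbol")
  for (f in .metadata_fields) {
    rhdf5::h5write(c$metadata[[f]], path, paste0("meta/samples/", f))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("1.0", fid, "version")
  rhdf5::h5writeAttribute(species, fid, "species")
  rhdf5::h5writeAttribute(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), fid, "created")
  rhdf5::h5writeAttribute(storage_mode, fid, "storage_mode")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a compendium from an HDF5 file
#'
#' Inverse of [write_compendium()]: reads the fixed layout back into a
#' `compendium`. Metadata fields missing from the file are filled with
#' empty strings; the required datasets are `/data/expression`,
#' `/meta/genes/gene_symbol` and `/meta/samples/sample_id`.
#'
#' @param path Path to an HDF5 compendium file.
#' @return A `compendium`.
#' @export
read_compendium <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  present <- paste(sub("^/$", "", contents$group), contents$name, sep = "/")
  required <- c("/data/expression", "/meta/genes/gene_symbol",
                "/meta/samples/sample_id")
  for (ds in required) {
    if (!ds %in% present) {
      stop("malformed compendium file: missing dataset '", ds, "'",
           call. = FALSE)
    }
  }
  expr <- rhdf5::h5read(path, "data/expression")
  storage.mode(expr) <- "double"
  genes <- as.character(rhdf5::h5read(path, "meta/genes/gene_symbol"))
  meta <- list()
  for (f in .metadata_fields) {
    ds <- paste0("/meta/samples/", f)
    meta[[f]] <- if (ds %in% present) {
      as.character(rhdf5::h5read(path, ds))
    } else {
      NULL
    }
  }
  sample_ids <- meta$sample_id
  if (nrow(expr) != length(genes)) {
    stop("malformed compendium file: expression has ", nrow(expr),
         " rows but ", length(genes), " gene symbols", call. = FALSE)
  }
  if (ncol(expr) != length(sample_ids)) {
    stop("malformed compendium file: expression has ", ncol(expr),
         " columns but ", length(sample_ids), " sample ids", call. = FALSE)
  }
  meta <- lapply(meta, function(x) if (is.null(x)) rep("", length(sample_ids)) else x)
  compendium(expr, genes, sample_ids, as.data.frame(meta, stringsAsFactors = FALSE))
}

#' Search sample metadata by keyword
#'
#' Case-insensitive token-AND substring search over selected metadata
#' fields, the query model used for keyword retrieval of samples from a
#' processed-expression resource: a sample matches when every
#' whitespace-separated query token occurs somewhere in the concatenation
#' of its selected fields.
#'
#' @param c A `compendium`.
#' @param query Non-empty query string; tokens are split on whitespace.
#' @param fields Metadata fields to search (default: all text fields).
#' @return A list of class `metadata_hits` with elements `sample_ids`
#'   (character), `series_ids` (deduplicated character, in hit order) and
#'   `hits` (tibble of the matching metadata rows).
#' @examples
#' cpd <- generate_compendium(synthetic_config(n_genes = 20, n_samples = 10,
#'   n_gene_modules = 2, n_sample_clusters = 2, seed = 1))$compendium
#' search_metadata(cpd, "tissue")
#' @export
search_metadata <- function(c, query,
                            fields = setdiff(.metadata_fields, "sample_id")) {
  validate_compendium(c)
  if (!is.character(query) || length(query) != 1 || !nzchar(trimws(query))) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  bad <- setdiff(fields, .metadata_fields)
  if (length(bad)) {
    stop("unknown metadata field(s): ", paste(bad, collapse = ", "),
         "; valid fields are: ", paste(.metadata_fields, collapse = ", "),
         call. = FALSE)
  }
  tokens <- tolower(strsplit(trimws(query), "\\s+")[[1]])
  haystack <- tolower(do.call(paste, c$metadata[, fields, drop = FALSE]))
  keep <- rep(TRUE, length(haystack))
  for (tok in tokens) {
    keep <- keep & grepl(tok, haystack, fixed = TRUE)
  }
  hits <- c$metadata[keep, , drop = FALSE]
  structure(
    list(
      sample_ids = hits$sample_id,
      series_ids = unique(hits$series_id[nzchar(hits$series_id)]),
      hits = hits,
      query = query,
      fields = fields
    ),
    class = "metadata_hits"
  )
}

#' @export
print.metadata_hits <- function(x, ...) {
  cat("<metadata_hits> query \"", x$query, "\": ", length(x$sample_ids),
      " sample(s) in ", length(x$series_ids), " series\n", sep = "")
  if (length(x$sample_ids)) print(head(x$hits, 10))
  invisible(x)
}

#' Export the count matrix of one series
#'
#' Produces a series matrix: a tab-separated table of raw counts for all
#' samples belonging to one series, samples as columns (in compendium
#' order) and genes as rows, the per-study export format attached to
#' expression-series landing pages.
#'
#' @param c A `compendium`.
#' @param series_id A series identifier present in the metadata.
#' @param path Optional output file; when `NULL` the TSV is only returned.
#' @return The TSV text as a single string, invisibly when `path` is given.
#' @export
export_series_matrix <- function(c, series_id, path = NULL) {
  validate_compendium(c)
  available <- unique(c$metadata$series_id)
  if (!series_id %in% available) {
    stop("unknown series '", series_id, "'; available series: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  in_series <- c$metadata$sample_id[c$metadata$series_id == series_id]
  keep <- c$sample_ids %in% in_series
  sub <- c$expression[, keep, drop = FALSE]
  header <- paste(c("gene_symbol", c$sample_ids[keep]), collapse = "\t")
  body <- paste0(
    c$gene_symbols, "\t",
    apply(format(sub, trim = TRUE, scientific = FALSE), 1, paste, collapse = "\t")
  )
  tsv <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", tsv), path)
    return(invisible(tsv))
  }
  tsv
}
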