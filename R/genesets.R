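#' Construct a gene-set library
#'
#' A gene-set library is a named collection of gene-symbol sets (GO terms,
#' pathways, transcription-factor targets, kinase substrates, phenotype
#' gene lists, or interaction-partner sets derived from a PPI network).
#' Members are deduplicated case-insensitively, preserving the first
#' spelling seen; empty sets are rejected.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param name Library name.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, name = "library") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list of gene-symbol vectors", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in library", call. = FALSE)
  }
  sets <- lapply(sets, function(members) {
    members <- as.character(members)
    members <- members[nzchar(members)]
    members[!duplicated(toupper(members))]
  })
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    stop("empty gene set(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, sets = sets), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("<gene_set_library> '", x$name, "': ", length(x$sets),
      " sets, member counts ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_library <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Comment lines
#' starting with `#` and blank lines are skipped. A line with fewer than
#' three columns (i.e. a set without members) is a parse error reported
#' with its line number.
#'
#' @param path Path to a GMT file.
#' @param name Library name; defaults to the file name.
#' @return A `gene_set_library`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3) {
      stop("GMT parse error at line ", i,
           ": expected name, description and at least one member",
           call. = FALSE)
    }
    sets[[parts[[1]]]] <- parts[-(1:2)]
  }
  if (!length(sets)) stop("GMT file contains no gene sets", call. = FALSE)
  gene_set_library(sets, name = name)
}

#' Write a gene-set library to GMT
#'
#' @param lib A `gene_set_library`.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled); defaults to the library name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path, descriptions = lib$name) {
  stopifnot(inherits(lib, "gene_set_library"))
  descriptions <- rep_len(descriptions, length(lib$sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(lib$sets), descriptions, lib$sets)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a protein-protein interaction network
#'
#' An undirected network over gene symbols, stored as a two-column edge
#' table. Self-loops are dropped and duplicate unordered pairs (compared
#' case-insensitively) are collapsed, keeping the first spelling seen.
#'
#' @param from,to Character vectors of gene symbols, one edge per element.
#' @return An object of class `ppi_network` whose `edges` element is a
#'   tibble with columns `a` and `b`.
#' @export
ppi_network <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("from and to must have equal length", call. = FALSE)
  }
  keep <- nzchar(from) & nzchar(to) & toupper(from) != toupper(to)
  from <- from[keep]
  to <- to[keep]
  ua <- toupper(from)
  ub <- toupper(to)
  key <- ifelse(ua < ub, paste(ua, ub, sep = "\r"), paste(ub, ua, sep = "\r"))
  first <- !duplicated(key)
  edges <- tibble::tibble(a = from[first], b = to[first])
  if (!nrow(edges)) stop("network has no edges", call. = FALSE)
  structure(list(edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  nodes <- unique(toupper(c(x$edges$a, x$edges$b)))
  cat("<ppi_network> ", nrow(x$edges), " edges over ", length(nodes),
      " proteins\n", sep = "")
  invisible(x)
}

#' Read a two-column edge list
#'
#' Each non-comment line holds two tab-separated gene symbols. Lines
#' starting with `#` and blank lines are skipped; self-loops and duplicate
#' unordered pairs are collapsed.
#'
#' @param path Path to a tab-separated edge-list file.
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (!length(lines)) stop("edge-list file contains no edges", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop("edge-list parse error: line with fewer than two columns",
         call. = FALSE)
  }
  ppi_network(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
}

#' Write a network as a two-column edge list
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges$a, net$edges$b, sep = "\t"), path)
  invisible(path)
}

# Canonical (case-folded, sorted) edge keys used for set algebra.
.edge_keys <- function(net) {
  ua <- toupper(net$edges$a)
  ub <- toupper(net$edges$b)
  ifelse(ua < ub, paste(ua, ub, sep = "\r"), paste(ub, ua, sep = "\r"))
}

#' Edge overlap between PPI networks
#'
#' Counts unordered edges in every exclusive region of the Venn partition
#' of two or three networks (edges compared case-insensitively). Region
#' counts sum to the size of the edge union.
#'
#' @param nets Named list of two or three `ppi_network` objects.
#' @return A tibble with columns `region` (e.g. `"A"`, `"A&B"`) and
#'   `count`.
#' @export
network_overlap <- function(nets) {
  if (!is.list(nets) || length(nets) < 2 || length(nets) > 3) {
    stop("nets must be a list of 2 or 3 networks", call. = FALSE)
  }
  stopifnot(all(vapply(nets, inherits, TRUE, "ppi_network")))
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- LETTERS[seq_along(nets)]
  }
  keys <- lapply(nets, .edge_keys)
  universe <- unique(unlist(keys))
  membership <- vapply(keys, function(k) universe %in% k, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(nets)))[-2^length(nets), , drop = FALSE]
  region <- apply(combos, 1, function(inc) paste(names(nets)[unlist(inc)], collapse = "&"))
  count <- apply(combos, 1, function(inc) {
    sum(apply(membership, 1, function(m) all(m == unlist(inc))))
  })
  tibble::tibble(region = region, count = as.integer(count))
}
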