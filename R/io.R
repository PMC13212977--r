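#' Read a GMT gene set file
#'
#' Parses the tab-separated GMT dialect used by MSigDB and friends: one set
#' per line as `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file (gzip-transparent).
#' @param normalize_ids Uppercase and whitespace-strip gene identifiers
#'   (exact-string matching is used downstream; no alias resolution).
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `provenance`.
#' @export
read_gmt <- function(path, normalize_ids = TRUE) {
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate pathway ids in GMT: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    g <- g[nzchar(g)]
    if (normalize_ids) g <- toupper(trimws(g))
    unique(g)
  })
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("GMT sets with no genes: ", paste(nm[empty], collapse = ", "))
  gene_set_collection(sets, provenance = basename(path))
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (pathway id -> gene ids).
#' @param provenance Free-text provenance string.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, provenance = "unspecified") {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("pathway ids must be unique and named")
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  structure(list(sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct genes (", x$provenance, ")\n")
  invisible(x)
}

#' Read a delimited numeric matrix (ids x samples)
#'
#' First column holds row identifiers (genes or pathways), header row holds
#' sample identifiers. Field separator is sniffed from the header (tab or
#' comma). Gzip-transparent.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  first <- readLines(con <- gzfile(path), n = 1L); close(con)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate row ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Write a delimited numeric matrix (ids x samples)
#'
#' @param m Matrix with dimnames.
#' @param path Output path; `.gz` suffix compresses.
#' @param sep Field separator.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/protein network edge list
#'
#' Supports the 3-column dialect `gene<sep>gene<sep>score` with scores either
#' already in \[0,1\] or STRING-style 0-1000 combined scores (auto-scaled when
#' values exceed 1), and the 2-column unscored dialect. Self-loops and
#' duplicate undirected edges are removed; the network is treated as
#' undirected for all distance computations.
#'
#' @param path Edge list file (tab/space/comma separated; header auto-skipped
#'   when non-numeric score field is detected).
#' @param min_confidence Drop edges with confidence below this value
#'   (ignored for unscored networks).
#' @return A `gene_network`: list with `nodes`, `edges` (two-column character
#'   matrix) and `confidence` (numeric or NULL).
#' @export
read_network <- function(path, min_confidence = 0) {
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "[[:space:]]+"
  parts <- strsplit(lines, sep)
  ncol1 <- length(parts[[1]])
  if (ncol1 >= 3 && is.na(suppressWarnings(as.numeric(parts[[1]][3]))))
    parts <- parts[-1]  # header row
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  conf <- NULL
  if (length(parts[[1]]) >= 3) {
    conf <- as.numeric(vapply(parts, `[[`, character(1), 3L))
    if (any(is.na(conf))) stop("non-numeric confidence scores in ", path)
    if (max(conf) > 1) conf <- conf / 1000  # STRING 0-1000 combined scores
    keep <- conf >= min_confidence
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  }
  gene_network(cbind(a, b), confidence = conf)
}

#' Construct an undirected gene network
#'
#' @param edges Two-column character matrix of gene pairs.
#' @param confidence Optional numeric vector in \[0,1\], one per edge.
#' @return A `gene_network` object (self-loops and duplicate undirected
#'   edges removed).
#' @export
gene_network <- function(edges, confidence = NULL) {
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2)
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  if (!is.null(confidence)) confidence <- confidence[keep]
  key <- ifelse(edges[, 1] < edges[, 2],
                paste(edges[, 1], edges[, 2], sep = "\r"),
                paste(edges[, 2], edges[, 1], sep = "\r"))
  dup <- duplicated(key)
  edges <- edges[!dup, , drop = FALSE]
  if (!is.null(confidence)) confidence <- confidence[!dup]
  structure(list(nodes = sort(unique(c(edges))), edges = edges,
                 confidence = confidence),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "undirected edges", if (!is.null(x$confidence)) "(scored)" else "", "\n")
  invisible(x)
}

#' Serialize a robust scaler state to JSON
#'
#' @param state A `scaler_state` from [fit_scaler()].
#' @param path Output path.
#' @export
write_scaler <- function(state, path) {
  obj <- list(cap = state$cap,
              pathways = stats::setNames(
                lapply(seq_along(state$pathway_ids), function(i)
                  list(center = state$center[i], scale = state$scale[i])),
                state$pathway_ids))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a robust scaler state from JSON
#'
#' @param path JSON file written by [write_scaler()].
#' @return A `scaler_state`.
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- names(obj$pathways)
  structure(list(pathway_ids = ids,
                 center = unname(vapply(obj$pathways, function(p) p$center,
                                        numeric(1))),
                 scale = unname(vapply(obj$pathways, function(p) p$scale,
                                       numeric(1))),
                 cap = obj$cap,
                 degenerate = character(0)),
            class = "scaler_state")
}
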