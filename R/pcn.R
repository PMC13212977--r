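#' Pairwise shortest-path distances between genes in a network
#'
#' Unweighted hop distances on the undirected network, restricted to the
#' requested genes. Genes absent from the network are dropped with a warning;
#' unreachable pairs are `Inf`.
#'
#' @param net A [gene_network()].
#' @param genes Character vector of gene ids.
#' @return Square numeric matrix of hop counts (dimnames = surviving genes).
#' @export
shortest_distances <- function(net, genes) {
  genes <- unique(genes)
  absent <- setdiff(genes, net$nodes)
  if (length(absent)) {
    warning("genes absent from network dropped: ", paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  if (length(genes) == 0L) stop("no requested gene is present in the network")
  g <- network_igraph(net)
  d <- igraph::distances(g, v = genes, to = genes)
  d[genes, genes, drop = FALSE]
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges[, 1], to = net$edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Network separation score between two pathways
#'
#' Quantifies how far apart two gene sets sit in an interaction network:
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>) / 2`, the mean cross-set shortest-path
#' distance minus the average of the within-set means. Low (especially
#' negative) values indicate overlapping network neighborhoods.
#'
#' Two conventions for the mean distance `<d_XY>` are supported:
#'
#' * `"nearest"` (default, the convention of the network-separation
#'   literature on disease modules): each gene of A u B contributes its
#'   distance to the nearest gene of the opposite set for `<d_AB>`, and each
#'   gene of X its distance to the nearest *other* member of X for `<d_XX>`
#'   (singleton sets contribute 0). Shared genes give cross-set distance 0.
#' * `"all_pairs"`: plain mean over all cross-set pairs, and over all
#'   ordered within-set pairs with distinct members.
#'
#' Gene sets are intersected with the network first. If no finite distance
#' exists for a required term (no connected gene pair within and/or between
#' the sets), `NA` is returned rather than an error.
#'
#' @param net A [gene_network()].
#' @param A,B Character vectors of gene ids.
#' @param convention `"nearest"` or `"all_pairs"`.
#' @param dist Optional precomputed distance matrix over all genes of
#'   interest (from [shortest_distances()]); avoids repeated BFS.
#' @return Scalar separation score, or `NA` when undefined.
#' @export
separation_score <- function(net, A, B, convention = c("nearest", "all_pairs"),
                             dist = NULL) {
  convention <- match.arg(convention)
  A <- unique(A); B <- unique(B)
  if (!is.null(dist)) {
    A <- intersect(A, rownames(dist)); B <- intersect(B, rownames(dist))
  } else {
    A <- intersect(A, net$nodes); B <- intersect(B, net$nodes)
    if (length(A) == 0L || length(B) == 0L) return(NA_real_)
    dist <- shortest_distances(net, union(A, B))
  }
  if (length(A) == 0L || length(B) == 0L) return(NA_real_)
  d_ab <- mean_cross_distance(dist, A, B, convention)
  d_aa <- mean_within_distance(dist, A, convention)
  d_bb <- mean_within_distance(dist, B, convention)
  if (!is.finite(d_ab) || !is.finite(d_aa) || !is.finite(d_bb)) return(NA_real_)
  d_ab - (d_aa + d_bb) / 2
}

mean_cross_distance <- function(dist, A, B, convention) {
  m <- dist[A, B, drop = FALSE]
  if (convention == "all_pairs") return(mean(m))
  # nearest-member: every gene of A u B to the closest gene of the other set
  to_b <- apply(m, 1, min)
  to_a <- apply(dist[B, A, drop = FALSE], 1, min)
  mean(c(to_b, to_a))
}

mean_within_distance <- function(dist, X, convention) {
  if (length(X) == 1L) return(0)
  m <- dist[X, X, drop = FALSE]
  diag(m) <- Inf
  if (convention == "all_pairs") {
    vals <- m[upper.tri(m)]
    return(mean(vals))
  }
  mean(apply(m, 1, min))
}

#' Gene overlap ratio (Jaccard index) between two pathways
#'
#' @param A,B Character vectors of gene ids (not both empty).
#' @return `|A n B| / |A u B|` in \[0, 1\].
#' @export
overlap_ratio <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) stop("overlap ratio undefined for two empty sets")
  length(intersect(A, B)) / u
}

#' All-pairs separation scores for a gene set collection
#'
#' Computes the symmetric table of [separation_score()] values over every
#' pathway pair, sharing one distance computation across pairs. Pathway gene
#' sets are intersected with the network first (genes missing from the
#' network are silently dropped, mirroring the usual near-complete coverage
#' of curated pathways).
#'
#' @param net A [gene_network()].
#' @param sets A [gene_set_collection()] or named list of gene id vectors.
#' @param convention Distance convention, see [separation_score()].
#' @return Symmetric numeric matrix (pathways x pathways) with `NA` for
#'   undefined pairs.
#' @export
separation_table <- function(net, sets, convention = c("nearest", "all_pairs")) {
  convention <- match.arg(convention)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  ids <- names(sets)
  pruned <- lapply(sets, intersect, y = net$nodes)
  all_genes <- unique(unlist(pruned))
  if (length(all_genes) == 0L) stop("no pathway gene is present in the network")
  dist <- shortest_distances(net, all_genes)
  n <- length(ids)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  within <- vapply(pruned, function(X) {
    if (length(X) == 0L) return(NA_real_)
    mean_within_distance(dist, X, convention)
  }, numeric(1))
  for (i in seq_len(n)) {
    for (j in i:n) {
      A <- pruned[[i]]; B <- pruned[[j]]
      if (length(A) == 0L || length(B) == 0L) next
      d_ab <- mean_cross_distance(dist, A, B, convention)
      s <- d_ab - (within[i] + within[j]) / 2
      if (!is.finite(s)) s <- NA_real_
      out[i, j] <- out[j, i] <- s
    }
  }
  out
}

#' All-pairs gene overlap ratios for a gene set collection
#'
#' @param sets A [gene_set_collection()] or named list of gene id vectors.
#' @return Symmetric matrix of Jaccard indices with unit diagonal.
#' @export
overlap_table <- function(sets) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  ids <- names(sets)
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n))
    for (j in i:n)
      out[i, j] <- out[j, i] <- overlap_ratio(sets[[i]], sets[[j]])
  out
}

#' Pairwise Pearson correlations between pathway score profiles
#'
#' @param scores A `pathway_scores` object or pathways x samples matrix with
#'   at least 3 samples.
#' @return Symmetric correlation matrix; rows of zero-variance pathways are
#'   `NA` with a warning.
#' @export
pathway_correlations <- function(scores) {
  m <- score_matrix(scores)
  if (ncol(m) < 3) stop("pathway correlations need >= 3 samples")
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning("zero-variance pathways, correlations set to NA: ",
            paste(rownames(m)[flat], collapse = ", "))
  out <- suppressWarnings(stats::cor(t(m)))
  out[flat, ] <- NA_real_
  out[, flat] <- NA_real_
  out
}

#' Select the K nearest pathways per source (one PCN relation)
#'
#' For each source pathway the K closest targets are selected by ranking the
#' primary scores (ascending for separation scores, descending for
#' correlations; `NA` entries are excluded, never imputed). When fewer than
#' K primary scores are available, the shortfall is filled from the fallback
#' table by highest gene overlap ratio. Edges are directed: A choosing B
#' does not make B choose A. Ties break by lexicographic pathway id.
#'
#' @param primary Square score matrix (pathways x pathways, `NA` allowed).
#' @param K Number of neighbors per source pathway (default 5).
#' @param higher_is_closer `FALSE` for separation scores (lowest = closest),
#'   `TRUE` for correlations.
#' @param fallback Optional square matrix (e.g. [overlap_table()]) ranked
#'   descending to fill shortfalls; `NULL` disables the fallback.
#' @return Data frame with columns `source`, `target`.
#' @export
build_knn_relation <- function(primary, K = 5, higher_is_closer = FALSE,
                               fallback = NULL) {
  stopifnot(is.matrix(primary), nrow(primary) == ncol(primary), K >= 1)
  ids <- rownames(primary)
  if (is.null(ids)) stop("primary score matrix needs pathway dimnames")
  if (length(ids) - 1L < K)
    warning("fewer than K candidate pathways; taking all")
  src <- character(0); tgt <- character(0)
  for (p in ids) {
    cand <- setdiff(ids, p)
    sc <- primary[p, cand]
    avail <- cand[!is.na(sc)]
    sc <- sc[!is.na(sc)]
    o <- order(if (higher_is_closer) -sc else sc, avail)
    chosen <- avail[o][seq_len(min(K, length(avail)))]
    if (length(chosen) < K && !is.null(fallback)) {
      rest <- setdiff(cand, chosen)
      fb <- fallback[p, rest]
      keep <- !is.na(fb)
      rest <- rest[keep]; fb <- fb[keep]
      o2 <- order(-fb, rest)
      extra <- rest[o2][seq_len(min(K - length(chosen), length(rest)))]
      chosen <- c(chosen, extra)
    }
    src <- c(src, rep(p, length(chosen)))
    tgt <- c(tgt, chosen)
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

#' Assemble a multi-relation pathway crosstalk network graph
#'
#' Combines the three directed KNN relations (PPI-derived, GRN-derived,
#' correlation-derived) into one typed-edge graph over a fixed pathway order
#' shared with the pathway score matrix.
#'
#' @param ppi_edges,grn_edges,corr_edges Data frames with `source`, `target`
#'   (from [build_knn_relation()]); an empty relation is allowed with a
#'   warning.
#' @param pathway_order Character vector fixing the node order.
#' @param K Neighbor count used to build the relations (metadata).
#' @return A `pcn_graph`: list with `pathway_ids`, `edges` (data frame
#'   `source`, `target`, `relation`), `K`.
#' @export
assemble_pcn <- function(ppi_edges, grn_edges, corr_edges, pathway_order,
                         K = 5) {
  rels <- list(ppi = ppi_edges, grn = grn_edges, corr = corr_edges)
  parts <- lapply(names(rels), function(r) {
    e <- rels[[r]]
    if (is.null(e) || nrow(e) == 0L) {
      warning("relation '", r, "' has no edges")
      return(data.frame(source = character(0), target = character(0),
                        relation = character(0), stringsAsFactors = FALSE))
    }
    unknown <- setdiff(unique(c(e$source, e$target)), pathway_order)
    if (length(unknown))
      stop("relation '", r, "' references unknown pathways: ",
           paste(unknown, collapse = ", "))
    if (any(e$source == e$target)) stop("self-edges are not allowed")
    data.frame(source = e$source, target = e$target, relation = r,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, parts)
  key <- paste(edges$source, edges$target, edges$relation, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate typed edges removed")
    edges <- edges[!duplicated(key), ]
  }
  structure(list(pathway_ids = pathway_order, edges = edges, K = K),
            class = "pcn_graph")
}

#' @export
print.pcn_graph <- function(x, ...) {
  tab <- table(factor(x$edges$relation, levels = c("ppi", "grn", "corr")))
  cat("pcn_graph:", length(x$pathway_ids), "pathways, K =", x$K, "| edges:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the full PCN graph from a network pair and pathway scores
#'
#' Convenience wrapper running [separation_table()] on the PPI and GRN
#' networks (with [overlap_table()] fallback), [pathway_correlations()] on
#' the score matrix, [build_knn_relation()] per relation, and
#' [assemble_pcn()].
#'
#' @param ppi_net,grn_net [gene_network()] objects.
#' @param sets A [gene_set_collection()].
#' @param scores A `pathway_scores` object (order defines the node order).
#' @param K Neighbors per relation (default 5).
#' @param convention Separation distance convention.
#' @return A `pcn_graph`.
#' @export
build_pcn <- function(ppi_net, grn_net, sets, scores, K = 5,
                      convention = c("nearest", "all_pairs")) {
  convention <- match.arg(convention)
  sm <- score_matrix(scores)
  ids <- rownames(sm)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  sets <- sets[ids]
  ov <- overlap_table(sets)
  sep_ppi <- separation_table(ppi_net, sets, convention)
  sep_grn <- separation_table(grn_net, sets, convention)
  cor_m <- pathway_correlations(sm)
  assemble_pcn(
    ppi_edges = build_knn_relation(sep_ppi, K, FALSE, fallback = ov),
    grn_edges = build_knn_relation(sep_grn, K, FALSE, fallback = ov),
    corr_edges = build_knn_relation(cor_m, K, TRUE, fallback = NULL),
    pathway_order = ids, K = K)
}

#' Degree-preserving edge perturbation of a PCN graph
#'
#' Rewires every relation independently with a degree-preserving double-edge
#' swap (in- and out-degree sequences preserved per relation; no self-edges
#' or duplicate edges introduced). Used as the structural null model: it
#' keeps local connectivity statistics while destroying which pathways are
#' actually linked.
#'
#' @param pcn A `pcn_graph`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return A perturbed `pcn_graph` of identical shape.
#' @export
perturb_pcn <- function(pcn, seed, swaps_per_edge = 10) {
  stopifnot(inherits(pcn, "pcn_graph"))
  set.seed(as.integer(seed))
  parts <- lapply(split(pcn$edges, pcn$edges$relation), function(e) {
    if (nrow(e) < 2) {
      warning("relation with < 2 edges left unperturbed")
      return(e)
    }
    g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                       directed = TRUE,
                                       vertices = data.frame(name = pcn$pathway_ids))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = swaps_per_edge * nrow(e)))
    el <- igraph::as_edgelist(g2)
    data.frame(source = el[, 1], target = el[, 2],
               relation = e$relation[1], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, parts)
  rownames(edges) <- NULL
  structure(list(pathway_ids = pcn$pathway_ids, edges = edges, K = pcn$K),
            class = "pcn_graph")
}

#' Write a PCN graph as a typed edge list plus JSON header
#'
#' @param pcn A `pcn_graph`.
#' @param path Output TSV path; a `.json` sidecar with the pathway order and
#'   construction metadata is written next to it.
#' @export
write_pcn <- function(pcn, path) {
  utils::write.table(pcn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(pathway_order = pcn$pathway_ids, K = pcn$K),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PCN graph written by [write_pcn()]
#'
#' @param path TSV path (expects the `.json` sidecar next to it).
#' @return A `pcn_graph`.
#' @export
read_pcn <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(pathway_ids = meta$pathway_order, edges = edges, K = meta$K),
            class = "pcn_graph")
}
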