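#' Normalize a gene expression matrix
#'
#' Gene-level normalizations applied before pathway scoring. `log2_pc1` is
#' the canonical transform for TPM-like abundances (log2(x + 1)); `arcsinh`
#' is a variance-stabilizing alternative; `z_sample` standardizes each sample
#' (column) to mean 0 / sd 1 (population sd); `z_gene` standardizes each gene
#' (row) across samples; `none` is the identity.
#'
#' @param raw Numeric matrix, genes x samples, with unique dimnames.
#' @param method One of `"log2_pc1"`, `"arcsinh"`, `"z_sample"`, `"z_gene"`,
#'   `"none"`.
#' @return Normalized matrix of the same shape. Zero-variance genes under
#'   `z_gene` are set to all zeros and recorded in the
#'   `"degenerate_genes"` attribute.
#' @export
normalize_expression <- function(raw,
                                 method = c("log2_pc1", "arcsinh", "z_sample",
                                            "z_gene", "none")) {
  method <- match.arg(method)
  check_expression(raw)
  switch(method,
    none = raw,
    log2_pc1 = {
      if (any(raw < 0)) stop("log2_pc1 requires non-negative values")
      log2(raw + 1)
    },
    arcsinh = {
      if (any(raw < 0)) stop("arcsinh normalization requires non-negative values")
      asinh(raw)
    },
    z_sample = {
      mu <- colMeans(raw)
      sdv <- sqrt(colMeans(raw^2) - mu^2)  # population sd per sample
      sdv[sdv == 0] <- 1
      sweep(sweep(raw, 2, mu, "-"), 2, sdv, "/")
    },
    z_gene = {
      mu <- rowMeans(raw)
      sdv <- sqrt(rowMeans(raw^2) - mu^2)
      flat <- sdv == 0
      sdv[flat] <- 1
      out <- sweep(sweep(raw, 1, mu, "-"), 1, sdv, "/")
      out[flat, ] <- 0
      attr(out, "degenerate_genes") <- rownames(raw)[flat]
      out
    })
}

check_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (!all(is.finite(m))) stop("expression values must be finite")
  invisible(m)
}

# registry for pluggable scoring backends (e.g. a user-supplied gsva)
.scoring_backends <- new.env(parent = emptyenv())

#' Register a pathway scoring backend
#'
#' Plugs an external single-sample scoring implementation (for example a
#' wrapper around the GSVA package) behind [score_pathways()]. The backend
#' receives `(expr, sets)` where `sets` is a named list of gene id vectors
#' already intersected with the expression rows, and must return a
#' pathways x samples numeric matrix in the same set order.
#'
#' @param method Method name to register (`"gsva"` or any custom name).
#' @param fun Function `(expr, sets) -> matrix`.
#' @export
register_scoring_backend <- function(method, fun) {
  stopifnot(is.character(method), length(method) == 1L, is.function(fun))
  assign(method, fun, envir = .scoring_backends)
  invisible(method)
}

#' Score pathway activity per sample
#'
#' Summarizes gene-level expression into one activity score per pathway and
#' sample. The built-in scorers are rank-based and operate per sample:
#'
#' * `singscore`: genes are ranked 1..N per sample (ascending, average ranks
#'   for ties); for a set of size n with mean member rank m, the score is
#'   `(m - (n+1)/2) / (N - n) - 0.5`, i.e. the mean rank normalized to
#'   \[0,1\] between its theoretical minimum `(n+1)/2` and maximum
#'   `N-(n-1)/2`, recentered to \[-0.5, 0.5\].
#' * `ssgsea`: single-sample weighted Kolmogorov-Smirnov enrichment
#'   (weight exponent 0.25); scores are normalized by the global score range
#'   across the matrix. `ssgsea_nonorm` skips that final normalization.
#' * `gsva`: population-referenced variation scoring. Each gene is first
#'   mapped to its ECDF value across the sample population (so genes are
#'   scored as over- or under-expressed relative to the cohort, which
#'   removes per-gene location shifts between separately scored datasets);
#'   per sample, genes are ranked with symmetric weights `|rank - N/2|`
#'   and the set score is the signed sum of the extreme deviations of the
#'   weighted KS random walk. Needs >= 2 samples. An external
#'   implementation registered via [register_scoring_backend()] takes
#'   precedence over the built-in.
#'
#' Genes absent from `expr` are dropped from each set; sets left with no
#' genes are dropped with a warning.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param sets A [gene_set_collection()] (or named list of gene id vectors).
#' @param method Scoring method.
#' @return A `pathway_scores` object: list with `scores`
#'   (pathways x samples matrix), `method`, and `dropped_sets`.
#' @export
score_pathways <- function(expr, sets,
                           method = c("singscore", "ssgsea", "ssgsea_nonorm",
                                      "gsva")) {
  method <- match.arg(method)
  check_expression(expr)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- rownames(expr)
  pruned <- lapply(sets, intersect, y = genes)
  dropped <- names(pruned)[lengths(pruned) == 0L]
  if (length(dropped) == length(pruned))
    stop("no gene set shares any gene with the expression matrix")
  if (length(dropped))
    warning("dropping sets with no genes in the expression matrix: ",
            paste(dropped, collapse = ", "))
  pruned <- pruned[lengths(pruned) > 0L]

  scores <- switch(method,
    singscore = score_singscore(expr, pruned),
    ssgsea = score_ssgsea(expr, pruned, normalize = TRUE),
    ssgsea_nonorm = score_ssgsea(expr, pruned, normalize = FALSE),
    gsva = {
      if (ncol(expr) < 2) stop("gsva-style scoring needs >= 2 samples")
      backend <- get0("gsva", envir = .scoring_backends)
      if (is.null(backend)) {
        score_gsva(expr, pruned)
      } else {
        m <- backend(expr, pruned)
        stopifnot(nrow(m) == length(pruned), ncol(m) == ncol(expr))
        dimnames(m) <- list(names(pruned), colnames(expr))
        m
      }
    })
  structure(list(scores = scores, method = method, dropped_sets = dropped),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat("pathway_scores:", nrow(x$scores), "pathways x", ncol(x$scores),
      "samples (", x$method, ")\n")
  invisible(x)
}

score_singscore <- function(expr, sets) {
  n_genes <- nrow(expr)
  ranks <- apply(expr, 2, rank, ties.method = "average")  # genes x samples
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (i in seq_along(sets)) {
    idx <- match(sets[[i]], rownames(expr))
    n <- length(idx)
    if (n >= n_genes) stop("gene set '", names(sets)[i],
                           "' covers every gene; score undefined")
    m <- colMeans(ranks[idx, , drop = FALSE])
    out[i, ] <- (m - (n + 1) / 2) / (n_genes - n) - 0.5
  }
  out
}

# Population-referenced variation scoring: each gene's expression is first
# replaced by its ECDF value across the sample population (which removes
# per-gene location shifts between datasets scored separately), genes are
# then ranked per sample with symmetric rank weights |rank - N/2|^tau, and
# the set score is the signed sum of the maximal positive and negative
# deviations of the weighted KS random walk (the max-deviation-difference
# convention). A built-in reimplementation of the population-referenced
# scoring family; an external implementation can replace it through
# register_scoring_backend("gsva", ...).
score_gsva <- function(expr, sets, tau = 1) {
  n_genes <- nrow(expr)
  n_samp <- ncol(expr)
  ecdf_vals <- t(apply(expr, 1, rank, ties.method = "average")) / n_samp
  out <- matrix(NA_real_, length(sets), n_samp,
                dimnames = list(names(sets), colnames(expr)))
  member <- lapply(sets, function(s) rownames(expr) %in% s)
  mid <- (n_genes + 1) / 2
  for (j in seq_len(n_samp)) {
    r <- rank(ecdf_vals[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w_all <- abs(r - mid)^tau
    for (i in seq_along(sets)) {
      inset <- member[[i]][ord]
      n <- sum(inset)
      w <- w_all[ord] * inset
      dev <- cumsum(w) / sum(w) - cumsum(!inset) / (n_genes - n)
      out[i, j] <- max(dev) + min(dev)
    }
  }
  out
}

# Single-sample weighted-KS enrichment (ssGSEA), weight exponent alpha on the
# expression ranks; the score is the sum of the running-sum differences.
score_ssgsea <- function(expr, sets, normalize = TRUE, alpha = 0.25) {
  n_genes <- nrow(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  member <- lapply(sets, function(s) rownames(expr) %in% s)
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)     # highest expression first
    w_all <- r^alpha
    for (i in seq_along(sets)) {
      inset <- member[[i]][ord]
      n <- sum(inset)
      w <- w_all[ord] * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (n_genes - n)
      out[i, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  out
}

#' Fit a robust per-pathway scaler
#'
#' Median / interquartile-range scaler over training samples (the robust
#' analogue of z-scoring, insensitive to outliers). Quantiles use linear
#' interpolation (type 7). Pathways with zero IQR get scale 1 and are
#' recorded in `degenerate` so downstream pathway order stays aligned with
#' the PCN node order.
#'
#' @param train_scores A `pathway_scores` object or pathways x samples matrix.
#' @param cap Absolute z-score cap applied by [apply_scaler()] (default 10).
#' @return A `scaler_state`.
#' @export
fit_scaler <- function(train_scores, cap = 10) {
  m <- score_matrix(train_scores)
  if (ncol(m) < 2) stop("fitting the scaler needs >= 2 training samples")
  stopifnot(cap > 0)
  center <- apply(m, 1, stats::median)
  q <- t(apply(m, 1, stats::quantile, probs = c(0.25, 0.75), type = 7,
               names = FALSE))
  scale <- q[, 2] - q[, 1]
  degenerate <- rownames(m)[scale == 0]
  scale[scale == 0] <- 1
  structure(list(pathway_ids = rownames(m), center = unname(center),
                 scale = unname(scale), cap = cap, degenerate = degenerate),
            class = "scaler_state")
}

#' @export
print.scaler_state <- function(x, ...) {
  cat("scaler_state:", length(x$pathway_ids), "pathways, cap", x$cap,
      if (length(x$degenerate)) paste0("(", length(x$degenerate),
                                       " zero-IQR pathways)") else "", "\n")
  invisible(x)
}

#' Apply a fitted robust scaler
#'
#' Computes `(x - center) / scale` per pathway and clamps the result to
#' `[-cap, +cap]`.
#'
#' @param scores A `pathway_scores` object or pathways x samples matrix whose
#'   pathway set matches the scaler.
#' @param state A `scaler_state` from [fit_scaler()].
#' @return Scaled matrix (pathways x samples).
#' @export
apply_scaler <- function(scores, state) {
  m <- score_matrix(scores)
  if (!identical(rownames(m), state$pathway_ids)) {
    bad <- c(setdiff(rownames(m), state$pathway_ids),
             setdiff(state$pathway_ids, rownames(m)))
    if (length(bad))
      stop("pathway mismatch between scores and scaler: ",
           paste(unique(bad), collapse = ", "))
    m <- m[state$pathway_ids, , drop = FALSE]  # same set, different order
  }
  z <- sweep(sweep(m, 1, state$center, "-"), 1, state$scale, "/")
  pmin(pmax(z, -state$cap), state$cap)
}

score_matrix <- function(x) {
  m <- if (inherits(x, "pathway_scores")) x$scores else x
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
    stop("empty or invalid pathway score matrix")
  if (is.null(rownames(m))) stop("pathway score matrix needs pathway rownames")
  m
}
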