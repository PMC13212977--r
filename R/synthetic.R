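#' Generate a synthetic pharmacogenomic world
#'
#' Builds a fully self-contained benchmark world with known ground truth,
#' emulating the statistical structure the model assumes: a scale-free gene
#' interaction network, pathways sampled as connected network neighborhoods
#' (so network separation scores are informative), latent pathway activities
#' with factor-induced correlation, gene expression driven by pathway
#' activity plus per-batch gene-level shifts and measurement noise, and
#' drug responses that are (sparse) linear functions of the latent pathway
#' activities.
#'
#' Ground-truth model: for cell c and drug d,
#' `ln_ic50(c, d) = mu_d + sum_p beta[d, p] * activity[p, c] + N(0, noise_sd)`
#' with each drug's beta supported on at most 3 causal pathways.
#'
#' @param n_genes,n_pathways,n_cells,n_drugs World dimensions.
#' @param n_batches Number of expression batches (>= 2 enables batch-effect
#'   studies).
#' @param overlap_frac Approximate fraction of extra shared genes between
#'   neighboring pathways.
#' @param noise_sd Response noise standard deviation (ln(IC50) units).
#' @param pair_frac Fraction of all (cell, drug) pairs with a measured
#'   response.
#' @param baseline_sd Standard deviation of per-gene baseline abundances
#'   (log-expression units); real log-TPM spans several units between
#'   genes, and rank-based scoring relies on that stable structure.
#' @param batch_sd Standard deviation of per-batch gene-level offsets
#'   (log-expression units).
#' @param gene_noise_sd Per-measurement gene noise standard deviation.
#' @param pathway_size_range Min/max genes per pathway.
#' @param nonlinear Pass responses through a monotone tanh warp (robustness
#'   switch; default linear ground truth).
#' @param scrambled_pathways Replace neighborhood pathways with random gene
#'   sets (null case for perturbation studies).
#' @param seed Integer seed; the world regenerates bitwise-identically.
#' @return A `synthetic_world` list; see Details. Expression matrices are
#'   produced on demand by [world_expression()].
#' @export
gen_world <- function(n_genes = 600L, n_pathways = 30L, n_cells = 200L,
                      n_drugs = 50L, n_batches = 2L, overlap_frac = 0.1,
                      noise_sd = 0.3, pair_frac = 0.5, baseline_sd = 3,
                      batch_sd = 1, gene_noise_sd = 0.2,
                      pathway_size_range = c(10L, 20L),
                      nonlinear = FALSE, scrambled_pathways = FALSE,
                      seed = 1L) {
  min_size <- pathway_size_range[1]
  if (n_pathways * min_size > n_genes * (1 + overlap_frac) * 1.5)
    stop("infeasible sizes: too many/large pathways for the gene universe")
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  g <- igraph::sample_pa(n_genes, m = 3, directed = FALSE)
  igraph::V(g)$name <- genes
  el <- igraph::as_edgelist(g)
  network <- gene_network(el)

  sizes <- sample(seq(pathway_size_range[1], pathway_size_range[2]),
                  n_pathways, replace = TRUE)
  sets <- vector("list", n_pathways)
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  if (scrambled_pathways) {
    for (i in seq_len(n_pathways)) sets[[i]] <- sample(genes, sizes[i])
  } else {
    adj_list <- igraph::adjacent_vertices(g, igraph::V(g))
    for (i in seq_len(n_pathways)) {
      seed_gene <- sample.int(n_genes, 1)
      members <- seed_gene
      frontier <- seed_gene
      while (length(members) < sizes[i]) {
        nbrs <- unique(unlist(lapply(frontier, function(v)
          as.integer(adj_list[[v]]))))
        nbrs <- setdiff(nbrs, members)
        if (length(nbrs) == 0L) {
          nbrs <- sample.int(n_genes, 1)
          nbrs <- setdiff(nbrs, members)
          if (length(nbrs) == 0L) break
        }
        take <- head(sample(nbrs), sizes[i] - length(members))
        members <- c(members, take)
        frontier <- take
      }
      # controlled overlap with the previous pathway
      if (i > 1 && overlap_frac > 0) {
        k <- ceiling(overlap_frac * sizes[i])
        members <- unique(c(members,
                            match(head(sets[[i - 1]], k), genes)))
      }
      sets[[i]] <- genes[members]
    }
  }
  pathways <- gene_set_collection(sets, provenance = "synthetic neighborhoods")

  # latent activities: shared factors induce pathway-pathway correlation
  n_fac <- max(2L, n_pathways %/% 6L)
  fac_load <- matrix(stats::rnorm(n_pathways * n_fac, 0, 1), n_pathways)
  fac_load <- fac_load * (abs(fac_load) > 1)       # sparse loadings
  factors <- matrix(stats::rnorm(n_fac * n_cells), n_fac)
  lat <- 0.6 * fac_load %*% factors +
    matrix(stats::rnorm(n_pathways * n_cells), n_pathways)
  lat <- lat / apply(lat, 1, stats::sd)            # unit-variance activities
  cells <- sprintf("CELL%04d", seq_len(n_cells))
  dimnames(lat) <- list(names(sets), cells)

  gene_baseline <- stats::rnorm(n_genes, 0, baseline_sd)
  names(gene_baseline) <- genes
  # cell-intrinsic variation of genes outside every pathway: a property of
  # the cell line, shared across batches (only measurement noise differs)
  background_signal <- matrix(stats::rnorm(n_genes * n_cells), n_genes,
                              dimnames = list(genes, cells))
  batch_offsets <- matrix(stats::rnorm(n_batches * n_genes, 0, batch_sd),
                          n_batches, n_genes,
                          dimnames = list(NULL, genes))

  drug_tbl <- gen_drug_smiles(n_drugs, seed = seed)
  drug_effects <- lapply(seq_len(n_drugs), function(d) {
    k <- sample(1:3, 1)
    causal <- sample(names(sets), k)
    beta <- stats::setNames(sample(c(-1, 1), k, TRUE) *
                              stats::runif(k, 0.5, 1.5), causal)
    list(mu = stats::rnorm(1, 0, 1), beta = beta)
  })
  names(drug_effects) <- drug_tbl$drug_id

  pairs <- expand.grid(cell_id = cells, drug_id = drug_tbl$drug_id,
                       stringsAsFactors = FALSE)
  keep <- sample.int(nrow(pairs), round(pair_frac * nrow(pairs)))
  pairs <- pairs[sort(keep), ]
  signal <- mapply(function(cid, did) {
    ef <- drug_effects[[did]]
    ef$mu + sum(ef$beta * lat[names(ef$beta), cid])
  }, pairs$cell_id, pairs$drug_id)
  if (nonlinear) signal <- 3 * tanh(signal / 2)
  y <- signal + stats::rnorm(nrow(pairs), 0, noise_sd)
  responses <- response_table(data.frame(pairs, ln_ic50 = y,
                                         source = "SYNTHETIC",
                                         stringsAsFactors = FALSE))

  structure(list(gene_network = network, pathways = pathways,
                 latent_activity = lat, gene_baseline = gene_baseline,
                 background_signal = background_signal,
                 batch_offsets = batch_offsets,
                 drugs = drug_tbl, drug_effects = drug_effects,
                 responses = responses, noise_sd = noise_sd,
                 gene_noise_sd = gene_noise_sd, batch_sd = batch_sd,
                 seed = as.integer(seed),
                 params = list(n_genes = n_genes, n_pathways = n_pathways,
                               n_cells = n_cells, n_drugs = n_drugs,
                               n_batches = n_batches,
                               overlap_frac = overlap_frac,
                               pair_frac = pair_frac)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat("synthetic_world:", p$n_genes, "genes,", p$n_pathways, "pathways,",
      p$n_cells, "cells,", p$n_drugs, "drugs,",
      nrow(x$responses$records), "responses (seed", x$seed, ")\n")
  invisible(x)
}

#' Materialize the expression matrix of one batch
#'
#' Expression is log-scale: a stable per-gene baseline abundance plus the
#' mean activity of the pathways the gene belongs to, the batch's per-gene
#' offset and i.i.d. measurement noise; genes outside every pathway carry
#' standard normal variation around their baseline. Deterministic given the
#' world seed and batch number.
#'
#' @param world A `synthetic_world`.
#' @param batch Batch index (1-based).
#' @return Numeric matrix, genes x cells.
#' @export
world_expression <- function(world, batch = 1L) {
  stopifnot(batch >= 1, batch <= nrow(world$batch_offsets))
  p <- world$params
  genes <- colnames(world$batch_offsets)
  cells <- colnames(world$latent_activity)
  membership <- matrix(0, p$n_genes, p$n_pathways,
                       dimnames = list(genes, rownames(world$latent_activity)))
  for (pw in names(world$pathways$sets))
    membership[world$pathways$sets[[pw]], pw] <- 1
  n_mem <- rowSums(membership)
  load <- membership / pmax(n_mem, 1)
  set.seed((world$seed * 131L + batch) %% .Machine$integer.max)
  expr <- load %*% world$latent_activity +
    matrix(stats::rnorm(p$n_genes * p$n_cells, 0, world$gene_noise_sd),
           p$n_genes)
  bg <- n_mem == 0
  expr[bg, ] <- expr[bg, ] + world$background_signal[bg, ]
  expr <- expr + world$gene_baseline + world$batch_offsets[batch, ]
  dimnames(expr) <- list(genes, cells)
  expr
}

#' Sample drug records from the bundled SMILES vocabulary
#'
#' @param n_drugs Number of drugs (at most the vocabulary size; the bundled
#'   vocabulary holds several hundred curated, parseable structures).
#' @param seed Integer seed.
#' @return Data frame with `drug_id`, `smiles`.
#' @export
gen_drug_smiles <- function(n_drugs, seed = 1L) {
  vocab <- readLines(system.file("extdata", "smiles_vocab.txt",
                                 package = "pcndrp", mustWork = TRUE))
  if (n_drugs > length(vocab))
    stop("n_drugs exceeds the bundled SMILES vocabulary (",
         length(vocab), ")")
  set.seed(as.integer(seed))
  data.frame(drug_id = sprintf("DRUG%04d", seq_len(n_drugs)),
             smiles = sample(vocab, n_drugs), stringsAsFactors = FALSE)
}

#' Add Gaussian noise to pathway scores
#'
#' Ablation helper: element-wise additive N(0, sd) noise, deterministic
#' given the seed.
#'
#' @param scores A `pathway_scores` object or numeric matrix.
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Object of the same type with noise added.
#' @export
add_score_noise <- function(scores, sd, seed = 1L) {
  stopifnot(sd >= 0)
  m <- score_matrix(scores)
  if (sd > 0) {
    set.seed(as.integer(seed))
    m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
  }
  if (inherits(scores, "pathway_scores")) {
    scores$scores <- m
    scores
  } else m
}

#' Write a synthetic world to standard-format files
#'
#' Emits the world as the same file dialects real data would arrive in:
#' GMT gene sets, a network edge list, per-batch expression matrices, a
#' drug table CSV and the canonical response TSV.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gmt = file.path(dir, "pathways.gmt"),
             network = file.path(dir, "network.tsv"),
             drugs = file.path(dir, "drugs.csv"),
             responses = file.path(dir, "responses.tsv"))
  gmt_lines <- vapply(names(world$pathways$sets), function(pw)
    paste(c(pw, "synthetic", world$pathways$sets[[pw]]), collapse = "\t"),
    character(1))
  writeLines(gmt_lines, paths["gmt"])
  utils::write.table(world$gene_network$edges, paths["network"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(world$drugs, paths["drugs"], row.names = FALSE,
                   quote = FALSE)
  write_response_tsv(world$responses, paths["responses"])
  for (b in seq_len(nrow(world$batch_offsets))) {
    pb <- file.path(dir, sprintf("expression_batch%d.tsv", b))
    write_matrix(world_expression(world, b), pb)
    paths[paste0("expression_batch", b)] <- pb
  }
  invisible(paths)
}

#' Preset synthetic worlds
#'
#' `tiny` is sized for smoke tests (seconds), `small` for the full
#' end-to-end benchmark (minutes), `paper_shaped` mirrors the reference
#' pathway-collection shape (292 pathways, K = 5 neighbor selection).
#'
#' @param preset `"tiny"`, `"small"`, or `"paper_shaped"`.
#' @param seed Integer seed.
#' @return A `synthetic_world`.
#' @export
world_preset <- function(preset = c("tiny", "small", "paper_shaped"),
                         seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = gen_world(n_genes = 150L, n_pathways = 10L, n_cells = 24L,
                     n_drugs = 12L, n_batches = 2L, pair_frac = 1,
                     pathway_size_range = c(6L, 10L), seed = seed),
    small = gen_world(n_genes = 600L, n_pathways = 30L, n_cells = 200L,
                      n_drugs = 50L, n_batches = 2L, noise_sd = 0.3,
                      pair_frac = 0.5, seed = seed),
    paper_shaped = gen_world(n_genes = 1500L, n_pathways = 292L,
                             n_cells = 120L, n_drugs = 100L, n_batches = 2L,
                             pathway_size_range = c(5L, 12L),
                             pair_frac = 0.5, seed = seed))
}
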