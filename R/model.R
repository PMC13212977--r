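#' Model configuration
#'
#' Architecture and optimizer hyperparameters for the drug response network.
#' The default architecture is a 3-layer relational GCN cell
#' encoder with hidden widths \[8, 8, 8\] over the 3-relation PCN (dense
#' cross-layer concatenation, per-pathway output 24, flattened and projected
#' to a 256-dim cell embedding), a 3-layer, 4-head graph attention drug
#' encoder with hidden widths \[128, 128, 128\] (dense concatenation,
#' per-atom output 384, global max pooling, projected to 256), and a
#' two-layer fully connected head on the concatenated 512-dim pair vector.
#'
#' @param n_pathways Number of PCN nodes (pathways).
#' @param n_relations Number of PCN edge types (default 3).
#' @param cell_hidden,drug_hidden Hidden widths per graph layer.
#' @param gat_heads Attention heads in the drug encoder.
#' @param cell_embed,drug_embed Encoder output embedding sizes.
#' @param head_hidden Width of the first head layer (the second maps to the
#'   scalar prediction).
#' @param atom_feat_dim,bond_feat_dim Drug graph feature widths.
#' @param dropout Dropout rate on the fully connected layers during training.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_pathways, n_relations = 3L,
                         cell_hidden = c(8L, 8L, 8L),
                         drug_hidden = c(128L, 128L, 128L),
                         gat_heads = 4L, cell_embed = 256L, drug_embed = 256L,
                         head_hidden = 128L, atom_feat_dim = 85L,
                         bond_feat_dim = 10L, dropout = 0.2, lr = 1e-3,
                         batch_size = 1024L, seed = 1L) {
  stopifnot(n_pathways >= 1, n_relations >= 1,
            length(cell_hidden) == length(drug_hidden))
  structure(list(n_pathways = as.integer(n_pathways),
                 n_relations = as.integer(n_relations),
                 cell_hidden = as.integer(cell_hidden),
                 drug_hidden = as.integer(drug_hidden),
                 gat_heads = as.integer(gat_heads),
                 cell_embed = as.integer(cell_embed),
                 drug_embed = as.integer(drug_embed),
                 head_hidden = as.integer(head_hidden),
                 atom_feat_dim = as.integer(atom_feat_dim),
                 bond_feat_dim = as.integer(bond_feat_dim),
                 dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' @param config A [model_config()].
#' @return A `model_state`: list with `params` (named list of matrices),
#'   `config`, and `meta` (training metadata).
#' @export
init_model <- function(config) {
  set.seed(config$seed)
  p <- list()
  # cell encoder: relational GCN with dense concatenation
  d_in <- 1L
  for (l in seq_along(config$cell_hidden)) {
    h <- config$cell_hidden[l]
    p[[paste0("cell_Wself_", l)]] <- glorot(d_in, h)
    for (r in seq_len(config$n_relations))
      p[[paste0("cell_W_", l, "_r", r)]] <- glorot(d_in, h)
    p[[paste0("cell_b_", l)]] <- matrix(0, 1, h)
    d_in <- d_in + h
  }
  cell_out <- sum(config$cell_hidden)
  p$cell_fc_W <- glorot(config$n_pathways * cell_out, config$cell_embed)
  p$cell_fc_b <- matrix(0, 1, config$cell_embed)
  # drug encoder: multi-head GAT with dense concatenation
  d_in <- config$atom_feat_dim
  for (l in seq_along(config$drug_hidden)) {
    f <- config$drug_hidden[l]
    for (h in seq_len(config$gat_heads)) {
      p[[paste0("drug_W_", l, "_h", h)]] <- glorot(d_in, f)
      p[[paste0("drug_asrc_", l, "_h", h)]] <- glorot(f, 1L)
      p[[paste0("drug_adst_", l, "_h", h)]] <- glorot(f, 1L)
      p[[paste0("drug_aedge_", l, "_h", h)]] <- glorot(f, 1L)
    }
    p[[paste0("drug_We_", l)]] <- glorot(config$bond_feat_dim, f)
    p[[paste0("drug_proj_W_", l)]] <- glorot(config$gat_heads * f, f)
    p[[paste0("drug_proj_b_", l)]] <- matrix(0, 1, f)
    d_in <- d_in + f
  }
  drug_out <- sum(config$drug_hidden)
  p$drug_fc_W <- glorot(drug_out, config$drug_embed)
  p$drug_fc_b <- matrix(0, 1, config$drug_embed)
  # prediction head: two fully connected layers on the 512-dim pair vector
  p$head_W1 <- glorot(config$cell_embed + config$drug_embed,
                      config$head_hidden)
  p$head_b1 <- matrix(0, 1, config$head_hidden)
  p$head_W2 <- glorot(config$head_hidden, 1L)
  p$head_b2 <- matrix(0, 1, 1)
  structure(list(params = p, config = config,
                 meta = list(epochs_run = 0L, best_val_mse = NA_real_)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("model_state:", length(x$params), "tensors,", n_par, "parameters;",
      "epochs run:", x$meta$epochs_run,
      "| best val MSE:", signif(x$meta$best_val_mse, 4), "\n")
  invisible(x)
}

# relation-wise row-normalized adjacency (message flows source -> target)
pcn_adjacency <- function(pcn) {
  P <- length(pcn$pathway_ids)
  rels <- c("ppi", "grn", "corr")
  lapply(rels, function(r) {
    e <- pcn$edges[pcn$edges$relation == r, , drop = FALSE]
    if (nrow(e) == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(P, P)))
    ti <- match(e$target, pcn$pathway_ids)
    si <- match(e$source, pcn$pathway_ids)
    if (anyNA(ti) || anyNA(si)) stop("PCN edge references unknown pathway")
    indeg <- tabulate(ti, nbins = P)
    Matrix::sparseMatrix(i = ti, j = si, x = 1 / indeg[ti], dims = c(P, P))
  })
}

# wrap parameters as tape leaves; returns a parallel named list of nodes
wrap_params <- function(tape, params) lapply(params, ad_leaf, tape = tape)

# expand per-relation P x P adjacencies to a batch of S stacked samples
# (block-diagonal replication), with transposes precomputed for backward
expand_adjacency <- function(adj, S) {
  lapply(adj, function(A) {
    Ab <- if (S == 1L) A else Matrix::kronecker(Matrix::Diagonal(S), A)
    list(A = Ab, At = Matrix::t(Ab))
  })
}

# cell encoder forward; `scores` is P x S (pathway order == pcn order).
# `adj_b` comes from expand_adjacency(pcn_adjacency(pcn), ncol(scores)).
# Returns list(embed = S x cell_embed node, layer1 = first-layer activation
# node ((S*P) x h1)).
cell_forward_ad <- function(tape, pw, config, adj_b, scores) {
  P <- config$n_pathways
  S <- ncol(scores)
  stopifnot(nrow(scores) == P)
  X <- matrix(as.numeric(scores), S * P, 1)  # sample-major stacking
  acc <- list(X)
  layer1 <- NULL
  for (l in seq_along(config$cell_hidden)) {
    Hcat <- if (length(acc) == 1L) acc[[1]] else ad_concat_cols(tape, acc)
    z <- ad_matmul(tape, Hcat, pw[[paste0("cell_Wself_", l)]])
    for (r in seq_len(config$n_relations)) {
      msg <- if (is_ad(Hcat))
               ad_matmul(tape, ad_spmm(tape, adj_b[[r]], Hcat),
                         pw[[paste0("cell_W_", l, "_r", r)]])
             else ad_matmul(tape, as.matrix(adj_b[[r]]$A %*% Hcat),
                            pw[[paste0("cell_W_", l, "_r", r)]])
      z <- ad_add(tape, z, msg)
    }
    z <- ad_add(tape, z, pw[[paste0("cell_b_", l)]])
    out <- ad_elu(tape, z)
    if (l == 1L) layer1 <- out
    acc <- c(acc, list(out))
  }
  pe <- ad_concat_cols(tape, acc[-1])           # (S*P) x sum(hidden)
  flat <- ad_flatten_nodes(tape, pe, S, P)      # S x (P * sum(hidden))
  emb <- ad_relu(tape, ad_add(tape, ad_matmul(tape, flat, pw$cell_fc_W),
                              pw$cell_fc_b))
  list(embed = emb, layer1 = layer1)
}

# sparse-constant %*% node; `ab` carries the matrix and its transpose
ad_spmm <- function(tape, ab, x) {
  ad_node(tape, as.matrix(ab$A %*% ad_val(x)),
          list(At = ab$At, x = x), function(nd) {
    if (is_ad(nd$parents$x))
      acc_grad(nd$parents$x, as.matrix(nd$parents$At %*% nd$grad))
  })
}

# stack a list of drug_graphs into one disconnected batch graph
stack_drug_graphs <- function(graphs, bond_feat_dim) {
  n_atoms <- vapply(graphs, function(g) nrow(g$atom_features), integer(1))
  offset <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "atom_features"))
  groups <- rep(seq_along(graphs), n_atoms)
  src <- integer(0); tgt <- integer(0)
  B <- matrix(numeric(0), 0, bond_feat_dim)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$bond_index) > 0) {
      src <- c(src, g$bond_index[, 1] + offset[i])
      tgt <- c(tgt, g$bond_index[, 2] + offset[i])
      B <- rbind(B, g$bond_features)
    }
  }
  # self-loops so every atom attends to itself (zero bond features)
  n <- nrow(X)
  src <- c(src, seq_len(n)); tgt <- c(tgt, seq_len(n))
  B <- rbind(B, matrix(0, n, bond_feat_dim))
  list(X = X, src = src, tgt = tgt, B = B, groups = groups,
       n_graphs = length(graphs))
}

# drug encoder forward over a stacked batch graph; the per-head weight
# matmuls and attention ops run blocked over all heads at once
drug_forward_ad <- function(tape, pw, config, batch) {
  acc <- list(batch$X)
  n <- nrow(batch$X)
  H <- config$gat_heads
  for (l in seq_along(config$drug_hidden)) {
    f <- config$drug_hidden[l]
    Hcat <- if (length(acc) == 1L) acc[[1]] else ad_concat_cols(tape, acc)
    Eproj <- ad_matmul(tape, batch$B, pw[[paste0("drug_We_", l)]])
    Wall <- ad_concat_cols(tape, lapply(seq_len(H), function(h)
      pw[[paste0("drug_W_", l, "_h", h)]]))
    Z <- ad_matmul(tape, Hcat, Wall)                      # n x (H*f)
    z_src <- ad_gather(tape, Z, batch$src)
    z_tgt <- ad_gather(tape, Z, batch$tgt)
    a_src <- lapply(seq_len(H), function(h) pw[[paste0("drug_asrc_", l, "_h", h)]])
    a_dst <- lapply(seq_len(H), function(h) pw[[paste0("drug_adst_", l, "_h", h)]])
    a_edge <- ad_concat_cols(tape, lapply(seq_len(H), function(h)
      pw[[paste0("drug_aedge_", l, "_h", h)]]))
    logit <- ad_add(tape,
      ad_add(tape, ad_headwise_dot(tape, z_src, a_src),
             ad_headwise_dot(tape, z_tgt, a_dst)),
      ad_matmul(tape, Eproj, a_edge))                     # E x H
    logit <- ad_leaky_relu(tape, logit, 0.2)
    # numerically stable segment softmax over incoming edges per atom
    lv <- ad_val(logit)
    mx <- apply(lv, 2, function(col) {
      sm <- tapply(col, batch$tgt, max)
      sm[as.character(batch$tgt)]
    })
    ex <- ad_exp(tape, ad_add(tape, logit, -mx))
    denom <- ad_seg_sum(tape, ex, batch$tgt, n)
    alpha <- ad_div(tape, ex, ad_gather(tape, denom, batch$tgt))  # E x H
    msg <- ad_rep_col_scale(tape, z_src, alpha, f)
    cat_h <- ad_seg_sum(tape, msg, batch$tgt, n)          # n x (H*f)
    out <- ad_elu(tape, ad_add(tape,
      ad_matmul(tape, cat_h, pw[[paste0("drug_proj_W_", l)]]),
      pw[[paste0("drug_proj_b_", l)]]))
    acc <- c(acc, list(out))
  }
  pa <- ad_concat_cols(tape, acc[-1])        # atoms x sum(drug_hidden)
  pooled <- ad_group_max(tape, pa, batch$groups, batch$n_graphs)
  ad_relu(tape, ad_add(tape, ad_matmul(tape, pooled, pw$drug_fc_W),
                       pw$drug_fc_b))
}

# prediction head over gathered (cell, drug) embedding pairs
head_forward_ad <- function(tape, pw, config, cell_emb, drug_emb,
                            cell_idx, drug_idx, dropout_masks = NULL) {
  ce <- ad_gather(tape, cell_emb, cell_idx)
  de <- ad_gather(tape, drug_emb, drug_idx)
  x <- ad_concat_cols(tape, list(ce, de))
  h <- ad_relu(tape, ad_add(tape, ad_matmul(tape, x, pw$head_W1), pw$head_b1))
  if (!is.null(dropout_masks)) h <- ad_mul(tape, h, dropout_masks)
  ad_add(tape, ad_matmul(tape, h, pw$head_W2), pw$head_b2)
}

#' Predict ln(IC50) for (cell, drug) pairs
#'
#' Deterministic forward pass in evaluation mode (no dropout).
#'
#' @param state A `model_state`.
#' @param pcn A `pcn_graph` (node order must match `scores` rows).
#' @param scores Scaled pathway score matrix (pathways x cells) whose
#'   columns are named by cell id.
#' @param graphs Named list of `drug_graph`s.
#' @param pairs Data frame with `cell_id`, `drug_id`.
#' @return Numeric vector of predictions, one per pair row.
#' @export
predict_response <- function(state, pcn, scores, graphs, pairs) {
  config <- state$config
  if (!identical(rownames(scores), pcn$pathway_ids))
    stop("node order mismatch between scores and PCN")
  cell_ids <- colnames(scores)
  drug_ids <- names(graphs)
  ci <- match(pairs$cell_id, cell_ids)
  di <- match(pairs$drug_id, drug_ids)
  if (anyNA(ci)) stop("pairs reference cells missing from the score matrix")
  if (anyNA(di)) stop("pairs reference drugs missing from the graph list")
  tape <- ad_tape()
  pw <- lapply(state$params, identity)  # constants: no gradient needed
  adj_b <- expand_adjacency(pcn_adjacency(pcn), ncol(scores))
  cell_emb <- cell_forward_ad(tape, pw, config, adj_b, scores)$embed
  batch <- stack_drug_graphs(graphs, config$bond_feat_dim)
  drug_emb <- drug_forward_ad(tape, pw, config, batch)
  pred <- head_forward_ad(tape, pw, config, cell_emb, drug_emb, ci, di)
  as.numeric(ad_val(pred))
}

#' Grad-CAM pathway attribution for one (cell, drug) prediction
#'
#' Computes pathway importance from the first hidden layer of the cell
#' encoder by backpropagating the prediction to the layer's activation
#' matrix A (pathways x channels). Two gradient-pooling rules are offered:
#'
#' * `"node"` (default): `importance_p = ReLU(sum_k dy/dA[p, k] * A[p, k])`
#'   -- per-pathway gradient weighting. Because the model head consumes a
#'   flattened, position-specific pathway embedding (there is no weight
#'   sharing across pathways), the gradient pattern over pathways carries
#'   the localization, and pooling it away would discard exactly the
#'   information that distinguishes pathways.
#' * `"channel"`: the textbook combination
#'   `alpha_k = mean_p dy/dA[p, k]`, `importance_p =
#'   ReLU(sum_k alpha_k A[p, k])` -- appropriate when channels act as
#'   shared feature detectors, kept for comparison.
#'
#' The `target` argument selects the direction being explained: with
#' `"sensitivity"` (default) the gradients of the negated prediction are
#' used, so importance highlights the pathways driving a *low* predicted
#' ln(IC50) -- the direction of interest when explaining why a pair is
#' predicted sensitive, which is how per-prediction attributions are used
#' in case studies; `"response"` uses the raw prediction gradients
#' (resistance direction). The final ReLU keeps only contributions aligned
#' with the chosen direction.
#'
#' @param state A trained (or initialized) `model_state`.
#' @param pcn A `pcn_graph`.
#' @param cell_scores Scaled score vector for one cell (length = pathways)
#'   or a one-column matrix.
#' @param drug_graph A `drug_graph`.
#' @param top_k Number of top pathways to report (default 5).
#' @param target `"sensitivity"` or `"response"` (see above).
#' @param pooling `"node"` or `"channel"` (see above).
#' @return An `attribution_result`: list with `pathway_ids`, `importance`
#'   (non-negative, named), `top_k` (ordered ids), `prediction`.
#' @export
grad_cam <- function(state, pcn, cell_scores, drug_graph, top_k = 5,
                     target = c("sensitivity", "response"),
                     pooling = c("node", "channel")) {
  target <- match.arg(target)
  pooling <- match.arg(pooling)
  config <- state$config
  scores <- matrix(as.numeric(cell_scores), ncol = 1,
                   dimnames = list(pcn$pathway_ids, "query"))
  tape <- ad_tape()
  pw <- wrap_params(tape, state$params)
  adj_b <- expand_adjacency(pcn_adjacency(pcn), 1L)
  cf <- cell_forward_ad(tape, pw, config, adj_b, scores)
  batch <- stack_drug_graphs(list(drug_graph), config$bond_feat_dim)
  drug_emb <- drug_forward_ad(tape, pw, config, batch)
  pred <- head_forward_ad(tape, pw, config, cf$embed, drug_emb, 1L, 1L)
  ad_backward(tape, pred)
  A <- ad_val(cf$layer1)                 # pathways x channels (single sample)
  dA <- cf$layer1$grad
  if (is.null(dA)) dA <- matrix(0, nrow(A), ncol(A))
  if (target == "sensitivity") dA <- -dA
  imp <- if (pooling == "channel") grad_cam_from_activations(A, dA)
         else pmax(rowSums(dA * A), 0)
  names(imp) <- pcn$pathway_ids
  ord <- order(-imp, pcn$pathway_ids)
  structure(list(pathway_ids = pcn$pathway_ids, importance = imp,
                 top_k = pcn$pathway_ids[ord][seq_len(min(top_k, length(imp)))],
                 prediction = as.numeric(ad_val(pred))),
            class = "attribution_result")
}

# the Grad-CAM combination rule: channel weights are the gradient means
# over pathways, importance is the ReLU of the weighted activations
grad_cam_from_activations <- function(A, dA) {
  alpha <- colMeans(dA)
  pmax(as.numeric(A %*% alpha), 0)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("attribution_result: prediction", signif(x$prediction, 4),
      "| top pathways:", paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameter matrices, configuration and training
#' metadata; predictions round-trip bit-exactly.
#'
#' @param state A `model_state`.
#' @param path Checkpoint path (RDS).
#' @export
save_model <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `model_state`.
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "model_state"))
  state
}
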