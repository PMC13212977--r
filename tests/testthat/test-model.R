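small_cfg <- function(P, seed = 3) {
  model_config(n_pathways = P, cell_hidden = c(4L, 4L, 4L),
               drug_hidden = c(8L, 8L, 8L), gat_heads = 2L,
               cell_embed = 16L, drug_embed = 16L, head_hidden = 8L,
               dropout = 0, seed = seed)
}

test_that("backpropagation matches finite-difference gradients", {
  art <- tiny_artifacts()
  P <- length(art$pcn$pathway_ids)
  mc <- small_cfg(P)
  state <- init_model(mc)
  graphs <- art$graphs[1:4]
  r <- art$world$responses$records
  r <- r[r$drug_id %in% names(graphs), ][1:20, ]
  ns <- asNamespace("pcndrp")
  adj <- ns$expand_adjacency(ns$pcn_adjacency(art$pcn), ncol(art$z))
  bg <- ns$stack_drug_graphs(graphs, mc$bond_feat_dim)
  ci <- match(r$cell_id, colnames(art$z))
  di <- match(r$drug_id, names(graphs))
  y <- matrix(r$ln_ic50, ncol = 1)
  run <- function(params, grads = TRUE) {
    tape <- ns$ad_tape()
    pw <- if (grads) ns$wrap_params(tape, params) else params
    ce <- ns$cell_forward_ad(tape, pw, mc, adj, art$z)$embed
    de <- ns$drug_forward_ad(tape, pw, mc, bg)
    pred <- ns$head_forward_ad(tape, pw, mc, ce, de, ci, di)
    diff <- ns$ad_add(tape, pred, -y)
    loss <- ns$ad_mean(tape, ns$ad_mul(tape, diff, diff))
    if (grads) {
      ns$ad_backward(tape, loss)
      list(loss = as.numeric(loss$val), pw = pw)
    } else as.numeric(loss$val)
  }
  res <- run(state$params)
  set.seed(17)
  eps <- 1e-5
  for (trial in 1:20) {
    nm <- sample(names(state$params), 1)
    i <- sample(length(state$params[[nm]]), 1)
    up <- state$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- state$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    numeric_grad <- (run(up, FALSE) - run(dn, FALSE)) / (2 * eps)
    analytic <- res$pw[[nm]]$grad
    analytic <- if (is.null(analytic)) 0 else analytic[i]
    denom <- max(abs(numeric_grad), abs(analytic), 1e-8)
    expect_lt(abs(numeric_grad - analytic) / denom, 1e-4)
  }
})

test_that("default architecture produces the stated dimensions", {
  # 292-pathway collection: per-pathway 24, flattened 7008, embedding 256
  P <- 292L
  mc <- model_config(n_pathways = P)
  expect_equal(sum(mc$cell_hidden), 24L)
  expect_equal(P * sum(mc$cell_hidden), 7008L)
  state <- init_model(mc)
  expect_equal(dim(state$params$cell_fc_W), c(7008L, 256L))
  expect_equal(dim(state$params$head_W1)[1], 512L)
  # drug per-atom concatenation width under plain concatenation
  expect_equal(sum(mc$drug_hidden), 384L)
  expect_equal(dim(state$params$drug_fc_W), c(384L, 256L))

  ids <- sprintf("PW%03d", seq_len(P))
  edges <- data.frame(source = ids, target = c(ids[-1], ids[1]))
  pcn <- assemble_pcn(edges, edges, edges, ids, K = 1)
  scores <- matrix(rnorm(P * 4), P, 4,
                   dimnames = list(ids, paste0("s", 1:4)))
  ns <- asNamespace("pcndrp")
  tape <- ns$ad_tape()
  adj <- ns$expand_adjacency(ns$pcn_adjacency(pcn), 4L)
  out <- ns$cell_forward_ad(tape, state$params, mc, adj, scores)
  expect_equal(dim(out$embed$val), c(4L, 256L))  # batch of 4 -> 4 embeddings
  g <- featurize_drug("c1ccccc1")
  bg <- ns$stack_drug_graphs(list(g), mc$bond_feat_dim)
  de <- ns$drug_forward_ad(tape, state$params, mc, bg)
  expect_equal(dim(de$val), c(1L, 256L))
})

test_that("an edgeless PCN still yields well-defined cell embeddings", {
  ids <- c("A", "B", "C")
  pcn <- suppressWarnings(assemble_pcn(NULL, NULL, NULL, ids, K = 1))
  mc <- small_cfg(3)
  state <- init_model(mc)
  scores <- matrix(rnorm(6), 3, 2, dimnames = list(ids, c("s1", "s2")))
  graphs <- list(d1 = featurize_drug("CC"))
  pred <- predict_response(state, pcn, scores, graphs,
                           data.frame(cell_id = c("s1", "s2"),
                                      drug_id = "d1"))
  expect_length(pred, 2)
  expect_true(all(is.finite(pred)))
})

test_that("drug embeddings are invariant to atom renumbering", {
  art <- tiny_artifacts()
  mc <- small_cfg(length(art$pcn$pathway_ids))
  state <- init_model(mc)
  ns <- asNamespace("pcndrp")
  # same molecule written from different start atoms
  pairs <- list(c("CCO", "OCC"), c("c1ccccc1O", "Oc1ccccc1"),
                c("NC(=O)c1ccccc1", "c1ccccc1C(N)=O"))
  for (p in pairs) {
    e1 <- ns$drug_forward_ad(ns$ad_tape(), state$params, mc,
                             ns$stack_drug_graphs(list(featurize_drug(p[1])),
                                                  mc$bond_feat_dim))
    e2 <- ns$drug_forward_ad(ns$ad_tape(), state$params, mc,
                             ns$stack_drug_graphs(list(featurize_drug(p[2])),
                                                  mc$bond_feat_dim))
    expect_equal(e1$val, e2$val, tolerance = 1e-10)
  }
})

test_that("a single-atom molecule embeds without bonds", {
  mc <- small_cfg(5)
  state <- init_model(mc)
  ns <- asNamespace("pcndrp")
  g <- featurize_drug("C")
  expect_equal(nrow(g$bond_index), 0)
  e <- ns$drug_forward_ad(ns$ad_tape(), state$params, mc,
                          ns$stack_drug_graphs(list(g), mc$bond_feat_dim))
  expect_equal(dim(e$val), c(1L, 16L))
  expect_true(all(is.finite(e$val)))
})

test_that("prediction is deterministic and validates alignment", {
  art <- tiny_artifacts()
  mc <- small_cfg(length(art$pcn$pathway_ids))
  state <- init_model(mc)
  pairs <- art$world$responses$records[1:10, ]
  p1 <- predict_response(state, art$pcn, art$z, art$graphs, pairs)
  p2 <- predict_response(state, art$pcn, art$z, art$graphs, pairs)
  expect_identical(p1, p2)
  zz <- art$z[rev(seq_len(nrow(art$z))), ]
  expect_error(predict_response(state, art$pcn, zz, art$graphs, pairs),
               "node order")
})

test_that("zeroing the output layer reduces predictions to its bias", {
  art <- tiny_artifacts()
  mc <- small_cfg(length(art$pcn$pathway_ids))
  state <- init_model(mc)
  state$params$head_W2[] <- 0
  state$params$head_b2[] <- 1.25
  pred <- predict_response(state, art$pcn, art$z, art$graphs,
                           art$world$responses$records[1:5, ])
  expect_equal(pred, rep(1.25, 5))
})

test_that("checkpoints round-trip with bit-identical predictions", {
  art <- tiny_artifacts()
  mc <- small_cfg(length(art$pcn$pathway_ids))
  state <- init_model(mc)
  pairs <- art$world$responses$records[1:6, ]
  p <- file.path(tempdir(), "model.rds")
  save_model(state, p)
  state2 <- load_model(p)
  expect_identical(predict_response(state, art$pcn, art$z, art$graphs, pairs),
                   predict_response(state2, art$pcn, art$z, art$graphs, pairs))
})

test_that("cell encoder is equivariant under consistent node relabeling", {
  art <- tiny_artifacts()
  P <- length(art$pcn$pathway_ids)
  mc <- small_cfg(P)
  state <- init_model(mc)
  ns <- asNamespace("pcndrp")
  set.seed(8)
  perm <- sample(P)
  ids2 <- art$pcn$pathway_ids[perm]
  pcn2 <- art$pcn
  pcn2$pathway_ids <- ids2
  z2 <- art$z[ids2, , drop = FALSE]
  # per-pathway first-layer activations permute with the nodes
  t1 <- ns$ad_tape()
  a1 <- ns$cell_forward_ad(t1, state$params, mc,
                           ns$expand_adjacency(ns$pcn_adjacency(art$pcn), 1L),
                           art$z[, 1, drop = FALSE])
  t2 <- ns$ad_tape()
  a2 <- ns$cell_forward_ad(t2, state$params, mc,
                           ns$expand_adjacency(ns$pcn_adjacency(pcn2), 1L),
                           z2[, 1, drop = FALSE])
  expect_equal(a2$layer1$val, a1$layer1$val[perm, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("Grad-CAM returns complete non-negative attributions", {
  art <- tiny_artifacts()
  mc <- small_cfg(length(art$pcn$pathway_ids))
  state <- init_model(mc)
  att <- grad_cam(state, art$pcn, art$z[, 1], art$graphs[[1]])
  expect_length(att$importance, length(art$pcn$pathway_ids))
  expect_true(all(att$importance >= 0))
  expect_length(att$top_k, 5)
})

test_that("Grad-CAM matches the closed form on a linear surrogate head", {
  art <- tiny_artifacts()
  P <- length(art$pcn$pathway_ids)
  mc <- small_cfg(P)
  state <- init_model(mc)
  ns <- asNamespace("pcndrp")
  # forward once to read the first-layer activations A
  tape <- ns$ad_tape()
  cf <- ns$cell_forward_ad(tape, state$params, mc,
                           ns$expand_adjacency(ns$pcn_adjacency(art$pcn), 1L),
                           art$z[, 1, drop = FALSE])
  A <- cf$layer1$val
  # surrogate whose output is a fixed linear functional of A:
  # yhat = sum(W * A); then dyhat/dA = W exactly, alpha = colMeans(W)
  W <- matrix(seq_len(length(A)) / length(A), nrow(A), ncol(A))
  surrogate_importance <- pmax(as.numeric(A %*% colMeans(W)), 0)
  got <- ns$grad_cam_from_activations(A, W)
  expect_equal(got, surrogate_importance)

  # symmetric wiring: two pathways with identical activations and weights
  A2 <- rbind(A, A[1, ])
  W2 <- rbind(W, W[1, ])
  got2 <- ns$grad_cam_from_activations(A2, W2)
  expect_equal(got2[1], got2[nrow(A2)])
})
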