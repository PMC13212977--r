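path_net <- function() gene_network(cbind(c("a", "b", "c"), c("b", "c", "d")))

test_that("shortest distances are BFS hop counts with Inf for unreachable", {
  net <- gene_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                            c("x", "y")))
  d <- shortest_distances(net, c("a", "b", "c", "d", "x"))
  expect_equal(d["a", "d"], 3)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "x"], Inf)
  expect_warning(shortest_distances(net, c("a", "zz")), "absent")
  expect_error(suppressWarnings(shortest_distances(net, "zz")), "no requested gene")
})

test_that("separation score matches hand-computed path-graph cases", {
  net <- path_net()
  expect_equal(separation_score(net, c("a", "b"), c("c", "d")), 0.5)
  expect_equal(separation_score(net, c("a", "b"), c("a", "b")), -1)
  net2 <- gene_network(rbind(c("a", "b"), c("x", "y")))
  expect_true(is.na(separation_score(net2, "a", "x")))
})

test_that("separation score equals the brute-force oracle on random graphs", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(6:50, 1)
    p <- runif(1, 0.05, 0.2)
    adj <- which(upper.tri(matrix(TRUE, n, n)) &
                   matrix(runif(n * n) < p, n, n), arr.ind = TRUE)
    if (nrow(adj) < 2) next
    nodes <- sprintf("n%02d", 1:n)
    edges <- cbind(nodes[adj[, 1]], nodes[adj[, 2]])
    net <- gene_network(edges)
    A <- sample(net$nodes, min(sample(1:6, 1), length(net$nodes)))
    B <- sample(net$nodes, min(sample(1:6, 1), length(net$nodes)))
    for (conv in c("nearest", "all_pairs")) {
      got <- separation_score(net, A, B, convention = conv)
      want <- oracle_separation(edges, A, B, convention = conv)
      expect_identical(is.na(got), is.na(want))
      if (!is.na(want)) expect_equal(got, want)
    }
  }
})

test_that("separation and overlap are symmetric", {
  set.seed(9)
  art <- tiny_artifacts()
  sets <- art$world$pathways$sets
  st <- separation_table(art$world$gene_network, sets)
  expect_equal(st, t(st))
  ov <- overlap_table(sets)
  expect_equal(ov, t(ov))
  expect_equal(unname(diag(ov)), rep(1, length(sets)))
})

test_that("overlap ratio is the Jaccard index", {
  expect_equal(overlap_ratio(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_ratio(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_ratio(c("1", "2", "3"), c("3", "4")), 0.25)
  expect_error(overlap_ratio(character(0), character(0)), "undefined")
})

test_that("pathway correlations follow Pearson with NA for flat pathways", {
  m <- rbind(p1 = c(1, 2, 3), p2 = c(2, 4, 6), p3 = c(3, 2, 1),
             p4 = c(1, 3, 2), p5 = c(5, 5, 5))
  colnames(m) <- c("s1", "s2", "s3")
  expect_warning(cc <- pathway_correlations(m), "zero-variance")
  expect_equal(cc["p1", "p2"], 1)
  expect_equal(cc["p1", "p3"], -1)
  expect_equal(cc["p1", "p4"], 0.5)
  expect_true(all(is.na(cc["p5", ])))
  expect_error(pathway_correlations(m[, 1:2]), ">= 3 samples")
})

test_that("KNN relation ranks primary scores and falls back to overlap", {
  ids <- c("P1", "P2", "P3", "P4")
  prim <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  prim["P1", "P2"] <- 0.1; prim["P1", "P3"] <- 0.5
  e <- build_knn_relation(prim, K = 2)
  expect_equal(e[e$source == "P1", "target"], c("P2", "P3"))

  prim2 <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  prim2["P1", "P2"] <- 0.1
  fb <- matrix(0, 4, 4, dimnames = list(ids, ids))
  fb["P1", "P3"] <- 0.4; fb["P1", "P4"] <- 0.2
  e2 <- build_knn_relation(prim2, K = 2, fallback = fb)
  expect_equal(e2[e2$source == "P1", "target"], c("P2", "P3"))

  corr <- matrix(0, 4, 4, dimnames = list(ids, ids))
  corr["P1", "P2"] <- 1; corr["P1", "P3"] <- 0.3
  e3 <- build_knn_relation(corr, K = 1, higher_is_closer = TRUE)
  expect_equal(e3[e3$source == "P1", "target"], "P2")
})

test_that("KNN selection is directional: A->B without B->A", {
  ids <- c("P1", "P2", "P3")
  prim <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  # P1 is closest to P2, but P2's closest is P3
  prim["P1", "P2"] <- 0.1; prim["P1", "P3"] <- 5
  prim["P2", "P1"] <- 2;   prim["P2", "P3"] <- 0.2
  prim["P3", "P1"] <- 2;   prim["P3", "P2"] <- 0.2
  e <- build_knn_relation(prim, K = 1)
  has <- function(s, t) any(e$source == s & e$target == t)
  expect_true(has("P1", "P2"))
  expect_false(has("P2", "P1"))
})

test_that("PCN assembly types, deduplicates and validates edges", {
  ids <- c("P1", "P2", "P3")
  ab <- data.frame(source = c("P1", "P1"), target = c("P2", "P3"))
  pcn <- suppressWarnings(assemble_pcn(ab, ab, NULL, ids, K = 2))
  expect_s3_class(pcn, "pcn_graph")
  expect_equal(nrow(pcn$edges), 4)
  expect_warning(assemble_pcn(ab, ab, data.frame(), ids), "no edges")
  dup <- rbind(ab, ab[1, ])
  expect_warning(assemble_pcn(dup, ab, ab, ids), "duplicate")
  bad <- data.frame(source = "P1", target = "P9")
  expect_error(suppressWarnings(assemble_pcn(bad, ab, NULL, ids)), "unknown")
})

test_that("every node has out-degree K per relation when candidates suffice", {
  art <- tiny_artifacts()
  pcn <- art$pcn
  for (rel in c("ppi", "grn", "corr")) {
    e <- pcn$edges[pcn$edges$relation == rel, ]
    outdeg <- table(factor(e$source, levels = pcn$pathway_ids))
    expect_true(all(outdeg == pcn$K),
                label = paste("out-degree", pcn$K, "for", rel))
  }
  expect_false(any(pcn$edges$source == pcn$edges$target))
})

test_that("degree-preserving perturbation keeps degrees and is seeded", {
  art <- tiny_artifacts()
  pcn <- art$pcn
  p1 <- perturb_pcn(pcn, seed = 5)
  p2 <- perturb_pcn(pcn, seed = 5)
  expect_identical(p1$edges, p2$edges)
  for (rel in c("ppi", "grn", "corr")) {
    e0 <- pcn$edges[pcn$edges$relation == rel, ]
    e1 <- p1$edges[p1$edges$relation == rel, ]
    lv <- pcn$pathway_ids
    expect_equal(table(factor(e1$source, lv)), table(factor(e0$source, lv)))
    expect_equal(table(factor(e1$target, lv)), table(factor(e0$target, lv)))
    expect_false(any(e1$source == e1$target))
    expect_false(any(duplicated(paste(e1$source, e1$target))))
  }
})

test_that("perturbation rewires a third or more of edges across seeds", {
  set.seed(77)
  # random 50-node, K=5 style directed relation
  ids <- sprintf("P%02d", 1:50)
  src <- rep(ids, each = 5)
  tgt <- unlist(lapply(seq_along(ids), function(i)
    sample(ids[-i], 5)))
  pcn <- assemble_pcn(data.frame(source = src, target = tgt),
                      data.frame(source = src, target = tgt),
                      data.frame(source = src, target = tgt), ids, K = 5)
  for (sd in 1:10) {
    pp <- perturb_pcn(pcn, seed = sd)
    key0 <- paste(pcn$edges$source, pcn$edges$target, pcn$edges$relation)
    key1 <- paste(pp$edges$source, pp$edges$target, pp$edges$relation)
    changed <- 1 - length(intersect(key0, key1)) / length(key0)
    expect_gt(changed, 0.30)
  }
})

test_that("PCN files round-trip through the TSV + JSON header", {
  art <- tiny_artifacts()
  p <- file.path(tempdir(), "pcn.tsv")
  write_pcn(art$pcn, p)
  back <- read_pcn(p)
  expect_equal(back$pathway_ids, art$pcn$pathway_ids)
  expect_equal(back$K, art$pcn$K)
  expect_equal(back$edges, art$pcn$edges)
})

test_that("network readers handle scored and unscored dialects", {
  p <- file.path(tempdir(), "net3.tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "a\tb\t900", "b\tc\t400", "a\ta\t999"), p)
  net <- read_network(p, min_confidence = 0.7)
  expect_equal(nrow(net$edges), 1)  # low-confidence and self-loop dropped
  expect_equal(net$confidence, 0.9)
  p2 <- file.path(tempdir(), "net2.tsv")
  writeLines(c("a\tb", "b\tc", "b\ta"), p2)
  net2 <- read_network(p2)
  expect_equal(nrow(net2$edges), 2)  # duplicate undirected edge dropped
})
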