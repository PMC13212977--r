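toy_table <- function(n_cells = 12, n_drugs = 12, seed = 1) {
  set.seed(seed)
  pairs <- expand.grid(cell_id = sprintf("c%02d", 1:n_cells),
                       drug_id = sprintf("d%02d", 1:n_drugs),
                       stringsAsFactors = FALSE)
  response_table(data.frame(pairs, ln_ic50 = rnorm(nrow(pairs))))
}

test_that("fold counts are 10/10/10/25 and splits are 8:1:1 rotations", {
  tb <- toy_table()
  for (sc in c("unblinded", "cell_blind", "drug_blind"))
    expect_length(make_splits(tb, sc, seed = 1)$folds, 10)
  expect_length(make_splits(tb, "strict_blind", seed = 1)$folds, 25)

  plan <- make_splits(tb, "unblinded", seed = 2)
  n <- nrow(tb$records)
  for (f in plan$folds) {
    expect_equal(sort(c(f$train, f$val, f$test)), seq_len(n))
    expect_equal(length(f$test) / n, 0.1, tolerance = 0.05)
    expect_equal(length(f$val) / n, 0.1, tolerance = 0.05)
  }
  # every pair is tested exactly once across folds
  tested <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_equal(sort(tested), seq_len(n))
})

test_that("unblinded partition keeps every cell in every part", {
  tb <- toy_table(10, 30)
  plan <- make_splits(tb, "unblinded", seed = 5)
  for (f in plan$folds) {
    test_cells <- unique(tb$records$cell_id[f$test])
    expect_setequal(test_cells, unique(tb$records$cell_id))
  }
})

test_that("blind scenarios never leak the blinded entity into training", {
  tb <- toy_table()
  for (sc in c("cell_blind", "drug_blind")) {
    col <- if (sc == "cell_blind") "cell_id" else "drug_id"
    plan <- make_splits(tb, sc, seed = 3)
    tested <- unlist(lapply(plan$folds, `[[`, "test"))
    expect_equal(sort(tested), seq_len(nrow(tb$records)))
    for (f in plan$folds) {
      test_e <- unique(tb$records[[col]][f$test])
      seen_e <- unique(tb$records[[col]][c(f$train, f$val)])
      expect_length(intersect(test_e, seen_e), 0)
    }
  }
})

test_that("strict-blind tests each 5x5 block once with 2x2 test blocks", {
  tb <- toy_table(10, 10)  # complete 10 x 10 grid
  plan <- make_splits(tb, "strict_blind", seed = 7)
  expect_length(plan$folds, 25)
  r <- tb$records
  for (f in plan$folds) {
    expect_length(f$test, 4)  # 2 cells x 2 drugs
    test_cells <- unique(r$cell_id[f$test])
    test_drugs <- unique(r$drug_id[f$test])
    expect_length(test_cells, 2)
    expect_length(test_drugs, 2)
    train_cells <- unique(r$cell_id[f$train])
    train_drugs <- unique(r$drug_id[f$train])
    expect_length(intersect(test_cells, train_cells), 0)
    expect_length(intersect(test_drugs, train_drugs), 0)
    val_cells <- unique(r$cell_id[f$val])
    expect_length(intersect(test_cells, val_cells), 0)
  }
  # grid coverage: the 25 test blocks tile all pairs exactly once
  tested <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_equal(sort(tested), seq_len(nrow(r)))
})

test_that("split plans serialize to JSON and back", {
  tb <- toy_table()
  plan <- make_splits(tb, "cell_blind", seed = 9)
  p <- file.path(tempdir(), "plan.json")
  write_split_plan(plan, p)
  back <- read_split_plan(p)
  expect_equal(back$scenario, plan$scenario)
  expect_equal(back$folds[[3]]$test, plan$folds[[3]]$test)
})

test_that("metrics match hand-computed values and handle degenerate truth", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$pcc, 1)
  expect_equal(m$scc, 1)

  m2 <- compute_metrics(c(0, 0), c(3, 4))
  expect_equal(m2$rmse, sqrt(12.5))

  # monotone but nonlinear: rank correlation saturates, linear does not
  y <- 1:10
  p <- exp(y)
  m3 <- compute_metrics(p, y)
  expect_equal(m3$scc, 1)
  expect_lt(m3$pcc, 1)

  m4 <- compute_metrics(c(1, 2, 3), c(5, 5, 5))
  expect_equal(m4$rmse, sqrt(mean((c(1, 2, 3) - 5)^2)))
  expect_true(is.na(m4$pcc) && is.na(m4$scc))
})

test_that("grouped metrics require at least 3 pairs per entity", {
  pred <- c(1, 2, 3, 4, 5, 6)
  truth <- c(1.1, 2.2, 2.9, 4, 7, 8)
  grp <- c("a", "a", "a", "a", "b", "b")
  m <- compute_metrics(pred, truth, group_by = grp)
  expect_equal(m$per_group$group, "a")
  expect_equal(m$per_group$n, 4L)
})

test_that("model comparison reproduces the enumerated exact p-value", {
  # A = {1,2} vs B = {3,4}: of the C(4,2)=6 equally likely orderings only
  # one puts both A values lowest -> one-sided exact p = 1/6
  res <- compare_models(c(1, 2, 5), c(3, 4, 6), better = "lower")
  p12 <- suppressWarnings(stats::wilcox.test(c(1, 2), c(3, 4),
                                             alternative = "less",
                                             exact = TRUE))$p.value
  expect_equal(p12, 1 / 6, tolerance = 1e-12)

  a <- c(1.1, 2.3, 3.7, 0.4)
  b <- c(2.0, 2.9, 4.1, 5.5)
  lo <- compare_models(a, b, "lower")
  # "A lower than B" is the same one-sided test as "B higher than A"
  expect_equal(compare_models(b, a, "higher")$p_value, lo$p_value)
  # exact-test symmetry: P(U <= u) + P(U >= u) = 1 + P(U = u)
  swapped <- compare_models(b, a, "lower")
  expect_gte(lo$p_value + swapped$p_value, 1)
  expect_lte(lo$p_value + swapped$p_value, 1 + 4 / choose(8, 4))

  same <- compare_models(c(1, 1, 1), c(1, 1, 1), "lower")
  expect_equal(same$p_value, 0.5)
  expect_match(same$flag, "identical")

  eq <- compare_models(c(1, 2, 3, 4), c(1, 2, 3, 4), "lower")
  expect_gte(eq$p_value, 0.5)
})

test_that("responder analysis reports effect size and one-sided p", {
  res <- responder_analysis(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$effect_size, -2)
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)

  flat <- responder_analysis(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(flat$effect_size, 0)

  # predictions inconsistent with labels: positive effect, large p
  inc <- responder_analysis(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(inc$effect_size, 0)
  expect_gt(inc$p_value, 0.5)

  expect_error(responder_analysis(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("entity statistics compute moments, bimodality and coverage", {
  tb <- response_table(data.frame(
    cell_id = c(rep("c1", 3), rep("c2", 2), rep("c3", 40)),
    drug_id = "d",
    ln_ic50 = c(0, 0, 3, 5, 5, rnorm(40))))
  st <- entity_statistics(tb, by = "cell")
  c1 <- st[st$id == "c1", ]
  expect_equal(c1$mean, 1)
  expect_equal(c1$sd, sqrt(3))
  expect_true(is.na(c1$bimodality))  # n < 4
  c2 <- st[st$id == "c2", ]
  expect_equal(c2$sd, 0)
  c3 <- st[st$id == "c3", ]
  expect_false(is.na(c3$bimodality))
  expect_true(c3$density_coverage > 0 && c3$density_coverage <= 1)

  # an entity drawn from the global distribution approaches full coverage
  set.seed(31)
  big <- response_table(data.frame(
    cell_id = rep(c("a", "b"), each = 2000), drug_id = "d",
    ln_ic50 = rnorm(4000)))
  stb <- entity_statistics(big, by = "cell")
  expect_gt(min(stb$density_coverage), 0.9)
})

test_that("training converges, stops early, and is seed-deterministic", {
  art <- tiny_artifacts()
  r <- art$world$responses$records
  mc <- model_config(n_pathways = length(art$pcn$pathway_ids),
                     cell_hidden = c(4L, 4L, 4L), drug_hidden = c(8L, 8L, 8L),
                     gat_heads = 2L, cell_embed = 16L, drug_embed = 16L,
                     head_hidden = 8L, dropout = 0, lr = 3e-3, seed = 21)
  idx <- seq_len(nrow(r))
  train <- idx[idx %% 5 != 0]
  val <- idx[idx %% 5 == 0]
  st <- train_model(init_model(mc), art$pcn, art$z, art$graphs, r, train,
                    val, train_config(max_epochs = 50, patience = 49,
                                      seed = 21))
  baseline <- mean((r$ln_ic50[val] - mean(r$ln_ic50[train]))^2)
  expect_lt(st$meta$best_val_mse, baseline)

  st2 <- train_model(init_model(mc), art$pcn, art$z, art$graphs, r, train,
                     val, train_config(max_epochs = 50, patience = 49,
                                       seed = 21))
  expect_equal(st2$meta$best_epoch, st$meta$best_epoch)
  expect_identical(st2$params, st$params)

  # early stopping halts within patience epochs after the best epoch
  st3 <- train_model(init_model(mc), art$pcn, art$z, art$graphs, r, train,
                     val, train_config(max_epochs = 50, patience = 3,
                                       seed = 21))
  expect_lte(st3$meta$epochs_run, st3$meta$best_epoch + 3)
})
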