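#' Training configuration
#'
#' @param max_epochs Epoch cap (default 300).
#' @param patience Early-stopping patience in epochs without validation MSE
#'   improvement (default 10; must be below `max_epochs`).
#' @param seed Integer seed controlling shuffling, dropout and
#'   initialization.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 300L, patience = 10L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# assemble the numeric training arrays once: scores matrix columns / drug
# graphs restricted to the ids actually used, pair index triples
prepare_training_data <- function(pcn, scores, graphs, records) {
  if (!identical(rownames(scores), pcn$pathway_ids))
    stop("node order mismatch between scores and PCN")
  cell_ids <- colnames(scores)
  drug_ids <- names(graphs)
  ci <- match(records$cell_id, cell_ids)
  di <- match(records$drug_id, drug_ids)
  if (anyNA(ci)) stop("records reference cells missing from the score matrix")
  if (anyNA(di)) stop("records reference drugs missing from the graph list")
  list(scores = scores, graphs = graphs, cell_idx = ci, drug_idx = di,
       y = records$ln_ic50)
}

#' Train the drug response model on one fold
#'
#' Minibatch Adam on mean squared error with early stopping on validation
#' MSE: training halts when the validation MSE has not improved for
#' `patience` epochs or at `max_epochs`, and the returned state carries the
#' best-validation parameters. Deterministic given the seed (single
#' threaded).
#'
#' @param state An initialized `model_state` (see [init_model()]).
#' @param pcn A `pcn_graph`.
#' @param scores Scaled pathway score matrix (pathways x cells), columns
#'   named by cell id.
#' @param graphs Named list of `drug_graph`s.
#' @param records Data frame with `cell_id`, `drug_id`, `ln_ic50`.
#' @param train_idx,val_idx Integer row indices into `records` (non-empty).
#' @param config A [train_config()].
#' @return The trained `model_state`; `meta` holds `epochs_run`,
#'   `best_epoch`, `best_val_mse` and the loss traces.
#' @export
train_model <- function(state, pcn, scores, graphs, records, train_idx,
                        val_idx, config = train_config()) {
  stopifnot(length(train_idx) > 0, length(val_idx) > 0)
  dat <- prepare_training_data(pcn, scores, graphs, records)
  mc <- state$config
  set.seed(config$seed)
  adj_b <- expand_adjacency(pcn_adjacency(pcn), ncol(dat$scores))
  batch_graphs <- stack_drug_graphs(dat$graphs, mc$bond_feat_dim)

  params <- state$params
  m1 <- lapply(params, function(p) p * 0)
  m2 <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  trace_train <- trace_val <- numeric(0)

  val_mse <- function(p) {
    pred <- forward_pairs(p, mc, adj_b, dat$scores, batch_graphs,
                          dat$cell_idx[val_idx], dat$drug_idx[val_idx])
    mean((pred - dat$y[val_idx])^2)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    n_batches <- ceiling(length(ord) / mc$batch_size)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * mc$batch_size + 1L):min(b * mc$batch_size,
                                                     length(ord))]
      tape <- ad_tape()
      pw <- wrap_params(tape, params)
      cell_emb <- cell_forward_ad(tape, pw, mc, adj_b, dat$scores)$embed
      drug_emb <- drug_forward_ad(tape, pw, mc, batch_graphs)
      mask <- NULL
      if (mc$dropout > 0) {
        keep <- matrix(stats::rbinom(length(idx) * mc$head_hidden, 1,
                                     1 - mc$dropout),
                       length(idx), mc$head_hidden) / (1 - mc$dropout)
        mask <- keep
      }
      pred <- head_forward_ad(tape, pw, mc, cell_emb, drug_emb,
                              dat$cell_idx[idx], dat$drug_idx[idx],
                              dropout_masks = mask)
      diff <- ad_add(tape, pred, -matrix(dat$y[idx], ncol = 1))
      loss <- ad_mean(tape, ad_mul(tape, diff, diff))
      lv <- as.numeric(ad_val(loss))
      if (!is.finite(lv))
        stop("NaN/Inf training loss at epoch ", epoch, ", batch ", b,
             "; check input scaling and learning rate")
      epoch_loss <- epoch_loss + lv * length(idx)
      ad_backward(tape, loss)
      t_step <- t_step + 1L
      for (nm in names(params)) {
        g <- pw[[nm]]$grad
        if (is.null(g)) next
        m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g
        m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g^2
        mhat <- m1[[nm]] / (1 - beta1^t_step)
        vhat <- m2[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - mc$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vm <- val_mse(params)
    trace_train <- c(trace_train, epoch_loss / length(ord))
    trace_val <- c(trace_val, vm)
    if (config$verbose)
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %.4f", epoch,
                      epoch_loss / length(ord), vm))
    if (vm < best$val - 1e-9) {
      best <- list(val = vm, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  state$params <- best$params
  state$meta <- list(epochs_run = epoch, best_epoch = best$epoch,
                     best_val_mse = best$val, trace_train = trace_train,
                     trace_val = trace_val)
  state
}

# plain (tape-free gradients unused) forward pass for evaluation
forward_pairs <- function(params, mc, adj_b, scores, batch_graphs, cell_idx,
                          drug_idx) {
  tape <- ad_tape()
  cell_emb <- cell_forward_ad(tape, params, mc, adj_b, scores)$embed
  drug_emb <- drug_forward_ad(tape, params, mc, batch_graphs)
  pred <- head_forward_ad(tape, params, mc, cell_emb, drug_emb, cell_idx,
                          drug_idx)
  as.numeric(ad_val(pred))
}

#' Train and evaluate one fold of a split plan
#'
#' Convenience wrapper: initializes a model, trains on the fold's train/val
#' indices and reports test metrics.
#'
#' @param pcn,scores,graphs,table Pipeline artifacts (`pcn_graph`, scaled
#'   score matrix, named `drug_graph` list, `response_table`).
#' @param plan A `split_plan` from [make_splits()].
#' @param fold Fold number.
#' @param model_cfg A [model_config()]; defaults to one sized to the PCN.
#' @param train_cfg A [train_config()].
#' @return List with `state`, `metrics` (a `metrics_report` on the test
#'   fold), `predictions` (data frame with cell, drug, observed, predicted).
#' @export
run_fold <- function(pcn, scores, graphs, table, plan, fold = 1L,
                     model_cfg = NULL, train_cfg = train_config()) {
  f <- plan$folds[[fold]]
  r <- table$records
  if (is.null(model_cfg))
    model_cfg <- model_config(n_pathways = length(pcn$pathway_ids),
                              seed = train_cfg$seed)
  state <- init_model(model_cfg)
  state <- train_model(state, pcn, scores, graphs, r, f$train, f$val,
                       train_cfg)
  pred <- predict_response(state, pcn, scores, graphs, r[f$test, ])
  metrics <- compute_metrics(pred, r$ln_ic50[f$test])
  list(state = state, metrics = metrics,
       predictions = data.frame(cell_id = r$cell_id[f$test],
                                drug_id = r$drug_id[f$test],
                                y_true = r$ln_ic50[f$test], y_pred = pred,
                                stringsAsFactors = FALSE))
}
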